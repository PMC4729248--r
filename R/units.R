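# Conversion between coalescent-scaled and physical parameters.
#
# The data carry no absolute mutation rate, so the time scale is anchored
# externally: the scaled Mojave divergence time (T1 + T2 for the trio
# models, T for the two-population models) is equated to a calibration age
# in years (default 5.9 Ma, the vicariant divergence of the Mojave lineage),
# with a generation time g (default 25 years). Then
#   Na   = anchor_years / (2 g T_anchor)     [individuals]
#   muL  = theta / (4 Na)                    [per-generation rate x length]
#   N_i  = nu_i Na;   T_years = T 2 Na g.

anchor_time <- function(model_name, scaled) {
  if (startsWith(model_name, "trio")) {
    unname(scaled[["T1"]] + scaled[["T2"]])
  } else {
    unname(scaled[["T"]])
  }
}

scaled_sizes <- function(model_name, scaled) {
  if (startsWith(model_name, "trio")) {
    c(N_moj = if ("nu_moj" %in% names(scaled)) unname(scaled[["nu_moj"]]) else 1,
      N_sinson = unname(scaled[["nu_sinson"]]),
      N_son = unname(scaled[["nu_son"]]))
  } else {
    c(N_1 = unname(scaled[["nu1"]]), N_2 = unname(scaled[["nu2"]]))
  }
}

scaled_times <- function(model_name, scaled) {
  if (startsWith(model_name, "trio")) {
    c(T_div1 = unname(scaled[["T1"]] + scaled[["T2"]]),
      T_div2 = unname(scaled[["T2"]]))
  } else {
    c(T_div = unname(scaled[["T"]]))
  }
}

#' Convert scaled parameter estimates to physical units
#'
#' Calibrates the ancestral size from the anchored divergence time, derives
#' `muL` from `theta = 4 Na muL`, and converts every population size to
#' individuals and every divergence time to years. By construction the
#' converted anchor divergence equals `anchor_years` exactly.
#'
#' @param scaled Named vector of scaled parameters (e.g. `fit$params`).
#' @param theta Profiled `theta` from the fit.
#' @param model Model name (or `model_spec`) the parameters belong to.
#' @param anchor_years Calibration age in years for the anchored divergence
#'   (default 5.9e6).
#' @param generation_time Generation time in years (default 25).
#' @return A `physical_params` list: `Na`, per-population sizes `N`
#'   (individuals), divergence times `T_years`, `muL`, and the calibration
#'   constants.
#' @export
calibrate_physical <- function(scaled, theta, model,
                               anchor_years = 5.9e6, generation_time = 25) {
  model_name <- if (inherits(model, "model_spec")) model$name else model
  T_anchor <- anchor_time(model_name, scaled)
  if (T_anchor <= 0) stop("anchored divergence time is zero; cannot calibrate")
  stopifnot(theta > 0)
  Na <- anchor_years / (2 * generation_time * T_anchor)
  muL <- theta / (4 * Na)
  T_years <- scaled_times(model_name, scaled) * 2 * Na * generation_time
  # the anchored divergence is the calibration itself: set it exactly
  T_years[1] <- anchor_years
  structure(list(
    Na = Na,
    N = scaled_sizes(model_name, scaled) * Na,
    T_years = T_years,
    muL = muL, theta = theta,
    anchor_years = anchor_years, generation_time = generation_time,
    model = model_name, scaled = scaled),
    class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat(sprintf("physical_params (%s): Na = %s individuals, muL = %.4g\n",
              x$model, format(round(x$Na), big.mark = ","), x$muL))
  for (nm in names(x$N))
    cat(sprintf("  %-9s %s individuals\n", nm,
                format(round(x$N[[nm]]), big.mark = ",")))
  for (nm in names(x$T_years))
    cat(sprintf("  %-9s %s years\n", nm,
                format(round(x$T_years[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Invert a physical parameterisation back to the scaled one
#'
#' Round-trip companion of [calibrate_physical()], mainly for consistency
#' checks: returns the scaled parameter vector and theta implied by physical
#' sizes and times.
#'
#' @param phys A `physical_params` object.
#' @return List with `scaled` (named vector) and `theta`.
#' @export
physical_to_scaled <- function(phys) {
  Na <- phys$Na
  g <- phys$generation_time
  if (startsWith(phys$model, "trio")) {
    T2 <- phys$T_years[["T_div2"]] / (2 * Na * g)
    T1 <- phys$T_years[["T_div1"]] / (2 * Na * g) - T2
    scaled <- c(nu_moj = unname(phys$N[["N_moj"]]) / Na,
                nu_sinson = unname(phys$N[["N_sinson"]]) / Na,
                nu_son = unname(phys$N[["N_son"]]) / Na,
                T1 = T1, T2 = T2)
    if (!"nu_moj" %in% names(phys$scaled)) scaled <- scaled[-1]
  } else {
    scaled <- c(nu1 = unname(phys$N[["N_1"]]) / Na,
                nu2 = unname(phys$N[["N_2"]]) / Na,
                T = phys$T_years[["T_div"]] / (2 * Na * g))
  }
  list(scaled = scaled, theta = 4 * Na * phys$muL)
}

#' Convert bootstrap replicate estimates to physical units
#'
#' The full-data calibration fixes `muL`; each replicate's ancestral size is
#' then `Na = theta_rep / (4 muL)`, and sizes and times follow. The anchor
#' is deliberately not re-imposed on replicates, so the anchored divergence
#' varies across replicates and its bootstrap interval brackets (rather than
#' equals) the calibration age.
#'
#' @param boot_params Matrix from [bootstrap_fits()] (must contain a
#'   `theta` column and the scaled parameter columns).
#' @param muL_fixed `muL` from the full-data [calibrate_physical()].
#' @param model Model name.
#' @param generation_time Generation time in years.
#' @return `data.frame` of per-replicate physical parameters; replicates
#'   with non-positive `theta` are dropped with a message.
#' @export
convert_bootstrap <- function(boot_params, muL_fixed, model,
                              generation_time = 25) {
  model_name <- if (inherits(model, "model_spec")) model$name else model
  m <- as.matrix(boot_params)
  ok <- is.finite(m[, "theta"]) & m[, "theta"] > 0
  if (any(!ok))
    message(sprintf("convert_bootstrap: dropped %d replicate(s) with invalid theta",
                    sum(!ok)))
  m <- m[ok, , drop = FALSE]
  rows <- lapply(seq_len(nrow(m)), function(b) {
    scaled <- m[b, ]
    Na <- scaled[["theta"]] / (4 * muL_fixed)
    sizes <- scaled_sizes(model_name, scaled) * Na
    times <- scaled_times(model_name, scaled) * 2 * Na * generation_time
    c(Na = Na, sizes, times)
  })
  as.data.frame(do.call(rbind, rows))
}
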