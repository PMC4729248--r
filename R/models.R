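# Registry of divergence demographic models
#
# All parameters are in coalescent units scaled by the ancestral reference
# size Na: nu = N/Na, T in units of 2*Na generations (epochs measured
# backward from the present), M = 2*Na*m where m is the per-generation
# fraction of the receiving population replaced by migrants. theta = 4*Na*mu*L
# multiplies every expected spectrum and is profiled analytically, never
# optimised, so it is not listed among the free parameters.
#
# The three-population topology is fixed to ((SIN, SON), MOJ): the Mojave
# lineage splits from the common ancestor T1 + T2 ago and the Sinaloan and
# Sonoran lineages split T2 ago. Between the two splits the Sinaloan/Sonoran
# ancestral branch has size nu_sinson, which the contemporary Sinaloan
# population inherits.

model_registry <- local({
  reg <- list()

  # df is the conventional parameter count these model families are named
  # by: the three-population models count the implicit theta (equivalently
  # the ancestral size, which their physical parameter tables report) on
  # top of the scaled shape parameters; the two-population models count
  # shape parameters only. n_free is what the optimiser sees.
  add <- function(name, params, lower, upper, npops, df, describe,
                  demog_fn) {
    reg[[name]] <<- structure(
      list(name = name, params = params,
           lower = stats::setNames(lower, params),
           upper = stats::setNames(upper, params),
           df = df, n_free = length(params), npops = npops,
           description = describe, demography = demog_fn),
      class = "model_spec")
  }

  nu_b <- c(1e-3, 1e3); t_b <- c(0, 10); m_b <- c(0, 20)

  add("equilibrium_1pop", "nu", nu_b[1], nu_b[2], 1L, 1L,
      "Single constant-size population at equilibrium",
      function(p) demography(list(list(duration = Inf,
                                       demes = c(pop1 = p[["nu"]]),
                                       migration = NULL, merges = NULL)),
                             "pop1"))

  split2 <- function(nu1, nu2, T, M12 = 0, M21 = 0, T_c = T) {
    # contact (migration) only during the most recent T_c of the divergence
    T_c <- min(T_c, T)
    mig <- NULL
    if (M12 > 0 || M21 > 0) {
      mig <- matrix(0, 2, 2, dimnames = list(c("pop1", "pop2"),
                                             c("pop1", "pop2")))
      mig["pop1", "pop2"] <- M12   # lineages in pop1 trace back to pop2
      mig["pop2", "pop1"] <- M21
    }
    epochs <- list()
    if (T_c > 0 || T == 0)
      epochs <- c(epochs, list(list(
        duration = T_c, demes = c(pop1 = nu1, pop2 = nu2),
        migration = mig, merges = NULL)))
    if (T - T_c > 0)
      epochs <- c(epochs, list(list(
        duration = T - T_c, demes = c(pop1 = nu1, pop2 = nu2),
        migration = NULL, merges = NULL)))
    n <- length(epochs)
    if (n == 0)
      epochs <- list(list(duration = 0, demes = c(pop1 = nu1, pop2 = nu2),
                          migration = NULL, merges = NULL))
    epochs[[length(epochs)]]$merges <- c(pop1 = "anc", pop2 = "anc")
    epochs <- c(epochs, list(list(duration = Inf, demes = c(anc = 1),
                                  migration = NULL, merges = NULL)))
    demography(epochs, c("pop1", "pop2"))
  }

  add("split2_noMig", c("nu1", "nu2", "T"),
      c(nu_b[1], nu_b[1], t_b[1]), c(nu_b[2], nu_b[2], t_b[2]), 2L, 3L,
      "Two populations diverging in isolation (allopatric speciation)",
      function(p) split2(p[["nu1"]], p[["nu2"]], p[["T"]]))

  add("split2_IM", c("nu1", "nu2", "T", "M12", "M21"),
      c(nu_b[1], nu_b[1], t_b[1], m_b[1], m_b[1]),
      c(nu_b[2], nu_b[2], t_b[2], m_b[2], m_b[2]), 2L, 5L,
      "Two populations diverging with continuous gene flow",
      function(p) split2(p[["nu1"]], p[["nu2"]], p[["T"]],
                         p[["M12"]], p[["M21"]]))

  add("split2_SC", c("nu1", "nu2", "T", "T_c", "M12", "M21"),
      c(nu_b[1], nu_b[1], t_b[1], t_b[1], m_b[1], m_b[1]),
      c(nu_b[2], nu_b[2], t_b[2], t_b[2], m_b[2], m_b[2]), 2L, 6L,
      "Two populations: isolation then secondary contact with gene flow during the final T_c",
      function(p) split2(p[["nu1"]], p[["nu2"]], p[["T"]],
                         p[["M12"]], p[["M21"]], T_c = p[["T_c"]]))

  trio <- function(nu_moj, nu_sinson, nu_son, T1, T2, M_ss = 0) {
    mig <- NULL
    if (M_ss > 0) {
      mig <- matrix(0, 2, 2, dimnames = list(c("SON", "SIN"), c("SON", "SIN")))
      mig["SON", "SIN"] <- M_ss
      mig["SIN", "SON"] <- M_ss
    }
    demography(list(
      list(duration = T2,
           demes = c(MOJ = nu_moj, SON = nu_son, SIN = nu_sinson),
           migration = mig, merges = c(SON = "SS", SIN = "SS")),
      list(duration = T1, demes = c(MOJ = nu_moj, SS = nu_sinson),
           migration = NULL, merges = c(MOJ = "anc", SS = "anc")),
      list(duration = Inf, demes = c(anc = 1), migration = NULL,
           merges = NULL)),
      c("MOJ", "SON", "SIN"))
  }

  add("trio_5param", c("nu_sinson", "nu_son", "T1", "T2"),
      c(nu_b[1], nu_b[1], t_b[1], t_b[1]),
      c(nu_b[2], nu_b[2], t_b[2], t_b[2]), 3L, 5L,
      "((SIN,SON),MOJ) divergence, Mojave size fixed at the ancestral size",
      function(p) trio(1, p[["nu_sinson"]], p[["nu_son"]],
                       p[["T1"]], p[["T2"]]))

  add("trio_6param", c("nu_moj", "nu_sinson", "nu_son", "T1", "T2"),
      c(nu_b[1], nu_b[1], nu_b[1], t_b[1], t_b[1]),
      c(nu_b[2], nu_b[2], nu_b[2], t_b[2], t_b[2]), 3L, 6L,
      "((SIN,SON),MOJ) divergence with a free contemporary Mojave size",
      function(p) trio(p[["nu_moj"]], p[["nu_sinson"]], p[["nu_son"]],
                       p[["T1"]], p[["T2"]]))

  add("trio_6param_IM", c("nu_moj", "nu_sinson", "nu_son", "T1", "T2", "M_ss"),
      c(nu_b[1], nu_b[1], nu_b[1], t_b[1], t_b[1], m_b[1]),
      c(nu_b[2], nu_b[2], nu_b[2], t_b[2], t_b[2], m_b[2]), 3L, 7L,
      "((SIN,SON),MOJ) divergence with symmetric Sinaloan<->Sonoran gene flow",
      function(p) trio(p[["nu_moj"]], p[["nu_sinson"]], p[["nu_son"]],
                       p[["T1"]], p[["T2"]], p[["M_ss"]]))

  reg
})

# Explicit nesting relations: full model -> nested model -> constrained
# parameter values that reduce the full model to the nested one.
nesting_relations <- list(
  "trio_6param|trio_5param"    = c(nu_moj = 1),
  "trio_6param_IM|trio_6param" = c(M_ss = 0),
  "trio_6param_IM|trio_5param" = c(nu_moj = 1, M_ss = 0),
  "split2_IM|split2_noMig"     = c(M12 = 0, M21 = 0),
  "split2_SC|split2_noMig"     = c(M12 = 0, M21 = 0)
)

#' Look up a demographic model by name
#'
#' The registry covers the model families used for two- and three-population
#' divergence inference: `split2_noMig`, `split2_IM`, `split2_SC` (secondary
#' contact with migration only during the most recent `T_c`), `trio_5param`,
#' `trio_6param` (adds a free contemporary Mojave size) and `trio_6param_IM`
#' (adds symmetric Sinaloan/Sonoran migration).
#'
#' @param name Model name.
#' @return A `model_spec`: name, ordered free-parameter names, per-parameter
#'   bounds, degrees of freedom, number of populations and a function mapping
#'   a named parameter vector to a [demography()].
#' @export
get_model <- function(name) {
  if (!name %in% names(model_registry))
    stop("unknown model '", name, "'; registered models: ",
         paste(names(model_registry), collapse = ", "))
  model_registry[[name]]
}

#' List all registered demographic models
#' @return `data.frame` with model name, free parameters and df.
#' @export
list_models <- function() {
  data.frame(
    name = names(model_registry),
    params = vapply(model_registry, function(m)
      paste(m$params, collapse = ","), character(1)),
    df = vapply(model_registry, function(m) m$df, integer(1)),
    npops = vapply(model_registry, function(m) m$npops, integer(1)),
    row.names = NULL)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model '%s' (%d populations, df = %d)\n  %s\n  parameters: %s\n",
              x$name, x$npops, x$df, x$description,
              paste(sprintf("%s [%g, %g]", x$params, x$lower, x$upper),
                    collapse = ", ")))
  invisible(x)
}

#' Indices of the parameters constrained in a nested model
#'
#' For a registered (full, nested) model pair, returns which of the full
#' model's parameters are fixed in the nested model and at what values
#' (e.g. the Mojave size pinned to the ancestral size for the 5- vs
#' 6-parameter comparison, or migration pinned to zero for gene-flow tests).
#'
#' @param full,nested `model_spec` objects (see [get_model()]).
#' @return List with `indices` (positions in `full$params`), `values`
#'   (constraint values) and `df` (number of constrained parameters). The
#'   self-pair returns an empty constraint set.
#' @export
nested_indices <- function(full, nested) {
  if (identical(full$name, nested$name))
    return(list(indices = integer(0), values = numeric(0), df = 0L))
  key <- paste(full$name, nested$name, sep = "|")
  cons <- nesting_relations[[key]]
  if (is.null(cons))
    stop("'", nested$name, "' is not registered as nested within '",
         full$name, "'")
  idx <- match(names(cons), full$params)
  list(indices = idx, values = unname(cons), df = length(idx))
}

# Embed a nested model's parameter vector into the full model's
# parameterisation, filling the constrained entries with their pinned values.
embed_nested_params <- function(full, nested, nested_params) {
  info <- nested_indices(full, nested)
  p <- stats::setNames(numeric(full$df), full$params)
  p[info$indices] <- info$values
  free <- setdiff(full$params, full$params[info$indices])
  if (!all(free %in% nested$params))
    stop("cannot embed: free parameters of the full model missing from the nested model")
  p[free] <- nested_params[free]
  p
}
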