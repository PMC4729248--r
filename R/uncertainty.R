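# Uncertainty quantification under linkage: conventional bootstrap over
# contigs and the Godambe-information-corrected likelihood-ratio test.
# Sites within a contig share a genealogy, so the composite likelihood
# overstates the information in the data; both procedures here resample or
# correct at the contig level to account for that.

#' Conventional bootstrap over contigs
#'
#' Draws contigs with replacement (to the original contig count), rebuilds
#' the joint SFS from the concatenated sites of each draw, and returns the
#' replicate spectra. Resampling whole contigs propagates within-contig
#' linkage into the replicate-to-replicate variation.
#'
#' @param variants A filtered, complete-genotype [variant_table()].
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed; the replicate set is reproducible bit-for-bit.
#' @param pop_order Population order for the spectra (default: order of
#'   first appearance in the population map).
#' @param fold Fold the replicate spectra? (default `TRUE`).
#' @return A `bootstrap_set`: list of `joint_sfs` replicates, the contig
#'   multiset drawn for each, and the seed.
#' @export
bootstrap_by_contig <- function(variants, B = 100, seed = 1,
                                pop_order = NULL, fold = TRUE) {
  stopifnot(inherits(variants, "variant_table"), B >= 1)
  if (is.null(pop_order)) pop_order <- unique(unname(variants$popmap))
  contigs <- unique(variants$sites$contig)
  if (length(contigs) == 1L)
    warning("bootstrap over a single contig is degenerate")
  # per-contig spectra: tally each site's cell once, then replicates are
  # plain row sums
  pops <- variants$popmap
  dims <- integer(length(pop_order))
  idx <- vector("list", length(pop_order))
  for (j in seq_along(pop_order)) {
    cols <- which(pops == pop_order[j])
    dims[j] <- 2L * length(cols) + 1L
    idx[[j]] <- rowSums(variants$geno[, cols, drop = FALSE])
  }
  mult <- c(1, cumprod(dims[-length(dims)]))
  lin <- as.vector(do.call(cbind, idx) %*% mult) + 1L
  ctg <- factor(variants$sites$contig, levels = contigs)
  percell <- matrix(0, length(contigs), prod(dims))
  tab <- table(ctg, factor(lin, levels = seq_len(prod(dims))))
  percell[] <- as.numeric(tab)

  set.seed(seed)
  draws <- lapply(seq_len(B), function(b)
    sample.int(length(contigs), length(contigs), replace = TRUE))
  spectra <- lapply(draws, function(dr) {
    counts <- array(colSums(percell[dr, , drop = FALSE]), dims)
    s <- joint_sfs(counts, pop_order, folded = FALSE)
    if (fold) s <- fold_sfs(s)
    s
  })
  structure(list(sfs = spectra,
                 contig_sets = lapply(draws, function(dr) contigs[dr]),
                 B = B, seed = seed),
            class = "bootstrap_set")
}

#' @export
print.bootstrap_set <- function(x, ...) {
  cat(sprintf("bootstrap_set: %d replicates (seed %d), totals %g-%g sites\n",
              x$B, x$seed, min(vapply(x$sfs, sfs_total, numeric(1))),
              max(vapply(x$sfs, sfs_total, numeric(1)))))
  invisible(x)
}

#' Normal-approximation bootstrap confidence intervals
#'
#' Per parameter: `mean +/- 1.96 * sd` of the bootstrap point estimates.
#' Non-finite replicate values are dropped with a message.
#'
#' @param point_estimates Matrix (replicates x parameters) or data.frame of
#'   per-replicate parameter estimates.
#' @param conf_z Normal quantile (default 1.96 for 95%).
#' @return `data.frame` with columns parameter, mean, sd, low, high, n_used.
#' @export
param_ci <- function(point_estimates, conf_z = 1.96) {
  m <- as.matrix(point_estimates)
  if (nrow(m) < 2) stop("need at least 2 bootstrap replicates")
  out <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    ok <- is.finite(v)
    if (any(!ok))
      message(sprintf("param_ci: dropped %d non-finite replicate(s) for %s",
                      sum(!ok), colnames(m)[j]))
    v <- v[ok]
    data.frame(parameter = colnames(m)[j], mean = mean(v),
               sd = stats::sd(v),
               low = mean(v) - conf_z * stats::sd(v),
               high = mean(v) + conf_z * stats::sd(v),
               n_used = length(v))
  })
  do.call(rbind, out)
}

#' Finite-difference score of the profiled composite log-likelihood
#'
#' Central differences with a relative step, restricted to the requested
#' parameter indices. Points pushed outside the model bounds are clipped
#' inward with a warning; a non-finite likelihood at a perturbed point
#' triggers one step shrink before erroring.
#'
#' @param model `model_spec` or name.
#' @param params Named parameter vector (full parameterisation).
#' @param data Observed spectrum the score is taken against.
#' @param step Relative step size (default 1e-2).
#' @param indices Parameter indices to differentiate (default: all).
#' @param control Engine settings.
#' @return Named numeric gradient over the requested indices.
#' @export
score_vector <- function(model, params, data, step = 1e-2, indices = NULL,
                         control = list()) {
  if (is.character(model)) model <- get_model(model)
  params <- params[model$params]
  if (is.null(indices)) indices <- seq_len(model$n_free)
  ll_at <- function(p) composite_loglik(model, p, data, control)$ll
  g <- stats::setNames(numeric(length(indices)), model$params[indices])
  for (k in seq_along(indices)) {
    i <- indices[k]
    h <- step * max(abs(params[i]), step)
    attempt <- function(h) {
      lo <- params; hi <- params
      lo[i] <- lo[i] - h; hi[i] <- hi[i] + h
      clipped <- FALSE
      if (lo[i] < model$lower[i]) { lo[i] <- model$lower[i]; clipped <- TRUE }
      if (hi[i] > model$upper[i]) { hi[i] <- model$upper[i]; clipped <- TRUE }
      if (clipped)
        warning("score_vector: step at parameter ", model$params[i],
                " clipped to the model bounds")
      den <- hi[i] - lo[i]
      if (den <= 0) stop("score_vector: parameter ", model$params[i],
                         " is pinned at a bound; cannot differentiate")
      (ll_at(hi) - ll_at(lo)) / den
    }
    v <- attempt(h)
    if (!is.finite(v)) v <- attempt(h / 10)
    if (!is.finite(v))
      stop("score_vector: non-finite likelihood around parameter ",
           model$params[i])
    g[k] <- v
  }
  g
}

# negative Hessian of the profiled composite ll over the given indices,
# central finite differences
neg_hessian <- function(model, params, data, indices, step = 1e-2,
                        control = list()) {
  if (is.character(model)) model <- get_model(model)
  ll_at <- function(p) composite_loglik(model, p, data, control)$ll
  d <- length(indices)
  hs <- vapply(indices, function(i) step * max(abs(params[i]), step),
               numeric(1))
  # keep the whole stencil inside the bounds by shifting the centre inward
  centre <- params
  for (k in seq_len(d)) {
    i <- indices[k]
    centre[i] <- min(max(centre[i], model$lower[i] + hs[k]),
                     model$upper[i] - hs[k])
  }
  if (any(centre != params))
    warning("neg_hessian: evaluation centre moved inside the bounds")
  H <- matrix(0, d, d)
  ll0 <- ll_at(centre)
  for (k in seq_len(d)) {
    i <- indices[k]
    pp <- centre; pm <- centre
    pp[i] <- pp[i] + hs[k]; pm[i] <- pm[i] - hs[k]
    H[k, k] <- -(ll_at(pp) - 2 * ll0 + ll_at(pm)) / hs[k]^2
    if (k < d) for (l in seq(k + 1, d)) {
      j <- indices[l]
      fpp <- centre; fpm <- centre; fmp <- centre; fmm <- centre
      fpp[i] <- fpp[i] + hs[k]; fpp[j] <- fpp[j] + hs[l]
      fpm[i] <- fpm[i] + hs[k]; fpm[j] <- fpm[j] - hs[l]
      fmp[i] <- fmp[i] - hs[k]; fmp[j] <- fmp[j] + hs[l]
      fmm[i] <- fmm[i] - hs[k]; fmm[j] <- fmm[j] - hs[l]
      H[k, l] <- H[l, k] <-
        -(ll_at(fpp) - ll_at(fpm) - ll_at(fmp) + ll_at(fmm)) /
        (4 * hs[k] * hs[l])
    }
  }
  H
}

#' Godambe-corrected likelihood-ratio test for nested demographic models
#'
#' Composite-likelihood ratio statistics are inflated when sites are linked.
#' Following the Godambe-information approach, the raw statistic
#' `D = 2 (ll_full - ll_nested)` is rescaled by `df / tr(J H^-1)`, where `H`
#' is the negative Hessian of the composite log-likelihood with respect to
#' the constrained parameters at the nested optimum (embedded in the full
#' parameterisation, evaluated on the full data) and `J` is the variance of
#' the finite-difference scores of the bootstrap-replicate spectra at the
#' same point (mean outer product of the centred scores; centring removes
#' the common score offset present away from the full-model optimum). The
#' adjusted statistic is referred to a chi-squared distribution with `df` =
#' number of constrained parameters. With unlinked data the information
#' identity gives `J ~ H` and the adjustment is near 1; linkage inflates
#' `J` relative to `H` and deflates the statistic accordingly.
#'
#' @param full_fit,nested_fit `fit_result`s of the full and nested models on
#'   the same data.
#' @param data The observed spectrum both models were fitted to.
#' @param boots A [bootstrap_by_contig()] `bootstrap_set`.
#' @param step Relative finite-difference step (default 1e-2).
#' @param adjust Apply the Godambe correction? (`FALSE` gives the naive
#'   test.)
#' @param control Engine settings.
#' @return An `lrt_result`: raw `D`, adjustment factor, adjusted statistic,
#'   `df` and chi-squared p-value.
#' @export
godambe_adjusted_lrt <- function(full_fit, nested_fit, data, boots,
                                 step = 1e-2, adjust = TRUE,
                                 control = list()) {
  full <- get_model(full_fit$model)
  nested <- get_model(nested_fit$model)
  info <- nested_indices(full, nested)
  if (info$df == 0) stop("models are identical; nothing to test")
  D <- 2 * (full_fit$loglik - nested_fit$loglik)
  p0 <- embed_nested_params(full, nested, nested_fit$params)
  adjustment <- 1
  if (adjust) {
    if (length(boots$sfs) == 0) stop("bootstrap set is empty")
    H <- neg_hessian(full, p0, data, info$indices, step = step,
                     control = control)
    S <- do.call(rbind, lapply(boots$sfs, function(b)
      score_vector(full, p0, b, step = step, indices = info$indices,
                   control = control)))
    Sc <- sweep(S, 2L, colMeans(S))
    J <- crossprod(Sc) / nrow(S)
    Hi <- tryCatch(solve(H), error = function(e)
      stop("godambe_adjusted_lrt: singular Hessian; increase the ",
           "finite-difference step or the number of bootstraps"))
    adjustment <- info$df / sum(diag(J %*% Hi))
  }
  D_adj <- adjustment * D
  structure(list(D = D, adjustment = adjustment, D_adj = D_adj,
                 df = info$df,
                 p_value = stats::pchisq(D_adj, df = info$df,
                                         lower.tail = FALSE),
                 full_model = full$name, nested_model = nested$name),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "LRT %s vs %s: D = %.4f, adjustment = %.4f, D_adj = %.4f, df = %d, p = %.4g\n",
    x$full_model, x$nested_model, x$D, x$adjustment, x$D_adj, x$df,
    x$p_value))
  invisible(x)
}

#' Refit a model to every bootstrap replicate
#'
#' Warm-started re-optimisation: each replicate is fitted from the full-data
#' optimum plus a small number of perturbed restarts.
#'
#' @param boots A `bootstrap_set`.
#' @param fit A `fit_result` on the full data (provides model and warm
#'   start).
#' @param n_starts Starts per replicate (default 4: the full-data optimum
#'   plus three perturbed restarts).
#' @param seed Integer seed.
#' @param control Engine settings.
#' @param optim_control Optimiser settings passed to [fit_model()].
#' @return Matrix (replicates x parameters + theta + loglik) of bootstrap
#'   estimates.
#' @export
bootstrap_fits <- function(boots, fit, n_starts = 4, seed = 1,
                           control = list(), optim_control = list()) {
  model <- get_model(fit$model)
  rows <- lapply(seq_along(boots$sfs), function(b) {
    f <- tryCatch(
      fit_model(boots$sfs[[b]], model, n_starts = n_starts,
                init = fit$params, seed = seed + b, control = control,
                optim_control = optim_control),
      error = function(e) NULL)
    if (is.null(f))
      return(stats::setNames(rep(NA_real_, model$n_free + 2),
                             c(model$params, "theta", "loglik")))
    c(f$params, theta = f$theta, loglik = f$loglik)
  })
  do.call(rbind, rows)
}
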