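# Poisson composite-likelihood fitting of demographic models to a joint SFS.

#' Analytically optimal theta for a model spectrum
#'
#' The Poisson composite likelihood is maximised over the scale factor
#' `theta` at the ratio of total unmasked data mass to total unmasked model
#' mass.
#'
#' @param model_sfs Expected spectrum at `theta = 1` (a `joint_sfs`).
#' @param data Observed count spectrum, same shape/mask/folding.
#' @return The scalar `theta` maximising the Poisson likelihood.
#' @export
optimal_theta <- function(model_sfs, data) {
  live <- !(model_sfs$mask | data$mask)
  msum <- sum(model_sfs$counts[live])
  if (msum <= 0) stop("model spectrum has zero unmasked mass")
  sum(data$counts[live]) / msum
}

#' Poisson composite log-likelihood of a data spectrum
#'
#' Sum over unmasked cells of `k * log(theta * m) - theta * m - log(k!)`,
#' with `k` the observed count and `m` the model entry at `theta = 1`.
#' Sites are treated as independent (a composite likelihood); linkage is
#' handled downstream by bootstrap and Godambe corrections.
#'
#' @inheritParams optimal_theta
#' @param theta Positive scale factor (`4 Na mu L`).
#' @return Log-likelihood; `-Inf` (with a warning) if the model puts zero
#'   mass on a cell with observed counts.
#' @export
poisson_composite_ll <- function(model_sfs, data, theta) {
  stopifnot(theta > 0)
  if (!identical(dim(model_sfs$counts), dim(data$counts)))
    stop("model and data spectra have different shapes")
  live <- !(model_sfs$mask | data$mask)
  m <- theta * model_sfs$counts[live]
  k <- data$counts[live]
  if (any(m == 0 & k > 0)) {
    warning("model assigns zero mass to a cell with observed counts; ",
            "returning -Inf")
    return(-Inf)
  }
  term <- -m - lfactorial(k)
  pos <- k > 0
  term[pos] <- term[pos] + k[pos] * log(m[pos])
  sum(term)
}

#' Profiled composite log-likelihood of model parameters
#'
#' Computes the expected spectrum, profiles `theta` analytically and returns
#' the Poisson composite log-likelihood, the workhorse objective for
#' [fit_model()], [score_vector()] and the Godambe machinery.
#'
#' @inheritParams expected_sfs
#' @param data Observed count spectrum (`joint_sfs`).
#' @return List with `ll`, `theta` and the scaled model spectrum.
#' @export
composite_loglik <- function(model, params, data, control = list()) {
  exp_sfs <- expected_sfs(model, params,
                          sample_sizes = sfs_sample_sizes(data),
                          fold = data$folded, control = control)
  theta <- optimal_theta(exp_sfs, data)
  ll <- poisson_composite_ll(exp_sfs, data, theta)
  list(ll = ll, theta = theta, model_sfs = exp_sfs)
}

# optimisation-scale transform: nu and T parameters on log scale, migration
# rates linear (their natural boundary at zero is a hypothesis of interest)
param_transform <- function(model) {
  is_log <- !startsWith(model$params, "M")
  lower <- model$lower
  upper <- model$upper
  lower[is_log] <- pmax(lower[is_log], 1e-4)
  list(is_log = is_log,
       to_opt = function(p) ifelse(is_log, log(pmax(p, lower)), p),
       from_opt = function(x) {
         p <- ifelse(is_log, exp(x), x)
         stats::setNames(pmin(pmax(p, lower), upper), model$params)
       },
       lower_opt = ifelse(is_log, log(lower), lower),
       upper_opt = ifelse(is_log, log(upper), upper))
}

default_inits <- function(model) {
  p <- stats::setNames(numeric(model$n_free), model$params)
  p[startsWith(model$params, "nu")] <- 1
  p[startsWith(model$params, "T")] <- 0.4
  p[model$params == "T_c"] <- 0.2
  p[startsWith(model$params, "M")] <- 0.5
  p
}

#' Fit a demographic model to a joint SFS by maximum composite likelihood
#'
#' Runs `n_starts` bounded local optimisations (Nelder-Mead simplex refined
#' by L-BFGS-B) on log-transformed size and time parameters (migration rates
#' stay linear), from starting points perturbed log-uniformly by up to a
#' factor of two around the initial values. `theta` is profiled analytically
#' at every evaluation. The best start wins; likelihood ties within `1e-6`
#' are broken by the smaller L2 distance to the median start, so results are
#' deterministic given the seed.
#'
#' @param data Observed count spectrum (`joint_sfs`).
#' @param model A `model_spec` or model name.
#' @param n_starts Number of optimisation starts (default 20).
#' @param init Optional named vector of starting parameter values.
#' @param seed Integer seed for start perturbation.
#' @param control Engine numerical settings, see [expected_sfs()].
#' @param optim_control Optimiser settings: `nm_maxit`, `nm_reltol`
#'   (Nelder-Mead stage), `lbfgs_maxit`, `factr` (L-BFGS-B refinement).
#' @return A `fit_result`: best parameters, profiled `theta`, composite
#'   log-likelihood, and the endpoint of every start.
#' @export
fit_model <- function(data, model, n_starts = 20, init = NULL, seed = 1,
                      control = list(), optim_control = list()) {
  if (is.character(model)) model <- get_model(model)
  stopifnot(inherits(data, "joint_sfs"), n_starts >= 1)
  oc <- utils::modifyList(list(nm_maxit = 600, nm_reltol = 1e-9,
                               lbfgs_maxit = 100, factr = 1e9),
                          optim_control)
  tr <- param_transform(model)
  if (is.null(init)) init <- default_inits(model)
  init <- init[model$params]
  x0 <- tr$to_opt(init)

  negll <- function(x) {
    p <- tr$from_opt(x)
    # zero-mass cells en route are expected excursions of the optimiser:
    # penalise silently rather than warn on every evaluation
    v <- tryCatch(suppressWarnings(
      composite_loglik(model, p, data, control)$ll),
      error = function(e) -Inf)
    if (!is.finite(v)) return(1e12)
    -v
  }

  set.seed(seed)
  starts <- matrix(rep(x0, n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1) {
    for (r in 2:n_starts) {
      jitter <- stats::runif(model$n_free, -log(2), log(2))
      starts[r, ] <- ifelse(tr$is_log, x0 + jitter,
                            tr$from_opt(x0)[model$params] * exp(jitter))
      starts[r, ] <- pmin(pmax(starts[r, ], tr$lower_opt), tr$upper_opt)
    }
  }

  run_start <- function(x) {
    o1 <- if (length(x) == 1L) NULL else tryCatch(
      stats::optim(x, negll, method = "Nelder-Mead",
                   control = list(maxit = oc$nm_maxit,
                                  reltol = oc$nm_reltol)),
      error = function(e) NULL)
    xb <- if (!is.null(o1)) o1$par else x
    o2 <- tryCatch(
      stats::optim(xb, negll, method = "L-BFGS-B",
                   lower = tr$lower_opt, upper = tr$upper_opt,
                   control = list(maxit = oc$lbfgs_maxit, factr = oc$factr)),
      error = function(e) NULL)
    if (is.null(o2) && is.null(o1))
      return(list(par = x, value = negll(x), conv = -1L))
    if (is.null(o2)) return(list(par = o1$par, value = o1$value, conv = 1L))
    if (!is.null(o1) && o1$value < o2$value)
      return(list(par = o1$par, value = o1$value, conv = 0L))
    list(par = o2$par, value = o2$value, conv = o2$convergence)
  }

  results <- lapply(seq_len(n_starts), function(r) run_start(starts[r, ]))
  vals <- vapply(results, function(r) r$value, numeric(1))
  if (all(!is.finite(vals) | vals >= 1e12))
    stop("fit_model: no optimisation start converged to a finite likelihood")
  best_ll <- min(vals)
  tied <- which(vals <= best_ll + 1e-6)
  if (length(tied) > 1) {
    med <- apply(starts, 2L, stats::median)
    d2 <- vapply(tied, function(i) sum((results[[i]]$par - med)^2), numeric(1))
    best <- tied[which.min(d2)]
  } else best <- tied[1]

  p_best <- tr$from_opt(results[[best]]$par)
  final <- composite_loglik(model, p_best, data, control)
  start_tab <- data.frame(
    start = seq_len(n_starts),
    loglik = -vals,
    convergence = vapply(results, function(r) r$conv, integer(1)))
  for (j in seq_len(model$n_free))
    start_tab[[model$params[j]]] <-
      vapply(results, function(r) tr$from_opt(r$par)[j], numeric(1))

  structure(list(model = model$name, params = p_best, theta = final$theta,
                 loglik = final$ll, n_starts = n_starts, starts = start_tab,
                 seed = seed, model_sfs = final$model_sfs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: model %s, composite log-likelihood %.4f, theta %.4g\n",
              x$model, x$loglik, x$theta))
  print(round(x$params, 6))
  invisible(x)
}

#' Fit and rank several models on the same spectrum
#'
#' @param data Observed count spectrum.
#' @param models Character vector of model names.
#' @param n_starts,seed,control Passed to [fit_model()].
#' @return `data.frame` sorted by decreasing composite log-likelihood with
#'   columns model, df, loglik, delta_ll, theta; the individual
#'   `fit_result`s are attached as attribute `fits`. A model whose fit fails
#'   keeps its row with `NA` entries.
#' @export
compare_models <- function(data, models, n_starts = 20, seed = 1,
                           control = list()) {
  stopifnot(length(models) >= 1)
  fits <- lapply(models, function(mn) {
    tryCatch(fit_model(data, mn, n_starts = n_starts, seed = seed,
                       control = control),
             error = function(e) {
               warning("fit of model ", mn, " failed: ", conditionMessage(e))
               NULL
             })
  })
  names(fits) <- models
  tab <- data.frame(
    model = models,
    df = vapply(models, function(mn) get_model(mn)$df, integer(1)),
    loglik = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$loglik, numeric(1)),
    theta = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$theta, numeric(1)),
    row.names = NULL)
  tab <- tab[order(-tab$loglik, na.last = TRUE), ]
  tab$delta_ll <- tab$loglik[1] - tab$loglik
  attr(tab, "fits") <- fits
  tab
}
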