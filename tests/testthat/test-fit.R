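# Composite-likelihood machinery and model fitting.

test_that("optimal_theta is the unmasked mass ratio and maximises the likelihood", {
  m <- joint_sfs(array(4 / 23, c(5, 5)), c("A", "B"))     # total model mass 4
  d <- joint_sfs(array(100 / 23, c(5, 5)), c("A", "B"))   # total data mass 100
  expect_equal(optimal_theta(m, d), 25)

  d7 <- joint_sfs(7 * m$counts, c("A", "B"), mask = m$mask)
  expect_equal(optimal_theta(m, d7), 7)

  set.seed(5)
  mr <- joint_sfs(array(runif(25, 0.1, 2), c(5, 5)), c("A", "B"))
  dr <- joint_sfs(array(rpois(25, 6), c(5, 5)), c("A", "B"))
  th_hat <- optimal_theta(mr, dr)
  num <- optimize(function(t) poisson_composite_ll(mr, dr, t),
                  c(th_hat / 10, th_hat * 10), maximum = TRUE, tol = 1e-10)
  expect_equal(th_hat, num$maximum, tolerance = 1e-6)

  zero <- joint_sfs(array(0, c(5, 5)), c("A", "B"))
  expect_error(optimal_theta(zero, dr), "zero unmasked mass")
})

test_that("poisson_composite_ll matches hand-evaluated cells", {
  one <- function(k, tm) {
    m <- array(0, c(2, 3)); mask <- array(TRUE, c(2, 3))
    m[2, 2] <- tm; mask[2, 2] <- FALSE
    dd <- array(0, c(2, 3)); dd[2, 2] <- k
    poisson_composite_ll(joint_sfs(m, c("a", "b"), mask = mask),
                         joint_sfs(dd, c("a", "b"), mask = mask), theta = 1)
  }
  expect_equal(one(0, 1), -1)
  expect_equal(one(2, 2), 2 * log(2) - 2 - log(2), tolerance = 1e-12)

  # at data = theta * model, theta-hat is a maximum
  set.seed(6)
  mr <- joint_sfs(array(runif(25, 0.2, 1), c(5, 5)), c("A", "B"))
  dr <- joint_sfs(3 * mr$counts, c("A", "B"), mask = mr$mask)
  ll_hat <- poisson_composite_ll(mr, dr, 3)
  expect_gt(ll_hat, poisson_composite_ll(mr, dr, 1.5))
  expect_gt(ll_hat, poisson_composite_ll(mr, dr, 6))
  expect_gt(ll_hat, poisson_composite_ll(mr, dr, 3 * 1.01))
  expect_gt(ll_hat, poisson_composite_ll(mr, dr, 3 * 0.99))
})

test_that("noiseless spectra return the generating parameters for every model", {
  # equilibrium_1pop is excluded: its spectrum is exactly linear in nu, so
  # nu and theta are confounded and only their product is identifiable
  # (asserted separately below)
  cases <- list(
    split2_noMig = c(nu1 = 0.7, nu2 = 1.9, T = 0.45),
    split2_IM = c(nu1 = 0.8, nu2 = 1.4, T = 0.5, M12 = 0.8, M21 = 0.3),
    split2_SC = c(nu1 = 0.8, nu2 = 1.4, T = 0.6, T_c = 0.25, M12 = 1.1,
                  M21 = 0.6),
    trio_5param = c(nu_sinson = 0.5, nu_son = 1.6, T1 = 0.1, T2 = 0.3),
    trio_6param = c(nu_moj = 0.4, nu_sinson = 0.45, nu_son = 1.8,
                    T1 = 0.1, T2 = 0.34),
    trio_6param_IM = c(nu_moj = 0.5, nu_sinson = 0.6, nu_son = 1.5,
                       T1 = 0.15, T2 = 0.3, M_ss = 0.8))
  for (mn in names(cases)) {
    truth <- cases[[mn]]
    ss <- rep(4L, get_model(mn)$npops)
    exact <- expected_sfs(mn, truth, sample_sizes = ss, fold = TRUE)
    data <- joint_sfs(500 * exact$counts, exact$pop_ids, mask = exact$mask,
                      folded = TRUE)
    fit <- fit_model(data, mn, n_starts = 1, init = truth * 1.25, seed = 2,
                     control = list(rtol = 1e-6, atol = 1e-9),
                     optim_control = list(nm_maxit = 600, nm_reltol = 1e-9))
    expect_equal(unname(fit$params), unname(truth), tolerance = 0.02,
                 label = paste("params for", mn))
    expect_equal(fit$theta, 500, tolerance = 0.01,
                 label = paste("theta for", mn))
    # self-consistency: reported ll equals the likelihood recomputed at the
    # reported parameters
    expect_equal(fit$loglik,
                 composite_loglik(mn, fit$params, data)$ll,
                 tolerance = 1e-8)
  }

  # the single-population model recovers the identifiable product nu * theta
  exact1 <- expected_sfs("equilibrium_1pop", c(nu = 1.7), sample_sizes = 4,
                         fold = TRUE)
  data1 <- joint_sfs(500 * exact1$counts, exact1$pop_ids,
                     mask = exact1$mask, folded = TRUE)
  fit1 <- fit_model(data1, "equilibrium_1pop", n_starts = 1,
                    init = c(nu = 1), seed = 2)
  expect_equal(fit1$theta * fit1$params[["nu"]], 500 * 1.7,
               tolerance = 1e-4)
})

test_that("parameters are recovered from Poisson-sampled data", {
  truth <- c(nu1 = 0.7, nu2 = 1.9, T = 0.45)
  exact <- expected_sfs("split2_noMig", truth, sample_sizes = c(4, 4),
                        fold = TRUE)
  data <- sample_sfs_poisson(exact, theta = 4000, seed = 10)
  fit <- fit_model(data, "split2_noMig", n_starts = 6, seed = 3)
  expect_equal(unname(fit$params), unname(truth), tolerance = 0.1)
})

test_that("migration estimates go to the zero bound when data lack gene flow", {
  truth <- c(nu1 = 0.8, nu2 = 1.5, T = 0.5)
  exact <- expected_sfs("split2_noMig", truth, sample_sizes = c(4, 4),
                        fold = TRUE)
  data <- sample_sfs_poisson(exact, theta = 3000, seed = 4)
  fit <- fit_model(data, "split2_IM", n_starts = 2,
                   init = c(truth, M12 = 0.4, M21 = 0.4), seed = 5)
  expect_lt(max(fit$params[c("M12", "M21")]), 0.05)
})

test_that("fits are deterministic given the seed", {
  exact <- expected_sfs("split2_noMig", c(nu1 = 1, nu2 = 2, T = 0.4),
                        sample_sizes = c(4, 4), fold = TRUE)
  data <- sample_sfs_poisson(exact, theta = 800, seed = 8)
  f1 <- fit_model(data, "split2_noMig", n_starts = 1, seed = 99)
  f2 <- fit_model(data, "split2_noMig", n_starts = 1, seed = 99)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$starts, f2$starts)
})

test_that("compare_models ranks the generating model first", {
  truth <- c(nu_moj = 0.4, nu_sinson = 0.45, nu_son = 1.8, T1 = 0.1,
             T2 = 0.34)
  exact <- expected_sfs("trio_6param", truth, fold = TRUE)
  data <- sample_sfs_poisson(exact, theta = 3000, seed = 12)
  tab <- compare_models(data, c("trio_5param", "trio_6param"), n_starts = 3,
                        seed = 7)
  expect_equal(tab$model[1], "trio_6param")
  expect_equal(tab$delta_ll[1], 0)
  expect_true(all(diff(tab$loglik) <= 0))

  one <- compare_models(data, "trio_6param", n_starts = 2, seed = 7)
  expect_equal(nrow(one), 1L)
})
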