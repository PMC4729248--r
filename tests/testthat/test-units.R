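# Scaled <-> physical unit conversion and the calibration anchor.

test_that("calibration algebra matches hand values", {
  scaled <- c(nu_moj = 0.5, nu_sinson = 0.4, nu_son = 1.5, T1 = 0.2,
              T2 = 0.3)
  phys <- calibrate_physical(scaled, theta = 9440, model = "trio_6param")
  # T_anchor = 0.5 -> Na = 5.9e6 / (2 * 25 * 0.5) = 236,000
  expect_equal(phys$Na, 236000)
  expect_equal(phys$muL, 0.01)
  expect_equal(unname(phys$N["N_son"]), 1.5 * 236000)
  expect_identical(unname(phys$T_years["T_div1"]), 5.9e6)
  expect_equal(unname(phys$T_years["T_div2"]), 0.3 * 2 * 236000 * 25)
})

test_that("the converted anchor divergence equals the calibration age exactly", {
  set.seed(33)
  for (i in 1:4) {
    scaled <- c(nu_moj = exp(runif(1, -1, 1)),
                nu_sinson = exp(runif(1, -1, 1)),
                nu_son = exp(runif(1, -1, 1)),
                T1 = runif(1, 0.01, 1), T2 = runif(1, 0.01, 1))
    phys <- calibrate_physical(scaled, theta = runif(1, 100, 1e4),
                               model = "trio_6param")
    expect_identical(unname(phys$T_years["T_div1"]), 5.9e6)
  }
  expect_error(calibrate_physical(c(nu_moj = 1, nu_sinson = 1, nu_son = 1,
                                    T1 = 0, T2 = 0), 100, "trio_6param"),
               "zero")
})

test_that("physical -> scaled -> physical round-trips to 1e-10", {
  scaled <- c(nu_moj = 0.38, nu_sinson = 0.45, nu_son = 1.78, T1 = 0.0149,
              T2 = 0.336)
  phys <- calibrate_physical(scaled, theta = 5500, model = "trio_6param")
  back <- physical_to_scaled(phys)
  expect_equal(back$scaled, scaled, tolerance = 1e-10)
  expect_equal(back$theta, 5500, tolerance = 1e-10)

  scaled2 <- c(nu1 = 0.8, nu2 = 1.3, T = 0.4)
  phys2 <- calibrate_physical(scaled2, theta = 900, model = "split2_noMig")
  back2 <- physical_to_scaled(phys2)
  expect_equal(back2$scaled, scaled2, tolerance = 1e-10)
})

test_that("bootstrap conversion fixes muL and scales with replicate theta", {
  scaled <- c(nu_moj = 0.4, nu_sinson = 0.45, nu_son = 1.8, T1 = 0.015,
              T2 = 0.34)
  theta_hat <- 5600
  phys <- calibrate_physical(scaled, theta_hat, "trio_6param")

  # a replicate identical to the full data converts identically
  bp <- rbind(c(scaled, theta = theta_hat, loglik = 0))
  conv <- convert_bootstrap(bp, phys$muL, "trio_6param")
  expect_equal(conv$Na, phys$Na, tolerance = 1e-12)
  expect_equal(conv$T_div1, unname(phys$T_years["T_div1"]),
               tolerance = 1e-12)

  # doubling theta doubles Na; years are unchanged iff scaled times halve
  bp2 <- rbind(c(scaled, theta = 2 * theta_hat, loglik = 0),
               c(scaled / 2, theta = 2 * theta_hat, loglik = 0))
  bp2[2, c("nu_moj", "nu_sinson", "nu_son")] <-
    scaled[c("nu_moj", "nu_sinson", "nu_son")]
  conv2 <- convert_bootstrap(bp2, phys$muL, "trio_6param")
  expect_equal(conv2$Na, rep(2 * phys$Na, 2), tolerance = 1e-12)
  expect_equal(conv2$T_div1[2], unname(phys$T_years["T_div1"]),
               tolerance = 1e-12)

  # non-positive theta replicates are dropped with a message
  bp3 <- rbind(bp, c(scaled, theta = -1, loglik = 0))
  expect_message(conv3 <- convert_bootstrap(bp3, phys$muL, "trio_6param"),
                 "dropped 1")
  expect_equal(nrow(conv3), 1L)
})
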