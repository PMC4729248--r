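# Linked-site generator and the Poisson spectrum sampler.

test_that("the generator is deterministic and honours the configuration", {
  cfg <- sim_config(n_contigs = 60, seed = 5)
  vt1 <- simulate_variants(cfg)
  vt2 <- simulate_variants(cfg)
  expect_identical(vt1$sites, vt2$sites)
  expect_identical(vt1$geno, vt2$geno)

  # identical VCF bytes under the same seed
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_variants(vt1, f1)
  write_vcf_variants(vt2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(n_variants(simulate_variants(sim_config(n_contigs = 0,
                                                       seed = 1))), 0)

  # population structure: 2 diploids in each of the three populations
  expect_equal(unname(table(vt1$popmap)[c("MOJ", "SON", "SIN")]),
               rep(2L, 3), ignore_attr = TRUE)
  expect_true(all(vt1$sites$annotation %in%
                    c("synonymous", "nonsynonymous", "ambiguous")))
})

test_that("generator spectra match the engine expectation in the mean", {
  # scaled-down replicate study: cellwise means over independent generator
  # runs against theta x engine expectation, in Monte-Carlo SE units
  n_rep <- 12
  cfg0 <- sim_config(n_contigs = 400, seed = 1)
  exp_f <- expected_sfs("trio_6param", cfg0$params, fold = TRUE)
  live <- !exp_f$mask
  acc <- matrix(0, n_rep, sum(live))
  theta_eff <- NULL
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_contigs = 400, seed = 1000 + r)
    vt <- simulate_variants(cfg)
    flt <- suppress_all(filter_variants(vt))
    s <- build_joint_sfs(flt, c("MOJ", "SON", "SIN"), fold = TRUE)
    acc[r, ] <- s$counts[live]
    truth <- attr(vt, "truth")
    theta_eff <- truth$theta *
      (1 - cfg$frac_nonsynonymous - cfg$frac_ambiguous) *
      (1 - cfg$frac_low_quality) * (1 - cfg$frac_missing)
  }
  mu <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(n_rep)
  expected <- theta_eff * exp_f$counts[live]
  z <- abs(mu - expected) / pmax(se, 1e-9)
  # a few of the 62 folded cells may exceed 3 SE by chance; none should be
  # grossly off
  expect_gt(mean(z <= 3), 0.95)
  expect_true(all(z <= 6))
})

test_that("sample_sfs_poisson has the right mean and total variance", {
  exact <- expected_sfs("trio_6param", tortoise_trio_params(), fold = TRUE)
  z0 <- sample_sfs_poisson(exact, theta = 0, seed = 1)
  expect_equal(sfs_total(z0), 0)

  live <- !exact$mask
  cell <- which(live)[5]
  theta <- 50
  n_draw <- 2000
  draws <- vapply(seq_len(n_draw), function(i)
    sample_sfs_poisson(exact, theta, seed = i)$counts[cell], numeric(1))
  mu_exp <- theta * exact$counts[cell]
  expect_lt(abs(mean(draws) - mu_exp), 3 * sqrt(mu_exp / n_draw))

  totals <- vapply(seq_len(n_draw), function(i)
    sfs_total(sample_sfs_poisson(exact, theta, seed = 10000 + i)),
    numeric(1))
  lambda <- theta * sfs_total(exact)
  # Poisson: variance equals the mean; chi-squared bounds on the sample
  # variance at n = 2000
  ratio <- var(totals) / lambda
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
  expect_lt(abs(mean(totals) - lambda), 3 * sqrt(lambda / n_draw))
})

test_that("linked and unlinked generators share cellwise expectations", {
  # the linked generator and the Poisson sampler target the same mean
  # spectrum; only the variance differs (checked via bootstrap elsewhere)
  cfg <- sim_config(n_contigs = 1500, seed = 77, frac_nonsynonymous = 0,
                    frac_ambiguous = 0, frac_low_quality = 0,
                    frac_missing = 0)
  vt <- simulate_variants(cfg)
  s_link <- build_joint_sfs(suppress_all(filter_variants(vt)),
                            c("MOJ", "SON", "SIN"), fold = TRUE)
  truth <- attr(vt, "truth")
  exp_f <- expected_sfs("trio_6param", cfg$params, fold = TRUE)
  s_pois <- sample_sfs_poisson(exp_f, truth$theta, seed = 78)
  live <- !exp_f$mask
  mu <- truth$theta * exp_f$counts[live]
  # both totals within 5 sd of the common expectation (linked data are
  # overdispersed, hence the loose factor)
  expect_lt(abs(sfs_total(s_link) - sum(mu)), 5 * sqrt(sum(mu)) * 3)
  expect_lt(abs(sfs_total(s_pois) - sum(mu)), 5 * sqrt(sum(mu)))
})
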