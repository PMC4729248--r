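# Contig bootstrap, confidence intervals, scores and the corrected LRT.

test_that("bootstrap_by_contig is reproducible and additive over contigs", {
  # three contigs with disjoint cells
  dos <- list(c(1L, 0L, 0L, 0L, 0L, 0L),
              c(1L, 0L, 0L, 0L, 0L, 0L),
              c(0L, 0L, 1L, 0L, 0L, 0L),
              c(0L, 0L, 0L, 0L, 1L, 1L))
  vt <- toy_variants(dos, contig = c("cA", "cA", "cB", "cC"))
  b1 <- bootstrap_by_contig(vt, B = 2, seed = 42, fold = FALSE,
                            pop_order = c("MOJ", "SON", "SIN"))
  b2 <- bootstrap_by_contig(vt, B = 2, seed = 42, fold = FALSE,
                            pop_order = c("MOJ", "SON", "SIN"))
  expect_identical(lapply(b1$sfs, function(s) s$counts),
                   lapply(b2$sfs, function(s) s$counts))
  expect_identical(b1$contig_sets, b2$contig_sets)

  # replicate spectra equal the sum of the drawn contigs' spectra
  per_contig <- list(
    cA = build_joint_sfs(toy_variants(dos[1:2], contig = c("cA", "cA")),
                         c("MOJ", "SON", "SIN"), fold = FALSE)$counts,
    cB = build_joint_sfs(toy_variants(dos[3], contig = "cB"),
                         c("MOJ", "SON", "SIN"), fold = FALSE)$counts,
    cC = build_joint_sfs(toy_variants(dos[4], contig = "cC"),
                         c("MOJ", "SON", "SIN"), fold = FALSE)$counts)
  for (b in 1:2) {
    expected <- Reduce(`+`, per_contig[b1$contig_sets[[b]]])
    expect_equal(b1$sfs[[b]]$counts, expected)
  }

  expect_warning(bootstrap_by_contig(toy_variants(dos[1:2],
                                                  contig = c("cA", "cA")),
                                     B = 2, seed = 1),
                 "single contig")
})

test_that("bootstrap replicate totals match the original in expectation", {
  set.seed(14)
  counts <- array(rpois(125, 2), c(5, 5, 5))
  counts[1] <- 0; counts[125] <- 0
  vt <- variants_from_sfs(counts,
                          contigs_of = function(i) sprintf("c%02d", i %% 40))
  n0 <- n_variants(vt)
  boots <- bootstrap_by_contig(vt, B = 200, seed = 3, fold = FALSE)
  totals <- vapply(boots$sfs, sfs_total, numeric(1))
  # mean replicate total ~ original within binomial-ish Monte Carlo error
  expect_lt(abs(mean(totals) - n0) / n0, 3 * sd(totals) / sqrt(200) / n0)
})

test_that("param_ci reproduces the mean +/- 1.96 sd formula", {
  ci <- param_ci(cbind(x = c(9, 10, 11)))
  expect_equal(ci$mean, 10)
  expect_equal(ci$sd, 1)
  expect_equal(ci$low, 10 - 1.96)
  expect_equal(ci$high, 10 + 1.96)

  ci0 <- param_ci(cbind(x = rep(5, 10)))
  expect_equal(ci0$low, 5)
  expect_equal(ci0$high, 5)

  expect_message(param_ci(cbind(x = c(1, 2, NA, Inf, 3))), "non-finite")
})

test_that("scores vanish at a noiseless optimum and are step-stable", {
  truth <- c(nu1 = 0.9, nu2 = 1.7, T = 0.4)
  exact <- expected_sfs("split2_noMig", truth, sample_sizes = c(4, 4),
                        fold = TRUE)
  data <- joint_sfs(2000 * exact$counts, exact$pop_ids, mask = exact$mask,
                    folded = TRUE)
  g <- score_vector("split2_noMig", truth, data, step = 1e-3)
  # likelihood scale here is ~1e4; stationarity to ~1e-3 relative per unit
  expect_lt(max(abs(g)) / 2000, 1e-3)

  # away from the optimum, halving the step barely changes the score
  p_off <- truth * c(1.15, 0.9, 1.1)
  g1 <- score_vector("split2_noMig", p_off, data, step = 1e-2)
  g2 <- score_vector("split2_noMig", p_off, data, step = 5e-3)
  expect_lt(max(abs(g1 - g2) / pmax(abs(g1), 1e-6)), 0.01)

  expect_warning(score_vector("split2_IM", c(truth, M12 = 0, M21 = 0), data,
                              indices = 4L),
                 "clipped")
})

test_that("chi-squared reference values for the adjusted statistic", {
  expect_equal(round(pchisq(9.242, df = 1, lower.tail = FALSE), 4), 0.0024)
  expect_equal(pchisq(3.841, df = 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
})

test_that("the Godambe adjustment is near one for unlinked data", {
  # data simulated under the nested (5-parameter) model, one SNP per contig
  truth5 <- c(nu_sinson = 0.5, nu_son = 1.7, T1 = 0.12, T2 = 0.3)
  exact <- expected_sfs("trio_5param", truth5, fold = TRUE)
  counts <- sample_sfs_poisson(exact, theta = 2500, seed = 21)$counts
  vt <- variants_from_sfs(counts)   # every site its own contig
  data <- build_joint_sfs(vt, c("MOJ", "SON", "SIN"), fold = TRUE)
  f5 <- fit_model(data, "trio_5param", n_starts = 2, init = truth5, seed = 2)
  f6 <- fit_model(data, "trio_6param", n_starts = 2,
                  init = c(nu_moj = 1, f5$params), seed = 2)
  boots <- bootstrap_by_contig(vt, B = 100, seed = 9)
  lrt <- godambe_adjusted_lrt(f6, f5, data, boots)
  expect_equal(lrt$df, 1L)
  expect_gt(lrt$adjustment, 0.8)
  expect_lt(lrt$adjustment, 1.25)
  expect_gte(lrt$D, -1e-6)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)

  naive <- godambe_adjusted_lrt(f6, f5, data, boots, adjust = FALSE)
  expect_equal(naive$adjustment, 1)
  expect_equal(naive$D_adj, naive$D)
})
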