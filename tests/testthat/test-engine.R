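# Deterministic expected-SFS engine: closed forms, smoothness, folding
# consistency. (The Monte-Carlo oracle equivalence across all models lives
# in the acceptance suite; here we keep the cheap exact checks.)

test_that("single-population equilibrium spectrum is theta/i", {
  s <- expected_sfs("equilibrium_1pop", c(nu = 1), sample_sizes = 4,
                    fold = FALSE)
  expect_equal(as.vector(s$counts[2:4]), c(1, 1 / 2, 1 / 3),
               tolerance = 1e-12)
  # linear in the population size
  s2 <- expected_sfs("equilibrium_1pop", c(nu = 2.5), sample_sizes = 4,
                     fold = FALSE)
  expect_equal(as.vector(s2$counts[2:4]), 2.5 * c(1, 1 / 2, 1 / 3),
               tolerance = 1e-12)
  # larger sample
  s8 <- expected_sfs("equilibrium_1pop", c(nu = 1), sample_sizes = 8,
                     fold = FALSE)
  expect_equal(as.vector(s8$counts[2:8]), 1 / (1:7), tolerance = 1e-12)
})

test_that("a split of duration zero redistributes the panmictic spectrum hypergeometrically", {
  s <- expected_sfs("split2_noMig", c(nu1 = 1, nu2 = 1, T = 0),
                    sample_sizes = c(4, 4), fold = FALSE)
  ref <- matrix(0, 5, 5)
  for (k in 1:7) for (i in max(0, k - 4):min(4, k)) {
    ref[i + 1, k - i + 1] <- ref[i + 1, k - i + 1] +
      (1 / k) * dhyper(i, 4, 4, k)
  }
  expect_equal(s$counts, ref, tolerance = 1e-10)
})

test_that("expected spectra are smooth in the parameters", {
  p <- c(nu_moj = 0.4, nu_sinson = 0.45, nu_son = 1.8, T1 = 0.015,
         T2 = 0.34)
  base <- expected_sfs("trio_6param", p, fold = TRUE)
  live <- !base$mask
  for (j in seq_along(p)) {
    pp <- p
    pp[j] <- pp[j] * (1 + 1e-6)
    pert <- expected_sfs("trio_6param", pp, fold = TRUE)
    rel <- abs(pert$counts[live] - base$counts[live]) /
      pmax(base$counts[live], 1e-12)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("folding the unfolded engine output equals asking for folded output", {
  p <- c(nu_moj = 0.4, nu_sinson = 0.45, nu_son = 1.8, T1 = 0.015,
         T2 = 0.34)
  un <- expected_sfs("trio_6param", p, fold = FALSE)
  fo <- expected_sfs("trio_6param", p, fold = TRUE)
  expect_equal(fold_sfs(un)$counts, fo$counts, tolerance = 1e-12)
  expect_equal(sfs_total(un), sfs_total(fo), tolerance = 1e-12)
})

test_that("strong symmetric migration approaches the panmictic island limit", {
  p_base <- c(nu1 = 1, nu2 = 1, T = 6)
  lim <- matrix(0, 5, 5)   # pooled population of relative size 2, n = 8
  for (k in 1:7) for (i in max(0, k - 4):min(4, k)) {
    lim[i + 1, k - i + 1] <- lim[i + 1, k - i + 1] +
      (2 / k) * dhyper(i, 4, 4, k)
  }
  dev <- function(M) {
    s <- expected_sfs("split2_IM", c(p_base, M12 = M, M21 = M),
                      sample_sizes = c(4, 4), fold = FALSE)
    live <- !s$mask
    # mass-weighted L1 deviation: the limit is approached at rate ~1/M, so
    # assert monotone approach and closeness at the strongest admissible M
    sum(abs(s$counts[live] - lim[live])) / sum(lim[live])
  }
  devs <- c(dev(2), dev(8), dev(20))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.05)
})

test_that("the Monte-Carlo oracle is reproducible and seed-consistent", {
  p <- c(nu1 = 1, nu2 = 2, T = 0.5)
  a <- mc_expected_sfs("split2_noMig", p, sample_sizes = c(4, 4),
                       n_replicates = 3000, fold = FALSE, seed = 11)
  a2 <- mc_expected_sfs("split2_noMig", p, sample_sizes = c(4, 4),
                        n_replicates = 3000, fold = FALSE, seed = 11)
  expect_identical(a$counts, a2$counts)
  b <- mc_expected_sfs("split2_noMig", p, sample_sizes = c(4, 4),
                       n_replicates = 3000, fold = FALSE, seed = 12)
  live <- !a$mask
  joint_se <- sqrt(attr(a, "se")[live]^2 + attr(b, "se")[live]^2)
  expect_true(all(abs(a$counts[live] - b$counts[live]) <=
                    6 * pmax(joint_se, 1e-12)))
})
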