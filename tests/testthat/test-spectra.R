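# Joint SFS construction, folding, marginals, residuals and flat-file I/O.

test_that("filter_variants applies quality, completeness and annotation rules", {
  dos <- replicate(5, c(1L, 0L, 0L, 0L, 0L, 0L), simplify = FALSE)
  vt <- toy_variants(dos, qual = c(99, 19.5, 20, 35, 99))
  out <- suppress_all(filter_variants(vt, min_quality = 20,
                                      require_complete = FALSE,
                                      synonymous_only = FALSE))
  expect_equal(n_variants(out), 4)   # 19.5 fails, 20.0 passes the boundary

  dos3 <- list(c(1L, 0L, 0L, 0L, 0L, 0L),
               c(1L, NA, 0L, 0L, 0L, 0L),
               c(0L, 0L, 1L, 1L, 0L, 0L))
  vt3 <- toy_variants(dos3)
  out3 <- suppress_all(filter_variants(vt3, require_complete = TRUE,
                                       synonymous_only = FALSE))
  expect_equal(n_variants(out3), 2)

  vt4 <- toy_variants(replicate(4, c(1L, 0L, 0L, 0L, 0L, 0L),
                                simplify = FALSE),
                      annotation = c("synonymous", "synonymous",
                                     "nonsynonymous", "ambiguous"))
  out4 <- suppress_all(filter_variants(vt4, synonymous_only = TRUE))
  expect_equal(n_variants(out4), 2)
  expect_identical(out4$sites$pos, 1:2)   # order preserved

  expect_warning(suppressMessages(filter_variants(vt4, min_quality = 1e6)),
                 "no records")
})

test_that("build_joint_sfs tallies dosage configurations into cells", {
  vt <- toy_variants(list(c(1L, 0L, 0L, 0L, 0L, 0L)))
  s <- build_joint_sfs(vt, c("MOJ", "SON", "SIN"), fold = FALSE)
  expect_equal(s$counts[2, 1, 1], 1)
  expect_equal(sfs_total(s), 1)

  # three hand-written sites: MOJ dosage sums 1, 2, 0; SON 0, 1, 3; SIN 0, 0, 2
  vt3 <- toy_variants(list(c(1L, 0L, 0L, 0L, 0L, 0L),
                           c(2L, 0L, 1L, 0L, 0L, 0L),
                           c(0L, 0L, 2L, 1L, 2L, 0L)))
  s3 <- build_joint_sfs(vt3, c("MOJ", "SON", "SIN"), fold = FALSE)
  expect_equal(s3$counts[2, 1, 1], 1)
  expect_equal(s3$counts[3, 2, 1], 1)
  expect_equal(s3$counts[1, 4, 3], 1)
  expect_equal(sfs_total(s3), 3)

  # monomorphic records land in the always-masked corners
  vt_mono <- toy_variants(list(c(0L, 0L, 0L, 0L, 0L, 0L),
                               c(2L, 2L, 2L, 2L, 2L, 2L),
                               c(1L, 0L, 0L, 0L, 0L, 0L)))
  s_mono <- suppress_all(build_joint_sfs(vt_mono, c("MOJ", "SON", "SIN"),
                                         fold = FALSE))
  expect_equal(sfs_total(s_mono), 1)
  expect_equal(s_mono$counts[1, 1, 1], 1)
  expect_equal(s_mono$counts[5, 5, 5], 1)
  expect_true(s_mono$mask[1, 1, 1] && s_mono$mask[5, 5, 5])

  # shape of the study-scale folded spectrum: 2 diploids per population
  sf <- build_joint_sfs(vt3, c("MOJ", "SON", "SIN"), fold = TRUE)
  expect_equal(dim(sf$counts), c(5L, 5L, 5L))
  expect_true(sf$folded)
})

test_that("folding sums complement cells and handles ties once", {
  # single population, n = 4: interior (3, 2, 1) folds to (4, 2, -)
  s <- joint_sfs(c(0, 3, 2, 1, 0), "p1")
  f <- fold_sfs(s)
  expect_equal(f$counts[2], 4)
  expect_equal(f$counts[3], 2)          # tie cell, counted once
  expect_true(f$mask[4] && f$mask[5])
  expect_equal(sfs_total(f), sfs_total(s))

  # symmetric spectrum (a, b, a) -> (2a, b, -)
  s2 <- joint_sfs(c(0, 7, 5, 7, 0), "p1")
  f2 <- fold_sfs(s2)
  expect_equal(f2$counts[2], 14)
  expect_equal(f2$counts[3], 5)

  # two populations: cell (1,0) = 2 and complement (3,4) = 5 fold to 7
  c2 <- array(0, c(5, 5))
  c2[2, 1] <- 2; c2[4, 5] <- 5
  f3 <- fold_sfs(joint_sfs(c2, c("a", "b")))
  expect_equal(f3$counts[2, 1], 7)
  expect_true(f3$mask[4, 5])

  expect_warning(fold_sfs(f3), "already folded")
})

test_that("folding is idempotent and conserves mass on random spectra", {
  set.seed(42)
  for (i in 1:5) {
    a <- array(rpois(125, 4), c(5, 5, 5))
    s <- joint_sfs(a, c("A", "B", "C"))
    f <- fold_sfs(s)
    expect_equal(sfs_total(f), sfs_total(s))
    f2 <- suppressWarnings(fold_sfs(f))
    expect_identical(f2$counts, f$counts)
  }
})

test_that("marginalize_pair sums the remaining axis and conserves mass", {
  a <- array(0, c(5, 5, 5))
  a[2, 3, 1] <- 1
  s <- joint_sfs(a, c("MOJ", "SON", "SIN"))
  m <- marginalize_pair(s, "MOJ", "SON")
  expect_equal(m$counts[2, 3], 1)
  expect_equal(m$pop_ids, c("MOJ", "SON"))

  u <- joint_sfs(array(1, c(5, 5, 5)), c("A", "B", "C"))
  mu <- marginalize_pair(u, "A", "B")
  # uniform x axis length, minus the two masked corner contributions
  expect_equal(mu$counts[2, 2], 5)

  set.seed(7)
  r <- array(rpois(125, 3), c(5, 5, 5))
  sr <- joint_sfs(r, c("A", "B", "C"))
  mr <- marginalize_pair(sr, "A", "C")
  brute <- apply(replace(r, sr$mask, 0), c(1, 3), sum)
  expect_equal(mr$counts, brute)

  expect_error(marginalize_pair(s, "MOJ", "XXX"), "unknown population")
})

test_that("anscombe residuals match the Poisson variance-stabilised form", {
  a <- array(4, c(5, 5))
  s_model <- joint_sfs(a, c("A", "B"))
  s_data <- joint_sfs(a, c("A", "B"))
  r <- anscombe_residuals(s_model, s_data)
  expect_true(all(r[!s_model$mask] == 0))
  expect_true(all(is.na(r[s_model$mask])))

  d <- array(4, c(5, 5)); d[2, 2] <- 8
  s_d8 <- joint_sfs(d, c("A", "B"))
  # hand evaluation: 1.5 (8^{2/3} - 4^{2/3}) / 4^{1/6} = 1.7622032,
  # negated under the model-minus-data convention
  expect_equal(anscombe_residuals(s_model, s_d8)[2, 2], -1.76220315590460,
               tolerance = 1e-10)
  expect_equal(anscombe_residuals(s_model, s_d8, sign = "data_minus_model")[2, 2],
               1.76220315590460, tolerance = 1e-10)

  bad <- joint_sfs(array(4, c(4, 4)), c("A", "B"))
  expect_error(anscombe_residuals(s_model, bad), "different shapes")
})

test_that("SFS flat files round-trip through write_sfs/read_sfs", {
  set.seed(9)
  s <- fold_sfs(joint_sfs(array(rpois(125, 2), c(5, 5, 5)),
                          c("MOJ", "SON", "SIN")))
  p <- withr::local_tempfile(fileext = ".fs")
  write_sfs(s, p)
  s2 <- read_sfs(p)
  expect_equal(s2$counts, s$counts)
  expect_identical(s2$mask, s$mask)
  expect_identical(s2$folded, s$folded)
  expect_identical(s2$pop_ids, s$pop_ids)
})

test_that("VCF and annotation files round-trip through vcfR", {
  vt <- toy_variants(list(c(1L, 0L, 0L, 0L, 0L, 0L),
                          c(2L, 1L, NA, 0L, 0L, 1L),
                          c(0L, 0L, 2L, 1L, 2L, 0L)),
                     qual = c(50, 18.2, 99),
                     annotation = c("synonymous", "nonsynonymous",
                                    "synonymous"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_vcf_variants(vt, vcf)
  write_annotation(vt, ann)
  back <- read_vcf_variants(vcf, read_annotation(ann), toy_popmap())
  expect_equal(back$geno, vt$geno)
  expect_equal(back$sites$qual, vt$sites$qual)
  expect_equal(back$sites$annotation, vt$sites$annotation)
})
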