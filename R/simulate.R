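# Linked-site synthetic data generator.
#
# Emulates the statistical structure of the transcriptome variant data the
# pipeline is designed for: a few thousand contigs, each carrying a handful
# of synonymous SNPs that share a single coalescent genealogy (full
# within-contig linkage, free recombination between contigs), genotyped in
# two diploids per population. A configurable fraction of sites carries
# non-synonymous/ambiguous annotations, sub-threshold quality scores or a
# missing genotype, so the variant filters have realistic work to do.

#' Published best-fit demography for the desert-tortoise trio
#'
#' The six-parameter ((Sinaloan, Sonoran), Mojave) divergence demography in
#' coalescent-scaled units, derived from the physical estimates: ancestral
#' size 336,200; contemporary Mojave 128,400, Sinaloan 149,600 and Sonoran
#' 600,000 individuals; Mojave divergence 5.9 Ma and Sinaloan/Sonoran
#' divergence 5.65 Ma at a 25-year generation time.
#'
#' @param anchor_years,generation_time Calibration constants.
#' @return Named scaled parameter vector for model `trio_6param`.
#' @export
tortoise_trio_params <- function(anchor_years = 5.9e6, generation_time = 25) {
  Na <- 336200
  c(nu_moj = 128400 / Na,
    nu_sinson = 149600 / Na,
    nu_son = 600000 / Na,
    T1 = (anchor_years - 5.65e6) / (2 * generation_time * Na),
    T2 = 5.65e6 / (2 * generation_time * Na))
}

#' Configuration for the synthetic variant generator
#'
#' Defaults reproduce the scale of the study data: 7,665 contigs carrying on
#' average 20,126/7,665 ~ 2.63 retained synonymous SNPs each, two diploids
#' per population, under the published tortoise-trio demography.
#'
#' @param model Model name (default `trio_6param`).
#' @param params Scaled generating parameters (default
#'   [tortoise_trio_params()]).
#' @param n_contigs Number of contigs.
#' @param mean_syn_snps_per_contig Expected number of retained synonymous,
#'   complete-genotype, quality-passing SNPs per contig.
#' @param diploids_per_pop Diploid individuals sampled per population.
#' @param frac_nonsynonymous,frac_ambiguous Fractions of sites annotated
#'   nonsynonymous / ambiguous (exercise the annotation filter).
#' @param frac_low_quality Fraction of sites given sub-threshold (< 20)
#'   quality scores.
#' @param frac_missing Fraction of sites with one missing genotype.
#' @param contig_length Contig length in bp (positions are placed within
#'   it).
#' @param seed Integer seed (mandatory: generated data must be
#'   reproducible).
#' @return A `sim_config` list.
#' @export
sim_config <- function(model = "trio_6param",
                       params = tortoise_trio_params(),
                       n_contigs = 7665,
                       mean_syn_snps_per_contig = 20126 / 7665,
                       diploids_per_pop = 2,
                       frac_nonsynonymous = 0.15,
                       frac_ambiguous = 0.05,
                       frac_low_quality = 0.05,
                       frac_missing = 0.02,
                       contig_length = 1000,
                       seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  stopifnot(n_contigs >= 0, mean_syn_snps_per_contig > 0,
            diploids_per_pop >= 1,
            frac_nonsynonymous + frac_ambiguous < 1,
            frac_low_quality < 1, frac_missing < 1)
  structure(list(model = model, params = params, n_contigs = n_contigs,
                 mean_syn_snps_per_contig = mean_syn_snps_per_contig,
                 diploids_per_pop = diploids_per_pop,
                 frac_nonsynonymous = frac_nonsynonymous,
                 frac_ambiguous = frac_ambiguous,
                 frac_low_quality = frac_low_quality,
                 frac_missing = frac_missing,
                 contig_length = contig_length, seed = seed),
            class = "sim_config")
}

#' Simulate a linked-site variant table under a demographic model
#'
#' Each contig gets one structured-coalescent genealogy; mutation counts are
#' Poisson with intensity calibrated so the expected number of sites
#' surviving the standard filters (synonymous, complete, quality >= 20)
#' matches `mean_syn_snps_per_contig * n_contigs`. Mutations land on
#' branches proportionally to length, giving correlated site patterns
#' within a contig. Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A [variant_table()] with attributes `truth` (generating model,
#'   parameters and theta) attached.
#' @export
simulate_variants <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  model <- get_model(cfg$model)
  n_per_pop <- 2L * cfg$diploids_per_pop
  sample_sizes <- rep(n_per_pop, model$npops)
  dem <- model$demography(as.list(cfg$params))
  cdem <- compile_demography(dem)
  pops <- dem$sampled_demes
  sample_names <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(cfg$diploids_per_pop))))
  popmap <- stats::setNames(rep(pops, each = cfg$diploids_per_pop),
                            sample_names)
  n_ind <- length(sample_names)

  # intensity calibration: expected retained synonymous count ->
  # per-contig mutation parameter, inflated for the filtered fractions
  exp_unf <- expected_sfs(model, cfg$params, sample_sizes, fold = FALSE)
  total_m <- sfs_total(exp_unf)
  frac_syn <- 1 - cfg$frac_nonsynonymous - cfg$frac_ambiguous
  keep_frac <- frac_syn * (1 - cfg$frac_low_quality) * (1 - cfg$frac_missing)
  theta_target <- cfg$mean_syn_snps_per_contig * cfg$n_contigs /
    (total_m * keep_frac)
  theta_contig <- if (cfg$n_contigs > 0) theta_target / cfg$n_contigs else 0

  # per-mask dosage rows: chromosomes 2i-1, 2i belong to individual i
  n_tot <- sum(sample_sizes)
  masks_all <- 0:(2^n_tot - 1)
  dosage_tab <- matrix(0L, length(masks_all), n_ind)
  for (i in seq_len(n_ind)) {
    bit1 <- bitwShiftL(1L, 2L * i - 2L)
    bit2 <- bitwShiftL(1L, 2L * i - 1L)
    dosage_tab[, i] <- (bitwAnd(masks_all, bit1) > 0) +
      (bitwAnd(masks_all, bit2) > 0)
  }

  set.seed(cfg$seed)
  nucs <- c("A", "C", "G", "T")
  contig_rows <- vector("list", cfg$n_contigs)
  geno_rows <- vector("list", cfg$n_contigs)
  for (ci in seq_len(cfg$n_contigs)) {
    g <- sim_genealogy(cdem, sample_sizes)
    Ltot <- sum(g$lengths)
    nmut <- stats::rpois(1, theta_contig / 2 * Ltot)
    if (nmut == 0) next
    seg <- sample.int(length(g$lengths), nmut, replace = TRUE,
                      prob = g$lengths)
    site_masks <- g$masks[seg]
    dos <- dosage_tab[site_masks + 1L, , drop = FALSE]
    # site metadata
    pos <- sort(sample.int(cfg$contig_length, min(nmut, cfg$contig_length)))
    if (length(pos) < nmut)
      pos <- sort(c(pos, sample.int(cfg$contig_length, nmut - length(pos),
                                    replace = TRUE)))
    ref <- sample(nucs, nmut, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1L), character(1))
    ann <- sample(c("synonymous", "nonsynonymous", "ambiguous"), nmut,
                  replace = TRUE,
                  prob = c(frac_syn, cfg$frac_nonsynonymous,
                           cfg$frac_ambiguous))
    low_q <- stats::runif(nmut) < cfg$frac_low_quality
    qual <- ifelse(low_q, stats::runif(nmut, 2, 19.99),
                   20 + stats::rexp(nmut, 1 / 60))
    miss <- stats::runif(nmut) < cfg$frac_missing
    if (any(miss)) {
      who <- sample.int(n_ind, sum(miss), replace = TRUE)
      dos[cbind(which(miss), who)] <- NA_integer_
    }
    contig_rows[[ci]] <- data.frame(
      contig = sprintf("c%05d", ci), pos = pos, ref = ref, alt = alt,
      qual = round(qual, 2), annotation = ann, stringsAsFactors = FALSE)
    geno_rows[[ci]] <- dos
  }
  keep <- !vapply(contig_rows, is.null, logical(1))
  if (!any(keep)) {
    sites <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        qual = numeric(0), annotation = character(0))
    geno <- matrix(integer(0), 0, n_ind,
                   dimnames = list(NULL, sample_names))
  } else {
    sites <- do.call(rbind, contig_rows[keep])
    geno <- do.call(rbind, geno_rows[keep])
    colnames(geno) <- sample_names
  }
  out <- variant_table(sites, geno, popmap)
  attr(out, "truth") <- list(model = cfg$model, params = cfg$params,
                             theta = theta_target, config = cfg)
  out
}

#' Poisson-sampled spectrum from a model expectation
#'
#' Fast linkage-free test data: each unmasked cell is an independent
#' Poisson draw with mean `theta` times the model entry.
#'
#' @param expected Expected spectrum at `theta = 1` (a `joint_sfs`).
#' @param theta Positive scale factor.
#' @param seed Integer seed.
#' @return A `joint_sfs` of integer counts with the same shape, mask and
#'   folding.
#' @export
sample_sfs_poisson <- function(expected, theta, seed = 1) {
  stopifnot(theta >= 0)
  set.seed(seed)
  counts <- expected$counts
  live <- !expected$mask
  counts[live] <- stats::rpois(sum(live), theta * expected$counts[live])
  counts[!live] <- 0
  joint_sfs(counts, expected$pop_ids, mask = expected$mask,
            folded = expected$folded)
}
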