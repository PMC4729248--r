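# End-to-end inference pipeline: filter -> spectra -> two-population fits
# (gene-flow hypothesis tests) -> three-population fits -> corrected LRT ->
# bootstrap confidence intervals -> physical units.

#' Pipeline configuration
#'
#' @param pop_order Population order for the joint spectrum.
#' @param min_quality Phred quality threshold for [filter_variants()].
#' @param pair_models Models fitted to every population pair.
#' @param trio_models Three-population models to fit and rank.
#' @param fit_trio_gene_flow Also fit the trio model with Sinaloan/Sonoran
#'   migration?
#' @param n_starts Optimisation starts for full-data fits.
#' @param B Bootstrap replicates over contigs.
#' @param boot_starts Restarts per bootstrap refit.
#' @param pair_n_starts Starts for the pairwise isolation-model fits.
#' @param pair_gf_starts Starts for the warm-started pairwise gene-flow
#'   fits.
#' @param boot_optim Optimiser settings for the warm-started bootstrap
#'   refits (they start at the full-data optimum, so fewer simplex
#'   iterations suffice).
#' @param seed Master seed; all stage seeds derive from it.
#' @param anchor_years,generation_time Calibration for physical units.
#' @param outdir Optional directory for persisted stage artifacts.
#' @param control Engine numerical settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pop_order = c("MOJ", "SON", "SIN"),
                            min_quality = 20,
                            pair_models = c("split2_noMig", "split2_IM"),
                            trio_models = c("trio_5param", "trio_6param"),
                            fit_trio_gene_flow = FALSE,
                            n_starts = 20, B = 100, boot_starts = 4,
                            pair_n_starts = 8, pair_gf_starts = 2,
                            boot_optim = list(nm_maxit = 400,
                                              nm_reltol = 1e-8),
                            seed = 1,
                            anchor_years = 5.9e6, generation_time = 25,
                            outdir = NULL, control = list()) {
  structure(as.list(environment()), class = "pipeline_config")
}

persist <- function(outdir, name, writer) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writer(file.path(outdir, name))
}

#' Run the full demographic inference pipeline
#'
#' Stages, in order: variant filtering (quality, completeness, synonymous
#' annotation); folded joint AFS construction; two-population fits for every
#' population pair with and without gene flow (the isolation vs gene-flow
#' hypothesis tests); three-population fits; Godambe-corrected LRT between
#' the trio models; contig bootstrap confidence intervals on the winning
#' model; conversion to physical units. Deterministic given inputs, config
#' and seed.
#'
#' @param variants A [variant_table()], or a path to a VCF file.
#' @param annotation Annotation `data.frame` or TSV path (ignored when
#'   `variants` is already a `variant_table`).
#' @param popmap Named sample-to-population vector or TSV path (ignored when
#'   `variants` is already a `variant_table`).
#' @param config A [pipeline_config()].
#' @return A `run_report` with filter counts, the AFS summary, the model
#'   comparison tables, gene-flow and nested-model LRTs, bootstrap CIs and
#'   the physical-units table.
#' @export
run_full_inference <- function(variants, annotation = NULL, popmap = NULL,
                               config = pipeline_config()) {
  cfg <- config
  if (is.character(variants)) {
    if (is.character(annotation)) annotation <- read_annotation(annotation)
    if (is.character(popmap)) popmap <- read_popmap(popmap)
    variants <- read_vcf_variants(variants, annotation, popmap)
  }
  n_raw <- n_variants(variants)
  flt <- filter_variants(variants, min_quality = cfg$min_quality,
                         require_complete = TRUE, synonymous_only = TRUE)
  n_kept <- n_variants(flt)
  persist(cfg$outdir, "filtered.vcf",
          function(p) write_vcf_variants(flt, p))

  afs <- build_joint_sfs(flt, cfg$pop_order, fold = TRUE)
  persist(cfg$outdir, "joint_afs.fs", function(p) write_sfs(afs, p))

  # ---- two-population stage: gene-flow hypothesis tests per pair ----------
  # the isolation model is fitted with full multistarts; the gene-flow
  # variants are warm-started from it (standard nested-model practice)
  pairs <- utils::combn(cfg$pop_order, 2, simplify = FALSE)
  pair_results <- lapply(seq_along(pairs), function(pi) {
    pr <- pairs[[pi]]
    psfs <- suppressMessages(
      build_joint_sfs(subset_populations(flt, pr), pr, fold = TRUE))
    fits <- list()
    for (mn in cfg$pair_models) {
      fits[[mn]] <- tryCatch({
        if (mn == "split2_noMig" || is.null(fits$split2_noMig)) {
          fit_model(psfs, mn, n_starts = cfg$pair_n_starts,
                    seed = cfg$seed + 100 + pi, control = cfg$control)
        } else {
          m <- get_model(mn)
          init <- default_inits(m)
          shared <- intersect(names(init), names(fits$split2_noMig$params))
          init[shared] <- fits$split2_noMig$params[shared]
          init[startsWith(names(init), "M")] <- 0.5
          fit_model(psfs, mn, n_starts = cfg$pair_gf_starts, init = init,
                    seed = cfg$seed + 100 + pi, control = cfg$control)
        }
      }, error = function(e) {
        warning("pair ", paste(pr, collapse = "-"), " fit of ", mn,
                " failed: ", conditionMessage(e))
        NULL
      })
    }
    ok <- !vapply(fits, is.null, logical(1))
    cmp <- data.frame(
      model = names(fits)[ok],
      df = vapply(names(fits)[ok], function(m) get_model(m)$df, integer(1)),
      loglik = vapply(fits[ok], function(f) f$loglik, numeric(1)),
      theta = vapply(fits[ok], function(f) f$theta, numeric(1)),
      row.names = NULL)
    cmp <- cmp[order(-cmp$loglik), ]
    cmp$delta_ll <- cmp$loglik[1] - cmp$loglik
    gf <- NULL
    if (!is.null(fits$split2_IM) && !is.null(fits$split2_noMig)) {
      gf <- list(
        M_hat = fits$split2_IM$params[c("M12", "M21")],
        D = 2 * (fits$split2_IM$loglik - fits$split2_noMig$loglik))
    }
    list(pair = pr, comparison = cmp, gene_flow = gf, fits = fits)
  })
  names(pair_results) <- vapply(pairs, paste, character(1), collapse = "-")

  # hypothesis labels: isolation vs gene flow for the two focal pairs
  hyp <- list()
  for (lbl in list(c("H-MS", "MOJ-SON"), c("H-SS", "SON-SIN"))) {
    pr <- pair_results[[lbl[2]]]
    if (is.null(pr)) pr <- pair_results[[paste(rev(strsplit(lbl[2], "-")[[1]]),
                                               collapse = "-")]]
    if (!is.null(pr) && !is.null(pr$gene_flow))
      hyp[[lbl[1]]] <- list(pair = pr$pair, M_hat = pr$gene_flow$M_hat,
                            D = pr$gene_flow$D)
  }

  # ---- three-population stage ---------------------------------------------
  trio_models <- cfg$trio_models
  if (cfg$fit_trio_gene_flow) trio_models <- c(trio_models, "trio_6param_IM")
  trio_cmp <- compare_models(afs, trio_models, n_starts = cfg$n_starts,
                             seed = cfg$seed + 200, control = cfg$control)
  trio_fits <- attr(trio_cmp, "fits")
  best_name <- trio_cmp$model[1]
  best_fit <- trio_fits[[best_name]]

  # ---- bootstrap ----------------------------------------------------------
  boots <- bootstrap_by_contig(flt, B = cfg$B, seed = cfg$seed + 300,
                               pop_order = cfg$pop_order, fold = TRUE)

  lrt <- NULL
  if (all(c("trio_5param", "trio_6param") %in% trio_models) &&
      !is.null(trio_fits$trio_6param) && !is.null(trio_fits$trio_5param)) {
    lrt <- godambe_adjusted_lrt(trio_fits$trio_6param,
                                trio_fits$trio_5param,
                                afs, boots, control = cfg$control)
  }
  lrt_gf <- NULL
  if (cfg$fit_trio_gene_flow && !is.null(trio_fits$trio_6param_IM) &&
      !is.null(trio_fits$trio_6param)) {
    lrt_gf <- godambe_adjusted_lrt(trio_fits$trio_6param_IM,
                                   trio_fits$trio_6param,
                                   afs, boots, control = cfg$control)
  }

  bf <- bootstrap_fits(boots, best_fit, n_starts = cfg$boot_starts,
                       seed = cfg$seed + 400, control = cfg$control,
                       optim_control = cfg$boot_optim)
  ci_scaled <- param_ci(bf[, c(get_model(best_name)$params, "theta"),
                           drop = FALSE])

  # ---- physical units -----------------------------------------------------
  phys <- calibrate_physical(best_fit$params, best_fit$theta, best_name,
                             anchor_years = cfg$anchor_years,
                             generation_time = cfg$generation_time)
  phys_boot <- convert_bootstrap(bf, phys$muL, best_name,
                                 generation_time = cfg$generation_time)
  ci_phys <- param_ci(phys_boot)
  phys_table <- data.frame(
    parameter = c("Na", names(phys$N), names(phys$T_years)),
    estimate = unname(c(phys$Na, phys$N, phys$T_years)))
  phys_table <- merge(phys_table, ci_phys[, c("parameter", "low", "high")],
                      by = "parameter", sort = FALSE)

  report <- structure(list(
    n_raw = n_raw, n_kept = n_kept,
    afs = afs,
    pair_results = pair_results,
    hypotheses = hyp,
    trio_comparison = trio_cmp,
    best_model = best_name,
    best_fit = best_fit,
    lrt_nested = lrt,
    lrt_gene_flow = lrt_gf,
    bootstrap = bf,
    ci_scaled = ci_scaled,
    physical = phys,
    physical_table = phys_table,
    config = cfg,
    seed = cfg$seed), class = "run_report")
  persist(cfg$outdir, "report.json", function(p) write_report_json(report, p))
  persist(cfg$outdir, "report.md", function(p) write_report_md(report, p))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d/%d variants retained; best model %s (ll %.2f)\n",
              x$n_kept, x$n_raw, x$best_model, x$best_fit$loglik))
  if (!is.null(x$lrt_nested)) print(x$lrt_nested)
  for (h in names(x$hypotheses)) {
    hh <- x$hypotheses[[h]]
    cat(sprintf("  %s (%s): M_hat = (%.4g, %.4g)\n", h,
                paste(hh$pair, collapse = "/"), hh$M_hat[1], hh$M_hat[2]))
  }
  cat("physical parameters:\n")
  print(x$physical_table, row.names = FALSE)
  invisible(x)
}

report_as_list <- function(x) {
  list(
    filters = list(n_raw = x$n_raw, n_kept = x$n_kept),
    afs = list(shape = dim(x$afs$counts), folded = x$afs$folded,
               total = sfs_total(x$afs), pop_ids = x$afs$pop_ids),
    hypotheses = lapply(x$hypotheses, function(h)
      list(pair = h$pair, M_hat = as.list(h$M_hat), D = h$D)),
    trio_comparison = x$trio_comparison[, c("model", "df", "loglik",
                                            "delta_ll", "theta")],
    best_model = x$best_model,
    best_params = as.list(x$best_fit$params),
    theta = x$best_fit$theta,
    loglik = x$best_fit$loglik,
    lrt_nested = if (!is.null(x$lrt_nested)) unclass(x$lrt_nested),
    lrt_gene_flow = if (!is.null(x$lrt_gene_flow)) unclass(x$lrt_gene_flow),
    ci_scaled = x$ci_scaled,
    physical_table = x$physical_table,
    seed = x$seed,
    config = x$config[setdiff(names(x$config), c("outdir", "control"))])
}

write_report_json <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

write_report_md <- function(report, path) {
  x <- report
  lines <- c(
    "# Demographic inference report", "",
    sprintf("- Variants: %d raw, %d retained after filters", x$n_raw,
            x$n_kept),
    sprintf("- Folded joint AFS: %s, %g segregating sites",
            paste(dim(x$afs$counts), collapse = "x"), sfs_total(x$afs)),
    "", "## Gene-flow hypotheses (pairwise)", "")
  for (h in names(x$hypotheses)) {
    hh <- x$hypotheses[[h]]
    lines <- c(lines, sprintf("- %s (%s): M_hat = (%.4g, %.4g), D = %.3f",
                              h, paste(hh$pair, collapse = "/"),
                              hh$M_hat[1], hh$M_hat[2], hh$D))
  }
  lines <- c(lines, "", "## Three-population model ranking", "",
             utils::capture.output(print(
               x$trio_comparison[, c("model", "df", "loglik", "delta_ll")],
               row.names = FALSE)))
  if (!is.null(x$lrt_nested))
    lines <- c(lines, "", sprintf(
      "Corrected LRT (%s vs %s): D_adj = %.3f, df = %d, p = %.4g",
      x$lrt_nested$full_model, x$lrt_nested$nested_model,
      x$lrt_nested$D_adj, x$lrt_nested$df, x$lrt_nested$p_value))
  lines <- c(lines, "", "## Physical parameters (95% bootstrap CI)", "",
             utils::capture.output(print(x$physical_table,
                                         row.names = FALSE)),
             "", sprintf("Seed: %d", x$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Marginal-spectrum comparison plot
#'
#' Draws, for one population pair, the observed marginal spectrum, the model
#' marginal and the Anscombe residuals (model minus data), in the style of
#' the standard joint-AFS diagnostic panels.
#'
#' @param model_sfs Model spectrum scaled by theta (`joint_sfs`).
#' @param data Observed spectrum.
#' @param pop_a,pop_b Pair to marginalise onto.
#' @export
plot_pair_residuals <- function(model_sfs, data, pop_a, pop_b) {
  md <- marginalize_pair(model_sfs, pop_a, pop_b)
  dd <- marginalize_pair(data, pop_a, pop_b)
  res <- anscombe_residuals(md, dd)
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  draw <- function(a, main, col) {
    graphics::image(0:(nrow(a) - 1), 0:(ncol(a) - 1),
                    log10(pmax(a, 1e-3)),
                    xlab = pop_a, ylab = pop_b, main = main, col = col)
  }
  pal <- grDevices::hcl.colors(25, "YlOrRd", rev = TRUE)
  draw(dd$counts, "data (log10)", pal)
  draw(md$counts, "model (log10)", pal)
  graphics::image(0:(nrow(res) - 1), 0:(ncol(res) - 1), res,
                  xlab = pop_a, ylab = pop_b, main = "Anscombe residuals",
                  col = grDevices::hcl.colors(25, "Blue-Red"))
  invisible(res)
}
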