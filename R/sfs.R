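#' Joint site frequency spectrum
#'
#' A `joint_sfs` holds a k-dimensional array of site counts (or real-valued
#' expectations) indexed by the per-population derived/minor allele count, a
#' logical mask of cells excluded from likelihood computations, a folding flag
#' and the ordered population labels. Cell `(i1, ..., ik)` (0-based allele
#' counts, 1-based array indices) counts variant sites whose summed alternate
#' allele dosage in population j is `ij`. The fixed corners (all-zero and
#' all-n) are always masked: they carry no information about polymorphism.
#'
#' @param counts Numeric k-dimensional array of shape `(n1+1, ..., nk+1)`.
#' @param pop_ids Character vector of population labels, one per dimension.
#' @param mask Logical array of the same shape; `TRUE` marks excluded cells.
#'   Defaults to masking only the two corners.
#' @param folded Logical; is this a minor-allele (folded) spectrum?
#'
#' @return An object of class `joint_sfs`.
#' @export
joint_sfs <- function(counts, pop_ids, mask = NULL, folded = FALSE) {
  counts <- as.array(counts)
  if (is.null(dim(counts))) dim(counts) <- length(counts)
  if (length(pop_ids) != length(dim(counts)))
    stop("pop_ids must have one label per spectrum dimension")
  if (is.null(mask)) {
    mask <- array(FALSE, dim(counts))
    mask[corner_index(dim(counts), "zero")] <- TRUE
    mask[corner_index(dim(counts), "full")] <- TRUE
  }
  mask <- as.array(mask)
  if (is.null(dim(mask))) dim(mask) <- length(mask)
  if (!identical(dim(mask), dim(counts)))
    stop("mask and counts must have identical shape")
  # corners are non-informative and always masked
  mask[corner_index(dim(counts), "zero")] <- TRUE
  mask[corner_index(dim(counts), "full")] <- TRUE
  if (any(counts[!mask] < 0)) stop("unmasked spectrum entries must be >= 0")
  structure(list(counts = counts, mask = mask, folded = folded,
                 pop_ids = as.character(pop_ids)),
            class = "joint_sfs")
}

corner_index <- function(dims, which = c("zero", "full")) {
  which <- match.arg(which)
  idx <- if (which == "zero") rep(1L, length(dims)) else dims
  matrix(idx, nrow = 1L)
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("joint_sfs: %s spectrum, shape (%s), pops [%s]\n",
              if (x$folded) "folded" else "unfolded",
              paste(dim(x$counts), collapse = " x "),
              paste(x$pop_ids, collapse = ", ")))
  cat(sprintf("  unmasked mass: %.6g over %d cells (%d masked)\n",
              sfs_total(x), sum(!x$mask), sum(x$mask)))
  invisible(x)
}

#' Total unmasked mass of a spectrum
#' @param sfs A `joint_sfs`.
#' @return Sum of counts over unmasked cells.
#' @export
sfs_total <- function(sfs) sum(sfs$counts[!sfs$mask])

#' Sample sizes (chromosomes per population) implied by a spectrum's shape
#' @param sfs A `joint_sfs`.
#' @return Integer vector of haploid sample sizes.
#' @export
sfs_sample_sizes <- function(sfs) dim(sfs$counts) - 1L

# 0-based index grid: column j holds the allele count along dimension j for
# every cell of the array, in R (column-major) storage order.
sfs_index_grid <- function(dims) {
  g <- do.call(expand.grid, lapply(dims, function(d) 0:(d - 1L)))
  as.matrix(g)
}

#' Fold a joint spectrum onto minor-allele counts
#'
#' Each cell `c` and its complement `(n1-i1, ..., nk-ik)` are summed into
#' whichever of the two has total allele count at most half the total sample
#' size; the other member of the pair is zeroed and masked. When the total is
#' exactly half (a tie), the pair is counted once in the lexicographically
#' smaller cell; a self-complementary tie cell keeps its own count. Masked
#' cells propagate: a folded cell is masked only if both contributors were
#' masked. Folding an already folded spectrum is a no-op with a warning.
#'
#' @param sfs A `joint_sfs`.
#' @return The folded `joint_sfs`; total unmasked mass is conserved.
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) {
    warning("spectrum is already folded; returning unchanged")
    return(sfs)
  }
  dims <- dim(sfs$counts)
  fp <- fold_plan(dims)
  kept <- fp$kept
  comp <- fp$comp

  counts <- as.vector(sfs$counts)
  masked <- as.vector(sfs$mask)
  # treat masked contributions as zero so mass bookkeeping stays honest
  live <- counts
  live[masked] <- 0

  out <- numeric(length(counts))
  self_pair <- comp[kept] == kept
  out[kept] <- live[kept] + ifelse(self_pair, 0, live[comp[kept]])
  out_mask <- rep(TRUE, length(counts))
  out_mask[kept] <- masked[kept] & masked[comp[kept]]

  joint_sfs(array(out, dims), sfs$pop_ids,
            mask = array(out_mask, dims), folded = TRUE)
}

#' Build a joint SFS from a variant table
#'
#' Tabulates the summed alternate-allele dosage per population for every
#' record. Records monomorphic in the sample (summed dosage 0 or twice the
#' number of diploids) fall into the always-masked corner cells, so they are
#' retained for bookkeeping but excluded from likelihoods.
#'
#' @param variants A [variant_table()]; all genotypes must be complete.
#' @param pop_order Character vector ordering the populations along the
#'   spectrum dimensions; must cover every population in the table.
#' @param fold Fold the spectrum onto minor-allele counts?
#' @return A `joint_sfs` whose unmasked mass equals the number of
#'   polymorphic-in-sample records.
#' @export
build_joint_sfs <- function(variants, pop_order, fold = TRUE) {
  stopifnot(inherits(variants, "variant_table"))
  pops <- variants$popmap
  if (!setequal(pop_order, unique(pops)))
    stop("pop_order must list exactly the populations present: ",
         paste(unique(pops), collapse = ", "))
  if (anyNA(variants$geno))
    stop("build_joint_sfs requires complete genotypes; run filter_variants ",
         "with require_complete = TRUE first")
  dims <- integer(length(pop_order))
  idx_list <- vector("list", length(pop_order))
  nrec <- nrow(variants$sites)
  for (j in seq_along(pop_order)) {
    cols <- which(pops == pop_order[j])
    dims[j] <- 2L * length(cols) + 1L
    idx_list[[j]] <- if (nrec > 0)
      rowSums(variants$geno[, cols, drop = FALSE]) else integer(0)
  }
  counts <- array(0, dims)
  if (nrec > 0) {
    mult <- c(1, cumprod(dims[-length(dims)]))
    lin <- as.vector(do.call(cbind, idx_list) %*% mult) + 1L
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(tab, dims)
  }
  n_mono <- counts[corner_index(dims, "zero")] + counts[corner_index(dims, "full")]
  if (n_mono > 0)
    message(sprintf("build_joint_sfs: %d monomorphic record(s) routed to masked corners",
                    n_mono))
  out <- joint_sfs(counts, pop_order, folded = FALSE)
  if (fold) out <- fold_sfs(out)
  out
}

#' Marginal two-population spectrum
#'
#' Sums the joint spectrum over all dimensions other than the two requested
#' populations. A marginal cell is masked only if every contributing cell was
#' masked; total unmasked mass is conserved for unfolded spectra (folded
#' spectra marginalise the stored array as-is).
#'
#' @param sfs A `joint_sfs` with at least two dimensions.
#' @param pop_a,pop_b Labels of the two populations to keep, in order.
#' @return A 2-dimensional `joint_sfs`.
#' @export
marginalize_pair <- function(sfs, pop_a, pop_b) {
  ia <- match(pop_a, sfs$pop_ids)
  ib <- match(pop_b, sfs$pop_ids)
  if (is.na(ia) || is.na(ib))
    stop("unknown population label; available: ",
         paste(sfs$pop_ids, collapse = ", "))
  live <- sfs$counts
  live[sfs$mask] <- 0
  m <- apply(live, c(ia, ib), sum)
  allmask <- apply(sfs$mask, c(ia, ib), all)
  joint_sfs(m, c(pop_a, pop_b), mask = allmask, folded = sfs$folded)
}

#' Anscombe residuals between a model and a data spectrum
#'
#' Variance-stabilised residuals for Poisson counts,
#' `r = 1.5 * (data^(2/3) - model^(2/3)) / model^(1/6)`, evaluated per
#' unmasked cell. The default sign convention `"model_minus_data"` negates
#' this so that cells where the model exceeds the data are positive.
#'
#' @param model `joint_sfs` of model expectations (already scaled by theta);
#'   entries must be positive on unmasked cells.
#' @param data `joint_sfs` of observed counts with identical shape, mask and
#'   folding.
#' @param sign Residual orientation.
#' @return Numeric array of residuals; masked cells are `NA`.
#' @export
anscombe_residuals <- function(model, data,
                               sign = c("model_minus_data", "data_minus_model")) {
  sign <- match.arg(sign)
  if (!identical(dim(model$counts), dim(data$counts)))
    stop("model and data spectra have different shapes")
  if (!identical(model$mask, data$mask) || !identical(model$folded, data$folded))
    stop("model and data spectra must share mask and folding")
  live <- !model$mask
  if (any(model$counts[live] <= 0))
    stop("model entries must be > 0 on unmasked cells")
  r <- array(NA_real_, dim(model$counts))
  r[live] <- 1.5 * (data$counts[live]^(2 / 3) - model$counts[live]^(2 / 3)) /
    model$counts[live]^(1 / 6)
  if (sign == "model_minus_data") r <- -r
  r
}

#' Write a joint SFS to the flat text format
#'
#' Line 1: shape, `folded`/`unfolded`, and quoted population labels.
#' Line 2: counts in row-major (last index fastest) order.
#' Line 3: mask bits (1 = masked) in the same order.
#'
#' @param sfs A `joint_sfs`.
#' @param path Output file path.
#' @export
write_sfs <- function(sfs, path) {
  dims <- dim(sfs$counts)
  header <- paste(c(dims, if (sfs$folded) "folded" else "unfolded",
                    sprintf('"%s"', sfs$pop_ids)), collapse = " ")
  rowmajor <- function(a) as.vector(aperm(a, rev(seq_along(dims))))
  lines <- c(header,
             paste(format(rowmajor(sfs$counts), digits = 17, trim = TRUE),
                   collapse = " "),
             paste(as.integer(rowmajor(sfs$mask)), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a joint SFS from the flat text format
#' @param path File written by [write_sfs()] (comment lines starting with
#'   `#` are skipped).
#' @return A `joint_sfs`.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 3) stop("malformed SFS file: expected 3 content lines")
  toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  ndim <- which(is.na(suppressWarnings(as.integer(toks))))[1] - 1L
  dims <- as.integer(toks[seq_len(ndim)])
  folded <- identical(toks[ndim + 1L], "folded")
  pop_ids <- gsub('"', "", toks[-seq_len(ndim + 1L)])
  if (length(pop_ids) == 0) pop_ids <- paste0("pop", seq_len(ndim))
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  bits <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  if (length(vals) != prod(dims) || length(bits) != prod(dims))
    stop("malformed SFS file: entry count does not match shape")
  colmajor <- function(v) aperm(array(v, rev(dims)), rev(seq_along(dims)))
  joint_sfs(colmajor(vals), pop_ids, mask = colmajor(bits) > 0, folded = folded)
}
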