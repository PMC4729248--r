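#' Per-site variant table
#'
#' Container for biallelic SNP genotypes used to build joint spectra. Sites
#' carry a contig identifier (the bootstrap resampling unit), a 1-based
#' position, REF/ALT nucleotides, a Phred-scaled site quality and a functional
#' annotation class; genotypes are stored as the per-sample alternate-allele
#' dosage (0, 1, 2, or `NA` for missing).
#'
#' @param sites `data.frame` with columns `contig`, `pos`, `ref`, `alt`,
#'   `qual`, `annotation` (one of `synonymous`, `nonsynonymous`, `other`,
#'   `ambiguous`).
#' @param geno Integer matrix, sites x samples, entries in `{0, 1, 2, NA}`;
#'   column names are sample identifiers.
#' @param popmap Named character vector mapping sample name to population
#'   label.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, popmap) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(sites) != nrow(geno))
    stop("sites and geno must have the same number of records")
  if (is.null(colnames(geno)) || !all(colnames(geno) %in% names(popmap)))
    stop("every geno column must be named and present in popmap")
  popmap <- popmap[colnames(geno)]
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("genotype dosages must be 0, 1, 2 or NA")
  sites$annotation <- as.character(sites$annotation)
  known <- c("synonymous", "nonsynonymous", "other", "ambiguous")
  if (!all(sites$annotation %in% known))
    stop("annotation classes must be one of: ", paste(known, collapse = ", "))
  structure(list(sites = sites, geno = geno, popmap = popmap),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites on %d contig(s), %d samples (%s)\n",
              nrow(x$sites), length(unique(x$sites$contig)), ncol(x$geno),
              paste(sprintf("%s:%d", names(table(x$popmap)), table(x$popmap)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of records in a variant table
#' @param x A `variant_table`.
#' @export
n_variants <- function(x) nrow(x$sites)

subset_variants <- function(x, keep) {
  variant_table(x$sites[keep, , drop = FALSE],
                x$geno[keep, , drop = FALSE], x$popmap)
}

#' Restrict a variant table to a subset of populations
#'
#' Drops the samples of all other populations; records that become
#' monomorphic within the retained populations are kept (they land in the
#' masked spectrum corners downstream).
#'
#' @param x A `variant_table`.
#' @param pops Population labels to keep.
#' @return A `variant_table` over the retained samples.
#' @export
subset_populations <- function(x, pops) {
  cols <- names(x$popmap)[x$popmap %in% pops]
  if (length(cols) == 0) stop("no samples in the requested populations")
  variant_table(x$sites, x$geno[, cols, drop = FALSE], x$popmap[cols])
}

#' Filter variant records for demographic inference
#'
#' Applies, in order: rejection of malformed dosages (anything outside
#' 0/1/2/missing was already rejected at construction), a Phred site-quality
#' threshold, a complete-genotype requirement, and restriction to sites
#' unambiguously annotated as synonymous. Record order is preserved and the
#' retained count is reported.
#'
#' @param raw A `variant_table`.
#' @param min_quality Minimum Phred-scaled site quality (default 20).
#' @param require_complete Drop records with any missing genotype?
#' @param synonymous_only Keep only records annotated `synonymous`?
#' @return The filtered `variant_table`.
#' @export
filter_variants <- function(raw, min_quality = 20, require_complete = TRUE,
                            synonymous_only = TRUE) {
  stopifnot(inherits(raw, "variant_table"), is.finite(min_quality))
  keep <- raw$sites$qual >= min_quality
  if (require_complete) keep <- keep & !apply(is.na(raw$geno), 1L, any)
  if (synonymous_only) keep <- keep & raw$sites$annotation == "synonymous"
  out <- subset_variants(raw, keep)
  message(sprintf("filter_variants: retained %d of %d records (quality >= %g%s%s)",
                  sum(keep), length(keep), min_quality,
                  if (require_complete) ", complete genotypes" else "",
                  if (synonymous_only) ", synonymous only" else ""))
  if (sum(keep) == 0) warning("no records passed the filters")
  out
}

#' Read a sample-to-population map
#' @param path Two-column TSV: sample, population (no header).
#' @return Named character vector sample -> population.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "pop"),
                          colClasses = "character")
  stats::setNames(df$pop, df$sample)
}

#' Read a per-site annotation table
#' @param path Three-column TSV: contig, position, class (no header), the
#'   summary format produced by transcript-annotation tools such as SNPdat.
#' @return `data.frame` with columns `contig`, `pos`, `annotation`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "pos", "annotation"),
                          colClasses = c("character", "integer", "character"))
  df
}

#' Read biallelic SNPs from a VCF into a variant table
#'
#' Parses standard VCF 4.x columns with `vcfR`; site quality is taken from
#' `QUAL` and dosages from the `GT` field. Non-biallelic or non-SNP records
#' are rejected with a logged count. Sites absent from the annotation table
#' are classed `other`.
#'
#' @param vcf_path Path to an (uncompressed or gzipped) VCF.
#' @param annotation `data.frame` from [read_annotation()], or `NULL` to
#'   class every site `other`.
#' @param popmap Named character vector from [read_popmap()].
#' @return A `variant_table`.
#' @export
read_vcf_variants <- function(vcf_path, annotation, popmap) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt[, -1, drop = FALSE]
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_rej <- sum(!is_snp)
  if (n_rej > 0)
    message(sprintf("read_vcf_variants: rejected %d non-biallelic-SNP record(s)",
                    n_rej))
  fix <- fix[is_snp, , drop = FALSE]
  gt_raw <- gt_raw[is_snp, , drop = FALSE]
  # GT prefix of the colon-separated FORMAT payload -> dosage
  gtfield <- sub(":.*$", "", gt_raw)
  dosage <- array(NA_integer_, dim(gtfield))
  dosage[gtfield %in% c("0/0", "0|0")] <- 0L
  dosage[gtfield %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gtfield %in% c("1/1", "1|1")] <- 2L
  colnames(dosage) <- colnames(gt_raw)
  sites <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      qual = as.numeric(fix$QUAL),
                      annotation = "other", stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    key <- paste(sites$contig, sites$pos)
    akey <- paste(annotation$contig, annotation$pos)
    hit <- match(key, akey)
    sites$annotation[!is.na(hit)] <- annotation$annotation[hit[!is.na(hit)]]
  }
  variant_table(sites, dosage, popmap)
}

#' Write a variant table as a minimal VCF 4.2 file
#' @param x A `variant_table`.
#' @param path Output path.
#' @export
write_vcf_variants <- function(x, path) {
  gt <- matrix("./.", nrow(x$geno), ncol(x$geno))
  gt[which(x$geno == 0L)] <- "0/0"
  gt[which(x$geno == 1L)] <- "0/1"
  gt[which(x$geno == 2L)] <- "1/1"
  body <- paste(x$sites$contig, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                format(x$sites$qual, trim = TRUE), "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(x$geno)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the three-column annotation TSV matching a variant table
#' @param x A `variant_table`.
#' @param path Output path.
#' @export
write_annotation <- function(x, path) {
  utils::write.table(x$sites[, c("contig", "pos", "annotation")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
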