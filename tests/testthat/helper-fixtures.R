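# Shared fixtures: small hand-written variant tables and converters used
# across the suite. Everything is built in code; nothing is read from disk.

toy_popmap <- function() {
  stats::setNames(rep(c("MOJ", "SON", "SIN"), each = 2),
                  c("MOJ_1", "MOJ_2", "SON_1", "SON_2", "SIN_1", "SIN_2"))
}

# n records with customisable fields; dosage rows given as a list of
# length-6 integer vectors
toy_variants <- function(dosages,
                         contig = sprintf("c%03d", seq_along(dosages)),
                         qual = rep(99, length(dosages)),
                         annotation = rep("synonymous", length(dosages))) {
  geno <- do.call(rbind, dosages)
  colnames(geno) <- names(toy_popmap())
  sites <- data.frame(contig = contig, pos = seq_along(dosages),
                      ref = "A", alt = "G", qual = qual,
                      annotation = annotation, stringsAsFactors = FALSE)
  variant_table(sites, geno, toy_popmap())
}

# Deterministic variant table realising a given 3-population count
# spectrum, one record per site. contigs_of(i) assigns site i to a contig;
# the default gives every site its own contig (fully unlinked data).
variants_from_sfs <- function(counts, contigs_of = function(i)
                                sprintf("c%05d", i)) {
  dims <- dim(counts)
  grid <- as.matrix(do.call(expand.grid, lapply(dims, function(d) 0:(d - 1))))
  dosage_of <- function(i) c(min(i, 2L), max(i - 2L, 0L))
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    k <- counts[cell]
    if (is.na(k) || k < 1) next
    dos <- unlist(lapply(grid[cell, ], dosage_of))
    rows <- c(rows, replicate(round(k), dos, simplify = FALSE))
  }
  toy_variants(rows, contig = vapply(seq_along(rows), contigs_of,
                                     character(1)))
}

suppress_all <- function(expr) suppressWarnings(suppressMessages(expr))
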