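# Demography descriptions
#
# A demography is a list of epochs ordered from the present backwards in
# time. Each epoch carries the active demes with their sizes relative to the
# ancestral reference size, a backward migration rate matrix, a duration in
# units of 2*Na generations, and the deme mergers applied at the epoch's
# (pastward) end. The final epoch has infinite duration and a single deme.
# The same object drives the deterministic expectation engine, the
# Monte-Carlo oracle and the linked-site data simulator.

#' Construct a demography description
#'
#' @param epochs List of epochs (present first). Each epoch is a list with
#'   `duration` (time in units of 2*Na generations; `Inf` for the last),
#'   `demes` (named numeric vector of relative sizes nu), `migration`
#'   (named square matrix of scaled backward migration rates `M[a, b]` =
#'   2*Na*m, the rate at which an `a` lineage traces back to deme `b`;
#'   `NULL` for none), and `merges` (named character vector mapping source
#'   deme -> destination deme applied at the epoch end; destination may be a
#'   new deme whose size is given in the next epoch).
#' @param sampled_demes Character vector: present-day demes carrying samples,
#'   in spectrum dimension order.
#' @return An object of class `demography`.
#' @export
demography <- function(epochs, sampled_demes) {
  stopifnot(length(epochs) >= 1)
  last <- epochs[[length(epochs)]]
  if (!is.infinite(last$duration) || length(last$demes) != 1L)
    stop("final epoch must have infinite duration and a single (ancestral) deme")
  for (e in epochs) {
    if (any(e$demes <= 0)) stop("deme sizes must be positive")
    if (e$duration < 0) stop("epoch durations must be non-negative")
    if (!is.null(e$migration)) {
      if (any(e$migration < 0)) stop("migration rates must be non-negative")
      if (!all(rownames(e$migration) %in% names(e$demes)))
        stop("migration matrix demes must be active in the epoch")
    }
  }
  if (!all(sampled_demes %in% names(epochs[[1]]$demes)))
    stop("sampled demes must be active in the first epoch")
  structure(list(epochs = epochs, sampled_demes = sampled_demes),
            class = "demography")
}

# TRUE when no epoch carries a positive migration rate
demography_is_tree <- function(dem) {
  !any(vapply(dem$epochs, function(e)
    !is.null(e$migration) && any(e$migration > 0), logical(1)))
}
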