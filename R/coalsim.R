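# Structured-coalescent genealogy simulation.
#
# Shared backend for the Monte-Carlo expectation oracle and the linked-site
# data generator. Lineages are tracked as bitmasks over the sampled
# chromosomes, so a simulated genealogy can be interrogated either for the
# per-population descendant configuration (for the SFS) or for the exact
# descendant chromosome set (for genotype assignment).

# population index of each sampled chromosome, in mask bit order
chrom_pops <- function(sample_sizes) rep(seq_along(sample_sizes), sample_sizes)

# lookup: bitmask + 1 -> class vid (column-major linear index over dims n+1)
mask_vid_table <- function(sample_sizes) {
  n_tot <- sum(sample_sizes)
  if (n_tot > 30) stop("bitmask genealogies support at most 30 sampled chromosomes")
  pops <- chrom_pops(sample_sizes)
  dims <- sample_sizes + 1L
  mult <- c(1, cumprod(dims[-length(dims)]))
  masks <- 0:(2^n_tot - 1)
  vid <- integer(length(masks))
  acc <- numeric(length(masks))
  for (b in seq_len(n_tot)) {
    bit <- bitwAnd(masks, bitwShiftL(1L, b - 1L)) > 0
    acc <- acc + bit * mult[pops[b]]
  }
  as.integer(acc + 1)
}

# Pre-resolve deme names to integer indices per epoch, with the relabelling
# applied at each epoch boundary, so the per-event simulation loop is free
# of name lookups.
compile_demography <- function(dem) {
  eps <- lapply(dem$epochs, function(e) {
    nd <- names(e$demes)
    mf <- integer(0); mt <- integer(0); mr <- numeric(0)
    if (!is.null(e$migration)) {
      for (a in rownames(e$migration)) for (b in colnames(e$migration)) {
        if (a == b || e$migration[a, b] <= 0) next
        mf <- c(mf, match(a, nd)); mt <- c(mt, match(b, nd))
        mr <- c(mr, e$migration[a, b])
      }
    }
    list(duration = e$duration, nu = unname(e$demes), nd = length(nd),
         names = nd, mig_from = mf, mig_to = mt, mig_rate = mr)
  })
  for (i in seq_along(eps)[-length(eps)]) {
    from <- eps[[i]]$names
    m <- dem$epochs[[i]]$merges
    dest <- ifelse(from %in% names(m), unname(m[from]), from)
    eps[[i]]$trans <- match(dest, eps[[i + 1]]$names)
    if (anyNA(eps[[i]]$trans))
      stop("demography error: deme '",
           from[is.na(eps[[i]]$trans)][1], "' has no successor deme")
  }
  list(epochs = eps,
       start_demes = match(dem$sampled_demes, eps[[1]]$names))
}

# Simulate one genealogy under a compiled demography; returns parallel
# vectors of branch segments: the descendant bitmask and the segment length
# (time in units of 2*Na generations).
sim_genealogy <- function(cdem, sample_sizes) {
  pops <- chrom_pops(sample_sizes)
  n_tot <- sum(sample_sizes)
  masks <- bitwShiftL(1L, seq_len(n_tot) - 1L)
  demes <- cdem$start_demes[pops]
  seg_masks <- integer(2L * n_tot)
  seg_len <- numeric(2L * n_tot)
  nseg <- 0L
  alive_at <- numeric(n_tot)  # time each current lineage segment started

  t_now <- 0
  for (e in cdem$epochs) {
    t_end <- t_now + e$duration
    nmig <- length(e$mig_rate)
    repeat {
      if (length(masks) <= 1L) break
      k_d <- tabulate(demes, e$nd)
      coal_rates <- k_d * (k_d - 1) / 2 / e$nu
      rates <- if (nmig > 0) c(coal_rates, k_d[e$mig_from] * e$mig_rate)
               else coal_rates
      tot <- sum(rates)
      if (tot <= 0) break
      dt <- stats::rexp(1, tot)
      if (t_now + dt > t_end) break
      t_now <- t_now + dt
      ev <- sample.int(length(rates), 1L, prob = rates)
      if (ev <= e$nd) {
        pair <- sample(which(demes == ev), 2L)
        i <- pair[1]; j <- pair[2]
        seg_masks[nseg + 1L] <- masks[i]
        seg_len[nseg + 1L] <- t_now - alive_at[i]
        seg_masks[nseg + 2L] <- masks[j]
        seg_len[nseg + 2L] <- t_now - alive_at[j]
        nseg <- nseg + 2L
        masks[i] <- bitwOr(masks[i], masks[j])
        alive_at[i] <- t_now
        masks <- masks[-j]; demes <- demes[-j]; alive_at <- alive_at[-j]
      } else {
        mi <- ev - e$nd
        from <- e$mig_from[mi]
        cand <- which(demes == from)
        li <- if (length(cand) == 1L) cand else sample(cand, 1L)
        demes[li] <- e$mig_to[mi]
      }
    }
    if (length(masks) <= 1L) break
    t_now <- t_end
    if (!is.null(e$trans)) demes <- e$trans[demes]
  }
  list(masks = seg_masks[seq_len(nseg)], lengths = seg_len[seq_len(nseg)])
}

#' Monte-Carlo estimate of the expected joint SFS
#'
#' Independent structured-coalescent validation oracle for [expected_sfs()]:
#' simulates genealogies under the model's demography and averages the
#' branch length subtending each allele configuration, on the same
#' `theta = 1` scale as the deterministic engine. Returns per-cell Monte
#' Carlo standard errors so agreement can be asserted in units of SE.
#'
#' @inheritParams expected_sfs
#' @param n_replicates Number of simulated genealogies (>= 1e4 recommended
#'   for validation use).
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @return A `joint_sfs` whose entries are the Monte-Carlo means, with an
#'   `se` attribute holding the same-shaped array of standard errors.
#' @export
mc_expected_sfs <- function(model, params, sample_sizes = NULL,
                            n_replicates = 1e4, fold = TRUE, seed = 1) {
  if (is.character(model)) model <- get_model(model)
  if (is.null(names(params)))
    params <- stats::setNames(as.numeric(params), model$params)
  if (is.null(sample_sizes)) sample_sizes <- rep(4L, model$npops)
  sample_sizes <- as.integer(sample_sizes)
  dem <- model$demography(as.list(params))
  cdem <- compile_demography(dem)
  vid_tab <- mask_vid_table(sample_sizes)
  dims <- sample_sizes + 1L
  nclass <- prod(dims)
  # folding is linear, so fold each replicate's class-length vector and
  # accumulate moments on the reported scale
  vid_tab_eff <- if (fold) fold_plan(dims)$target[vid_tab] else vid_tab
  ssum <- numeric(nclass)
  ssum2 <- numeric(nclass)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    g <- sim_genealogy(cdem, sample_sizes)
    li <- numeric(nclass)
    vids <- vid_tab_eff[g$masks + 1L]
    for (i in seq_along(vids)) li[vids[i]] <- li[vids[i]] + g$lengths[i]
    li <- li / 2
    ssum <- ssum + li
    ssum2 <- ssum2 + li^2
  }
  mean_l <- ssum / n_replicates
  se_l <- sqrt(pmax(ssum2 / n_replicates - mean_l^2, 0) / n_replicates)
  mask <- if (fold) fold_sfs(joint_sfs(array(0, dims), dem$sampled_demes))$mask
          else NULL
  out <- joint_sfs(array(mean_l, dims), dem$sampled_demes, mask = mask,
                   folded = fold)
  attr(out, "se") <- array(se_l, dims)
  attr(out, "n_replicates") <- n_replicates
  out
}

# mapping from each cell to the cell it folds into (linear indices)
fold_plan <- function(dims) {
  key <- paste0("fold:", paste(dims, collapse = ","))
  fp <- .sfsinfer_cache[[key]]
  if (!is.null(fp)) return(fp)
  n <- dims - 1L
  half <- sum(n) / 2
  grid <- sfs_index_grid(dims)
  tot <- rowSums(grid)
  mult <- c(1, cumprod(dims[-length(dims)]))
  lin <- as.vector(grid %*% mult) + 1L
  comp <- as.vector(sweep(-grid, 2L, n, "+") %*% mult) + 1L
  target <- ifelse(tot < half, lin, ifelse(tot > half, comp, pmin(lin, comp)))
  fp <- list(target = target, comp = comp, kept = which(target == lin))
  .sfsinfer_cache[[key]] <- fp
  fp
}
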