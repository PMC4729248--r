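# Combinatorial kernels for the exact coalescent expectation engine.
#
# The engine computes, for every allele configuration c, the expected total
# genealogy branch length subtending exactly c, by tracking ancestral lineage
# configurations backward in time. Within a panmictic epoch the process
# factorises into (i) the lineage-count death chain, whose holding times give
# the expected time spent at each level, and (ii) the parameter-free merge
# jump chain, whose partition distribution at each level is Kingman's
# exchangeable partition formula. Migration epochs use the full
# continuous-time Markov chain over (deme, descendant-vector) multisets.

.sfsinfer_cache <- new.env(parent = emptyenv())

# Descendant-vector ("class") space for haploid sample sizes n: every vector
# 0..n_j per population, identified with its column-major linear index (vid).
class_space <- function(n) {
  key <- paste0("cs:", paste(n, collapse = ","))
  cs <- .sfsinfer_cache[[key]]
  if (!is.null(cs)) return(cs)
  dims <- as.integer(n) + 1L
  grid <- sfs_index_grid(dims)
  mult <- c(1, cumprod(dims[-length(dims)]))
  cs <- new.env(parent = emptyenv())
  cs$n <- as.integer(n)
  cs$dims <- dims
  cs$nclass <- prod(dims)
  cs$grid <- grid
  cs$mult <- mult
  cs$unit_vids <- vapply(seq_along(n), function(j) {
    v <- integer(length(n)); v[j] <- 1L
    as.integer(sum(v * mult) + 1L)
  }, integer(1))
  cs$shifts <- new.env(parent = emptyenv())   # vid of shift w -> vid mapping
  cs$Ncache <- new.env(parent = emptyenv())   # subset-count DP tables
  cs$Ecache <- new.env(parent = emptyenv())   # exit distributions
  cs$Fcache <- new.env(parent = emptyenv())   # root contribution vectors
  cs$mset_ids <- new.env(parent = emptyenv()) # multiset key -> integer id
  cs$mset_list <- list()                      # id -> sorted vids
  cs$union_tab <- list()                      # id x id -> union multiset id
  cs$exit_list <- list()                      # id -> exit distributions
  cs$contrib_list <- list()                   # id -> contribution matrix
  cs$rootf_list <- list()                     # id -> root length vector
  cs$ctmc_cache <- new.env(parent = emptyenv())
  cs$sep_cache <- new.env(parent = emptyenv())  # single-epoch plans
  cs$root_cache <- new.env(parent = emptyenv()) # final-epoch matrices
  .sfsinfer_cache[[key]] <- cs
  cs
}

vid_add <- function(cs, vid_a, vid_b) {
  target <- cs$grid[vid_a, ] + cs$grid[vid_b, ]
  as.integer(sum(target * cs$mult) + 1L)
}

# vid -> vid + w mapping (NA outside the class space), cached per shift w
shift_map <- function(cs, w_vid) {
  key <- as.character(w_vid)
  m <- cs$shifts[[key]]
  if (!is.null(m)) return(m)
  w <- cs$grid[w_vid, ]
  target <- sweep(cs$grid, 2L, w, "+")
  ok <- !apply(sweep(target, 2L, cs$n, ">"), 1L, any)
  m <- rep(NA_integer_, cs$nclass)
  m[ok] <- as.integer(target[ok, , drop = FALSE] %*% cs$mult + 1L)
  cs$shifts[[key]] <- m
  m
}

# Lah numbers L(m, r) = C(m-1, r-1) * m! / r!: the total Kingman partition
# weight sum(prod b_i!) over set partitions of m items into r blocks.
lah_number <- function(m, r) {
  if (m == 0 && r == 0) return(1)
  if (r == 0 || r > m) return(0)
  choose(m - 1, r - 1) * exp(lgamma(m + 1) - lgamma(r + 1))
}

# P(a fixed subset of size b of j exchangeable lineages forms one block when
# the merge jump chain is at level k), Kingman's partition distribution.
# Returned as a (j x j) matrix indexed [b, k]; cached per j.
pblock_matrix <- function(j) {
  key <- paste0("pb:", j)
  P <- .sfsinfer_cache[[key]]
  if (!is.null(P)) return(P)
  P <- matrix(0, j, j)
  P[1, j] <- 1
  lfac <- lgamma(seq_len(max(j, 2)) + 1)  # log factorials 1..j
  lf <- function(x) if (x == 0) 0 else lfac[x]
  for (k in seq_len(j - 1)) {
    base <- exp(lf(j - k) + lf(k) + lf(k - 1) - lf(j) - lf(j - 1))
    for (b in seq_len(j - k + 1)) {
      P[b, k] <- base * exp(lf(b)) * lah_number(j - b, k - 1)
    }
  }
  .sfsinfer_cache[[key]] <- P
  P
}

# Lineage-count death chain over an epoch: expected end-level distribution
# and expected time at each level, for every starting level up to jmax.
# Time is pre-scaled: pass tau = duration / nu. Rows index the start level,
# columns the level. occ[j, k] = E[time at level k | start j] (in tau units,
# multiply by nu to recover epoch time units).
level_occupancy <- function(jmax, tau) {
  J <- as.integer(jmax)
  if (J == 1L) {
    return(list(end = matrix(1, 1, 1), occ = matrix(min(tau, Inf), 1, 1)))
  }
  if (tau == 0) {
    return(list(end = diag(J), occ = matrix(0, J, J)))
  }
  rates <- c(0, choose(2:J, 2))
  Q <- matrix(0, J, J)
  for (k in 2:J) {
    Q[k, k] <- -rates[k]
    Q[k, k - 1] <- rates[k]
  }
  A <- rbind(cbind(Q, diag(J)), matrix(0, J, 2L * J))
  E <- as.matrix(Matrix::expm(A * tau))
  list(end = E[seq_len(J), seq_len(J), drop = FALSE],
       occ = E[seq_len(J), J + seq_len(J), drop = FALSE])
}

canon_key <- function(x) paste(x, collapse = ",")

# Number of subsets of the entering lineage multiset of each size b whose
# descendant vectors sum to each class: matrix (j+1) x nclass, row b+1.
subset_counts <- function(cs, vids) {
  vids <- sort(vids)
  key <- canon_key(vids)
  N <- cs$Ncache[[key]]
  if (!is.null(N)) return(N)
  j <- length(vids)
  N <- matrix(0, j + 1L, cs$nclass)
  N[1L, 1L] <- 1   # empty subset sums to the zero vector (vid 1)
  for (w in vids) {
    sm <- shift_map(cs, w)
    ok <- which(!is.na(sm))
    for (b in seq(j, 1L)) {
      N[b + 1L, sm[ok]] <- N[b + 1L, sm[ok]] + N[b, ok]
    }
  }
  cs$Ncache[[key]] <- N
  N
}

# Enumerate set partitions of j labeled items by restricted growth strings.
set_partitions <- function(j) {
  if (j == 1) return(list(list(1L)))
  key <- paste0("sp:", j)
  cached <- .sfsinfer_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- list()
  rgs <- integer(j)
  recurse <- function(i, maxblock) {
    if (i > j) {
      blocks <- split(seq_len(j), rgs)
      out[[length(out) + 1L]] <<- unname(blocks)
      return(invisible())
    }
    for (a in seq_len(maxblock + 1L)) {
      rgs[i] <<- a
      recurse(i + 1L, max(maxblock, a))
    }
  }
  recurse(1L, 0L)
  .sfsinfer_cache[[key]] <- out
  out
}

# Distribution of the exit lineage multiset, by end level m, for an entering
# multiset: Kingman-weighted grouping of all set partitions. Cached
# (parameter-free). Returns list indexed by m of list(keys, vids, probs).
exit_distributions <- function(cs, vids) {
  vids <- sort(vids)
  key <- canon_key(vids)
  ed <- cs$Ecache[[key]]
  if (!is.null(ed)) return(ed)
  j <- length(vids)
  acc <- lapply(seq_len(j), function(m) new.env(parent = emptyenv()))
  for (p in set_partitions(j)) {
    m <- length(p)
    w <- prod(vapply(p, function(B) factorial(length(B)), numeric(1)))
    merged <- sort(vapply(p, function(B) {
      vid <- vids[B[1]]
      for (i in B[-1]) vid <- vid_add(cs, vid, vids[i])
      vid
    }, integer(1)))
    k <- canon_key(merged)
    e <- acc[[m]]
    cur <- e[[k]]
    if (is.null(cur)) e[[k]] <- list(vids = merged, w = w)
    else e[[k]]$w <- cur$w + w
  }
  ed <- lapply(seq_len(j), function(m) {
    e <- acc[[m]]
    keys <- ls(e)
    ws <- vapply(keys, function(k) e[[k]]$w, numeric(1))
    list(keys = keys,
         vids = lapply(keys, function(k) e[[k]]$vids),
         probs = unname(ws / sum(ws)))
  })
  cs$Ecache[[key]] <- ed
  ed
}

# Expected subtending branch length per class contributed by a panmictic
# epoch entered by the given multiset, given the level occupancy row
# (already in epoch time units). Includes level 1 (the epoch's root class).
epoch_class_lengths <- function(cs, vids, occ_row) {
  j <- length(vids)
  N <- subset_counts(cs, vids)
  P <- pblock_matrix(j)
  wb <- P %*% occ_row[seq_len(j)]           # expected time each size-b subset is a block
  as.vector(crossprod(N[-1L, , drop = FALSE], wb))
}

# Expected subtending branch length per class over an infinite final epoch
# of relative size 1 (scale externally by nu_root). Level 1 is excluded: a
# single surviving lineage subtends the always-masked full corner.
root_class_lengths <- function(cs, vids) {
  vids <- sort(vids)
  key <- canon_key(vids)
  f <- cs$Fcache[[key]]
  if (!is.null(f)) return(f)
  j <- length(vids)
  if (j == 1L) {
    f <- numeric(cs$nclass)
  } else {
    N <- subset_counts(cs, vids)
    P <- pblock_matrix(j)
    et <- c(0, 1 / choose(2:j, 2))          # E[time at level k], nu = 1
    wb <- P %*% et
    f <- as.vector(crossprod(N[-1L, , drop = FALSE], wb))
  }
  cs$Fcache[[key]] <- f
  f
}
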