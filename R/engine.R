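# Deterministic expected-SFS engine.
#
# Demographies without migration factorise over demes: each deme's lineage
# multiset evolves by the parameter-free merge jump chain, with epoch timing
# entering only through the lineage-count occupancy (a small matrix
# exponential). Epochs with migration are integrated as a linear ODE over
# the full multiset-of-(deme, descendant-vector) state space. Both paths
# accumulate the expected branch length subtending every allele
# configuration; dividing by two gives the expected spectrum at theta = 1.
#
# All parameter-independent structure (lineage multiset registries, exit
# distributions, per-multiset contribution matrices, CTMC generators) is
# cached in the class-space environment, so repeated evaluations during
# optimisation reduce to small dense/sparse linear algebra.

# ---- lineage-multiset registry (integer ids) --------------------------------

mset_id <- function(cs, vids) {
  vids <- sort.int(vids)
  key <- paste(vids, collapse = ",")
  id <- cs$mset_ids[[key]]
  if (is.null(id)) {
    id <- length(cs$mset_list) + 1L
    cs$mset_list[[id]] <- vids
    cs$mset_ids[[key]] <- id
  }
  id
}

mset_vids <- function(cs, id) cs$mset_list[[id]]

union_id <- function(cs, a, b) {
  tab <- if (a <= length(cs$union_tab)) cs$union_tab[[a]] else integer(0)
  if (b <= length(tab) && !is.na(tab[b])) return(tab[b])
  id <- mset_id(cs, c(mset_vids(cs, a), mset_vids(cs, b)))
  tab[b] <- id
  cs$union_tab[[a]] <- tab
  id
}

# exit distributions keyed by multiset id: per end level m, integer ids and
# probabilities of the exit multisets
exit_dist_id <- function(cs, id) {
  ed <- if (id <= length(cs$exit_list)) cs$exit_list[[id]] else NULL
  if (!is.null(ed)) return(ed)
  raw <- exit_distributions(cs, mset_vids(cs, id))
  ed <- lapply(raw, function(dm) {
    list(ids = vapply(dm$vids, function(v) mset_id(cs, v), integer(1)),
         probs = dm$probs)
  })
  cs$exit_list[[id]] <- ed
  ed
}

# epoch contribution matrix A (nclass x j): expected subtending length per
# class = A %*% occupancy-row
contrib_matrix <- function(cs, id) {
  A <- if (id <= length(cs$contrib_list)) cs$contrib_list[[id]] else NULL
  if (!is.null(A)) return(A)
  vids <- mset_vids(cs, id)
  j <- length(vids)
  N <- subset_counts(cs, vids)
  A <- crossprod(N[-1L, , drop = FALSE], pblock_matrix(j))
  cs$contrib_list[[id]] <- A
  A
}

root_f_id <- function(cs, id) {
  f <- if (id <= length(cs$rootf_list)) cs$rootf_list[[id]] else NULL
  if (!is.null(f)) return(f)
  f <- root_class_lengths(cs, mset_vids(cs, id))
  cs$rootf_list[[id]] <- f
  f
}

# cached final-epoch contribution matrices: columns are the root length
# vectors of each support multiset (single cluster) or of every pairwise
# union (two clusters entering the root together)
root_matrix_single <- function(cs, ids) {
  key <- paste0("rms:", paste(ids, collapse = ","))
  Fm <- cs$root_cache[[key]]
  if (is.null(Fm)) {
    Fm <- vapply(ids, function(id) root_f_id(cs, id), numeric(cs$nclass))
    cs$root_cache[[key]] <- Fm
  }
  Fm
}

root_matrix_pair <- function(cs, ids_a, ids_b) {
  key <- paste0("rmp:", paste(ids_a, collapse = ","), "|",
                paste(ids_b, collapse = ","))
  Fm <- cs$root_cache[[key]]
  if (is.null(Fm)) {
    Fm <- matrix(0, cs$nclass, length(ids_a) * length(ids_b))
    k <- 0L
    for (jb in seq_along(ids_b)) for (ia in seq_along(ids_a)) {
      k <- k + 1L
      Fm[, k] <- root_f_id(cs, union_id(cs, ids_a[ia], ids_b[jb]))
    }
    cs$root_cache[[key]] <- Fm
  }
  Fm
}

# aggregate duplicate ids, dropping negligible weights
aggregate_ids <- function(ids, ws) {
  o <- rowsum(ws, ids)
  list(ids = as.integer(rownames(o)), ws = as.vector(o))
}

# ---- single-deme (migration-free) epoch -------------------------------------

# cluster kinds: "single" = list(kind, deme, ids, ws);
#                "joint"  = list(kind, demes, states = list(demes, vids, w))

# Parameter-free structure for evolving a fixed support of lineage
# multisets through one panmictic epoch: stacked contribution matrices and
# a sparse (state, level) -> exit-multiset transfer operator. Weights and
# level occupancies are the only per-evaluation inputs.
single_epoch_plan <- function(cs, ids) {
  key <- paste0("sep:", paste(ids, collapse = ","))
  plan <- cs$sep_cache[[key]]
  if (!is.null(plan)) return(plan)
  js <- lengths(cs$mset_list[ids])
  ncol_total <- sum(js)
  col_of <- c(0L, cumsum(js))   # z-vector column offsets per state
  Astack <- matrix(0, cs$nclass, ncol_total)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  out_index <- new.env(parent = emptyenv())
  out_ids <- integer(0)
  out_of <- function(id) {
    k <- as.character(id)
    v <- out_index[[k]]
    if (is.null(v)) {
      out_ids[length(out_ids) + 1L] <<- id
      v <- length(out_ids)
      out_index[[k]] <- v
    }
    v
  }
  for (i in seq_along(ids)) {
    j <- js[i]
    Astack[, col_of[i] + seq_len(j)] <- contrib_matrix(cs, ids[i])
    ed <- exit_dist_id(cs, ids[i])
    for (m in seq_len(j)) {
      rows <- vapply(ed[[m]]$ids, out_of, integer(1))
      ti <- c(ti, rows)
      tj <- c(tj, rep(col_of[i] + m, length(rows)))
      tx <- c(tx, ed[[m]]$probs)
    }
  }
  Tmat <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                               dims = c(length(out_ids), ncol_total))
  plan <- list(ids = ids, js = js, col_of = col_of, jmax = max(js),
               Astack = Astack, Tmat = Tmat, out_ids = out_ids)
  cs$sep_cache[[key]] <- plan
  plan
}

single_epoch <- function(cs, cl, nu, duration, L) {
  plan <- single_epoch_plan(cs, cl$ids)
  lo <- level_occupancy(plan$jmax, duration / nu)
  z_occ <- numeric(sum(plan$js))
  z_end <- numeric(sum(plan$js))
  for (i in seq_along(cl$ids)) {
    j <- plan$js[i]
    cols <- plan$col_of[i] + seq_len(j)
    z_occ[cols] <- cl$ws[i] * lo$occ[j, seq_len(j)] * nu
    z_end[cols] <- cl$ws[i] * lo$end[j, seq_len(j)]
  }
  L <- L + as.vector(plan$Astack %*% z_occ)
  ws_out <- as.vector(plan$Tmat %*% z_end)
  keep <- ws_out > 0
  list(cluster = list(kind = "single", deme = cl$deme,
                      ids = plan$out_ids[keep], ws = ws_out[keep]),
       L = L)
}

product_single <- function(cs, a, b, deme) {
  n_a <- length(a$ids); n_b <- length(b$ids)
  ids <- integer(n_a * n_b); ws <- numeric(n_a * n_b)
  k <- 0L
  for (i in seq_len(n_a)) for (j in seq_len(n_b)) {
    k <- k + 1L
    ids[k] <- union_id(cs, a$ids[i], b$ids[j])
    ws[k] <- a$ws[i] * b$ws[j]
  }
  agg <- aggregate_ids(ids, ws)
  list(kind = "single", deme = deme, ids = agg$ids, ws = agg$ws)
}

# ---- migration epochs: full configuration CTMC ------------------------------

joint_state_key <- function(demes, vids) {
  o <- order(demes, vids)
  paste(demes[o], vids[o], sep = "#", collapse = ",")
}

ctmc_structure <- function(cs, demes, support_states) {
  # The reachable state set is closed under coalescence and migration, so a
  # structure built once per deme set covers any support that later arises
  # within the same cluster; rebuild only if a support state is missing.
  skey <- paste0("ctmc:", paste(sort(demes), collapse = "|"))
  st <- cs$ctmc_cache[[skey]]
  if (!is.null(st)) {
    covered <- all(vapply(support_states, function(s)
      !is.null(st$index[[joint_state_key(s$demes, s$vids)]]), logical(1)))
    if (covered) return(st)
    support_states <- c(st$states, support_states)
  }

  index <- new.env(parent = emptyenv())
  states <- list()
  push <- function(demes_v, vids_v) {
    o <- order(demes_v, vids_v)
    demes_v <- demes_v[o]; vids_v <- vids_v[o]
    k <- paste(demes_v, vids_v, sep = "#", collapse = ",")
    id <- index[[k]]
    if (is.null(id)) {
      states[[length(states) + 1L]] <<- list(demes = demes_v, vids = vids_v)
      id <- length(states)
      index[[k]] <- id
    }
    id
  }
  for (s in support_states) push(s$demes, s$vids)

  comp <- new.env(parent = emptyenv())
  addtrip <- function(name, from, to) {
    cc <- comp[[name]]
    if (is.null(cc)) cc <- list(i = integer(0), j = integer(0))
    cc$i <- c(cc$i, from); cc$j <- c(cc$j, to)
    comp[[name]] <- cc
  }

  qi <- 0L
  while (qi < length(states)) {
    qi <- qi + 1L
    s <- states[[qi]]
    k <- length(s$vids)
    if (k >= 2) {
      for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
        if (s$demes[a] != s$demes[b]) next
        nv <- s$vids
        nv[a] <- vid_add(cs, nv[a], nv[b])
        addtrip(paste0("coal:", s$demes[a]), qi, push(s$demes[-b], nv[-b]))
      }
    }
    for (a in seq_len(k)) {
      for (d2 in demes) {
        if (d2 == s$demes[a]) next
        nd <- s$demes; nd[a] <- d2
        addtrip(paste0("mig:", s$demes[a], ">", d2), qi, push(nd, s$vids))
      }
    }
  }

  ns <- length(states)
  mats <- list()
  for (name in ls(comp)) {
    cc <- comp[[name]]
    off <- Matrix::sparseMatrix(i = cc$i, j = cc$j, x = rep(1, length(cc$i)),
                                dims = c(ns, ns))
    mats[[name]] <- Matrix::t(off - Matrix::Diagonal(x = Matrix::rowSums(off)))
  }
  ci <- integer(0); cj <- integer(0); cx <- numeric(0)
  merge_ids <- integer(ns)
  for (si in seq_len(ns)) {
    tb <- table(states[[si]]$vids)
    ci <- c(ci, rep(si, length(tb)))
    cj <- c(cj, as.integer(names(tb)))
    cx <- c(cx, as.numeric(tb))
    merge_ids[si] <- mset_id(cs, states[[si]]$vids)
  }
  Ct <- Matrix::t(Matrix::sparseMatrix(i = ci, j = cj, x = cx,
                                       dims = c(ns, cs$nclass)))
  st <- list(states = states, index = index, mats = mats, Ct = Ct,
             ns = ns, merge_ids = merge_ids)
  cs$ctmc_cache[[skey]] <- st
  st
}

ctmc_epoch <- function(cs, cl, nu, mig, duration, L, control) {
  st <- ctmc_structure(cs, cl$demes, cl$states)
  Qt <- NULL
  addQ <- function(Qt, M) if (is.null(Qt)) M else Qt + M
  for (d in cl$demes) {
    nm <- paste0("coal:", d)
    if (!is.null(st$mats[[nm]])) Qt <- addQ(Qt, st$mats[[nm]] / nu[[d]])
  }
  if (!is.null(mig)) {
    for (a in cl$demes) for (b in cl$demes) {
      if (a == b) next
      nm <- paste0("mig:", a, ">", b)
      if (a %in% rownames(mig) && b %in% colnames(mig) &&
          mig[a, b] > 0 && !is.null(st$mats[[nm]]))
        Qt <- addQ(Qt, st$mats[[nm]] * mig[a, b])
    }
  }
  p0 <- numeric(st$ns)
  for (s in cl$states)
    p0[st$index[[joint_state_key(s$demes, s$vids)]]] <- s$w
  y0 <- c(p0, numeric(cs$nclass))
  ns <- st$ns
  Ct <- st$Ct
  deriv <- function(t, y, parms) {
    p <- y[seq_len(ns)]
    list(c(as.vector(Qt %*% p), as.vector(Ct %*% p)))
  }
  sol <- deSolve::ode(y0, times = c(0, duration), func = deriv, parms = NULL,
                      method = control$ode_method, rtol = control$rtol,
                      atol = control$atol)
  yT <- sol[nrow(sol), -1]
  if (anyNA(yT) || attr(sol, "istate")[1] < 0)
    stop("expected_sfs: CTMC integration failed to converge ",
         sprintf("(duration %g, %d states); ", duration, st$ns),
         "tighten control$rtol or check parameter values")
  pT <- pmax(yT[seq_len(ns)], 0)
  L <- L + yT[ns + seq_len(cs$nclass)]
  keep <- which(pT > 0)
  list(cluster = list(kind = "joint", demes = cl$demes,
                      states = lapply(keep, function(i) {
                        s <- st$states[[i]]
                        list(demes = s$demes, vids = s$vids, w = pT[i])
                      }),
                      merge_ids = st$merge_ids[keep], merge_ws = pT[keep]),
       L = L)
}

# ---- demography walker ------------------------------------------------------

as_joint <- function(cs, cl) {
  if (cl$kind == "joint") return(cl)
  list(kind = "joint", demes = cl$deme,
       states = lapply(seq_along(cl$ids), function(i)
         list(demes = rep(cl$deme, length(mset_vids(cs, cl$ids[i]))),
              vids = mset_vids(cs, cl$ids[i]), w = cl$ws[i])))
}

product_joint <- function(cs, a, b) {
  env <- new.env(parent = emptyenv())
  for (sa in a$states) for (sb in b$states) {
    demes <- c(sa$demes, sb$demes); vids <- c(sa$vids, sb$vids)
    o <- order(demes, vids)
    demes <- demes[o]; vids <- vids[o]
    k <- paste(demes, vids, sep = "#", collapse = ",")
    cur <- env[[k]]
    if (is.null(cur)) env[[k]] <- list(demes = demes, vids = vids,
                                       w = sa$w * sb$w)
    else env[[k]]$w <- cur$w + sa$w * sb$w
  }
  list(kind = "joint", demes = union(a$demes, b$demes),
       states = lapply(ls(env), function(k) env[[k]]))
}

cluster_demes <- function(cl) if (cl$kind == "single") cl$deme else cl$demes

solve_demography <- function(dem, sample_sizes, control) {
  cs <- class_space(sample_sizes)
  L <- numeric(cs$nclass)
  clusters <- lapply(seq_along(dem$sampled_demes), function(i) {
    d <- dem$sampled_demes[i]
    list(kind = "single", deme = d,
         ids = mset_id(cs, rep(cs$unit_vids[i], sample_sizes[i])),
         ws = 1)
  })

  unify <- function(idx) {
    # combine the given clusters into one joint (or single) cluster
    cls <- clusters[idx]
    demes <- unique(unlist(lapply(cls, cluster_demes)))
    if (length(cls) == 1L && length(demes) == 1L) return(cls[[1]])
    if (length(demes) == 1L && all(vapply(cls, function(c) c$kind == "single",
                                          logical(1)))) {
      acc <- cls[[1]]
      for (c2 in cls[-1]) acc <- product_single(cs, acc, c2, demes)
      return(acc)
    }
    acc <- as_joint(cs, cls[[1]])
    for (c2 in cls[-1]) acc <- product_joint(cs, acc, as_joint(cs, c2))
    acc
  }

  n_epochs <- length(dem$epochs)
  for (ei in seq_len(n_epochs)) {
    e <- dem$epochs[[ei]]
    if (is.infinite(e$duration)) {
      nu_root <- unname(e$demes[1])
      singles <- vapply(clusters, function(cl) cl$kind == "single",
                        logical(1))
      if (length(clusters) == 2L && all(singles)) {
        # two lineage sets meet at the root: cached pairwise-union matrix
        Fm <- root_matrix_pair(cs, clusters[[1]]$ids, clusters[[2]]$ids)
        w <- as.vector(outer(clusters[[1]]$ws, clusters[[2]]$ws))
        L <- L + nu_root * as.vector(Fm %*% w)
        return(array(L / 2, cs$dims))
      }
      cl <- unify(seq_along(clusters))
      if (cl$kind == "joint") {
        ids <- vapply(cl$states, function(s) mset_id(cs, s$vids), integer(1))
        ws <- vapply(cl$states, function(s) s$w, numeric(1))
        agg <- aggregate_ids(ids, ws)
        cl <- list(kind = "single", ids = agg$ids, ws = agg$ws)
      }
      Fm <- root_matrix_single(cs, cl$ids)
      L <- L + nu_root * as.vector(Fm %*% cl$ws)
      return(array(L / 2, cs$dims))
    }

    # union clusters whose demes exchange migrants this epoch
    if (!is.null(e$migration) && any(e$migration > 0)) {
      mig_demes <- union(rownames(e$migration)[apply(e$migration > 0, 1, any)],
                         colnames(e$migration)[apply(e$migration > 0, 2, any)])
      touched <- vapply(clusters, function(cl)
        any(cluster_demes(cl) %in% mig_demes), logical(1))
      if (sum(touched) > 1)
        clusters <- c(clusters[!touched], list(unify(which(touched))))
    }

    if (e$duration > 0) {
      clusters <- lapply(clusters, function(cl) {
        if (cl$kind == "single") {
          res <- single_epoch(cs, cl, unname(e$demes[[cl$deme]]),
                              e$duration, L)
        } else {
          sub <- intersect(cl$demes, rownames(e$migration))
          mig <- if (!is.null(e$migration) && length(sub) > 1 &&
                     any(e$migration[sub, sub] > 0)) e$migration else NULL
          res <- ctmc_epoch(cs, cl, e$demes, mig, e$duration, L, control)
        }
        L <<- res$L
        res$cluster
      })
    }

    if (!is.null(e$merges) && length(e$merges) > 0) {
      clusters <- lapply(clusters, function(cl) {
        demes <- cluster_demes(cl)
        hit <- demes %in% names(e$merges)
        if (!any(hit)) return(cl)
        if (cl$kind == "single") {
          cl$deme <- unname(e$merges[[cl$deme]])
          return(cl)
        }
        # joint cluster: all demes must merge to a single destination
        dest <- unique(unname(e$merges[demes[hit]]))
        if (all(hit) && length(dest) == 1L) {
          if (!is.null(cl$merge_ids)) {
            agg <- aggregate_ids(cl$merge_ids, cl$merge_ws)
          } else {
            ids <- vapply(cl$states, function(s) mset_id(cs, s$vids),
                          integer(1))
            agg <- aggregate_ids(ids, vapply(cl$states, function(s) s$w,
                                             numeric(1)))
          }
          return(list(kind = "single", deme = dest, ids = agg$ids,
                      ws = agg$ws))
        }
        # partial merge of an entangled cluster: relabel demes state by state
        states <- lapply(cl$states, function(s) {
          idx <- s$demes %in% names(e$merges)
          s$demes[idx] <- unname(e$merges[s$demes[idx]])
          s
        })
        list(kind = "joint",
             demes = unique(c(demes[!hit], unname(e$merges[demes[hit]]))),
             states = states)
      })
      # same-deme single clusters combine by product -- unless the next
      # epoch is the root, where the cached pairwise-union path absorbs
      # them without materialising the product support
      next_is_root <- ei + 1L <= n_epochs &&
        is.infinite(dem$epochs[[ei + 1L]]$duration)
      if (!next_is_root) {
        demes_now <- lapply(clusters, cluster_demes)
        for (d in unique(unlist(demes_now))) {
          idx <- which(vapply(demes_now, function(x)
            identical(x, d), logical(1)))
          if (length(idx) > 1) {
            clusters <- c(clusters[-idx], list(unify(idx)))
            demes_now <- lapply(clusters, cluster_demes)
          }
        }
      }
    }
  }
  stop("demography walked off the epoch list without an infinite final epoch")
}

#' Expected joint SFS under a demographic model
#'
#' Computes the expected per-site spectrum at `theta = 1` by exact coalescent
#' Markov-chain expectation: entry `c` is half the expected total genealogy
#' branch length (in units of 2*Na generations) subtending exactly the
#' allele configuration `c` in a sample of the given sizes, so that the
#' expected count of variant sites in cell `c` equals `theta` times the
#' entry. The computation is deterministic and smooth in the parameters.
#'
#' @param model A `model_spec` from [get_model()], or a model name.
#' @param params Named (or positionally ordered) numeric vector of the
#'   model's free parameters.
#' @param sample_sizes Haploid sample sizes per population (default 4 per
#'   population, i.e. two diploids each).
#' @param fold Return the folded (minor-allele) spectrum?
#' @param control List of numerical settings: `rtol`, `atol` for migration
#'   epochs integrated by ODE.
#' @return A `joint_sfs` with real-valued entries, population labels taken
#'   from the model's present-day demes.
#' @export
expected_sfs <- function(model, params, sample_sizes = NULL, fold = TRUE,
                         control = list()) {
  if (is.character(model)) model <- get_model(model)
  control <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10,
                                    ode_method = "ode45"), control)
  if (is.null(names(params))) {
    if (length(params) != model$n_free)
      stop("expected ", model$n_free, " parameters for model ", model$name)
    params <- stats::setNames(as.numeric(params), model$params)
  }
  if (!all(model$params %in% names(params)))
    stop("missing parameters: ",
         paste(setdiff(model$params, names(params)), collapse = ", "))
  params <- params[model$params]
  bad <- params < model$lower | params > model$upper
  if (any(bad))
    stop("parameters outside bounds: ",
         paste(model$params[bad], collapse = ", "))
  if (is.null(sample_sizes)) sample_sizes <- rep(4L, model$npops)
  if (length(sample_sizes) != model$npops || any(sample_sizes < 2))
    stop("sample_sizes must give >= 2 chromosomes for each of ",
         model$npops, " populations")
  dem <- model$demography(as.list(params))
  counts <- solve_demography(dem, as.integer(sample_sizes), control)
  out <- joint_sfs(counts, dem$sampled_demes, folded = FALSE)
  if (fold) out <- fold_sfs(out)
  out
}
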