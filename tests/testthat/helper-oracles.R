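# Independent oracles. Each one recomputes a result by a route that shares
# no code with the implementation it checks: bio3d's fitting for RMSD,
# explicit loops for the clustering rules, exhaustive grids for rotations.

# superposed RMSD of two n x 3 coordinate sets via bio3d's fitting
# (bio3d::rmsd() rounds to 3 decimals, so superpose with fit.xyz and
# measure the deviation unrounded)
oracle_rmsd <- function(a, b) {
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(a)),
                                            as.vector(t(b))))
  sqrt(mean((as.vector(t(a)) - fitted)^2) * 3)
}

# pairwise superposed RMSD matrix via bio3d
oracle_rmsd_matrix <- function(frames) {
  n <- length(frames)
  m <- matrix(0, n, n)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- oracle_rmsd(frames[[i]], frames[[j]])
    }
  }
  m
}

# Literal transcription of the neighbour-count clustering rule, written as
# plain loops over an RMSD matrix: repeatedly find the frame with the most
# neighbours within the cutoff (lowest index on ties), emit centre +
# neighbours as a cluster, remove them. Returns 0-based members/centres.
oracle_gromos <- function(m, cutoff) {
  n <- nrow(m)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0) {
    best_count <- -1L
    best_frame <- NA_integer_
    for (f in remaining) {
      cnt <- 0L
      for (g in remaining) {
        if (g != f && m[f, g] <= cutoff) cnt <- cnt + 1L
      }
      if (cnt > best_count) {
        best_count <- cnt
        best_frame <- f
      }
    }
    members <- integer()
    for (g in remaining) {
      if (g == best_frame || m[best_frame, g] <= cutoff)
        members <- c(members, g)
    }
    clusters[[length(clusters) + 1]] <-
      list(centre = best_frame - 1L, members = members - 1L,
           size = length(members))
    remaining <- setdiff(remaining, members)
  }
  clusters
}

# Naive agglomerative clustering by repeated merging; returns a membership
# vector (named by the matrix labels) with k clusters.
oracle_agglomerative <- function(m, k, linkage) {
  n <- nrow(m)
  groups <- as.list(seq_len(n))
  linkfun <- switch(linkage, complete = max, single = min, average = mean)
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        d <- linkfun(m[groups[[i]], groups[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  assign <- integer(n)
  for (g in seq_along(groups)) assign[groups[[g]]] <- g
  names(assign) <- rownames(m)
  assign
}

euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# Exhaustive coarse-to-fine grid search over SO(3) (z-y-z Euler angles)
# for the minimum RMSD between two point clouds; translation handled by
# centroid alignment, which is optimal for any fixed rotation.
oracle_grid_min_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  rmsd_at <- function(a, b, g) {
    R <- euler_rotation(a, b, g)
    sqrt(mean(rowSums((Q - P %*% t(R))^2)))
  }
  best <- c(0, 0, 0); bestv <- Inf
  step <- pi / 9
  grid_a <- seq(0, 2 * pi - step, by = step)
  grid_b <- seq(0, pi, by = step)
  for (a in grid_a) for (b in grid_b) for (g in grid_a) {
    v <- rmsd_at(a, b, g)
    if (v < bestv) { bestv <- v; best <- c(a, b, g) }
  }
  for (lev in 1:4) {
    step <- step / 5
    loc <- seq(-3 * step, 3 * step, by = step)
    for (da in loc) for (db in loc) for (dg in loc) {
      v <- rmsd_at(best[1] + da, best[2] + db, best[3] + dg)
      if (v < bestv) { bestv <- v; best <- best + c(da, db, dg) }
    }
  }
  bestv
}

# Brute-force pocket selection: loop over every protein atom / ligand atom
# pair in the file and keep residues with any pair distance <= r.
oracle_pocket <- function(pdb_path, ligand_resid, r) {
  at <- bio3d::read.pdb(pdb_path, verbose = FALSE)$atom
  lig <- at[at$type == "HETATM" & at$resid == ligand_resid, ]
  prot <- at[at$type == "ATOM", ]
  hits <- integer()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                  (prot$z[i] - lig$z[j])^2)
      if (d <= r) hits <- c(hits, prot$resno[i])
    }
  }
  sort(unique(hits))
}

# Brute-force top-fraction recovery: recount actives over the prefix.
oracle_top_recovery <- function(ids_in_rank_order, actives, q) {
  n_top <- floor(q * length(ids_in_rank_order))
  found <- 0
  for (i in seq_len(n_top)) {
    if (ids_in_rank_order[i] %in% actives) found <- found + 1
  }
  100 * found / length(actives)
}

# Brute-force multi-conformation hit count: per conformation_site, sort by
# energy (ties by id) and count prefix membership per compound.
oracle_hit_counts <- function(t, q) {
  ids <- paste(t$conformation, t$site)
  counts <- list()
  for (cs in unique(ids)) {
    sub <- t[ids == cs, ]
    sub <- sub[order(sub$energy, sub$compound_id), ]
    top <- sub$compound_id[seq_len(floor(q * nrow(sub)))]
    for (cid in top)
      counts[[cid]] <- (counts[[cid]] %||% 0L) + 1L
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
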