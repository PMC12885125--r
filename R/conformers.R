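# Conformational analysis: pairwise-RMSD matrices, hierarchical clustering
# of structure sets, GROMOS-style trajectory clustering, RMSF profiles.

#' Pairwise windowed Calpha RMSD matrix
#'
#' Computes the symmetric matrix of superposed Calpha RMSDs between all
#' pairs of structures over a common residue selection. Each pair is
#' computed once; residues are paired by shared residue number, so
#' structures with deletions simply contribute fewer atoms.
#'
#' @param items List of [structure3d] objects (>= 2).
#' @param selection A [residue_selection] (typically a distance or sequence
#'   window measured in a reference structure) or NULL for all shared
#'   residues.
#' @param superpose_scope Passed to [ca_rmsd()]: `"selection"` (local fit,
#'   default) or `"whole"`.
#' @param labels Item labels; default the structure ids (made unique).
#' @return An `rmsd_matrix`: a labelled symmetric numeric matrix (Angstrom)
#'   with zero diagonal.
#' @export
pairwise_rmsd <- function(items, selection = NULL,
                          superpose_scope = c("selection", "whole"),
                          labels = NULL) {
  superpose_scope <- match.arg(superpose_scope)
  stopifnot(is.list(items), length(items) >= 2L)
  lapply(items, function(s) stopifnot(inherits(s, "structure3d")))
  if (is.null(labels))
    labels <- make.unique(vapply(items, `[[`, "", "id"), sep = "#")
  n <- length(items)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- tryCatch(
        ca_rmsd(items[[i]], items[[j]], selection = selection,
                superpose_scope = superpose_scope),
        error = function(e) stop("pair (", labels[i], ", ", labels[j],
                                 "): ", conditionMessage(e), call. = FALSE))
      m[i, j] <- m[j, i] <- as.numeric(v)
    }
  }
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat("<rmsd_matrix> ", nrow(x), " x ", ncol(x), " (Angstrom)\n", sep = "")
  print(unclass(round(x, 3)))
  invisible(x)
}

#' Plot an RMSD matrix as a shaded image
#'
#' A basic heatmap of the pairwise RMSD values in label order; darker is
#' more similar.
#'
#' @param x An `rmsd_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.rmsd_matrix <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), unclass(x)[, n:1, drop = FALSE],
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = rownames(x), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(colnames(x)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

# Tightness statistic shared by both clusterers: the minimum, over cluster
# members, of the mean RMSD from that member to all other members.
# Singletons score 0 by convention. Returns the value and the argmin member.
cluster_tightness <- function(m, members_idx) {
  if (length(members_idx) == 1L)
    return(list(tightness = 0, min_avg_idx = members_idx))
  sub <- m[members_idx, members_idx, drop = FALSE]
  avg <- rowSums(sub) / (length(members_idx) - 1L)
  i <- which.min(avg)
  list(tightness = avg[[i]], min_avg_idx = members_idx[i])
}

new_cluster_result <- function(clusters, method, params) {
  out <- list(clusters = clusters, method = method, params = params)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> method=", x$method, ", ",
      length(x$clusters), " clusters\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Tabulate a cluster result
#'
#' One row per cluster: size, representative and tightness RMSD (the
#' minimum over members of the mean RMSD to the rest; 0 for singletons).
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A data frame with columns `cluster`, `size`, `representative`,
#'   `tightness_rmsd`.
#' @export
as.data.frame.cluster_result <- function(x, ...) {
  data.frame(
    cluster = seq_along(x$clusters),
    size = vapply(x$clusters, `[[`, 0L, "size"),
    representative = vapply(x$clusters,
                            function(cl) as.character(cl$representative), ""),
    tightness_rmsd = vapply(x$clusters, `[[`, 0, "tightness_rmsd"),
    stringsAsFactors = FALSE)
}

#' Agglomerative clustering of an RMSD matrix
#'
#' Hierarchical clustering on the pairwise RMSD matrix treated as a
#' distance matrix, with the tree cut at `k` clusters. Clusters are
#' numbered in dendrogram leaf order, matching how groups read off a
#' clustered heatmap from left to right along the diagonal.
#'
#' `k` is supplied by the user: no objective selection rule is imposed, and
#' [silhouette_widths()] is available as a diagnostic across candidate `k`.
#'
#' @param m An `rmsd_matrix` from [pairwise_rmsd()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage Agglomeration method: `"complete"` (default), `"average"`
#'   or `"single"`.
#' @return A `cluster_result`; each cluster has `members` (labels),
#'   `representative` (the member with the lowest mean RMSD to the rest),
#'   `size` and `tightness_rmsd`.
#' @export
hierarchical_cluster <- function(m, k,
                                 linkage = c("complete", "average",
                                             "single")) {
  linkage <- match.arg(linkage)
  n <- nrow(m)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  assign <- stats::cutree(hc, k = k)
  # number clusters by first appearance along the dendrogram leaf order
  leaf_assign <- assign[hc$order]
  cluster_ids <- unique(leaf_assign)
  clusters <- lapply(cluster_ids, function(cid) {
    idx <- which(assign == cid)
    tt <- cluster_tightness(m, idx)
    list(members = rownames(m)[idx],
         representative = rownames(m)[tt$min_avg_idx],
         size = length(idx), tightness_rmsd = tt$tightness)
  })
  new_cluster_result(clusters, "hierarchical",
                     list(k = k, linkage = linkage))
}

#' Mean silhouette width for a candidate cluster count
#'
#' Diagnostic only: reports, for each `k` in `ks`, the mean silhouette
#' width of the [hierarchical_cluster()] partition of `m`.
#'
#' @param m An `rmsd_matrix`.
#' @param ks Integer vector of candidate cluster counts (each >= 2).
#' @param linkage Linkage method, as in [hierarchical_cluster()].
#' @return Data frame with columns `k` and `mean_silhouette`.
#' @export
silhouette_widths <- function(m, ks, linkage = "complete") {
  stopifnot(all(ks >= 2L), all(ks <= nrow(m)))
  res <- vapply(ks, function(k) {
    cr <- hierarchical_cluster(m, k, linkage)
    assign <- integer(nrow(m))
    names(assign) <- rownames(m)
    for (ci in seq_along(cr$clusters))
      assign[cr$clusters[[ci]]$members] <- ci
    s <- vapply(seq_len(nrow(m)), function(i) {
      own <- which(assign == assign[i])
      a <- if (length(own) > 1L) mean(m[i, setdiff(own, i)]) else 0
      b <- min(vapply(setdiff(unique(assign), assign[i]), function(cj) {
        mean(m[i, which(assign == cj)])
      }, 0))
      if (length(own) == 1L) 0 else (b - a) / max(a, b)
    }, 0)
    mean(s)
  }, 0)
  data.frame(k = as.integer(ks), mean_silhouette = res)
}

#' Wild-type/mutant composition of clusters
#'
#' Summarises each cluster of a [hierarchical_cluster()] or
#' [gromos_cluster()] result by size, tightness and the percentage of
#' members carrying each variant label. Percentages are reported to one
#' decimal place (raw fractions are retained alongside).
#'
#' @param cr A `cluster_result`.
#' @param labels Named character vector mapping every member id to `"WT"`
#'   or `"mutant"`.
#' @return A data frame with columns `cluster`, `size`, `tightness_rmsd`,
#'   `pct_wt`, `pct_mutant` (one-decimal percentages) and `frac_wt`,
#'   `frac_mutant` (exact fractions).
#' @export
composition <- function(cr, labels) {
  stopifnot(inherits(cr, "cluster_result"))
  rows <- lapply(seq_along(cr$clusters), function(ci) {
    cl <- cr$clusters[[ci]]
    lab <- labels[as.character(cl$members)]
    if (any(is.na(lab)))
      stop("unlabeled member(s) in cluster ", ci, ": ",
           paste(cl$members[is.na(lab)], collapse = ", "))
    bad <- setdiff(unique(lab), c("WT", "mutant"))
    if (length(bad) > 0L)
      stop("labels must be 'WT' or 'mutant'; got: ",
           paste(bad, collapse = ", "))
    fw <- mean(lab == "WT")
    data.frame(cluster = ci, size = cl$size,
               tightness_rmsd = cl$tightness_rmsd,
               pct_wt = round(100 * fw, 1),
               pct_mutant = round(100 * (1 - fw), 1),
               frac_wt = fw, frac_mutant = 1 - fw)
  })
  do.call(rbind, rows)
}

# Pairwise superposed RMSD matrix over trajectory frames, restricted to the
# topology rows in `idx`.
frame_rmsd_matrix <- function(frames, idx) {
  n <- length(frames)
  m <- matrix(0, n, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    a <- frames[[i]][idx, , drop = FALSE]
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        kabsch_superpose(frames[[j]][idx, , drop = FALSE], a)$rmsd
    }
  }
  m
}

#' GROMOS-style neighbour-count clustering of a trajectory
#'
#' Implements the classic RMSD-threshold clustering of molecular-dynamics
#' frames: compute all pairwise superposed Calpha RMSDs, take the frame
#' with the most neighbours within `cutoff` as the centre ("middle frame")
#' of the first cluster, assign the centre and its neighbours to that
#' cluster, remove them, and repeat on the remainder until no frames are
#' left. The centre is the representative structure for its cluster.
#'
#' Neighbour counting excludes the frame itself; ties in neighbour count
#' are broken towards the lowest frame index so the procedure is fully
#' deterministic. Singleton clusters (a centre with no neighbours) report
#' a tightness RMSD of 0.
#'
#' @param t A [trajectory3d].
#' @param cutoff RMSD cutoff in Angstrom (> 0). No default: choose it
#'   relative to the fluctuation scale of the trajectory.
#' @param selection Optional [residue_selection] (or resnum vector)
#'   restricting both superposition and RMSD to those residues; default the
#'   whole topology.
#' @return A `cluster_result` (method `"gromos"`). Cluster members and
#'   representatives are 0-based frame indices; clusters appear in
#'   discovery order. Each cluster also records `min_avg_member`, the
#'   member minimising the mean RMSD to the rest (it usually, but not
#'   always, coincides with the centre).
#' @export
gromos_cluster <- function(t, cutoff, selection = NULL) {
  stopifnot(inherits(t, "trajectory3d"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive RMSD in Angstrom")
  sel <- selection_resnums(selection)
  if (is.null(sel)) {
    idx <- seq_along(t$topology$resnum)
  } else {
    idx <- match(sel, t$topology$resnum)
    if (any(is.na(idx)))
      stop("selection residues absent from topology: ",
           paste(sel[is.na(idx)], collapse = ", "))
  }
  if (length(idx) < 3L) stop("selection must cover at least 3 residues")
  n <- length(t$frames)
  m <- frame_rmsd_matrix(t$frames, idx)
  within <- m <= cutoff
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0L) {
    sub <- within[remaining, remaining, drop = FALSE]
    counts <- colSums(sub) - 1L          # exclude self
    centre_pos <- which.max(counts)      # first max = lowest frame index
    members_pos <- which(sub[centre_pos, ])
    midx <- remaining[members_pos]
    tt <- cluster_tightness(m, midx)
    clusters[[length(clusters) + 1L]] <- list(
      members = t$frame_index[midx],
      representative = t$frame_index[remaining[centre_pos]],
      size = length(midx),
      tightness_rmsd = tt$tightness,
      min_avg_member = t$frame_index[tt$min_avg_idx])
    remaining <- setdiff(remaining, midx)
  }
  new_cluster_result(clusters, "gromos",
                     list(cutoff = cutoff,
                          selection = if (is.null(sel)) "all" else sel))
}

#' Extract representative frames as structures
#'
#' Materialises each cluster representative of a [gromos_cluster()] result
#' as a [structure3d] (e.g. to write the docking receptor ensemble as
#' single-model PDBs with [write_structure()]).
#'
#' @param t The clustered [trajectory3d].
#' @param cr The `cluster_result` from [gromos_cluster()].
#' @return A list of [structure3d] objects named `conf<frame_index>`.
#' @export
representative_frames <- function(t, cr) {
  stopifnot(inherits(t, "trajectory3d"), inherits(cr, "cluster_result"))
  reps <- vapply(cr$clusters, function(cl) as.integer(cl$representative), 0L)
  out <- lapply(reps, function(fi) {
    s <- t$topology
    s$ca <- t$frames[[match(fi, t$frame_index)]]
    s$id <- paste0(s$id, "_conf", fi)
    s
  })
  names(out) <- paste0("conf", reps)
  out
}

#' Per-residue Calpha RMSF profile
#'
#' Root-mean-square fluctuation of each residue's Calpha about its mean
#' position, after superposing every frame onto a common reference with a
#' whole-topology Calpha fit. High values mark flexible residues.
#'
#' With `superpose_to = "mean"` (default) the frames are first fitted to
#' frame 0, the mean structure is computed, and the original frames are
#' refitted to that mean before the fluctuations are measured; `"frame0"`
#' fits to the first frame only.
#'
#' @param t A [trajectory3d] with at least 2 frames.
#' @param superpose_to `"mean"` (default) or `"frame0"`.
#' @return An `rmsf_profile`: `resnum`, `rmsf` (Angstrom) and an empty
#'   annotation slot fillable with [annotate_rmsf()].
#' @export
rmsf <- function(t, superpose_to = c("mean", "frame0")) {
  superpose_to <- match.arg(superpose_to)
  stopifnot(inherits(t, "trajectory3d"))
  if (length(t$frames) < 2L)
    stop("RMSF requires at least 2 frames")
  fit_all <- function(frames, ref)
    lapply(frames, function(f)
      apply_superposition(kabsch_superpose(f, ref), f))
  fitted <- fit_all(t$frames, t$frames[[1L]])
  if (superpose_to == "mean") {
    mref <- Reduce(`+`, fitted) / length(fitted)
    fitted <- fit_all(t$frames, mref)
  }
  mpos <- Reduce(`+`, fitted) / length(fitted)
  dev2 <- lapply(fitted, function(f) rowSums((f - mpos)^2))
  vals <- sqrt(Reduce(`+`, dev2) / length(dev2))
  out <- list(resnum = t$topology$resnum, rmsf = vals, annotations = NULL)
  class(out) <- "rmsf_profile"
  out
}

#' Annotate an RMSF profile with site markers
#'
#' Attaches named residue sets (e.g. binding-site residues, variant
#' positions) so exports and plots can mark them.
#'
#' @param profile An `rmsf_profile`.
#' @param sites Named list of integer residue-number vectors.
#' @return The annotated profile.
#' @export
annotate_rmsf <- function(profile, sites) {
  stopifnot(inherits(profile, "rmsf_profile"), is.list(sites))
  profile$annotations <- lapply(sites, as.integer)
  profile
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("<rmsf_profile> ", length(x$resnum), " residues, RMSF ",
      format(min(x$rmsf), digits = 3), "-",
      format(max(x$rmsf), digits = 3), " A\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rmsf_profile <- function(x, ...) {
  ann <- rep("", length(x$resnum))
  for (nm in names(x$annotations)) {
    hit <- x$resnum %in% x$annotations[[nm]]
    ann[hit] <- ifelse(nzchar(ann[hit]), paste(ann[hit], nm, sep = ";"), nm)
  }
  data.frame(resnum = x$resnum, rmsf = as.numeric(x$rmsf),
             annotation = ann, stringsAsFactors = FALSE)
}
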