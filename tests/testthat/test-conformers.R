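test_that("pairwise_rmsd is zero for copies and rigidly moved copies, and separates planted conformers", {
  cfg <- synth_config(seed = 21, n_residues = 15)
  a <- make_chain(cfg)
  m <- pairwise_rmsd(list(a, a, a))
  expect_equal(unclass(m), matrix(0, 3, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(unname(diag(unclass(m))), c(0, 0, 0))

  set.seed(22)
  b <- a
  b$ca <- apply_rigid(a$ca, random_rotation(), c(5, -3, 2))
  m2 <- pairwise_rmsd(list(a, b))
  expect_lt(max(m2), 1e-8)

  # 2 planted conformers x 2 jittered replicas: sigma 0.05 A, separation 2 A
  set.seed(23)
  conf2 <- a
  d <- matrix(stats::rnorm(45), 15, 3)
  conf2$ca <- a$ca + d * 2 / sqrt(mean(rowSums(d^2)))
  jitter <- function(s) {
    s$ca <- s$ca + matrix(stats::rnorm(45, sd = 0.05), 15, 3)
    s
  }
  items <- list(jitter(a), jitter(a), jitter(conf2), jitter(conf2))
  m4 <- pairwise_rmsd(items, labels = c("a1", "a2", "b1", "b2"))
  expect_true(max(m4["a1", "a2"], m4["b1", "b2"]) <
                0.2 * min(m4["a1", "b1"], m4["a2", "b2"]))
  expect_equal(unclass(m4), t(unclass(m4)), tolerance = 1e-12)
})

test_that("hierarchical_cluster handles the k extremes", {
  cfg <- synth_config(seed = 31, n_residues = 10)
  set.seed(31)
  items <- lapply(1:5, function(i) {
    s <- make_chain(cfg)
    s$ca <- s$ca + matrix(stats::rnorm(30, sd = 0.5), 10, 3)
    s$id <- paste0("s", i)
    s
  })
  m <- pairwise_rmsd(items)
  singl <- hierarchical_cluster(m, k = 5)
  expect_length(singl$clusters, 5)
  expect_true(all(vapply(singl$clusters, `[[`, 0, "tightness_rmsd") == 0))
  one <- hierarchical_cluster(m, k = 1)
  expect_length(one$clusters, 1)
  expect_equal(one$clusters[[1]]$size, 5)
  expect_error(hierarchical_cluster(m, k = 0), "between")
  expect_error(hierarchical_cluster(m, k = 9), "between")
})

test_that("hierarchical_cluster recovers a planted 4+4 partition under every linkage", {
  cfg <- synth_config(seed = 33, n_residues = 12)
  base <- make_chain(cfg)
  set.seed(33)
  far <- base
  d <- matrix(stats::rnorm(36), 12, 3)
  far$ca <- base$ca + d * 2.5 / sqrt(mean(rowSums(d^2)))
  mk <- function(s, tag, i) {
    s$ca <- s$ca + matrix(stats::rnorm(36, sd = 0.03), 12, 3)
    s$id <- paste0(tag, i)
    s
  }
  items <- c(lapply(1:4, function(i) mk(base, "wt", i)),
             lapply(1:4, function(i) mk(far, "mut", i)))
  m <- pairwise_rmsd(items)
  truth <- list(sort(paste0("mut", 1:4)), sort(paste0("wt", 1:4)))
  for (linkage in c("complete", "average", "single")) {
    cr <- hierarchical_cluster(m, k = 2, linkage = linkage)
    expect_equal(partition_sets(cr), truth, ignore_attr = TRUE)
  }
})

test_that("hierarchical_cluster agrees with a naive agglomerative oracle on random matrices", {
  set.seed(55)
  for (rep in 1:6) {
    n <- 7
    p <- matrix(stats::rnorm(n * 12), n, 12)
    m <- as.matrix(stats::dist(p))
    dimnames(m) <- list(paste0("i", 1:n), paste0("i", 1:n))
    class(m) <- c("rmsd_matrix", class(m))
    k <- sample(2:4, 1)
    linkage <- sample(c("complete", "average", "single"), 1)
    cr <- hierarchical_cluster(m, k = k, linkage = linkage)
    ref <- oracle_agglomerative(m, k, linkage)
    expect_equal(partition_sets(cr), partition_from_assign(ref),
                 ignore_attr = TRUE,
                 label = paste("linkage", linkage, "k", k, "rep", rep))
  }
})

test_that("cluster tightness is the minimum mean RMSD to the rest and its argmin is the representative", {
  m <- matrix(c(0, 1, 4,
                1, 0, 3,
                4, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  class(m) <- c("rmsd_matrix", class(m))
  cr <- hierarchical_cluster(m, k = 1)
  # mean distances: a (1+4)/2=2.5, b (1+3)/2=2, c (4+3)/2=3.5
  expect_equal(cr$clusters[[1]]$tightness_rmsd, 2)
  expect_equal(cr$clusters[[1]]$representative, "b")
})

test_that("composition reports one-decimal WT/mutant percentages that sum to 100", {
  set.seed(66)
  mk_cr <- function(sizes) {
    # well-separated blobs in 1-D give exactly the wanted cluster sizes
    centers <- seq_along(sizes) * 100
    vals <- unlist(mapply(function(ctr, s) ctr + seq_len(s) * 0.01,
                          centers, sizes, SIMPLIFY = FALSE))
    m <- as.matrix(stats::dist(vals))
    labs <- paste0("x", seq_along(vals))
    dimnames(m) <- list(labs, labs)
    class(m) <- c("rmsd_matrix", class(m))
    hierarchical_cluster(m, k = length(sizes))
  }
  cr <- mk_cr(c(8, 13))
  sizes <- vapply(cr$clusters, `[[`, 0L, "size")
  i8 <- which(sizes == 8L); i13 <- which(sizes == 13L)
  members8 <- cr$clusters[[i8]]$members
  members13 <- cr$clusters[[i13]]$members
  labels <- c(stats::setNames(c(rep("WT", 1), rep("mutant", 7)), members8),
              stats::setNames(c(rep("WT", 3), rep("mutant", 10)), members13))
  comp <- composition(cr, labels)
  expect_equal(comp$pct_mutant[i8], 87.5)
  expect_equal(comp$pct_wt[i8], 12.5)
  expect_equal(comp$pct_wt[i13], 23.1)
  expect_equal(comp$pct_mutant[i13], 76.9)
  expect_equal(comp$frac_wt + comp$frac_mutant, c(1, 1), tolerance = 1e-12)

  # relabeling WT <-> mutant swaps the columns
  flipped <- ifelse(labels == "WT", "mutant", "WT")
  names(flipped) <- names(labels)
  comp2 <- composition(cr, flipped)
  expect_equal(comp2$pct_wt, comp$pct_mutant)
  expect_equal(comp2$pct_mutant, comp$pct_wt)

  # all-WT cluster
  all_wt <- composition(mk_cr(4),
                        stats::setNames(rep("WT", 4), paste0("x", 1:4)))
  expect_equal(all_wt$pct_mutant, 0)

  expect_error(composition(cr, labels[-1]), "unlabeled")
})

test_that("gromos_cluster degenerates correctly at the cutoff extremes", {
  cfg <- synth_config(seed = 41, n_residues = 10, n_frames = 6,
                      jitter_sigma = 0, conformer_weights = 1)
  tr <- make_trajectory(cfg)     # all frames identical
  cr <- gromos_cluster(tr, cutoff = 0.1)
  expect_length(cr$clusters, 1)
  expect_equal(cr$clusters[[1]]$size, 6)
  expect_equal(cr$clusters[[1]]$tightness_rmsd, 0)

  cfg2 <- synth_config(seed = 42, n_residues = 10, n_frames = 5,
                       jitter_sigma = 0.3, conformer_weights = 1)
  tr2 <- make_trajectory(cfg2)
  cr2 <- gromos_cluster(tr2, cutoff = 1e-6)  # below every pairwise RMSD
  expect_length(cr2$clusters, 5)
  expect_true(all(vapply(cr2$clusters, `[[`, 0L, "size") == 1L))
  expect_true(all(vapply(cr2$clusters, `[[`, 0, "tightness_rmsd") == 0))

  expect_error(gromos_cluster(tr, cutoff = 0), "positive")
})

test_that("gromos_cluster recovers a 5+4+3 planted partition and matches the brute-force rule", {
  cfg <- synth_config(seed = 43, n_residues = 12, n_frames = 12,
                      conformer_weights = c(5, 4, 3) / 12,
                      jitter_sigma = 0.05, conformer_separation = 2)
  tr <- make_trajectory(cfg)
  truth <- attr(tr, "conformer")
  cr <- gromos_cluster(tr, cutoff = 0.5)
  got <- lapply(cr$clusters, function(cl) sort(as.integer(cl$members)))
  want <- unname(lapply(split(0:11, truth), sort))
  expect_setequal(got, want)

  ref <- oracle_gromos(oracle_rmsd_matrix(tr$frames), 0.5)
  expect_equal(lapply(cr$clusters, function(cl) sort(as.integer(cl$members))),
               lapply(ref, function(cl) sort(cl$members)))
  expect_equal(vapply(cr$clusters, function(cl) as.integer(cl$representative), 0L),
               vapply(ref, `[[`, 0L, "centre"))
})

test_that("every gromos member lies within the cutoff of its representative and sizes sum to the frame count", {
  cfg <- synth_config(seed = 44, n_frames = 25, n_residues = 15,
                      jitter_sigma = 0.2)
  tr <- make_trajectory(cfg)
  cutoff <- 0.6
  cr <- gromos_cluster(tr, cutoff = cutoff)
  expect_equal(sum(vapply(cr$clusters, `[[`, 0L, "size")), 25L)
  for (cl in cr$clusters) {
    rep_i <- match(as.integer(cl$representative), tr$frame_index)
    for (mi in as.integer(cl$members)) {
      i <- match(mi, tr$frame_index)
      d <- kabsch_superpose(tr$frames[[i]], tr$frames[[rep_i]])$rmsd
      expect_lte(d, cutoff + 1e-9)
    }
  }
})

test_that("rmsf is zero for a constant trajectory and rejects single frames", {
  ch <- straight_chain(12)
  tr <- trajectory3d(ch, replicate(8, ch$ca, simplify = FALSE))
  prof <- rmsf(tr)
  expect_equal(prof$rmsf, rep(0, 12), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(rmsf(trajectory3d(ch, list(ch$ca))), "at least 2")
})

test_that("a 1 A two-frame displacement gives RMSF d/2 at the displaced residue", {
  # a large globular anchor pins the superposition; the residue nearest the
  # centroid is displaced so the fit can absorb almost none of it
  set.seed(67)
  n <- 80
  coords <- random_cloud(n, scale = 8)
  coords <- sweep(coords, 2, colMeans(coords))
  i <- which.min(rowSums(coords^2))
  anchor <- structure3d("anchor", 1:n, "A", rep("ALA", n), coords)
  f2 <- coords
  f2[i, 2] <- f2[i, 2] + 1
  prof <- rmsf(trajectory3d(anchor, list(coords, f2)),
               superpose_to = "mean")
  expect_equal(prof$rmsf[i], 0.5, tolerance = 0.02)
  expect_lt(max(prof$rmsf[-i]), 0.05)
})

test_that("rmsf is invariant under a global rigid motion of every frame", {
  cfg <- synth_config(seed = 51, n_frames = 10, n_residues = 12,
                      jitter_sigma = 0.3)
  tr <- make_trajectory(cfg)
  prof <- rmsf(tr)
  set.seed(52)
  R <- random_rotation(); tv <- c(10, -4, 7)
  tr2 <- trajectory3d(tr$topology,
                      lapply(tr$frames, apply_rigid, R = R, tvec = tv))
  prof2 <- rmsf(tr2)
  expect_lt(max(abs(prof$rmsf - prof2$rmsf)), 1e-6)
})

test_that("a planted flexible window stands out of a rigid background by > 5x", {
  n <- 30
  ch <- straight_chain(n)
  set.seed(53)
  window <- 13:17
  frames <- lapply(1:40, function(i) {
    f <- ch$ca + matrix(stats::rnorm(n * 3, sd = 0.05), n, 3)
    f[window, ] <- f[window, ] + matrix(stats::rnorm(15, sd = 1), 5, 3)
    f
  })
  prof <- rmsf(trajectory3d(ch, frames))
  expect_gt(mean(prof$rmsf[window]), 5 * mean(prof$rmsf[-window]))
})

test_that("rmsf profiles annotate and tabulate site markers", {
  cfg <- synth_config(seed = 54, n_frames = 5, n_residues = 10,
                      jitter_sigma = 0.1)
  prof <- annotate_rmsf(rmsf(make_trajectory(cfg)),
                        list(binding_site = c(2L, 3L), variant = 7L))
  df <- as.data.frame(prof)
  expect_equal(df$annotation[2], "binding_site")
  expect_equal(df$annotation[7], "variant")
  expect_equal(df$annotation[1], "")
})

test_that("representative frames materialise as structures and export as PDB", {
  cfg <- synth_config(seed = 61, n_frames = 12, n_residues = 10)
  tr <- make_trajectory(cfg)
  cr <- gromos_cluster(tr, cutoff = 0.5)
  reps <- representative_frames(tr, cr)
  expect_length(reps, length(cr$clusters))
  fi <- as.integer(cr$clusters[[1]]$representative)
  expect_equal(reps[[1]]$ca, tr$frames[[match(fi, tr$frame_index)]],
               ignore_attr = TRUE)
  p <- tempfile(fileext = ".pdb")
  write_structure(reps[[1]], p)
  expect_lt(max(abs(read_structure(p)$ca - reps[[1]]$ca)), 1e-3)
})
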