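# Synthetic fixtures: toy Calpha chains, trajectories with planted
# conformers, mutant variants, ligand complexes and docking score tables
# with planted actives. Every generator is a pure function of its
# configuration (including the seed): reruns are bit-identical, and the
# ground truth (conformer assignments, signal conformations, scripted
# pocket distances) is returned alongside the data so downstream checks
# never have to re-derive it.

# Evaluate `code` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-data configuration
#'
#' Collects every knob of the fixture generators with defaults chosen to
#' emulate the study conditions the package is built for: trajectories of
#' 100 recorded snapshots drawn from a few metastable conformers, and
#' virtual screens of 120 active molecules against 2500 decoys.
#'
#' @param seed Integer RNG seed (mandatory source of all randomness).
#' @param n_residues Chain length (>= 3); default 50.
#' @param resnum_start First residue number; default 1.
#' @param curvature Smooth random curvature of the idealized chain
#'   (0 = straight); default 0.15.
#' @param n_frames Trajectory frames; default 100.
#' @param conformer_weights Occupancy weights of the planted conformers
#'   (must sum to 1); their number sets the conformer count. Default
#'   `c(0.6, 0.3, 0.1)`.
#' @param jitter_sigma Per-coordinate Gaussian jitter sd in Angstrom
#'   around each conformer; default 0.05.
#' @param conformer_separation Approximate pairwise Calpha RMSD between
#'   planted conformers in Angstrom; default 2.
#' @param perturbation_radius Radius (Angstrom) of the mutation-induced
#'   displacement around the site; default 5.
#' @param perturbation_magnitude Displacement magnitude per affected
#'   residue in Angstrom; default 1.
#' @param n_actives,n_decoys Screen composition; defaults 120 and 2500.
#' @param decoy_energy_mu,decoy_energy_sigma Decoy docking-energy
#'   distribution, kcal/mol; defaults -7 and 1.
#' @param active_shift Mean energy shift of actives below decoys
#'   (kcal/mol, planted signal); default 2.
#' @param n_conformations,n_sites Receptor ensemble shape of the score
#'   table; defaults 5 conformations x 1 site.
#' @param signal_conformations Conformation ids (0-based) in which the
#'   active shift applies; NULL (default) = all.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_residues = 50L, resnum_start = 1L,
                         curvature = 0.15,
                         n_frames = 100L,
                         conformer_weights = c(0.6, 0.3, 0.1),
                         jitter_sigma = 0.05,
                         conformer_separation = 2,
                         perturbation_radius = 5,
                         perturbation_magnitude = 1,
                         n_actives = 120L, n_decoys = 2500L,
                         decoy_energy_mu = -7, decoy_energy_sigma = 1,
                         active_shift = 2,
                         n_conformations = 5L, n_sites = 1L,
                         signal_conformations = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_residues >= 3L, n_frames >= 1L,
            all(conformer_weights > 0),
            abs(sum(conformer_weights) - 1) < 1e-9,
            jitter_sigma >= 0, conformer_separation >= 0,
            n_actives >= 1L, n_decoys >= 1L, decoy_energy_sigma > 0,
            n_conformations >= 1L, n_sites >= 1L)
  cfg <- list(seed = as.integer(seed), n_residues = as.integer(n_residues),
              resnum_start = as.integer(resnum_start),
              curvature = curvature, n_frames = as.integer(n_frames),
              conformer_weights = conformer_weights,
              jitter_sigma = jitter_sigma,
              conformer_separation = conformer_separation,
              perturbation_radius = perturbation_radius,
              perturbation_magnitude = perturbation_magnitude,
              n_actives = as.integer(n_actives),
              n_decoys = as.integer(n_decoys),
              decoy_energy_mu = decoy_energy_mu,
              decoy_energy_sigma = decoy_energy_sigma,
              active_shift = active_shift,
              n_conformations = as.integer(n_conformations),
              n_sites = as.integer(n_sites),
              signal_conformations = signal_conformations)
  class(cfg) <- "synth_config"
  cfg
}

chain_coords <- function(n, curvature) {
  pos <- matrix(0, n, 3L)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    if (curvature > 0) {
      dir <- dir + curvature * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
    }
    pos[i, ] <- pos[i - 1L, ] + 3.8 * dir
  }
  pos
}

#' Generate an idealized Calpha chain
#'
#' Builds a smooth Calpha trace with exactly 3.8 Angstrom between
#' consecutive residues (the canonical trans-peptide Calpha-Calpha
#' distance); `curvature = 0` gives a straight chain along x. Residue
#' names are drawn uniformly from the 20 standard amino acids.
#'
#' @param cfg A [synth_config()].
#' @param id,variant Structure labelling.
#' @return A [structure3d].
#' @export
make_chain <- function(cfg, id = "synthetic", variant = "WT") {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_residues < 3L) stop("n_residues must be >= 3")
  with_seed(cfg$seed, {
    ca <- chain_coords(cfg$n_residues, cfg$curvature)
    resname <- sample(unname(AA1), cfg$n_residues, replace = TRUE)
    structure3d(id = id,
                resnum = seq(cfg$resnum_start,
                             length.out = cfg$n_residues),
                chain = "A", resname = resname, ca = ca,
                variant = variant)
  })
}

#' Generate a trajectory with planted conformers
#'
#' Frames are drawn from `length(conformer_weights)` base conformations
#' with the given occupancy weights; the base conformations are the chain
#' plus independent smooth displacement fields scaled so that their
#' pairwise Calpha RMSD is approximately `conformer_separation`. Each
#' frame adds i.i.d. Gaussian jitter of sd `jitter_sigma` per coordinate.
#'
#' The frame-to-conformer assignment is returned as ground truth in
#' attribute `"conformer"` (1-based conformer of each frame) and the base
#' coordinate sets in attribute `"conformer_coords"`.
#'
#' @param cfg A [synth_config()].
#' @param id Trajectory label.
#' @return A [trajectory3d] with ground-truth attributes.
#' @export
make_trajectory <- function(cfg, id = "synthetic_md") {
  stopifnot(inherits(cfg, "synth_config"))
  topo <- make_chain(cfg, id = id)
  k <- length(cfg$conformer_weights)
  n <- cfg$n_residues
  with_seed(cfg$seed + 1L, {
    # independent centred fields of per-atom rms norm sep/sqrt(2): any two
    # near-orthogonal fields then differ by ~ sep
    deltas <- lapply(seq_len(k), function(i) {
      d <- matrix(stats::rnorm(n * 3L), n, 3L)
      d <- sweep(d, 2L, colMeans(d))
      d * (cfg$conformer_separation / sqrt(2)) /
        sqrt(mean(rowSums(d^2)))
    })
    confs <- lapply(deltas, function(d) topo$ca + d)
    assign <- sample.int(k, cfg$n_frames, replace = TRUE,
                         prob = cfg$conformer_weights)
    frames <- lapply(assign, function(a) {
      f <- confs[[a]]
      if (cfg$jitter_sigma > 0)
        f <- f + matrix(stats::rnorm(n * 3L, sd = cfg$jitter_sigma),
                        n, 3L)
      f
    })
    t <- trajectory3d(topo, frames)
    attr(t, "conformer") <- assign
    attr(t, "conformer_coords") <- confs
    t
  })
}

#' Derive a mutant structure from a wild-type chain
#'
#' Substitutions rename the target residue and displace every residue
#' within `perturbation_radius` of the site (Calpha distance) by a random
#' direction of length `perturbation_magnitude`, emulating a localized
#' mutation-induced conformational change; magnitude 0 changes only the
#' residue name. Deletions remove the residues and keep the numbering, so
#' the gap survives residue mapping.
#'
#' @param s Wild-type [structure3d].
#' @param spec A [parse_mutation_spec()] result (or string).
#' @param cfg A [synth_config()] providing seed, radius and magnitude.
#' @return A [structure3d] labelled with the mutation.
#' @export
make_mutant <- function(s, spec, cfg) {
  stopifnot(inherits(s, "structure3d"), inherits(cfg, "synth_config"))
  if (is.character(spec)) spec <- parse_mutation_spec(spec)
  stopifnot(inherits(spec, "mutation_spec"))
  if (spec$kind == "substitution") {
    i <- match(spec$position, s$resnum)
    if (is.na(i)) stop("mutation site ", spec$position, " absent from '",
                       s$id, "'")
    out <- s
    out$resname[i] <- AA1[[spec$alt_residue]]
    if (cfg$perturbation_magnitude > 0) {
      win <- distance_window(s, spec$position, cfg$perturbation_radius)
      j <- match(win$resnums, s$resnum)
      out$ca[j, ] <- with_seed(cfg$seed + 2L, {
        dirs <- matrix(stats::rnorm(length(j) * 3L), length(j), 3L)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        s$ca[j, , drop = FALSE] + cfg$perturbation_magnitude * dirs
      })
    }
  } else {
    if (!all(spec$position %in% s$resnum))
      stop("deletion range ", min(spec$position), "-", max(spec$position),
           " not fully present in '", s$id, "'")
    keep <- !(s$resnum %in% spec$position)
    out <- s
    out$resnum <- s$resnum[keep]
    out$chain <- s$chain[keep]
    out$resname <- s$resname[keep]
    out$ca <- s$ca[keep, , drop = FALSE]
  }
  out$variant <- format(spec)
  out$id <- paste0(s$id, "_", format(spec))
  out
}

#' Generate a docking score table with planted actives
#'
#' Emulates an ensemble virtual screen: for every
#' (conformation, site) pair, decoy energies are drawn from
#' `Normal(decoy_energy_mu, decoy_energy_sigma)` and active energies from
#' the same distribution shifted down by `active_shift` -- but only in the
#' `signal_conformations`; elsewhere actives score like decoys. Draws are
#' independent across (conformation, site), as separate docking runs are.
#'
#' @param cfg A [synth_config()].
#' @return A [score_table()] with ground-truth attribute
#'   `"signal_conformations"`.
#' @export
make_score_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  compounds <- c(sprintf("ACT%04d", seq_len(cfg$n_actives)),
                 sprintf("DEC%04d", seq_len(cfg$n_decoys)))
  is_active <- c(rep(TRUE, cfg$n_actives), rep(FALSE, cfg$n_decoys))
  confs <- seq_len(cfg$n_conformations) - 1L   # 0 = starting structure
  signal <- if (is.null(cfg$signal_conformations)) confs
            else as.integer(cfg$signal_conformations)
  with_seed(cfg$seed + 3L, {
    rows <- list()
    for (cf in confs) {
      shift <- if (cf %in% signal) cfg$active_shift else 0
      for (st in seq_len(cfg$n_sites)) {
        mu <- ifelse(is_active, cfg$decoy_energy_mu - shift,
                     cfg$decoy_energy_mu)
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = compounds, conformation = cf, site = st,
          energy = stats::rnorm(length(compounds), mean = mu,
                                sd = cfg$decoy_energy_sigma),
          stringsAsFactors = FALSE)
      }
    }
    t <- score_table(do.call(rbind, rows),
                     actives = compounds[is_active])
    attr(t, "signal_conformations") <- signal
    t
  })
}

#' Write a toy protein-ligand complex with a scripted pocket
#'
#' Builds a PDB file containing a single-atom HETATM ligand at the origin
#' and protein residues whose nearest atom sits at exactly the scripted
#' distance from it, so the pocket at any radius is known by construction
#' (default distances 3.0, 4.9, 5.1, 6.5, 8.0 and 10.0 Angstrom place two
#' residues inside a 5 Angstrom pocket, with a deliberate 4.9/5.1 pair
#' straddling the threshold). Each residue carries three atoms; the
#' nearest one realises the scripted distance.
#'
#' @param path Output PDB path.
#' @param residue_distances Nearest-atom distance of each residue from the
#'   ligand, in Angstrom.
#' @param ligand_id Ligand residue name (default `"LIG"`).
#' @param n_ligand_copies 1 (default) or 2; the second copy, placed far
#'   away, makes the ligand name ambiguous on purpose.
#' @return Invisibly, a list with `path`, `residue_distances`,
#'   `ligand_id`, and `pocket`, a function of `r` returning the scripted
#'   pocket residue numbers.
#' @export
make_complex <- function(path,
                         residue_distances = c(3.0, 4.9, 5.1, 6.5, 8.0,
                                               10.0),
                         ligand_id = "LIG", n_ligand_copies = 1L) {
  m <- length(residue_distances)
  # spread residue directions over the sphere (golden spiral)
  gold <- pi * (3 - sqrt(5))
  dirs <- t(vapply(seq_len(m), function(i) {
    z <- 1 - 2 * (i - 0.5) / m
    r <- sqrt(max(1 - z^2, 0))
    c(r * cos(gold * i), r * sin(gold * i), z)
  }, numeric(3L)))
  type <- character(); resno <- integer(); resid <- character()
  elety <- character(); chain <- character(); xyz <- NULL
  for (i in seq_len(m)) {
    d <- residue_distances[i]; u <- dirs[i, ]
    at <- rbind(d * u,                 # nearest atom, exactly at d
                (d + 1.2) * u,
                (d + 2.4) * u)
    xyz <- rbind(xyz, at)
    type <- c(type, rep("ATOM", 3L))
    resno <- c(resno, rep(i, 3L))
    resid <- c(resid, rep("ALA", 3L))
    elety <- c(elety, c("CB", "CA", "N"))
    chain <- c(chain, rep("A", 3L))
  }
  xyz <- rbind(xyz, c(0, 0, 0))
  type <- c(type, "HETATM"); resno <- c(resno, 901L)
  resid <- c(resid, ligand_id); elety <- c(elety, "C1")
  chain <- c(chain, "A")
  if (n_ligand_copies >= 2L) {
    xyz <- rbind(xyz, c(500, 500, 500))
    type <- c(type, "HETATM"); resno <- c(resno, 902L)
    resid <- c(resid, ligand_id); elety <- c(elety, "C1")
    chain <- c(chain, "A")
  }
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)), type = type,
                   resno = resno, resid = resid, elety = elety,
                   chain = chain)
  invisible(list(path = path, residue_distances = residue_distances,
                 ligand_id = ligand_id,
                 pocket = function(r) which(residue_distances <= r)))
}
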