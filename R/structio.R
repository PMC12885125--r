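# Structure / trajectory I/O and residue bookkeeping.
#
# Structures are Calpha-only: an ordered residue list (resnum, chain, resname)
# with one Calpha coordinate per residue. Trajectories are an ordered set of
# frames sharing a single residue topology, read from multi-model PDB files.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Construct a Calpha-only structure
#'
#' A `structure3d` is the package's central container: an ordered list of
#' residues, each with a residue number, chain identifier, 3-letter residue
#' name and one Calpha coordinate in Angstrom, plus a variant label
#' (`"WT"` or a mutant name such as `"T790M"`).
#'
#' @param id Text label for the structure.
#' @param resnum Integer vector of residue numbers, strictly increasing
#'   within a chain.
#' @param chain Character vector of chain identifiers (recycled if length 1).
#' @param resname Character vector of 3-letter residue codes.
#' @param ca Numeric n x 3 matrix of Calpha coordinates (Angstrom).
#' @param variant Variant label; `"WT"` by default.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(id, resnum, chain, resname, ca, variant = "WT") {
  resnum <- as.integer(resnum)
  n <- length(resnum)
  if (length(chain) == 1L) chain <- rep(chain, n)
  ca <- matrix(as.numeric(ca), ncol = 3L,
               dimnames = list(NULL, c("x", "y", "z")))
  stopifnot(length(chain) == n, length(resname) == n, nrow(ca) == n)
  if (any(!is.finite(ca)))
    stop("non-finite Calpha coordinates")
  for (ch in unique(chain)) {
    r <- resnum[chain == ch]
    if (any(diff(r) <= 0L))
      stop("residue numbers must be strictly increasing within chain '",
           ch, "'")
  }
  out <- list(id = as.character(id), resnum = resnum,
              chain = as.character(chain),
              resname = as.character(resname), ca = ca,
              variant = as.character(variant))
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", x$id, " (", x$variant, "): ",
      length(x$resnum), " residues, chain ",
      paste(unique(x$chain), collapse = ","),
      ", resno ", min(x$resnum), "-", max(x$resnum), "\n", sep = "")
  invisible(x)
}

#' @export
length.structure3d <- function(x) length(x$resnum)

# Split raw PDB lines into per-model coordinate-record chunks.
# A file with no MODEL records is one model (index 0).
split_pdb_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts))
    ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) lines[(starts[i] + 1L):(ends[i] - 1L)])
}

# Parse one model chunk through bio3d; returns the bio3d pdb object.
parse_pdb_chunk <- function(chunk) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(chunk, "END"), tf)
  bio3d::read.pdb(tf, verbose = FALSE)
}

# Extract a structure3d from a bio3d pdb object (one model).
structure_from_pdb <- function(pdb, chain = NULL, id = "structure",
                               variant = "WT") {
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found")
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not present")
  ins <- !is.na(at$insert) & nzchar(at$insert)
  if (any(ins))
    stop("insertion-coded residues are not supported (first at residue ",
         at$resno[which(ins)[1L]], at$insert[which(ins)[1L]], ")")
  all_res <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  # one CA per residue: keep the first occurrence (altlocs already reduced)
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca) > 0L)
    warning("skipping ", length(missing_ca),
            " residue(s) without a Calpha atom: ",
            paste(utils::head(missing_ca, 5L), collapse = ", "),
            if (length(missing_ca) > 5L) ", ..." else "")
  if (nrow(ca) == 0L) stop("no Calpha atoms found")
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  structure3d(id = id, resnum = ca$resno, chain = ca$chain,
              resname = ca$resid, ca = cbind(ca$x, ca$y, ca$z),
              variant = variant)
}

#' Read a Calpha structure from a PDB file
#'
#' Reads one model from a (possibly multi-model) PDB file and returns its
#' Calpha trace. Residue numbering is taken verbatim from the file; non-CA
#' atoms are ignored; for alternate locations the blank/'A' record is kept.
#' Residues lacking a Calpha atom are skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param model_index Zero-based model index. A file without MODEL records
#'   counts as a single model with index 0.
#' @param chain Chain identifier to read; default the first chain in the file.
#' @param id Label for the structure; defaults to the file name.
#' @param variant Variant label attached to the structure.
#' @return A [structure3d] object.
#' @export
read_structure <- function(path, model_index = 0L, chain = NULL,
                           id = NULL, variant = "WT") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  if (model_index < 0L || model_index >= length(models))
    stop("model out of range: requested index ", model_index, " but file '",
         basename(path), "' has ", length(models), " model(s)")
  pdb <- parse_pdb_chunk(models[[model_index + 1L]])
  structure_from_pdb(pdb, chain = chain, id = id, variant = variant)
}

#' Construct a trajectory
#'
#' A `trajectory3d` holds an ordered list of coordinate frames sharing one
#' residue topology. Frame indices are contiguous from 0; index 0 is the
#' starting structure of the simulation.
#'
#' @param topology A [structure3d] giving the shared residue list (its
#'   coordinates are those of the reference/first frame unless stated).
#' @param frames List of n x 3 coordinate matrices, one per frame.
#' @return An object of class `trajectory3d` with fields `topology`,
#'   `frames`, and `frame_index` (0-based).
#' @export
trajectory3d <- function(topology, frames) {
  stopifnot(inherits(topology, "structure3d"), length(frames) >= 1L)
  n <- length(topology$resnum)
  frames <- lapply(frames, function(f) {
    f <- matrix(as.numeric(f), ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
    if (nrow(f) != n)
      stop("frame has ", nrow(f), " coordinates but topology has ",
           n, " residues")
    if (any(!is.finite(f))) stop("non-finite frame coordinates")
    f
  })
  out <- list(topology = topology, frames = frames,
              frame_index = seq_along(frames) - 1L)
  class(out) <- "trajectory3d"
  out
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat("<trajectory3d> ", x$topology$id, ": ", length(x$frames),
      " frames x ", length(x$topology$resnum), " residues\n", sep = "")
  invisible(x)
}

#' @export
length.trajectory3d <- function(x) length(x$frames)

#' Read a trajectory from a multi-model PDB file
#'
#' Every MODEL block must share an identical Calpha residue topology
#' (same residue numbers and names, in order); the first discordant residue
#' is named in the error otherwise. Frames keep file order and are indexed
#' from 0.
#'
#' @inheritParams read_structure
#' @return A [trajectory3d] object.
#' @export
read_trajectory <- function(path, chain = NULL, id = NULL, variant = "WT") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  frames <- vector("list", length(models))
  topo <- NULL
  for (i in seq_along(models)) {
    s <- structure_from_pdb(parse_pdb_chunk(models[[i]]), chain = chain,
                            id = id, variant = variant)
    if (is.null(topo)) {
      topo <- s
    } else {
      if (length(s$resnum) != length(topo$resnum) ||
          any(s$resnum != topo$resnum) || any(s$resname != topo$resname)) {
        bad <- topology_mismatch(topo, s)
        stop("topology mismatch in model ", i - 1L,
             ": first discordant residue ", bad)
      }
    }
    frames[[i]] <- s$ca
  }
  trajectory3d(topo, frames)
}

# Describe the first residue at which two topologies disagree.
topology_mismatch <- function(a, b) {
  n <- min(length(a$resnum), length(b$resnum))
  if (n > 0L) {
    diff <- which(a$resnum[seq_len(n)] != b$resnum[seq_len(n)] |
                  a$resname[seq_len(n)] != b$resname[seq_len(n)])
    if (length(diff) > 0L) {
      i <- diff[1L]
      return(paste0(a$resname[i], a$resnum[i], " vs ",
                    b$resname[i], b$resnum[i]))
    }
  }
  if (length(a$resnum) > length(b$resnum))
    paste0(a$resname[n + 1L], a$resnum[n + 1L], " (absent from model)")
  else
    paste0(b$resname[n + 1L], b$resnum[n + 1L], " (absent from reference)")
}

#' Write a structure or trajectory as a PDB file
#'
#' Calpha records only; coordinates are written at the PDB's 1e-3 Angstrom
#' precision, so a write/read round trip reproduces residue numbers and
#' names exactly and coordinates to 1e-3 Angstrom.
#'
#' @param x A [structure3d] or [trajectory3d].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  bio3d::write.pdb(file = path, xyz = as.vector(t(x$ca)),
                   resno = x$resnum, resid = x$resname,
                   elety = rep("CA", length(x$resnum)), chain = x$chain)
  invisible(path)
}

#' @rdname write_structure
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "trajectory3d"))
  xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  topo <- x$topology
  bio3d::write.pdb(file = path, xyz = xyz, resno = topo$resnum,
                   resid = topo$resname,
                   elety = rep("CA", length(topo$resnum)), chain = topo$chain)
  invisible(path)
}

#' Parse a mutation specification string
#'
#' Accepts point substitutions in the usual `<wt><position><alt>` notation
#' (e.g. `"T790M"`, `"L858R"`) and deletions as either an explicit range
#' (`"del746-750"`) or a named alias (`"del19"`), which must be resolved
#' through the `aliases` table because alias names carry no coordinates.
#'
#' @param text Mutation string.
#' @param aliases Named list mapping alias names (e.g. `"19"` or `"del19"`)
#'   to length-2 integer vectors `c(first, last)` of deleted residues.
#' @return A `mutation_spec` object with fields `kind`
#'   (`"substitution"` or `"deletion"`), `position` (integer, or the full
#'   deleted range for deletions), and for substitutions `wt_residue` and
#'   `alt_residue` (1-letter codes).
#' @export
parse_mutation_spec <- function(text, aliases = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([A-Z])([0-9]+)([A-Z])$", text))[[1L]]
  if (length(m) == 4L) {
    if (!(m[2L] %in% names(AA1)) || !(m[4L] %in% names(AA1)))
      stop("cannot parse mutation '", text, "': unknown amino-acid code")
    pos <- as.integer(m[3L])
    if (pos <= 0L) stop("mutation position must be positive")
    out <- list(kind = "substitution", wt_residue = m[2L], position = pos,
                alt_residue = m[4L])
    class(out) <- "mutation_spec"
    return(out)
  }
  m <- regmatches(text, regexec("^del([0-9]+)-([0-9]+)$", text))[[1L]]
  if (length(m) == 3L) {
    from <- as.integer(m[2L]); to <- as.integer(m[3L])
    if (from <= 0L || to < from)
      stop("invalid deletion range in '", text, "'")
    out <- list(kind = "deletion", position = from:to)
    class(out) <- "mutation_spec"
    return(out)
  }
  m <- regmatches(text, regexec("^del([A-Za-z0-9]+)$", text))[[1L]]
  if (length(m) == 2L) {
    key <- m[2L]
    rng <- aliases[[key]]
    if (is.null(rng)) rng <- aliases[[paste0("del", key)]]
    if (is.null(rng))
      stop("unresolved deletion alias 'del", key,
           "': supply its residue range via the alias table")
    rng <- as.integer(rng)
    if (length(rng) != 2L || rng[1L] <= 0L || rng[2L] < rng[1L])
      stop("alias 'del", key, "' must map to c(first, last)")
    out <- list(kind = "deletion", position = rng[1L]:rng[2L],
                alias = paste0("del", key))
    class(out) <- "mutation_spec"
    return(out)
  }
  stop("cannot parse mutation specification '", text, "'")
}

#' @export
format.mutation_spec <- function(x, ...) {
  if (x$kind == "substitution")
    paste0(x$wt_residue, x$position, x$alt_residue)
  else
    paste0("del", min(x$position), "-", max(x$position))
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec> ", format(x), " (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' Map shared residues between two structures
#'
#' Builds a one-to-one residue correspondence by matching residue numbers,
#' which are assumed to be pre-harmonized to a common numbering scheme.
#' Residues absent from either side (e.g. across a deletion) are left
#' unmapped rather than shifted.
#'
#' @param a,b [structure3d] objects.
#' @return A `residue_map`: a data frame with columns `resnum_a`, `resnum_b`
#'   (equal by construction), sorted by residue number, with attributes
#'   `unmapped_a` and `unmapped_b` listing residues unique to each side.
#' @export
map_shared_residues <- function(a, b) {
  stopifnot(inherits(a, "structure3d"), inherits(b, "structure3d"))
  shared <- sort(intersect(a$resnum, b$resnum))
  if (length(shared) == 0L)
    stop("no shared residue numbers between '", a$id, "' and '", b$id, "'")
  out <- data.frame(resnum_a = shared, resnum_b = shared)
  attr(out, "unmapped_a") <- sort(setdiff(a$resnum, shared))
  attr(out, "unmapped_b") <- sort(setdiff(b$resnum, shared))
  class(out) <- c("residue_map", "data.frame")
  out
}

#' @export
print.residue_map <- function(x, ...) {
  cat("<residue_map> ", nrow(x), " mapped pairs; ",
      length(attr(x, "unmapped_a")), "/", length(attr(x, "unmapped_b")),
      " unmapped (a/b)\n", sep = "")
  invisible(x)
}
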