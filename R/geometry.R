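# Rigid-body superposition, RMSD and residue-selection windows.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Computes the proper rotation and translation minimising the RMSD between
#' two paired point sets. Reflections are corrected by sign-flipping the
#' smallest singular vector, so chirality is always preserved.
#'
#' The returned transform maps `mobile` onto `target`:
#' `mobile %*% t(rotation) + translation` (row-vector convention).
#'
#' @param mobile,target Numeric n x 3 matrices of paired coordinates
#'   (Angstrom), n >= 3, no missing values.
#' @return A `superposition` object: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom, after superposition) and
#'   `n_atoms`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (ncol(mobile) != 3L || ncol(target) != 3L)
    stop("coordinate matrices must have 3 columns")
  if (nrow(mobile) != nrow(target))
    stop("point sets differ in length (", nrow(mobile), " vs ",
         nrow(target), ")")
  if (nrow(mobile) < 3L)
    stop("need at least 3 points to superpose")
  if (any(!is.finite(mobile)) || any(!is.finite(target)))
    stop("non-finite coordinates")
  pbar <- colMeans(mobile); qbar <- colMeans(target)
  P <- sweep(mobile, 2L, pbar); Q <- sweep(target, 2L, qbar)
  H <- crossprod(P, Q)                      # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((Q - P %*% t(R))^2)))
  out <- list(rotation = R, translation = as.numeric(qbar - R %*% pbar),
              rmsd = rmsd, n_atoms = nrow(mobile))
  class(out) <- "superposition"
  out
}

#' Apply a superposition transform to coordinates
#'
#' @param sup A `superposition` from [kabsch_superpose()].
#' @param coords Numeric n x 3 matrix.
#' @return The transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd ", format(x$rmsd, digits = 4), " A over ",
      x$n_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' Construct a residue selection
#'
#' @param resnums Integer residue numbers.
#' @param rule Text descriptor of the rule that produced the selection
#'   (e.g. `"distance-window r=5"`).
#' @param anchor Anchor residue number or ligand identifier, if any.
#' @return A `residue_selection` object.
#' @export
residue_selection <- function(resnums, rule = "manual", anchor = NA) {
  out <- list(resnums = sort(unique(as.integer(resnums))), rule = rule,
              anchor = anchor)
  class(out) <- "residue_selection"
  out
}

#' @export
print.residue_selection <- function(x, ...) {
  cat("<residue_selection> ", length(x$resnums), " residues [", x$rule,
      if (!all(is.na(x$anchor))) paste0(", anchor ", x$anchor) else "",
      "]\n", sep = "")
  invisible(x)
}

# Coerce selection-ish inputs to an integer resnum vector (NULL = everything).
selection_resnums <- function(selection) {
  if (is.null(selection)) return(NULL)
  if (inherits(selection, "residue_selection")) return(selection$resnums)
  as.integer(selection)
}

#' Residues within a spatial window of an anchor residue
#'
#' Selects residues whose Calpha lies within `r` Angstrom (closed threshold,
#' `d <= r`) of the anchor residue's Calpha; the anchor itself is always
#' included. This is the spatial "window surrounding the mutation site" used
#' for localized structure comparison; measure it once in a designated
#' reference structure and propagate the residue numbers to all structures
#' so pairwise RMSDs share one residue set.
#'
#' @param s A [structure3d].
#' @param anchor_resnum Residue number of the anchor (e.g. mutation site).
#' @param r Radius in Angstrom.
#' @return A [residue_selection].
#' @export
distance_window <- function(s, anchor_resnum, r) {
  stopifnot(inherits(s, "structure3d"), r >= 0)
  i <- match(as.integer(anchor_resnum), s$resnum)
  if (is.na(i)) stop("anchor residue ", anchor_resnum, " absent from '",
                     s$id, "'")
  d <- sqrt(rowSums(sweep(s$ca, 2L, s$ca[i, ])^2))
  residue_selection(s$resnum[d <= r],
                    rule = paste0("distance-window r=", r),
                    anchor = as.integer(anchor_resnum))
}

#' Residues within a sequence window of an anchor residue
#'
#' Selects residues with `|resnum - anchor| <= k` that exist in the
#' structure; windows truncate naturally at chain ends.
#'
#' @param s A [structure3d].
#' @param anchor_resnum Anchor residue number.
#' @param k Half-width in residues.
#' @return A [residue_selection].
#' @export
sequence_window <- function(s, anchor_resnum, k) {
  stopifnot(inherits(s, "structure3d"), k >= 0)
  anchor_resnum <- as.integer(anchor_resnum)
  if (!(anchor_resnum %in% s$resnum))
    stop("anchor residue ", anchor_resnum, " absent from '", s$id, "'")
  residue_selection(s$resnum[abs(s$resnum - anchor_resnum) <= k],
                    rule = paste0("sequence-window k=", k),
                    anchor = anchor_resnum)
}

#' Windowed Calpha RMSD between two structures
#'
#' Superposes `b` onto `a` over the residues given by `superpose_scope`
#' and reports the RMSD over the selected residues. Residues are paired
#' through `map` (by shared residue number); the selection and scope are
#' intersected with the mapped residues.
#'
#' The default scope `"selection"` is a local fit: the window itself is
#' superposed, which isolates local deformation around a mutation site.
#' `"whole"` superposes on all mapped residues and then measures the window,
#' which instead reports how far the window moves relative to the rest of
#' the domain.
#'
#' @param a,b [structure3d] objects.
#' @param selection A [residue_selection], integer resnum vector, or NULL
#'   for all mapped residues.
#' @param map A `residue_map` from [map_shared_residues()]; computed
#'   automatically when NULL.
#' @param superpose_scope `"selection"` (default) or `"whole"`.
#' @return RMSD in Angstrom (numeric scalar), with the fitted
#'   `superposition` attached as attribute `"superposition"`.
#' @export
ca_rmsd <- function(a, b, selection = NULL, map = NULL,
                    superpose_scope = c("selection", "whole")) {
  superpose_scope <- match.arg(superpose_scope)
  if (is.null(map)) map <- map_shared_residues(a, b)
  mapped <- map$resnum_a
  sel <- selection_resnums(selection)
  sel <- if (is.null(sel)) mapped else intersect(sel, mapped)
  if (length(sel) == 0L)
    stop("selection is empty after residue mapping")
  scope <- if (superpose_scope == "whole") mapped else sel
  if (length(scope) < 3L)
    stop("fewer than 3 mapped residues in superposition scope")
  ia <- match(scope, a$resnum); ib <- match(scope, b$resnum)
  sup <- kabsch_superpose(b$ca[ib, , drop = FALSE],
                          a$ca[ia, , drop = FALSE])
  ja <- match(sel, a$resnum); jb <- match(sel, b$resnum)
  bfit <- apply_superposition(sup, b$ca[jb, , drop = FALSE])
  rmsd <- sqrt(mean(rowSums((a$ca[ja, , drop = FALSE] - bfit)^2)))
  attr(rmsd, "superposition") <- sup
  rmsd
}

# Parse "LIG" / "LIG:A" ligand identifiers.
parse_ligand_id <- function(ligand_id) {
  parts <- strsplit(ligand_id, ":", fixed = TRUE)[[1L]]
  list(resid = parts[1L],
       chain = if (length(parts) > 1L) parts[2L] else NA_character_)
}

#' Binding-pocket residues around a ligand
#'
#' Reads a full-atom protein-ligand complex and selects every protein
#' residue having any atom within `r` Angstrom (closed, `d <= r`) of any
#' ligand atom. The default 5 Angstrom neighbourhood is the usual choice
#' for extracting a pocket around a bound inhibitor for single-point
#' energy evaluation.
#'
#' @param complex_pdb Path to a PDB file with the ligand as HETATM records.
#' @param ligand_id Ligand residue name, optionally `"NAME:CHAIN"`. If the
#'   name matches several ligand copies the call fails listing them;
#'   disambiguate with the chain or `ligand_resno`.
#' @param r Radius in Angstrom (default 5).
#' @param ligand_resno Optional residue number of the ligand copy.
#' @param output_pdb Optional path; when given, the pocket residues plus the
#'   ligand are written there as a PDB fragment suitable as input for
#'   downstream quantum-chemistry preparation.
#' @return A [residue_selection] of pocket residues, with attribute
#'   `"ligand"` describing the matched ligand copy.
#' @export
pocket_residues <- function(complex_pdb, ligand_id, r = 5,
                            ligand_resno = NULL, output_pdb = NULL) {
  stopifnot(r >= 0)
  if (!file.exists(complex_pdb)) stop("file not found: ", complex_pdb)
  pdb <- bio3d::read.pdb(complex_pdb, verbose = FALSE)
  at <- pdb$atom
  lig_id <- parse_ligand_id(ligand_id)
  het <- at[at$type == "HETATM" & at$resid == lig_id$resid, , drop = FALSE]
  if (!is.na(lig_id$chain)) het <- het[het$chain == lig_id$chain, , drop = FALSE]
  if (!is.null(ligand_resno)) het <- het[het$resno == ligand_resno, , drop = FALSE]
  if (nrow(het) == 0L)
    stop("ligand '", ligand_id, "' not found in ", basename(complex_pdb))
  copies <- unique(het[, c("chain", "resno")])
  if (nrow(copies) > 1L)
    stop("ligand '", ligand_id, "' is ambiguous; candidates: ",
         paste0(lig_id$resid, ":", copies$chain, ":", copies$resno,
                collapse = ", "))
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein ATOM records in file")
  P <- as.matrix(prot[, c("x", "y", "z")])
  L <- as.matrix(het[, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  hit <- mind <= r
  keyed <- paste(prot$chain, prot$resno)
  hit_res <- unique(prot[hit, c("chain", "resno")])
  sel <- residue_selection(hit_res$resno, rule = paste0("pocket r=", r),
                           anchor = ligand_id)
  attr(sel, "ligand") <- list(resid = lig_id$resid, chain = copies$chain,
                              resno = copies$resno)
  if (!is.null(output_pdb)) {
    keep <- keyed %in% paste(hit_res$chain, hit_res$resno)
    idx <- c(which(at$type == "ATOM")[keep],
             which(at$type == "HETATM" & at$resid == lig_id$resid &
                     at$chain == copies$chain & at$resno == copies$resno))
    sub <- at[idx, , drop = FALSE]
    bio3d::write.pdb(file = output_pdb,
                     xyz = as.vector(t(as.matrix(sub[, c("x", "y", "z")]))),
                     type = sub$type, resno = sub$resno, resid = sub$resid,
                     elety = sub$elety, chain = sub$chain)
  }
  sel
}

#' Serialize a residue selection to JSON
#'
#' @param sel A [residue_selection].
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
selection_to_json <- function(sel, path = NULL) {
  stopifnot(inherits(sel, "residue_selection"))
  x <- list(anchor = sel$anchor, rule = sel$rule, resnums = sel$resnums)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
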