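# Interaction-energy assembly from component single-point energies.
#
# The quantum-chemistry engine itself is external: this module consumes a
# component-energy table (label -> E_complex, E_protein, E_ligand, all
# kcal/mol) produced by any adapter honouring that contract, and assembles
# the binding energies and variant-preference report.

#' Ligand binding energy from component energies
#'
#' `E_binding = E_complex - (E_protein + E_ligand)`, the standard
#' interaction-energy definition: the energy of the pocket-ligand complex
#' minus the separate energies of the apoprotein (pocket residues without
#' the ligand) and the free ligand. More negative is more favourable;
#' this is the only reading consistent with favourable complexes scoring
#' negative. All quantities in kcal/mol (convert from hartree upstream).
#'
#' @param e_complex,e_protein,e_ligand Component energies in kcal/mol
#'   (vectorised).
#' @return Binding energy in kcal/mol.
#' @export
binding_energy <- function(e_complex, e_protein, e_ligand) {
  if (any(!is.finite(c(e_complex, e_protein, e_ligand))))
    stop("component energies must be finite")
  e_complex - (e_protein + e_ligand)
}

#' Read a component-energy table
#'
#' @param path CSV with columns `label`, `variant`, `e_complex`,
#'   `e_protein`, `e_ligand` and optionally `note` (energies kcal/mol).
#' @return Data frame of components.
#' @export
read_energy_components <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("label", "variant", "e_complex", "e_protein", "e_ligand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("e_complex", "e_protein", "e_ligand"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric column '", col, "'")
  if (!("note" %in% names(df))) df$note <- ""
  df
}

#' Rank variants by ligand binding preference
#'
#' Assembles the binding energy of every row with [binding_energy()],
#' sorts most-favourable first, flags rows with positive binding energy as
#' unfavourable, and derives a preference-order string (e.g.
#' `"T790M > L858R > WT"`) from the most favourable row per variant.
#'
#' @param rows Component data frame as returned by
#'   [read_energy_components()].
#' @return A `binding_report`: data frame `(label, e_binding, variant,
#'   unfavorable, note)` sorted ascending by `e_binding`, with the
#'   preference order in attribute `"preference_order"`.
#' @export
compare_variants <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  eb <- binding_energy(rows$e_complex, rows$e_protein, rows$e_ligand)
  out <- data.frame(label = as.character(rows$label),
                    e_binding = eb,
                    variant = as.character(rows$variant),
                    unfavorable = eb > 0,
                    note = if ("note" %in% names(rows))
                      as.character(rows$note) else "",
                    stringsAsFactors = FALSE)
  out <- out[order(out$e_binding, out$label), ]
  rownames(out) <- NULL
  best <- tapply(out$e_binding, out$variant, min)
  pref <- names(sort(best))
  attr(out, "preference_order") <- paste(pref, collapse = " > ")
  class(out) <- c("binding_report", "data.frame")
  out
}

#' @export
print.binding_report <- function(x, ...) {
  cat("<binding_report> preference: ", attr(x, "preference_order"),
      "\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}
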