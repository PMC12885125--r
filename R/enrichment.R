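# Ensemble docking-score aggregation and active/decoy enrichment analysis.
#
# Scores are long-format records (compound_id, conformation, site, energy)
# with free energies in kcal/mol: lower (more negative) is better. The
# conformation/site pair indexes the receptor ensemble ("c_s" labels:
# conformation c along the trajectory, 0 = the modelling output, and
# predicted binding site s within it).

#' Construct a docking score table
#'
#' @param records Data frame with columns `compound_id`, `conformation`,
#'   `site`, `energy` (kcal/mol). `(compound_id, conformation, site)` must
#'   be unique.
#' @param actives Character vector of known-active compound ids. Actives
#'   absent from the records are kept (with a warning) and count as
#'   never-found in enrichment curves.
#' @return A `score_table` (a validated data frame with an `actives`
#'   attribute).
#' @export
score_table <- function(records, actives = character()) {
  need <- c("compound_id", "conformation", "site", "energy")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- records[, need]
  records$compound_id <- as.character(records$compound_id)
  records$conformation <- as.integer(records$conformation)
  records$site <- as.integer(records$site)
  records$energy <- as.numeric(records$energy)
  if (any(!is.finite(records$energy)))
    stop("non-finite energies in score table")
  key <- paste(records$compound_id, records$conformation, records$site)
  if (anyDuplicated(key)) {
    warning("duplicate (compound, conformation, site) records: keeping ",
            "lowest energy")
    records <- records[order(records$energy), ]
    records <- records[!duplicated(paste(records$compound_id,
                                         records$conformation,
                                         records$site)), ]
    records <- records[order(records$compound_id, records$conformation,
                             records$site), ]
    rownames(records) <- NULL
  }
  actives <- unique(as.character(actives))
  absent <- setdiff(actives, records$compound_id)
  if (length(absent) > 0L)
    warning(length(absent), " active(s) absent from score records: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "")
  attr(records, "actives") <- actives
  class(records) <- c("score_table", "data.frame")
  records
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table> ", nrow(x), " records, ",
      length(unique(x$compound_id)), " compounds, ",
      length(unique(paste(x$conformation, x$site))),
      " conformation_site rankings, ",
      length(attr(x, "actives")), " actives\n", sep = "")
  invisible(x)
}

#' Load docking scores and an actives list from disk
#'
#' @param path CSV or TSV file with columns `compound_id`, `conformation`,
#'   `site`, `energy`. The delimiter is inferred from the extension
#'   (`.tsv`/`.tab` = tab, otherwise comma).
#' @param actives_path Optional newline-delimited file of active compound
#'   ids.
#' @return A [score_table()].
#' @export
load_scores <- function(path, actives_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        comment.char = "#")
  if ("energy" %in% names(df) && !is.numeric(df$energy))
    stop("non-numeric energy column in ", basename(path))
  actives <- character()
  if (!is.null(actives_path)) {
    if (!file.exists(actives_path))
      stop("file not found: ", actives_path)
    actives <- readLines(actives_path, warn = FALSE)
    actives <- actives[nzchar(trimws(actives))]
    actives <- trimws(actives)
  }
  score_table(df, actives = actives)
}

# conformation_site labels, "c_s"
conf_site_id <- function(conformation, site) paste0(conformation, "_", site)

#' Aggregate ensemble scores into a per-compound ranking
#'
#' Combines each compound's energies over all (conformation, site) rows
#' into one value: `"best"` takes the minimum (most favourable) energy and
#' `"average"` the arithmetic mean over the rows that are present --
#' compounds scored in only some conformations are averaged over those
#' only, since docking failures are routine and imputing a worst case
#' would bias enrichment.
#'
#' @param t A `score_table`, optionally pre-filtered to one
#'   conformation/site.
#' @param mode `"best"` or `"average"`.
#' @return A `compound_ranking`: data frame `(compound_id, energy, rank)`
#'   sorted by ascending energy, ties broken lexicographically by
#'   `compound_id`; the actives set and aggregation mode ride along as
#'   attributes.
#' @export
aggregate_scores <- function(t, mode = c("best", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "score_table"), nrow(t) > 0L)
  f <- if (mode == "best") min else mean
  energy <- tapply(t$energy, t$compound_id, f)
  df <- data.frame(compound_id = names(energy),
                   energy = as.numeric(energy),
                   stringsAsFactors = FALSE)
  df <- df[order(df$energy, df$compound_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "actives") <- attr(t, "actives")
  attr(df, "mode") <- mode
  class(df) <- c("compound_ranking", "data.frame")
  df
}

# Per-(conformation, site) rankings as a named list of compound_ranking.
split_rankings <- function(t) {
  stopifnot(inherits(t, "score_table"))
  ids <- conf_site_id(t$conformation, t$site)
  out <- lapply(split(seq_len(nrow(t)), ids), function(i) {
    sub <- t[i, , drop = FALSE]
    attr(sub, "actives") <- attr(t, "actives")
    class(sub) <- class(t)
    aggregate_scores(sub, "best")
  })
  # keep conformation-major order
  u <- unique(ids[order(t$conformation, t$site)])
  out[u]
}

#' Enrichment curve of a ranked screen
#'
#' At every rank cutoff, the percentage of the known actives found at or
#' above that rank, against the fraction of the library screened; the
#' random baseline at fraction f is 100 f. Actives missing from the
#' ranking stay in the denominator, so the curve then tops out below 100%.
#'
#' @param ranking A `compound_ranking` (or any data frame with
#'   `compound_id` in rank order).
#' @param actives Character vector of actives; defaults to the ranking's
#'   own actives attribute.
#' @param source Label recorded on the curve (a conformation_site id,
#'   `"average"` or `"best"`).
#' @return An `enrichment_curve`: data frame `(fraction_screened,
#'   pct_actives_found, baseline)` with one point per rank.
#' @export
enrichment_curve <- function(ranking, actives = NULL, source = "ranking") {
  if (is.null(actives)) actives <- attr(ranking, "actives")
  if (is.null(actives) || length(actives) == 0L)
    stop("no actives supplied")
  n <- nrow(ranking)
  hit <- ranking$compound_id %in% actives
  frac <- seq_len(n) / n
  pct <- 100 * cumsum(hit) / length(actives)
  out <- data.frame(fraction_screened = frac, pct_actives_found = pct,
                    baseline = 100 * frac)
  attr(out, "source") <- source
  attr(out, "n_actives") <- length(actives)
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' Recovery of actives in the top fraction of a ranking
#'
#' Counts the actives among the top `floor(q * N)` ranked compounds
#' (a deterministic, conservative cutoff) and reports the percentage of
#' all actives recovered, plus the enrichment factor
#' `recovery / (100 q)` (1 = random expectation).
#'
#' @param ranking A `compound_ranking`.
#' @param actives Actives; defaults to the ranking's attribute.
#' @param q Screened fraction, `0 < q <= 1` (default 0.1, the top 10%).
#' @return Named list `recovery_pct`, `enrichment_factor`, `n_top`,
#'   `n_actives_found`.
#' @export
top_fraction_recovery <- function(ranking, actives = NULL, q = 0.1) {
  if (is.null(actives)) actives <- attr(ranking, "actives")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("q must be in (0, 1]")
  if (is.null(actives) || length(actives) == 0L)
    stop("no actives supplied")
  n_top <- floor(q * nrow(ranking))
  found <- sum(utils::head(ranking$compound_id, n_top) %in% actives)
  rec <- 100 * found / length(actives)
  list(recovery_pct = rec, enrichment_factor = rec / (100 * q),
       n_top = n_top, n_actives_found = found)
}

#' Which ensemble members perform better than random?
#'
#' For every conformation_site ranking in the table, computes the top-`at`
#' active recovery and flags the ranking when it is strictly above the
#' random expectation `100 * at` -- i.e. its enrichment curve passes above
#' the random diagonal at that fraction. A ranking exactly on the baseline
#' is not flagged. The flag is the marginal curve-vs-diagonal comparison
#' itself, with no significance margin: with no true signal it is
#' satisfied about half the time by chance, so read the per-variant counts
#' comparatively, not as detections.
#'
#' @param t A `score_table`.
#' @param at Evaluation fraction (default 0.1).
#' @return A `data.frame` with one row per conformation_site:
#'   `conf_site`, `conformation`, `site`, `recovery_pct`,
#'   `enrichment_factor`, `flagged`, plus attributes `at` and
#'   `n_flagged`.
#' @export
better_than_random <- function(t, at = 0.1) {
  stopifnot(inherits(t, "score_table"))
  rks <- split_rankings(t)
  rows <- lapply(names(rks), function(id) {
    r <- top_fraction_recovery(rks[[id]], actives = attr(t, "actives"),
                               q = at)
    cs <- strsplit(id, "_", fixed = TRUE)[[1L]]
    data.frame(conf_site = id,
               conformation = as.integer(cs[1L]),
               site = as.integer(cs[2L]),
               recovery_pct = r$recovery_pct,
               enrichment_factor = r$enrichment_factor,
               flagged = r$recovery_pct > 100 * at,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "at") <- at
  attr(out, "n_flagged") <- sum(out$flagged)
  out
}

#' Multi-conformation hit selection
#'
#' Tier-1 selection of ensemble docking: a compound qualifies when it
#' ranks in the top fraction `q` of at least `min_conformations` of the
#' per-conformation_site rankings, favouring compounds that bind several
#' receptor conformations. Qualifiers are ordered by the number of
#' rankings hit (descending), then best energy (ascending), then
#' compound id.
#'
#' @param t A `score_table`.
#' @param q Top fraction per ranking (default 0.1).
#' @param min_conformations Minimum number of qualifying rankings
#'   (default 2).
#' @return A `hit_list` data frame: `compound_id`,
#'   `n_conformations_in_top_q`, `best_energy`, `mean_energy`.
#' @export
select_hits <- function(t, q = 0.1, min_conformations = 2L) {
  stopifnot(inherits(t, "score_table"))
  if (min_conformations < 1L) stop("min_conformations must be >= 1")
  if (!is.numeric(q) || q <= 0 || q > 1) stop("q must be in (0, 1]")
  rks <- split_rankings(t)
  counts <- table(unlist(lapply(rks, function(r)
    utils::head(r$compound_id, floor(q * nrow(r))))))
  qual <- names(counts)[counts >= min_conformations]
  if (length(qual) == 0L) {
    out <- data.frame(compound_id = character(),
                      n_conformations_in_top_q = integer(),
                      best_energy = numeric(), mean_energy = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    sub <- t[t$compound_id %in% qual, , drop = FALSE]
    best <- tapply(sub$energy, sub$compound_id, min)
    avg <- tapply(sub$energy, sub$compound_id, mean)
    out <- data.frame(compound_id = qual,
                      n_conformations_in_top_q =
                        as.integer(counts[qual]),
                      best_energy = as.numeric(best[qual]),
                      mean_energy = as.numeric(avg[qual]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n_conformations_in_top_q, out$best_energy,
                     out$compound_id), ]
    rownames(out) <- NULL
  }
  attr(out, "q") <- q
  attr(out, "min_conformations") <- min_conformations
  class(out) <- c("hit_list", "data.frame")
  out
}

#' Plot enrichment curves against the random baseline
#'
#' @param x An `enrichment_curve` or list of them.
#' @param ... Additional curves or graphical parameters.
#' @export
plot.enrichment_curve <- function(x, ...) {
  curves <- if (inherits(x, "enrichment_curve")) list(x) else x
  plot(NA, xlim = c(0, 1), ylim = c(0, 100),
       xlab = "fraction of library screened",
       ylab = "% actives recovered", ...)
  graphics::abline(0, 100, lty = 2)
  cols <- seq_along(curves)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$fraction_screened,
                    curves[[i]]$pct_actives_found, col = cols[i])
  labs <- vapply(curves, function(cv)
    as.character(attr(cv, "source") %||% "curve"), "")
  graphics::legend("bottomright", legend = c(labs, "random"),
                   col = c(cols, 1), lty = c(rep(1, length(curves)), 2),
                   cex = 0.7, bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
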