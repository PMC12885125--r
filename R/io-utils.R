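# Tabular output helpers: every report is TSV with '#' header comments
# recording the tool version and the parameters that produced it.

#' Write a data frame as a commented TSV report
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Named list recorded as `# key=value` header comments.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ensdock ",
                    as.character(utils::packageVersion("ensdock"))), con)
  for (nm in names(params))
    writeLines(paste0("# ", nm, "=",
                      paste(format(params[[nm]], trim = TRUE),
                            collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an RMSD matrix as labelled CSV
#'
#' @param m An `rmsd_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rmsd_csv <- function(m, path) {
  utils::write.table(cbind(label = rownames(m),
                           as.data.frame(unclass(m))),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a labelled RMSD matrix CSV
#'
#' @param path CSV written by [write_rmsd_csv()].
#' @return An `rmsd_matrix`.
#' @export
read_rmsd_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  storage.mode(m) <- "double"
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' Serialize a cluster result to JSON
#'
#' @param cr A `cluster_result`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
cluster_to_json <- function(cr, path = NULL) {
  stopifnot(inherits(cr, "cluster_result"))
  js <- jsonlite::toJSON(list(method = cr$method, params = cr$params,
                              clusters = cr$clusters),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
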