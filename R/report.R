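# Report emission: HTML summary, JSON machine twin, and a plain-text
# PyMOL-style visualization script.

#' Write the evaluation report
#'
#' Emits \code{report.html} (human summary), \code{report.json} (machine
#' twin of the ranking table, interface details and the complete
#' provenance log) and \code{session.pml} (a plain-text visualization
#' script loading the written models, coloring by confidence and
#' superposing everything onto the top-ranked model).
#'
#' @param rank a [rank_models()] result.
#' @param state optional [state_analysis()]; written via
#'   [write_state_analysis()].
#' @param outdir output directory (created if needed).
#' @param fs optional [feature_set()] whose provenance log is included.
#' @param model_paths optional named character vector of PDB paths for
#'   the visualization script.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(rank, state = NULL, outdir, fs = NULL,
                         model_paths = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  jpath <- file.path(outdir, "report.json")
  iface <- lapply(rank$interfaces, function(per_model)
    lapply(per_model, function(e) list(
      pair = e$pair, present = e$present,
      buried_area = if (is.null(e$report)) NA else e$report$buried_area,
      h_bonds = if (is.null(e$report)) NA else e$report$h_bonds,
      delta_g = if (is.null(e$report)) NA else e$report$delta_g,
      tier = if (is.null(e$report)) NA else e$report$tier)))
  jsonlite::write_json(list(table = rank$table, interfaces = iface,
                            provenance = fs$provenance %||% list()),
                       jpath, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  written <- c(written, jpath)

  hpath <- file.path(outdir, "report.html")
  tab <- rank$table
  cells <- apply(tab, 1, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>model report</title>",
            "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px}</style>",
            "</head><body><h1>Model ranking</h1><table><tr>",
            paste0("<th>", names(tab), "</th>", collapse = ""),
            "</tr>", cells, "</table>")
  if (!is.null(fs) && length(fs$provenance) > 0L) {
    html <- c(html, "<h2>Provenance</h2><ol>",
              vapply(fs$provenance, function(p) {
                par <- paste(names(p$params),
                             vapply(p$params, function(v)
                               paste(format(v), collapse = " "),
                               character(1)),
                             sep = "=", collapse = ", ")
                sprintf("<li>%s (%s)</li>", p$op, par)
              }, character(1)), "</ol>")
  }
  html <- c(html, "</body></html>")
  writeLines(html, hpath)
  written <- c(written, hpath)

  ppath <- file.path(outdir, "session.pml")
  pml <- c("# visualization script: load models, color by confidence,",
           "# superpose onto the top-ranked model")
  if (!is.null(model_paths)) {
    for (nm in names(model_paths))
      pml <- c(pml, sprintf("load %s, %s", model_paths[[nm]], nm))
    pml <- c(pml, "spectrum b, rainbow")
    first <- rank$table$model[1]
    for (nm in setdiff(names(model_paths), first))
      pml <- c(pml, sprintf("align %s, %s", nm, first))
  }
  writeLines(pml, ppath)
  written <- c(written, ppath)

  if (!is.null(state))
    written <- c(written, write_state_analysis(state, outdir))
  invisible(written)
}
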