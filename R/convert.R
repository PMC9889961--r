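# Whole-file converters wiring the readers, writers and the hybridization
# compiler together: SBML -> HMOD folds a recognized compiled ANN back
# into the [ML] block; HMOD -> SBML compiles the [ML] block into
# parameters + assignment rules before writing.

#' Convert an SBML document to HMOD text
#'
#' Reads the SBML, and — if the model contains the compiled
#' `annX_/annH_/annY_` structure written by [hybridize()] — splits it
#' back into a mechanistic skeleton plus an `[ML]` block (see
#' [recover_plan()]); otherwise serializes the mechanistic model as-is.
#'
#' @param x SBML path, XML string or `xml2` document.
#' @param path Optional output path for the HMOD text.
#' @return A list with elements `text` (HMOD) and `report`.
#' @export
sbml_to_hmod <- function(x, path = NULL) {
  res <- read_sbml(x)
  m <- res$model
  ann <- NULL
  plan <- recover_plan(m)
  if (!is.null(plan)) {
    parts <- dehybridize(m, plan)
    m <- parts$model
    ann <- parts$ann
  }
  txt <- serialize_hmod(m, ann = ann, path = path)
  list(text = txt, report = res$report)
}

#' Convert HMOD text to an SBML document
#'
#' Parses the HMOD; when an `[ML]` block is present the ANN is compiled
#' into the model with [hybridize()] first, so the written SBML is a
#' self-contained hybrid model.
#'
#' @param x HMOD path or text.
#' @param path Optional output path for the SBML document.
#' @return A list with elements `xml` (SBML text, `NULL` on fatal parse
#'   errors) and `report`.
#' @export
hmod_to_sbml <- function(x, path = NULL) {
  res <- parse_hmod(x)
  if (is.null(res$model)) {
    return(list(xml = NULL, report = res$report))
  }
  m <- res$model
  if (!is.null(res$ann)) {
    m <- hybridize(m, res$ann)$model
  }
  xml <- write_sbml(m, path = path)
  list(xml = xml, report = res$report)
}
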