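#' Load a shipped task-configuration preset
#'
#' Four presets ship with the package, encoding the type inventories and
#' generalisation sets of the two BioNLP-ST 2013 tasks the pipeline was
#' designed around: \code{"cg"} and \code{"pc"} collapse all entity types
#' into a single ENTITY group; \code{"cg-refined"} keeps the three general
#' entity groups of the task hierarchy (anatomical, pathological,
#' molecular); \code{"pc-refined"} collapses Gene_or_gene_product and
#' Complex into PROTEIN and leaves the other entity types intact. All four
#' collapse the regulation family into REGULATION, the modification event
#' family into PTM, event-valued argument types into EVENT, and share
#' event structures across the regulation types at prediction time.
#'
#' @param name one of \code{"cg"}, \code{"cg-refined"}, \code{"pc"},
#'   \code{"pc-refined"}.
#' @return a [TaskConfig-class].
#' @export
loadPresetConfig <- function(name = c("cg", "cg-refined", "pc", "pc-refined")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("config-", name, ".conf"),
                      package = "EventPipe", mustWork = TRUE)
  parseTaskConfig(path)
}

#' Load a shipped event-category map
#'
#' Maps event types to the scoring categories used in per-category
#' evaluation reports (hedge modifications are always reported under a
#' separate MOD category and need no entry).
#'
#' @param task \code{"cg"} or \code{"pc"}.
#' @return named character vector: event type -> category.
#' @export
loadCategoryMap <- function(task = c("cg", "pc")) {
  task <- match.arg(task)
  path <- system.file("extdata", paste0("categories-", task, ".tsv"),
                      package = "EventPipe", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(df$category, df$type)
}
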