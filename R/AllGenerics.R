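#' @rdname StandoffDocument-class
#' @param x,object a \code{StandoffDocument}.
#' @export
setGeneric("docId", function(x) standardGeneric("docId"))
#' @rdname StandoffDocument-class
#' @export
setGeneric("docText", function(x) standardGeneric("docText"))
#' @rdname StandoffDocument-class
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname StandoffDocument-class
#' @export
setGeneric("textbounds", function(x) standardGeneric("textbounds"))
#' @rdname StandoffDocument-class
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname StandoffDocument-class
#' @export
setGeneric("equivalences", function(x) standardGeneric("equivalences"))

#' @rdname StandoffDocument-class
#' @export
setMethod("docId", "StandoffDocument", function(x) x@id)
#' @rdname StandoffDocument-class
#' @export
setMethod("docText", "StandoffDocument", function(x) x@text)
#' @rdname StandoffDocument-class
#' @export
setMethod("tokens", "StandoffDocument", function(x) x@tokens)
#' @rdname StandoffDocument-class
#' @export
setMethod("textbounds", "StandoffDocument", function(x) x@textbounds)
#' @rdname StandoffDocument-class
#' @export
setMethod("events", "StandoffDocument", function(x) x@events)
#' @rdname StandoffDocument-class
#' @export
setMethod("equivalences", "StandoffDocument", function(x) x@equivalences)

setMethod("show", "StandoffDocument", function(object) {
  cat("StandoffDocument ", sQuote(object@id), "\n",
      "  ", nchar(object@text), " characters, ", nrow(object@tokens),
      " tokens, ", nrow(object@textbounds), " textbounds, ",
      length(object@events), " events\n", sep = "")
})

setMethod("show", "TaskConfig", function(object) {
  cat("TaskConfig\n",
      "  GOLD:       ", paste(object@goldTypes, collapse = ", "), "\n",
      "  PREDICTION: ", paste(object@predictionTypes, collapse = ", "), "\n",
      "  TRIGGERS:   ", paste(object@triggerTypes, collapse = ", "), "\n",
      "  ROLES:      ", paste(object@roleTypes, collapse = ", "), "\n",
      "  ", length(object@labelGen), " generalisation rule(s), ",
      length(object@instanceRules), " instance rule(s); mode=",
      taskOption(object, "mode"), ", C=", taskOption(object, "C"),
      ", hashBits=", taskOption(object, "hashBits"), "\n", sep = "")
})

setMethod("show", "DetectorModel", function(object) {
  cat("DetectorModel stage=", object@stage, ": ", length(object@labels),
      " label(s) + ", object@negativeLabel, ", 2^", object@hashBits,
      " dims, mode=", object@mode, "\n", sep = "")
})

setMethod("show", "PipelineModel", function(object) {
  cat("PipelineModel (", paste(names(object@detectors), collapse = " -> "),
      ")\n", sep = "")
  for (d in object@detectors) show(d)
})

setMethod("show", "ShiftWeights", function(object) {
  cat("ShiftWeights: ", length(object@l), " training instance(s), ",
      object@nTarget, " target instance(s)\n  mean l = ",
      signif(mean(object@l), 4), ", C_CS = ", signif(object@CCS, 4),
      " (C = ", object@cost, ")\n", sep = "")
})

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport (", object@mode, " matching)\n", sep = "")
  tab <- object@table
  tab$recall <- round(tab$recall, 4)
  tab$precision <- round(tab$precision, 4)
  tab$fscore <- round(tab$fscore, 4)
  print(tab, row.names = FALSE)
})

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec: ", object@nDocs, " docs, ",
      paste(object@sentencesPerDoc, collapse = "-"),
      " sentences/doc, shift=", object@shift, ", seed=", object@seed,
      "\n  entity types: ", paste(names(object@entityTypes), collapse = ", "),
      "\n  event types:  ",
      paste(vapply(object@grammar, function(g) g$type, character(1)),
            collapse = ", "), "\n", sep = "")
})

#' Extract the score table from a ScoreReport
#'
#' @param x a [ScoreReport-class].
#' @return the per-category data.frame.
#' @export
scoreTable <- function(x) {
  stopifnot(methods::is(x, "ScoreReport"))
  x@table
}
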