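#' StandoffDocument: one annotated document
#'
#' Container for a document in BioNLP shared-task standoff form: the raw
#' text, a token table with character offsets and a dependency parse,
#' text-bound annotations (entities and event triggers), events, and
#' annotator equivalence sets. Character offsets follow the standoff
#' convention throughout: 0-based, half-open \code{[start, end)} intervals
#' into the document text.
#'
#' Events are stored as a list of records, each a list with elements
#' \code{id} (E-prefixed), \code{type}, \code{trigger} (a text-bound id),
#' \code{args} (a data.frame with columns \code{role}, \code{target}, where
#' a target is a text-bound or event id) and \code{mods} (a character subset
#' of \code{c("Negation", "Speculation")}).
#'
#' @slot id document identifier (typically the file stem).
#' @slot text full document text.
#' @slot tokens data.frame with columns \code{surface}, \code{start},
#'   \code{end}, \code{base}, \code{stem}, \code{sentence}, \code{head}
#'   (1-based token index within the document; 0 marks a sentence root) and
#'   \code{deprel}.
#' @slot textbounds data.frame with columns \code{id}, \code{type},
#'   \code{start}, \code{end}, \code{text}.
#' @slot events list of event records (see Details).
#' @slot equivalences list of character vectors of interchangeable
#'   text-bound ids.
#'
#' @seealso [readDocument()], [writeAnnotations()], [validateDocument()]
#' @export
setClass("StandoffDocument",
  representation(id = "character", text = "character", tokens = "data.frame",
                 textbounds = "data.frame", events = "list",
                 equivalences = "list"),
  prototype(id = "doc", text = "", tokens = emptyTokens(),
            textbounds = emptyTextbounds(), events = list(),
            equivalences = list()))

setValidity("StandoffDocument", function(object) {
  v <- validateDocumentImpl(object)
  if (length(v) == 0L) TRUE else paste(v, collapse = "; ")
})

#' TaskConfig: task-specific type inventories and generalisation rules
#'
#' Everything the pipeline needs to know about an annotation scheme: which
#' annotation types arrive as given ("gold", the .a1 side), which must be
#' predicted, which types anchor events (triggers), the role inventory,
#' label-and-feature generalisation rules, instance-generation rules, and
#' solver options.
#'
#' @slot goldTypes character vector of types supplied in .a1 files.
#' @slot predictionTypes character vector of types the system must predict.
#' @slot triggerTypes character vector of event (trigger) types; must be a
#'   subset of the union of gold and prediction types.
#' @slot roleTypes character vector of role names (numbered forms included).
#' @slot labelGen named character vector mapping a type or role name to its
#'   generalisation group (e.g. \code{Positive_regulation -> REGULATION}).
#'   Two pseudo-names are understood: \code{@events} (any trigger type in
#'   argument position) and \code{@entities} (any entity type in argument
#'   position).
#' @slot instanceRules list of character vectors; the event types in one
#'   vector share their observed event structures at prediction time.
#' @slot options list of solver and feature options: \code{C} (SVM cost,
#'   default 1), \code{hashBits} (feature-space size exponent, default 20),
#'   \code{mode} (adaptation mode, one of \code{"none"}, \code{"weighting"},
#'   \code{"covariate_shift"}, \code{"combined"}), \code{seed},
#'   \code{charNgram}, \code{wordNgram}, \code{clip} (density-ratio clipping
#'   bounds), \code{pairCap} (argument pairs kept per trigger before subset
#'   enumeration).
#'
#' @seealso [parseTaskConfig()], [entityTypes()], [generalizeType()]
#' @export
setClass("TaskConfig",
  representation(goldTypes = "character", predictionTypes = "character",
                 triggerTypes = "character", roleTypes = "character",
                 labelGen = "character", instanceRules = "list",
                 options = "list"),
  prototype(goldTypes = character(), predictionTypes = character(),
            triggerTypes = character(), roleTypes = character(),
            labelGen = character(), instanceRules = list(),
            options = list()))

setValidity("TaskConfig", function(object) {
  msgs <- character()
  known <- union(object@goldTypes, object@predictionTypes)
  extra <- setdiff(object@triggerTypes, known)
  if (length(extra))
    msgs <- c(msgs, paste0("trigger types not in GOLD or PREDICTION: ",
                           paste(extra, collapse = ", ")))
  if (length(object@labelGen) &&
      (is.null(names(object@labelGen)) || any(!nzchar(names(object@labelGen))) ||
       any(!nzchar(object@labelGen))))
    msgs <- c(msgs, "labelGen must be a named character vector with non-empty names and groups")
  for (rule in object@instanceRules) {
    if (!is.character(rule) || length(rule) < 2L)
      msgs <- c(msgs, "each instance rule must name at least two event types")
    else if (length(setdiff(rule, object@triggerTypes)))
      msgs <- c(msgs, paste0("instance rule members must be trigger types: ",
                             paste(setdiff(rule, object@triggerTypes), collapse = ", ")))
  }
  if (length(msgs) == 0L) TRUE else paste(msgs, collapse = "; ")
})

#' TrainingBatch: labelled sparse instances for one binary problem
#'
#' @slot X sparse instance matrix (rows = instances, columns = hashed
#'   feature dimensions), a \code{Matrix::dgCMatrix}.
#' @slot y numeric vector of signed labels in \code{{+1, -1}}.
#' @slot cost numeric SVM cost constant (default 1).
#' @export
setClass("TrainingBatch",
  representation(X = "ANY", y = "numeric", cost = "numeric"),
  prototype(y = numeric(), cost = 1))

setValidity("TrainingBatch", function(object) {
  msgs <- character()
  if (!methods::is(object@X, "Matrix") && !is.matrix(object@X))
    msgs <- c(msgs, "X must be a matrix or Matrix")
  else if (nrow(object@X) != length(object@y))
    msgs <- c(msgs, "nrow(X) must equal length(y)")
  if (length(object@y) && !all(object@y %in% c(-1, 1)))
    msgs <- c(msgs, "y must contain only +1/-1")
  if (length(object@cost) != 1L || !is.finite(object@cost) || object@cost <= 0)
    msgs <- c(msgs, "C must be a single positive number")
  if (length(msgs) == 0L) TRUE else paste(msgs, collapse = "; ")
})

#' ShiftWeights: importance weights for covariate-shift training
#'
#' Per-instance density-ratio weights \eqn{l(x) =
#' (n_{train}/n_{target}) \, p_{target}(x)/p_{train}(x)} estimated from a
#' probabilistic train-vs-target domain classifier, together with the
#' rescaled loss constant \eqn{C_{CS} = n C / \sum_i l(x_i)} that keeps the
#' regularisation and loss terms balanced after weighting.
#'
#' @slot l numeric vector of clipped per-instance weights (training rows).
#' @slot pTrain,pTarget numeric vectors: domain-classifier probabilities for
#'   each training instance.
#' @slot nTrain,nTarget integer counts of training and target instances.
#' @slot cost the base SVM cost the weights were computed against.
#' @slot CCS the balancing constant \eqn{n_{train} C / \sum l(x_i)}.
#' @export
setClass("ShiftWeights",
  representation(l = "numeric", pTrain = "numeric", pTarget = "numeric",
                 nTrain = "integer", nTarget = "integer", cost = "numeric",
                 CCS = "numeric"))

setValidity("ShiftWeights", function(object) {
  msgs <- character()
  n <- length(object@l)
  if (length(object@pTrain) != n || length(object@pTarget) != n)
    msgs <- c(msgs, "pTrain/pTarget must match length(l)")
  if (n && (any(!is.finite(object@l)) || any(object@l < 0)))
    msgs <- c(msgs, "weights must be finite and nonnegative")
  if (n) {
    expect <- object@nTrain * object@cost / sum(object@l)
    if (abs(expect - object@CCS) > 1e-8 * max(1, abs(expect)))
      msgs <- c(msgs, "CCS inconsistent with n*C/sum(l)")
  }
  if (length(msgs) == 0L) TRUE else paste(msgs, collapse = "; ")
})

#' BinaryModel: one one-vs-rest linear scorer
#'
#' @slot label classification label the scorer votes for.
#' @slot w dense numeric weight vector over the hashed feature space.
#' @export
setClass("BinaryModel",
  representation(label = "character", w = "numeric"),
  prototype(label = "", w = numeric()))

#' DetectorModel: a full one-vs-rest multi-label detector
#'
#' One pipeline stage's classifier: the label inventory (the negative type
#' is implicit, scored at exactly 0), a weight matrix with one column per
#' positive label, and the metadata needed to reproduce the feature space.
#'
#' @slot stage detector stage name ("trigger", "argument", "structure",
#'   "hedge").
#' @slot labels character vector of positive labels (column order of
#'   \code{W}).
#' @slot W dense weight matrix, hashed dimension x length(labels).
#' @slot negativeLabel name of the implicit negative type.
#' @slot hashBits feature-space exponent the model was trained with.
#' @slot mode adaptation mode used in training.
#' @slot meta list of stage-specific inventories.
#' @export
setClass("DetectorModel",
  representation(stage = "character", labels = "character", W = "matrix",
                 negativeLabel = "character", hashBits = "integer",
                 mode = "character", meta = "list"),
  prototype(negativeLabel = "NONE", hashBits = 20L, mode = "none",
            meta = list()))

setValidity("DetectorModel", function(object) {
  msgs <- character()
  if (ncol(object@W) != length(object@labels))
    msgs <- c(msgs, "W must have one column per label")
  if (length(object@labels) && nrow(object@W) != 2L^object@hashBits)
    msgs <- c(msgs, "nrow(W) must equal 2^hashBits")
  if (length(msgs) == 0L) TRUE else paste(msgs, collapse = "; ")
})

#' PipelineModel: the trained four-detector pipeline
#'
#' @slot config the [TaskConfig-class] snapshot used in training.
#' @slot inventories list with elements \code{roleLabels},
#'   \code{structureLabels}, \code{headTable} (and their prediction-time
#'   expansions) collected from the training corpus.
#' @slot detectors named list of [DetectorModel-class] objects in pipeline
#'   order: trigger, argument, structure, hedge.
#' @slot meta list: package version, seed, hash choice.
#' @export
setClass("PipelineModel",
  representation(config = "TaskConfig", inventories = "list",
                 detectors = "list", meta = "list"))

#' SynthSpec: recipe for a synthetic standoff corpus
#'
#' Defines a template-based corpus generator with exact gold annotations:
#' an entity lexicon, an event grammar (triggers, role slots, nesting),
#' hedge cue words, an imbalance control (distractor sentences reusing
#' trigger head forms with no event), and a train-vs-target lexical shift
#' control.
#'
#' @slot entityTypes named list: entity type -> character lexicon.
#' @slot grammar list of rules; each rule is a list with elements
#'   \code{type}, \code{triggers} (lexicon), \code{slots} (data.frame with
#'   columns \code{role}, \code{filler}, \code{optional}), \code{nesting}
#'   (probability that an event-capable slot is filled by a nested event).
#' @slot nDocs number of documents.
#' @slot sentencesPerDoc integer length-2 range.
#' @slot cues named list: \code{Negation}/\code{Speculation} -> list(words,
#'   prob).
#' @slot distractorRate probability that a sentence is an event-free
#'   distractor reusing a trigger head form.
#' @slot fillerRate probability that a sentence is plain filler.
#' @slot shift numeric in [0, 1]: strength of the train-vs-target lexical
#'   distribution offset (0 = identical distributions).
#' @slot seed integer generator seed.
#' @export
setClass("SynthSpec",
  representation(entityTypes = "list", grammar = "list", nDocs = "integer",
                 sentencesPerDoc = "integer", cues = "list",
                 distractorRate = "numeric", fillerRate = "numeric",
                 shift = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
  msgs <- character()
  probs <- c(object@distractorRate, object@fillerRate, object@shift,
             vapply(object@cues, function(cu) cu$prob, numeric(1)),
             vapply(object@grammar, function(g) g$nesting, numeric(1)))
  if (any(probs < 0 | probs > 1)) msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (length(object@sentencesPerDoc) != 2L ||
      any(object@sentencesPerDoc < 1L) || diff(object@sentencesPerDoc) < 0L)
    msgs <- c(msgs, "sentencesPerDoc must be an increasing length-2 range")
  known <- c(names(object@entityTypes),
             vapply(object@grammar, function(g) g$type, character(1)))
  for (g in object@grammar) {
    bad <- setdiff(unlist(strsplit(g$slots$filler, "|", fixed = TRUE)), known)
    if (length(bad))
      msgs <- c(msgs, paste0("unknown slot filler type(s): ",
                             paste(bad, collapse = ", ")))
  }
  if (length(msgs) == 0L) TRUE else paste(msgs, collapse = "; ")
})

#' ScoreReport: per-category precision/recall/F table
#'
#' @slot table data.frame with one row per category plus a TOTAL row;
#'   columns \code{category}, \code{gold}, \code{matchedGold}, \code{pred},
#'   \code{matchedPred}, \code{recall}, \code{precision}, \code{fscore}.
#' @slot categories named character vector mapping event types to category
#'   names.
#' @slot mode matching mode used ("strict" or "partial").
#' @export
setClass("ScoreReport",
  representation(table = "data.frame", categories = "character",
                 mode = "character"))
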