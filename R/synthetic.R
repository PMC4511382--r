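## Synthetic standoff corpora from a template grammar. Sentences are built
## from fixed token templates (subject - trigger - object with optional
## hedge cues and distractor tokens), so gold spans, dependency paths and
## event structures are known exactly, and a trivial left-branching parse
## is emitted: the pipeline is testable end-to-end with no external parser
## or download. No linguistic realism is attempted.

defaultGrammar <- function() {
  list(
    list(type = "Gene_expression",
         triggers = c("expression", "expressed", "overexpression"),
         slots = data.frame(role = "Theme", filler = "Protein",
                            optional = FALSE, stringsAsFactors = FALSE),
         nesting = 0),
    list(type = "Binding",
         triggers = c("binding", "bound", "interaction"),
         slots = data.frame(role = c("Theme", "Theme2"),
                            filler = c("Protein", "Protein"),
                            optional = c(FALSE, FALSE),
                            stringsAsFactors = FALSE),
         nesting = 0),
    list(type = "Negative_regulation",
         triggers = c("inhibited", "suppressed", "blocked"),
         slots = data.frame(role = c("Theme", "Cause"),
                            filler = c("Protein|Gene_expression", "Protein"),
                            optional = c(FALSE, TRUE),
                            stringsAsFactors = FALSE),
         nesting = 0.35))
}

#' Construct a synthetic-corpus specification
#'
#' The defaults define the study conditions used throughout the package's
#' own experiments: one gold entity type, three event types (a simple
#' event, a two-Theme numbered-role event, and a regulation that may nest a
#' simple event as its Theme), hedge cues attached with probability 0.15,
#' an event-free distractor sentence rate of 0.3 reusing trigger head
#' forms (the class-imbalance control), and no train-vs-target shift.
#'
#' @param nDocs number of documents.
#' @param sentencesPerDoc integer range (length 2).
#' @param entityTypes named list: type -> lexicon.
#' @param grammar event grammar (see [SynthSpec-class]).
#' @param cueProb probability of each hedge cue on an event sentence.
#' @param distractorRate probability a sentence is an event-free
#'   distractor containing a trigger head form.
#' @param fillerRate probability a sentence is plain filler.
#' @param shift train-vs-target lexical shift strength in [0, 1].
#' @param seed integer seed; generation is a pure function of the spec.
#' @return a validated [SynthSpec-class].
#' @export
synthSpec <- function(nDocs = 50L, sentencesPerDoc = c(3L, 6L),
                      entityTypes = list(Protein = sprintf("PROT%02d", 1:24)),
                      grammar = defaultGrammar(), cueProb = 0.15,
                      distractorRate = 0.3, fillerRate = 0.2, shift = 0,
                      seed = 1L) {
  methods::new("SynthSpec", entityTypes = entityTypes, grammar = grammar,
               nDocs = as.integer(nDocs),
               sentencesPerDoc = as.integer(sentencesPerDoc),
               cues = list(Negation = list(words = c("not", "never"),
                                           prob = cueProb),
                           Speculation = list(words = c("possibly", "perhaps"),
                                              prob = cueProb)),
               distractorRate = distractorRate, fillerRate = fillerRate,
               shift = shift, seed = as.integer(seed))
}

## Context-word lexicons: sampled with the tilted distribution, so a
## lexical covariate shift survives entity masking (entity surfaces do
## not, by design of the masking step).
synthContextWords <- function() {
  c("observed", "detected", "measured", "reported", "confirmed", "recorded")
}
synthFillerNouns <- function() {
  c("cells", "samples", "cultures", "sections", "extracts", "aliquots")
}

## Tilted categorical draw: dir in [-1, 1] shifts mass linearly toward the
## front (dir > 0) or the back (dir < 0); |dir| >= 1 restricts to one half.
sampleTilt <- function(lexicon, dir) {
  L <- length(lexicon)
  if (L == 1L) return(lexicon)
  if (abs(dir) >= 1) {
    half <- seq_len(ceiling(L / 2))
    pool <- if (dir > 0) lexicon[half] else lexicon[-half]
    return(pool[sample.int(length(pool), 1L)])
  }
  lin <- seq(1, -1, length.out = L)
  w <- 1 + dir * lin
  lexicon[sample.int(L, 1L, prob = w)]
}

## Build one sentence worth of tokens + annotations. Returns list(tokens,
## entities = data.frame(type, tokenIndex), events = list of local event
## records referencing local entity/trigger token indices).
synthSentence <- function(spec, dir) {
  kind <- {
    u <- runif(1)
    if (u < spec@distractorRate) "distractor"
    else if (u < spec@distractorRate + spec@fillerRate) "filler"
    else "event"
  }
  ctx <- function() sampleTilt(synthContextWords(), dir)
  ent <- function(type) sampleTilt(spec@entityTypes[[type]], dir)
  if (kind == "filler") {
    return(list(words = c("the", sampleTilt(synthFillerNouns(), dir), "were",
                          "cultured", "overnight", "."),
                entities = list(), events = list()))
  }
  if (kind == "distractor") {
    allTrig <- unlist(lapply(spec@grammar, `[[`, "triggers"))
    return(list(words = c("the", "results", "were",
                          sampleTilt(allTrig, dir), "by", "design", "."),
                entities = list(), events = list()))
  }
  rule <- spec@grammar[[sample.int(length(spec@grammar), 1L)]]
  trig <- sampleTilt(rule$triggers, dir)
  words <- character(); entities <- list(); eventsOut <- list()
  addEnt <- function(type, idx) entities[[length(entities) + 1L]] <<-
    list(type = type, token = idx)
  if (rule$type == "Gene_expression") {
    e1 <- ent("Protein")
    words <- c("the", trig, "of", e1, "was", ctx(), ".")
    addEnt("Protein", 4L)
    eventsOut[[1]] <- list(type = rule$type, trigger = 2L,
                           args = list(list(role = "Theme", entity = 1L)))
  } else if (rule$type == "Binding") {
    e1 <- ent("Protein"); e2 <- ent("Protein")
    words <- c("the", trig, "of", e1, "to", e2, "was", ctx(), ".")
    addEnt("Protein", 4L); addEnt("Protein", 6L)
    eventsOut[[1]] <- list(type = rule$type, trigger = 2L,
                           args = list(list(role = "Theme", entity = 1L),
                                       list(role = "Theme2", entity = 2L)))
  } else {
    ## regulation family rule: optional Cause, Theme entity or nested event
    causeRows <- rule$slots$role == "Cause"
    hasCause <- any(causeRows) &&
      (any(!rule$slots$optional[causeRows]) || runif(1) < 0.6)
    nest <- runif(1) < rule$nesting
    eC <- ent("Protein")
    if (nest) {
      geRule <- NULL
      for (g in spec@grammar) if (g$type == "Gene_expression") geRule <- g
      geTrig <- sampleTilt(geRule$triggers, dir)
      eT <- ent("Protein")
      if (hasCause) {
        words <- c(eC, trig, "the", geTrig, "of", eT, ".")
        addEnt("Protein", 1L); addEnt("Protein", 6L)
        inner <- list(type = "Gene_expression", trigger = 4L,
                      args = list(list(role = "Theme", entity = 2L)))
        outer <- list(type = rule$type, trigger = 2L,
                      args = list(list(role = "Theme", event = 1L),
                                  list(role = "Cause", entity = 1L)))
      } else {
        words <- c("it", trig, "the", geTrig, "of", eT, ".")
        addEnt("Protein", 6L)
        inner <- list(type = "Gene_expression", trigger = 4L,
                      args = list(list(role = "Theme", entity = 1L)))
        outer <- list(type = rule$type, trigger = 2L,
                      args = list(list(role = "Theme", event = 1L)))
      }
      eventsOut <- list(inner, outer)
    } else {
      eT <- ent("Protein")
      if (hasCause) {
        words <- c(eC, trig, eT, "in", ctx(), "assays", ".")
        addEnt("Protein", 1L); addEnt("Protein", 3L)
        eventsOut[[1]] <- list(type = rule$type, trigger = 2L,
                               args = list(list(role = "Theme", entity = 2L),
                                           list(role = "Cause", entity = 1L)))
      } else {
        words <- c("it", trig, eT, "in", ctx(), "assays", ".")
        addEnt("Protein", 3L)
        eventsOut[[1]] <- list(type = rule$type, trigger = 2L,
                               args = list(list(role = "Theme", entity = 1L)))
      }
    }
  }
  ## hedge cues on the outermost event
  mods <- character()
  for (mname in names(spec@cues)) {
    cu <- spec@cues[[mname]]
    if (length(eventsOut) && runif(1) < cu$prob) {
      cueWord <- cu$words[sample.int(length(cu$words), 1L)]
      trigIdx <- eventsOut[[length(eventsOut)]]$trigger
      ## insert the cue immediately before the outer trigger token
      words <- append(words, cueWord, after = trigIdx - 1L)
      bump <- function(i) ifelse(i >= trigIdx, i + 1L, i)
      entities <- lapply(entities, function(en) { en$token <- bump(en$token); en })
      eventsOut <- lapply(eventsOut, function(ev) {
        ev$trigger <- bump(ev$trigger); ev
      })
      mods <- c(mods, mname)
    }
  }
  if (length(eventsOut))
    eventsOut[[length(eventsOut)]]$mods <- mods
  list(words = words, entities = entities, events = eventsOut)
}

#' Generate a gold-annotated synthetic corpus
#'
#' A pure function of the spec: the same spec yields bit-identical corpora.
#'
#' @param spec a [SynthSpec-class].
#' @param role \code{"train"} or \code{"target"}: which side of the lexical
#'   shift to sample from (identical when \code{spec@shift == 0}).
#' @return list of [StandoffDocument-class].
#' @export
generateCorpus <- function(spec, role = c("train", "target")) {
  methods::validObject(spec)
  role <- match.arg(role)
  dir <- if (role == "train") spec@shift else -spec@shift
  seed <- if (role == "train") spec@seed else childSeed(spec@seed, "target")
  withLocalSeed(seed, {
    lapply(seq_len(spec@nDocs), function(d)
      synthDocument(spec, dir, sprintf("%s%03d", substr(role, 1, 2), d)))
  })
}

synthDocument <- function(spec, dir, id) {
  lo <- spec@sentencesPerDoc[1]; hi <- spec@sentencesPerDoc[2]
  nSent <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  text <- ""
  tokRows <- list(); tbRows <- list(); evList <- list()
  tCount <- 0L; eCount <- 0L; tokOffset <- 0L
  for (s in seq_len(nSent)) {
    sen <- synthSentence(spec, dir)
    words <- sen$words
    starts <- integer(length(words))
    pos <- nchar(text)
    for (i in seq_along(words)) {
      if (nzchar(text)) { text <- paste0(text, " "); pos <- pos + 1L }
      starts[i] <- pos
      text <- paste0(text, words[i])
      pos <- pos + nchar(words[i])
    }
    for (i in seq_along(words)) {
      tokRows[[length(tokRows) + 1L]] <- data.frame(
        surface = words[i], start = starts[i],
        end = starts[i] + nchar(words[i]), base = tolower(words[i]),
        stem = stemWord(words[i]), sentence = s,
        head = if (i == 1L) 0L else tokOffset + i - 1L,
        deprel = if (i == 1L) "root" else "dep", stringsAsFactors = FALSE)
    }
    entIds <- character(length(sen$entities))
    for (k in seq_along(sen$entities)) {
      en <- sen$entities[[k]]
      tCount <- tCount + 1L
      entIds[k] <- paste0("T", tCount)
      w <- en$token
      tbRows[[length(tbRows) + 1L]] <- data.frame(
        id = entIds[k], type = en$type, start = starts[w],
        end = starts[w] + nchar(words[w]), text = words[w],
        stringsAsFactors = FALSE)
    }
    evIds <- character(length(sen$events))
    trigIds <- character(length(sen$events))
    for (k in seq_along(sen$events)) {
      ev <- sen$events[[k]]
      tCount <- tCount + 1L
      trigIds[k] <- paste0("T", tCount)
      w <- ev$trigger
      tbRows[[length(tbRows) + 1L]] <- data.frame(
        id = trigIds[k], type = ev$type, start = starts[w],
        end = starts[w] + nchar(words[w]), text = words[w],
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(sen$events)) {
      ev <- sen$events[[k]]
      eCount <- eCount + 1L
      evIds[k] <- paste0("E", eCount)
      args <- data.frame(role = character(), target = character(),
                         stringsAsFactors = FALSE)
      for (a in ev$args) {
        target <- if (!is.null(a$entity)) entIds[a$entity] else evIds[a$event]
        args <- rbind(args, data.frame(role = a$role, target = target,
                                       stringsAsFactors = FALSE))
      }
      evList[[length(evList) + 1L]] <-
        list(id = evIds[k], type = ev$type, trigger = trigIds[k],
             args = args, mods = ev$mods %||% character())
    }
    tokOffset <- tokOffset + length(words)
  }
  methods::new("StandoffDocument", id = id, text = text,
               tokens = do.call(rbind, tokRows),
               textbounds = if (length(tbRows)) do.call(rbind, tbRows)
                            else emptyTextbounds(),
               events = evList, equivalences = list())
}

#' Generate a train/target corpus pair under covariate shift
#'
#' Both corpora share the grammar and labelling function; only the lexical
#' sampling distributions differ, with strength \code{spec@shift}.
#'
#' @param spec a [SynthSpec-class] with \code{shift > 0} for a real shift.
#' @return list with elements \code{train} and \code{target}.
#' @export
generateShiftedPair <- function(spec) {
  list(train = generateCorpus(spec, "train"),
       target = generateCorpus(spec, "target"))
}

#' Summarise a corpus's annotation content
#'
#' @param corpus list of [StandoffDocument-class].
#' @return list of named integer tables: \code{entities} (entity-type
#'   counts over non-trigger textbounds), \code{events} (event-type
#'   counts), \code{structures} (concrete event-structure counts, numbered
#'   roles retained) and \code{modifications}.
#' @export
corpusSummary <- function(corpus) {
  ents <- character(); evs <- character(); strs <- character()
  mods <- character()
  for (doc in corpus) {
    trig <- vapply(doc@events, function(e) e$trigger, character(1))
    tb <- doc@textbounds
    ents <- c(ents, tb$type[!(tb$id %in% trig)])
    for (e in doc@events) {
      evs <- c(evs, e$type)
      argTypes <- vapply(e$args$target, function(t) eventTypeOf(doc, t),
                         character(1))
      strs <- c(strs, structureKey(e$type, e$args$role, argTypes))
      mods <- c(mods, e$mods)
    }
  }
  toTable <- function(x) {
    if (length(x) == 0L) return(integer())
    tab <- table(x)
    setNames(as.integer(tab), names(tab))
  }
  list(entities = toTable(ents), events = toTable(evs),
       structures = toTable(strs), modifications = toTable(mods))
}
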