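## Pipeline orchestration: train the four detectors in order, each on
## candidates generated from the predictions of the preceding stages over
## the training documents (training-on-predictions), then run the same
## stages at prediction time.

stageModes <- c("none", "weighting", "covariate_shift", "combined")

trainerMode <- function(mode) {
  switch(mode, none = "plain", weighting = "weighting",
         covariate_shift = "covariate_shift", combined = "combined",
         stopf("unknown adaptation mode '%s'", mode))
}

## Train one one-vs-rest detector over a shared candidate matrix.
## goldSets: list of character vectors (gold labels per candidate).
trainDetector <- function(stage, X, goldSets, labelPool, cfg, mode, sw = NULL,
                          meta = list()) {
  hashBits <- taskOption(cfg, "hashBits")
  labelPool <- as.character(labelPool %||% character())
  observed <- as.character(unique(unlist(goldSets)) %||% character())
  labels <- sort(intersect(labelPool, observed), method = "radix")
  tmode <- trainerMode(mode)
  W <- matrix(0, nrow = 2L^hashBits, ncol = length(labels))
  keep <- logical(length(labels))
  for (k in seq_along(labels)) {
    y <- ifelse(vapply(goldSets, function(g) labels[k] %in% g, logical(1)),
                1, -1)
    if (!any(y > 0)) next
    batch <- trainingBatch(X, y, C = taskOption(cfg, "C"))
    bm <- trainBinary(batch, mode = tmode, sw = sw, label = labels[k])
    W[, k] <- bm@w
    keep[k] <- TRUE
  }
  methods::new("DetectorModel", stage = stage, labels = labels[keep],
               W = W[, keep, drop = FALSE], negativeLabel = "NONE",
               hashBits = as.integer(hashBits), mode = mode, meta = meta)
}

## Multi-label decision per candidate row, restricted to allowed labels.
## labelMap translates an allowed label to the model column that scores it
## (expanded inventory entries borrow their source label's scorer).
decideLabels <- function(model, scores, allowed, labelMap = NULL) {
  cols <- if (is.null(labelMap)) allowed
          else ifelse(allowed %in% names(labelMap), labelMap[allowed], allowed)
  sc <- rep(-Inf, length(cols))
  hit <- cols %in% colnames(scores)
  sc[hit] <- scores[1, cols[hit]]
  names(sc) <- allowed
  sc <- c(sc, setNames(0, model@negativeLabel))
  out <- union(names(sc)[sc > 0], names(sc)[sc >= max(sc) - 1e-12])
  out
}

## ---- stage runners ---------------------------------------------------------

## Stage 1 over one document: returns candidates + features.
stage1Features <- function(state, headTable) {
  cands <- enumerateTriggerCandidates(state$doc, headTable, state$cfg)
  tb <- state$doc@textbounds
  goldAnchors <- anchorFrame(state, data.frame(
    token = vapply(seq_len(nrow(tb)), function(i)
      headTokenIndex(state$doc, tb$start[i], tb$end[i]), integer(1)),
    type = tb$type, stringsAsFactors = FALSE)[tb$type %in% state$cfg@goldTypes, ,
                                              drop = FALSE])
  feats <- lapply(cands, function(cd) featTrigger(state, cd$token, goldAnchors))
  list(cands = cands, feats = feats)
}

## Predicted textbound table for one document: gold pass-through plus
## positively classified trigger/entity candidates.
predictTriggerTbs <- function(state, model, headTable) {
  doc <- state$doc
  s1 <- stage1Features(state, headTable)
  tb <- doc@textbounds
  goldRows <- which(tb$type %in% state$cfg@goldTypes)
  out <- data.frame(id = character(), type = character(), start = integer(),
                    end = integer(), text = character(), token = integer(),
                    source = character(), stringsAsFactors = FALSE)
  for (i in goldRows) {
    out <- rbind(out, data.frame(
      id = tb$id[i], type = tb$type[i], start = tb$start[i], end = tb$end[i],
      text = tb$text[i],
      token = headTokenIndex(doc, tb$start[i], tb$end[i]),
      source = "gold", stringsAsFactors = FALSE))
  }
  if (length(s1$cands)) {
    X <- featureMatrix(s1$feats, model@hashBits)
    S <- scoreMatrix(model, X)
    nid <- 0L
    for (r in seq_along(s1$cands)) {
      cd <- s1$cands[[r]]
      labs <- decideLabels(model, S[r, , drop = FALSE], cd$allowed)
      labs <- setdiff(labs, model@negativeLabel)
      for (lab in labs) {
        nid <- nid + 1L
        tk <- doc@tokens[cd$token, ]
        out <- rbind(out, data.frame(
          id = paste0("TP", nid), type = lab, start = tk$start, end = tk$end,
          text = tk$surface, token = cd$token, source = "pred",
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

stage2Features <- function(state, tbs, roleLabels) {
  cands <- enumerateArgumentCandidates(tbs, roleLabels, state$cfg, state$doc)
  anchors <- anchorFrame(state, tbs)
  feats <- lapply(cands, function(cd)
    featPair(state, tbs$token[cd$trig], tbs$token[cd$arg],
             tbs$type[cd$trig], tbs$type[cd$arg], anchors))
  list(cands = cands, feats = feats)
}

## Positive pairs for one document: one row per (trigger row, arg row,
## role) with the decision score.
predictPairs <- function(state, tbs, model, roleLabels, labelMap) {
  s2 <- stage2Features(state, tbs, roleLabels)
  out <- data.frame(trig = integer(), arg = integer(), role = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  if (length(s2$cands) == 0L) return(out)
  X <- featureMatrix(s2$feats, model@hashBits)
  S <- scoreMatrix(model, X)
  for (r in seq_along(s2$cands)) {
    cd <- s2$cands[[r]]
    labs <- decideLabels(model, S[r, , drop = FALSE], cd$allowed, labelMap)
    labs <- setdiff(labs, model@negativeLabel)
    for (lab in labs) {
      role <- sub("^.*:(.*)-.*$", "\\1", lab)
      col <- if (lab %in% colnames(S)) lab else labelMap[[lab]]
      sc <- if (!is.null(col) && col %in% colnames(S)) S[r, col] else 0
      out <- rbind(out, data.frame(trig = cd$trig, arg = cd$arg, role = role,
                                   score = sc, stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

stage3Features <- function(state, tbs, pairs, matchIdx) {
  cfg <- state$cfg
  cands <- list(); feats <- list()
  if (nrow(pairs)) {
    for (ti in sort(unique(pairs$trig))) {
      sub <- pairs[pairs$trig == ti, , drop = FALSE]
      pf <- data.frame(role = sub$role, argType = tbs$type[sub$arg],
                       argRow = sub$arg, argToken = tbs$token[sub$arg],
                       argStart = tbs$start[sub$arg], score = sub$score,
                       stringsAsFactors = FALSE)
      cds <- enumerateEventCandidates(pf, tbs$type[ti], matchIdx, cfg)
      for (cd in cds) {
        cands[[length(cands) + 1L]] <-
          list(trig = ti, pairs = pf[cd$rows, , drop = FALSE],
               allowed = cd$allowed)
        feats[[length(feats) + 1L]] <-
          featStructure(state, tbs$token[ti], tbs$type[ti],
                        pf[cd$rows, , drop = FALSE], allPairs = pf)
      }
    }
  }
  list(cands = cands, feats = feats)
}

## Raw (unassembled) predicted events: trigger row + structure label +
## numbered role assignment over pair rows.
predictStructures <- function(state, tbs, pairs, model, structureLabels,
                              matchIdx, labelMap) {
  s3 <- stage3Features(state, tbs, pairs, matchIdx)
  out <- list()
  if (length(s3$cands) == 0L) return(out)
  X <- featureMatrix(s3$feats, model@hashBits)
  S <- scoreMatrix(model, X)
  for (r in seq_along(s3$cands)) {
    cd <- s3$cands[[r]]
    labs <- decideLabels(model, S[r, , drop = FALSE], cd$allowed, labelMap)
    labs <- setdiff(labs, model@negativeLabel)
    for (lab in labs) {
      assign <- assignNumberedRoles(structureLabels[[lab]], cd$pairs)
      if (is.null(assign)) next
      out[[length(out) + 1L]] <-
        list(trig = cd$trig,
             args = data.frame(role = assign$role,
                               argRow = cd$pairs$argRow[assign$row],
                               stringsAsFactors = FALSE))
    }
  }
  out
}

## Assemble nested events bottom-up; event-typed arguments must resolve to
## an already-assembled event anchored at the argument textbound (the
## first, in deterministic order, when several exist). Unresolvable or
## duplicate candidates are dropped.
assembleEvents <- function(state, tbs, rawEvents) {
  cfg <- state$cfg
  isTrig <- tbs$type %in% cfg@triggerTypes
  assembledByTb <- rep(NA_character_, nrow(tbs))
  events <- list()
  seen <- character()
  pending <- rawEvents
  repeat {
    progressed <- FALSE
    rest <- list()
    for (ev in pending) {
      targets <- character(nrow(ev$args))
      ok <- TRUE
      for (k in seq_len(nrow(ev$args))) {
        ar <- ev$args$argRow[k]
        if (isTrig[ar]) {
          if (is.na(assembledByTb[ar])) { ok <- FALSE; break }
          targets[k] <- assembledByTb[ar]
        } else targets[k] <- tbs$id[ar]
      }
      if (!ok) { rest[[length(rest) + 1L]] <- ev; next }
      key <- paste0(ev$trig, "|",
                    paste(sort(paste0(ev$args$role, "=", targets),
                               method = "radix"), collapse = ","))
      if (key %in% seen) { progressed <- TRUE; next }
      seen <- c(seen, key)
      id <- paste0("EP", length(events) + 1L)
      events[[length(events) + 1L]] <-
        list(id = id, type = tbs$type[ev$trig], trigger = tbs$id[ev$trig],
             trigRow = ev$trig,
             args = data.frame(role = ev$args$role, target = targets,
                               stringsAsFactors = FALSE),
             mods = character())
      if (is.na(assembledByTb[ev$trig])) assembledByTb[ev$trig] <- id
      progressed <- TRUE
    }
    pending <- rest
    if (!progressed || length(pending) == 0L) break
  }
  events
}

## ---- training --------------------------------------------------------------

#' Train the four-detector event-extraction pipeline
#'
#' Each stage is trained on candidate instances generated from the
#' predictions of the preceding stages over the training documents, so the
#' training-time instance distribution matches what each detector sees at
#' prediction time. Candidates that correspond to a gold annotation
#' inherit its label; all others get the negative type. Under the
#' covariate-shift and combined modes, per-stage importance weights are
#' estimated from the stage's candidate vectors on the training documents
#' versus the (unlabelled) target documents.
#'
#' @param trainDocs list of gold-annotated [StandoffDocument-class].
#' @param cfg a [TaskConfig-class].
#' @param mode adaptation mode overriding \code{cfg}'s option: one of
#'   \code{"none"}, \code{"weighting"}, \code{"covariate_shift"},
#'   \code{"combined"}.
#' @param seed integer seed (cross-fitting folds of the domain
#'   classifier; all other computations are deterministic).
#' @param targetDocs list of target-domain documents (text/tokens
#'   suffice); required for the covariate-shift and combined modes.
#' @return a [PipelineModel-class].
#' @export
trainPipeline <- function(trainDocs, cfg, mode = NULL, seed = NULL,
                          targetDocs = NULL) {
  if (length(trainDocs) == 0L) stopf("cannot train on an empty corpus")
  mode <- mode %||% taskOption(cfg, "mode")
  stopifnot(mode %in% stageModes)
  seed <- as.integer(seed %||% taskOption(cfg, "seed"))
  useShift <- mode %in% c("covariate_shift", "combined")
  if (useShift && length(targetDocs %||% list()) == 0L)
    stopf("mode '%s' requires targetDocs", mode)
  hashBits <- taskOption(cfg, "hashBits")
  clip <- taskOption(cfg, "clip")
  C <- taskOption(cfg, "C")

  inv <- collectInventories(trainDocs, cfg)
  roleExp <- expandRoleLabels(cfg, inv$roleLabels)
  structExp <- expandStructures(cfg, inv$structureLabels)
  matchIdx <- structureMatchIndex(structExp)
  roleMap <- setNames(ifelse(is.na(roleExp$expandedFrom), roleExp$key,
                             roleExp$expandedFrom), roleExp$key)
  structMap <- setNames(vapply(structExp, function(s)
    if (is.na(s$expandedFrom)) s$key else s$expandedFrom, character(1)),
    names(structExp))

  states <- lapply(trainDocs, docState, cfg = cfg)
  tgStates <- if (useShift) lapply(targetDocs, docState, cfg = cfg) else list()

  stageShift <- function(X, Xtg, stream) {
    if (!useShift || is.null(Xtg) || nrow(X) == 0L || nrow(Xtg) == 0L)
      return(NULL)
    estimateShiftWeights(X, Xtg, C = C, clip = clip,
                         seed = childSeed(seed, stream))
  }
  swOrUnit <- function(sw, n) {
    if (!useShift) return(NULL)
    sw %||% unitShiftWeights(n, C)
  }

  ## --- stage 1 ---
  s1 <- lapply(states, stage1Features, headTable = inv$headTable)
  goldSets1 <- list(); feats1 <- list()
  for (d in seq_along(states)) {
    gl <- goldTriggerLabels(states[[d]]$doc, cfg)
    for (r in seq_along(s1[[d]]$cands)) {
      cd <- s1[[d]]$cands[[r]]
      goldSets1[[length(goldSets1) + 1L]] <-
        intersect(gl[[as.character(cd$token)]] %||% character(), cd$allowed)
      feats1[[length(feats1) + 1L]] <- s1[[d]]$feats[[r]]
    }
  }
  X1 <- featureMatrix(feats1, hashBits)
  X1tg <- if (useShift) {
    ftg <- unlist(lapply(tgStates, function(st)
      stage1Features(st, inv$headTable)$feats), recursive = FALSE)
    featureMatrix(ftg, hashBits)
  } else NULL
  sw1 <- swOrUnit(stageShift(X1, X1tg, "sw1"), nrow(X1))
  det1 <- trainDetector("trigger", X1, goldSets1,
                        sort(unique(inv$headTable$type), method = "radix"),
                        cfg, mode, sw1)

  ## stage-1 predictions on the training (and target) documents
  tbsTr <- lapply(states, predictTriggerTbs, model = det1,
                  headTable = inv$headTable)
  tbsTg <- lapply(tgStates, predictTriggerTbs, model = det1,
                  headTable = inv$headTable)

  ## --- stage 2 ---
  goldIdxTr <- lapply(states, function(st) goldEventIndex(st$doc, cfg))
  s2 <- mapply(function(st, tbs) stage2Features(st, tbs, roleExp),
               states, tbsTr, SIMPLIFY = FALSE)
  goldSets2 <- list(); feats2 <- list()
  for (d in seq_along(states)) {
    tbs <- tbsTr[[d]]
    for (r in seq_along(s2[[d]]$cands)) {
      cd <- s2[[d]]$cands[[r]]
      roles <- goldPairRoles(goldIdxTr[[d]], tbs$token[cd$trig],
                             tbs$type[cd$trig], tbs$token[cd$arg],
                             tbs$type[cd$arg])
      keys <- if (length(roles)) {
        tG <- generalizeType(cfg, tbs$type[cd$trig], "argument_label", "trigger")
        aG <- generalizeType(cfg, tbs$type[cd$arg], "argument_label", "argument")
        intersect(roleLabelKey(tG, roles, aG), cd$allowed)
      } else character()
      goldSets2[[length(goldSets2) + 1L]] <- keys
      feats2[[length(feats2) + 1L]] <- s2[[d]]$feats[[r]]
    }
  }
  X2 <- featureMatrix(feats2, hashBits)
  X2tg <- if (useShift) {
    ftg <- unlist(mapply(function(st, tbs) stage2Features(st, tbs, roleExp)$feats,
                         tgStates, tbsTg, SIMPLIFY = FALSE),
                  recursive = FALSE)
    featureMatrix(ftg, hashBits)
  } else NULL
  sw2 <- swOrUnit(stageShift(X2, X2tg, "sw2"), nrow(X2))
  det2 <- trainDetector("argument", X2, goldSets2, inv$roleLabels$key, cfg,
                        mode, sw2)

  pairsTr <- mapply(function(st, tbs)
    predictPairs(st, tbs, det2, roleExp, roleMap),
    states, tbsTr, SIMPLIFY = FALSE)
  pairsTg <- mapply(function(st, tbs)
    predictPairs(st, tbs, det2, roleExp, roleMap),
    tgStates, tbsTg, SIMPLIFY = FALSE)

  ## --- stage 3 ---
  s3 <- mapply(function(st, tbs, prs) stage3Features(st, tbs, prs, matchIdx),
               states, tbsTr, pairsTr, SIMPLIFY = FALSE)
  goldSets3 <- list(); feats3 <- list()
  for (d in seq_along(states)) {
    tbs <- tbsTr[[d]]
    for (r in seq_along(s3[[d]]$cands)) {
      cd <- s3[[d]]$cands[[r]]
      ps <- data.frame(role = cd$pairs$role,
                       argToken = cd$pairs$argToken,
                       argType = cd$pairs$argType, stringsAsFactors = FALSE)
      gk <- goldStructureKey(goldIdxTr[[d]], cfg, tbs$token[cd$trig],
                             tbs$type[cd$trig], ps)
      goldSets3[[length(goldSets3) + 1L]] <-
        intersect(gk %||% character(), cd$allowed)
      feats3[[length(feats3) + 1L]] <- s3[[d]]$feats[[r]]
    }
  }
  X3 <- featureMatrix(feats3, hashBits)
  X3tg <- if (useShift) {
    ftg <- unlist(mapply(function(st, tbs, prs)
      stage3Features(st, tbs, prs, matchIdx)$feats,
      tgStates, tbsTg, pairsTg, SIMPLIFY = FALSE), recursive = FALSE)
    featureMatrix(ftg, hashBits)
  } else NULL
  sw3 <- swOrUnit(stageShift(X3, X3tg, "sw3"), nrow(X3))
  det3 <- trainDetector("structure", X3, goldSets3,
                        names(inv$structureLabels), cfg, mode, sw3)

  evTr <- mapply(function(st, tbs, prs) {
    raw <- predictStructures(st, tbs, prs, det3, structExp, matchIdx,
                             structMap)
    assembleEvents(st, tbs, raw)
  }, states, tbsTr, pairsTr, SIMPLIFY = FALSE)

  ## --- stage 4: hedges ---
  goldSets4 <- list(); feats4 <- list()
  for (d in seq_along(states)) {
    st <- states[[d]]; tbs <- tbsTr[[d]]
    for (ev in evTr[[d]]) {
      gm <- goldModsFor(goldIdxTr[[d]], st, tbs, ev, evTr[[d]])
      goldSets4[[length(goldSets4) + 1L]] <- gm
      feats4[[length(feats4) + 1L]] <-
        featHedge(st, tbs$token[ev$trigRow], ev$type)
    }
  }
  X4 <- featureMatrix(feats4, hashBits)
  X4tg <- NULL
  sw4 <- NULL
  if (useShift && length(feats4)) {
    ftg <- list()
    for (d in seq_along(tgStates)) {
      st <- tgStates[[d]]; tbs <- tbsTg[[d]]
      raw <- predictStructures(st, tbs, pairsTg[[d]], det3, structExp,
                               matchIdx, structMap)
      for (ev in assembleEvents(st, tbs, raw))
        ftg[[length(ftg) + 1L]] <- featHedge(st, tbs$token[ev$trigRow], ev$type)
    }
    if (length(ftg)) {
      X4tg <- featureMatrix(ftg, hashBits)
      sw4 <- stageShift(X4, X4tg, "sw4")
    }
    sw4 <- sw4 %||% unitShiftWeights(nrow(X4), C)
  }
  det4 <- trainDetector("hedge", X4, goldSets4,
                        c("Negation", "Speculation"), cfg, mode, sw4)

  methods::new("PipelineModel", config = cfg,
               inventories = list(roleLabels = inv$roleLabels,
                                  structureLabels = inv$structureLabels,
                                  headTable = inv$headTable,
                                  roleLabelsExpanded = roleExp,
                                  structureLabelsExpanded = structExp,
                                  roleMap = roleMap, structMap = structMap),
               detectors = list(trigger = det1, argument = det2,
                                structure = det3, hedge = det4),
               meta = list(seed = seed, mode = mode,
                           hash = "murmur2-32",
                           hashBits = as.integer(hashBits),
                           version = as.character(utils::packageVersion("EventPipe"))))
}

## Gold hedge labels for an assembled event: the modifications of the gold
## event it structurally matches (trigger token/type and full recursive
## argument agreement).
goldModsFor <- function(goldIdx, state, tbs, ev, allEvents) {
  evById <- setNames(allEvents, vapply(allEvents, function(e) e$id, character(1)))
  matchGold <- function(g, e) {
    if (g$type != e$type || g$trigTok != tbs$token[e$trigRow]) return(FALSE)
    if (length(g$args) != nrow(e$args)) return(FALSE)
    used <- rep(FALSE, length(g$args))
    for (k in seq_len(nrow(e$args))) {
      hit <- FALSE
      tgt <- e$args$target[k]
      for (j in seq_along(g$args)) {
        if (used[j]) next
        a <- g$args[[j]]
        if (deNumberRole(a$role) != deNumberRole(e$args$role[k])) next
        if (startsWith(tgt, "EP")) {
          sub <- evById[[tgt]]
          if (!is.null(sub) && a$type == sub$type &&
              a$token == tbs$token[sub$trigRow]) { hit <- TRUE }
        } else {
          row <- match(tgt, tbs$id)
          if (!is.na(row) && !is.na(a$token) && a$token == tbs$token[row] &&
              a$type == tbs$type[row]) { hit <- TRUE }
        }
        if (hit) { used[j] <- TRUE; break }
      }
      if (!hit) return(FALSE)
    }
    TRUE
  }
  for (g in goldIdx) if (matchGold(g, ev)) return(g$mods)
  character()
}

## ---- prediction ------------------------------------------------------------

#' Run the trained pipeline over a document
#'
#' Applies the four detectors in order and returns a copy of the document
#' carrying the predicted annotations: gold (.a1) entities pass through
#' untouched, predicted triggers are emitted only when an emitted event
#' references them, events are assembled bottom-up (nested events resolve
#' to already-assembled sub-events; exact structural duplicates are
#' deduplicated), and hedge modifications are attached per event.
#'
#' @param doc a [StandoffDocument-class] with text and tokens (gold
#'   entities optional, per the configuration).
#' @param model a [PipelineModel-class].
#' @return a [StandoffDocument-class] with predicted annotations.
#' @export
predictPipeline <- function(doc, model) {
  cfg <- model@config
  state <- docState(doc, cfg)
  inv <- model@inventories
  det <- model@detectors
  tbs <- predictTriggerTbs(state, det$trigger, inv$headTable)
  pairs <- predictPairs(state, tbs, det$argument, inv$roleLabelsExpanded,
                        inv$roleMap)
  matchIdx <- structureMatchIndex(inv$structureLabelsExpanded)
  raw <- predictStructures(state, tbs, pairs, det$structure,
                           inv$structureLabelsExpanded, matchIdx,
                           inv$structMap)
  evs <- assembleEvents(state, tbs, raw)
  evs <- detectHedges(evs, state, tbs, det$hedge)
  ## emit: gold pass-through entities, predicted entity types, and any
  ## textbound referenced by an emitted event
  referenced <- unique(c(vapply(evs, function(e) e$trigger, character(1)),
                         unlist(lapply(evs, function(e) e$args$target))))
  keep <- tbs$source == "gold" |
    (tbs$type %in% setdiff(entityTypes(cfg), cfg@goldTypes)) |
    (tbs$id %in% referenced)
  outTb <- tbs[keep, c("id", "type", "start", "end", "text"), drop = FALSE]
  rownames(outTb) <- NULL
  outEvents <- lapply(evs, function(e)
    list(id = e$id, type = e$type, trigger = e$trigger, args = e$args,
         mods = e$mods))
  methods::new("StandoffDocument", id = doc@id, text = doc@text,
               tokens = doc@tokens, textbounds = outTb, events = outEvents,
               equivalences = doc@equivalences)
}

#' Attach hedge modifications to assembled events
#'
#' Classifies every assembled event independently into the multi-label
#' hedge set \{Negation, Speculation\} (both may co-occur; the negative
#' type yields no modification).
#'
#' @param evs assembled event records (internal layout).
#' @param state internal document state.
#' @param tbs the detected textbound table.
#' @param model the hedge [DetectorModel-class].
#' @return the events with \code{mods} filled in.
#' @export
detectHedges <- function(evs, state, tbs, model) {
  if (length(evs) == 0L || length(model@labels) == 0L) return(evs)
  feats <- lapply(evs, function(ev) featHedge(state, tbs$token[ev$trigRow],
                                              ev$type))
  X <- featureMatrix(feats, model@hashBits)
  S <- scoreMatrix(model, X)
  for (r in seq_along(evs)) {
    labs <- decideLabels(model, S[r, , drop = FALSE], model@labels)
    evs[[r]]$mods <- sort(setdiff(labs, model@negativeLabel), method = "radix")
  }
  evs
}

## ---- persistence -----------------------------------------------------------

#' Save / load a trained pipeline model
#'
#' The archive is versioned and records the hash function and feature-space
#' size; loading a model whose hash choice does not match the running
#' package is an error, since feature indices would silently disagree.
#'
#' @param model a [PipelineModel-class].
#' @param path file path for the model archive.
#' @return \code{savePipelineModel} returns \code{path} invisibly;
#'   \code{loadPipelineModel} returns the model.
#' @export
savePipelineModel <- function(model, path) {
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname savePipelineModel
#' @export
loadPipelineModel <- function(path) {
  model <- readRDS(path)
  if (!methods::is(model, "PipelineModel"))
    stopf("%s is not a pipeline model archive", path)
  if (!identical(model@meta$hash, "murmur2-32"))
    stopf("model hash choice %s does not match this package (murmur2-32)",
          model@meta$hash %||% "<missing>")
  model
}
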