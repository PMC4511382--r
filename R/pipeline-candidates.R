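## Candidate enumeration, per-candidate features, and gold matching for the
## four detector stages. Candidates are plain list records; the heavy
## containers (documents, models) are S4.

## Per-document working state: the document, its entity-masked token table,
## and the original-token -> masked-row index map.
docState <- function(doc, cfg) {
  goldEnts <- intersect(entityTypes(cfg), cfg@goldTypes)
  masked <- maskEntitiesMapped(doc, goldEnts)
  list(doc = doc, masked = masked$tokens, map = masked$map, cfg = cfg)
}

## maskEntities plus an index map and head remapping, for internal use.
maskEntitiesMapped <- function(doc, goldTypes) {
  tk <- doc@tokens
  tb <- doc@textbounds
  ents <- tb[tb$type %in% goldTypes, , drop = FALSE]
  n <- nrow(tk)
  if (nrow(ents) == 0L || n == 0L)
    return(list(tokens = tk, map = seq_len(n)))
  ents <- ents[cOrder(-(ents$end - ents$start), ents$start), , drop = FALSE]
  owner <- rep(NA_integer_, n)
  for (i in seq_len(nrow(ents))) {
    cover <- which(tk$start < ents$end[i] & tk$end > ents$start[i])
    cover <- cover[is.na(owner[cover])]
    owner[cover] <- i
  }
  rows <- list(); map <- integer(n); rep_ <- integer(0)
  i <- 1L
  while (i <= n) {
    if (is.na(owner[i])) {
      rows[[length(rows) + 1L]] <- tk[i, ]
      rep_ <- c(rep_, i)
      map[i] <- length(rows)
      i <- i + 1L
    } else {
      o <- owner[i]
      run <- i
      while (run < n && !is.na(owner[run + 1L]) && owner[run + 1L] == o)
        run <- run + 1L
      span <- i:run
      ## representative: the token whose head lies outside the run
      ext <- span[!(tk$head[span] %in% span)]
      repTok <- if (length(ext)) ext[length(ext)] else run
      row <- tk[repTok, ]
      row$surface <- row$base <- row$stem <- ents$type[o]
      row$start <- min(tk$start[span]); row$end <- max(tk$end[span])
      rows[[length(rows) + 1L]] <- row
      rep_ <- c(rep_, repTok)
      map[span] <- length(rows)
      i <- run + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ## remap heads through the representatives (0 = root stays 0)
  h <- out$head
  nz <- h > 0L
  h[nz] <- map[h[nz]]
  h[h == seq_len(nrow(out))] <- 0L  # collapsed self-loop -> root
  out$head <- h
  list(tokens = out, map = map)
}

## ---- feature builders ------------------------------------------------------

prefixKeys <- function(df, prefix) {
  if (nrow(df)) df$key <- paste0(prefix, "|", df$key)
  df
}

windowFeatures <- function(masked, m, width = 3L) {
  sent <- which(masked$sentence == masked$sentence[m])
  pos <- match(m, sent)
  keys <- character()
  for (off in -width:width) {
    j <- pos + off
    if (j < 1L || j > length(sent) || off == 0L) next
    keys <- c(keys, paste0("u", off, ":", masked$stem[sent[j]]))
  }
  lo <- max(1L, pos - width); hi <- min(length(sent), pos + width)
  bi <- if (hi > lo)
    paste0("b:", masked$stem[sent[lo:(hi - 1L)]], "_",
           masked$stem[sent[(lo + 1L):hi]])
  else character()
  featureFrame("word_ngram", c(keys, bi))
}

anchorFrame <- function(state, tbs) {
  if (is.null(tbs) || nrow(tbs) == 0L)
    return(data.frame(token = integer(), type = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(token = state$map[tbs$token],
                    type = generalizeType(state$cfg, tbs$type, "feature",
                                          "argument"),
                    stringsAsFactors = FALSE)
  out[!is.na(out$token), , drop = FALSE]
}

featTrigger <- function(state, tokIdx, anchors = NULL) {
  m <- state$map[tokIdx]
  masked <- state$masked
  self <- charNgrams(masked$surface[m],
                     taskOption(state$cfg, "charNgram")[1],
                     taskOption(state$cfg, "charNgram")[2])
  lex <- featureFrame("word_ngram",
                      c(paste0("self.s:", masked$surface[m]),
                        paste0("self.b:", masked$base[m]),
                        paste0("self.st:", masked$stem[m])))
  ctx <- if (!is.null(anchors))
    contextFeatures(state$doc, m, anchors, tokens = masked)
  else NULL
  bindFeatures(self, lex, windowFeatures(masked, m), ctx)
}

featPair <- function(state, trigTok, argTok, trigType, argType,
                     anchors = NULL) {
  masked <- state$masked
  mt <- state$map[trigTok]; ma <- state$map[argTok]
  cfg <- state$cfg
  tG <- generalizeType(cfg, trigType, "feature", "trigger")
  aG <- generalizeType(cfg, argType, "feature", "argument")
  types <- featureFrame("word_ngram",
                        c(paste0("tt:", tG), paste0("at:", aG),
                          paste0("ta:", tG, "+", aG)))
  ct <- prefixKeys(charNgrams(masked$surface[mt], 2L, 4L), "t")
  ca <- prefixKeys(charNgrams(masked$surface[ma], 2L, 4L), "a")
  path <- shortestPathFeatures(state$doc, mt, ma, tokens = masked)
  if (is.null(path)) {
    path <- featureFrame("path", paste0("xsent:", distanceBucket(ma - mt)))
  }
  between <- if (masked$sentence[mt] == masked$sentence[ma]) {
    lo <- min(mt, ma); hi <- max(mt, ma)
    wordNgrams(masked$stem[lo:hi],
               taskOption(cfg, "wordNgram")[1],
               min(taskOption(cfg, "wordNgram")[2], 3L))
  } else NULL
  ctx <- if (!is.null(anchors))
    contextFeatures(state$doc, c(mt, ma), anchors, tokens = masked)
  else NULL
  bindFeatures(types, ct, ca, path, between, ctx)
}

featStructure <- function(state, trigTok, trigType, pairs, allPairs = NULL) {
  masked <- state$masked
  cfg <- state$cfg
  mt <- state$map[trigTok]
  tG <- generalizeType(cfg, trigType, "feature", "trigger")
  ## pairs left out of this combination are strong evidence against it
  excl <- if (!is.null(allPairs) && nrow(allPairs) > nrow(pairs)) {
    left <- allPairs[!(rownames(allPairs) %in% rownames(pairs)), ,
                     drop = FALSE]
    exG <- generalizeType(cfg, left$argType, "feature", "argument")
    featureFrame("word_ngram", c(paste0("excl:", left$role, "-", exG),
                                 paste0("n_excl:", nrow(left))))
  } else featureFrame("word_ngram", "n_excl:0")
  base <- featureFrame("word_ngram",
                       c(paste0("tt:", tG),
                         paste0("n_args:", nrow(pairs)),
                         paste0("roles:", paste(sort(pairs$role, method = "radix"),
                                                collapse = "+"))))
  ct <- prefixKeys(charNgrams(masked$surface[mt], 2L, 4L), "t")
  slotFeats <- list()
  for (k in seq_len(nrow(pairs))) {
    aG <- generalizeType(cfg, pairs$argType[k], "feature", "argument")
    slotFeats[[length(slotFeats) + 1L]] <-
      featureFrame("word_ngram", paste0("slot:", pairs$role[k], "-", aG))
    pf <- shortestPathFeatures(state$doc, mt, state$map[pairs$argToken[k]],
                               tokens = masked)
    if (!is.null(pf) && nrow(pf))
      slotFeats[[length(slotFeats) + 1L]] <- prefixKeys(pf, pairs$role[k])
  }
  bindFeatures(base, excl, ct, windowFeatures(masked, mt),
               do.call(bindFeatures, slotFeats))
}

featHedge <- function(state, trigTok, evType) {
  masked <- state$masked
  m <- state$map[trigTok]
  sent <- which(masked$sentence == masked$sentence[m])
  bindFeatures(
    featureFrame("word_ngram", paste0("evtype:", evType)),
    prefixKeys(wordNgrams(masked$stem[sent], 1L, 2L, group = "context_word"),
               "hedge"),
    windowFeatures(masked, m))
}

## ---- stage 1: trigger/entity candidates ------------------------------------

#' Enumerate trigger/entity candidates for one document
#'
#' One candidate per token whose surface, base form or stem appears in the
#' training head-word table, excluding tokens that overlap a given (.a1)
#' entity span. Admissible labels are the types recorded for the matched
#' head forms.
#'
#' @param doc a [StandoffDocument-class].
#' @param headTable head-word table from [collectInventories()].
#' @param cfg a [TaskConfig-class].
#' @return list of candidate records (fields \code{token},
#'   \code{allowed}).
#' @export
enumerateTriggerCandidates <- function(doc, headTable, cfg) {
  tk <- doc@tokens
  if (nrow(tk) == 0L || nrow(headTable) == 0L) return(list())
  goldTb <- doc@textbounds[doc@textbounds$type %in% cfg@goldTypes, ,
                           drop = FALSE]
  detect <- setdiff(union(cfg@predictionTypes, cfg@triggerTypes),
                    cfg@goldTypes)
  out <- list()
  for (i in seq_len(nrow(tk))) {
    if (nrow(goldTb) && any(goldTb$start < tk$end[i] & goldTb$end > tk$start[i]))
      next
    hit <- headTable$type[headTable$form %in%
                            c(tk$surface[i], tk$base[i], tk$stem[i])]
    hit <- intersect(unique(hit), detect)
    if (length(hit) == 0L) next
    out[[length(out) + 1L]] <-
      list(token = i, allowed = sort(hit, method = "radix"))
  }
  out
}

## Gold trigger labels per token: head token of each gold textbound of a
## detectable type.
goldTriggerLabels <- function(doc, cfg) {
  tb <- doc@textbounds
  detect <- setdiff(union(cfg@predictionTypes, cfg@triggerTypes),
                    cfg@goldTypes)
  labs <- list()
  for (i in seq_len(nrow(tb))) {
    if (!(tb$type[i] %in% detect)) next
    h <- headTokenIndex(doc, tb$start[i], tb$end[i])
    if (is.na(h)) next
    key <- as.character(h)
    labs[[key]] <- union(labs[[key]], tb$type[i])
  }
  labs
}

## ---- stage 2: argument-pair candidates -------------------------------------

#' Enumerate trigger-argument pair candidates
#'
#' One candidate per (trigger, participant) pair of detected annotations
#' whose generalised type combination occurs in the (possibly expanded)
#' role-label inventory. Participants include detected triggers, so nested
#' events are reachable. Cross-sentence pairs are enumerated only when the
#' inventory observed that combination across sentences in training.
#'
#' @param tbs data.frame of detected textbounds with columns \code{id},
#'   \code{type}, \code{start}, \code{end}, \code{token}.
#' @param roleLabels role-label inventory data.frame.
#' @param cfg a [TaskConfig-class].
#' @param doc the document (for sentence lookup).
#' @return list of candidate records (fields \code{trig}, \code{arg} (row
#'   indices into \code{tbs}), \code{allowed} (role-label keys)).
#' @export
enumerateArgumentCandidates <- function(tbs, roleLabels, cfg, doc) {
  out <- list()
  if (is.null(tbs) || nrow(tbs) == 0L || nrow(roleLabels) == 0L) return(out)
  trigRows <- which(tbs$type %in% cfg@triggerTypes)
  sent <- doc@tokens$sentence
  for (i in trigRows) {
    tG <- generalizeType(cfg, tbs$type[i], "argument_label", "trigger")
    for (j in seq_len(nrow(tbs))) {
      if (j == i) next
      aG <- generalizeType(cfg, tbs$type[j], "argument_label", "argument")
      hits <- roleLabels[roleLabels$trigger == tG & roleLabels$arg == aG, ,
                         drop = FALSE]
      if (nrow(hits) == 0L) next
      sameSent <- sent[tbs$token[i]] == sent[tbs$token[j]]
      if (!sameSent) hits <- hits[hits$crossSentence, , drop = FALSE]
      if (nrow(hits) == 0L) next
      out[[length(out) + 1L]] <-
        list(trig = i, arg = j, allowed = hits$key)
    }
  }
  out
}

## Gold event index for pair/structure matching: per event, the trigger's
## head token + type and each argument's anchor head token + concrete type
## + role.
goldEventIndex <- function(doc, cfg) {
  tb <- doc@textbounds
  lapply(doc@events, function(e) {
    ti <- match(e$trigger, tb$id)
    trigTok <- headTokenIndex(doc, tb$start[ti], tb$end[ti])
    args <- lapply(seq_len(nrow(e$args)), function(k) {
      anchor <- anchorTextbound(doc, e$args$target[k])
      ai <- match(anchor, tb$id)
      list(role = e$args$role[k],
           token = headTokenIndex(doc, tb$start[ai], tb$end[ai]),
           type = eventTypeOf(doc, e$args$target[k]))
    })
    list(id = e$id, type = e$type, trigTok = trigTok, args = args,
         mods = e$mods)
  })
}

goldPairRoles <- function(goldIdx, trigTok, trigType, argTok, argType) {
  roles <- character()
  for (g in goldIdx) {
    if (g$trigTok != trigTok || g$type != trigType) next
    for (a in g$args) {
      if (!is.na(a$token) && a$token == argTok && a$type == argType)
        roles <- union(roles, deNumberRole(a$role))
    }
  }
  roles
}

## ---- stage 3: event-structure candidates -----------------------------------

## Index the structure inventory by the de-numbered slot multiset, per
## generalised trigger component.
structureMatchIndex <- function(structureLabels) {
  idx <- list()
  for (s in structureLabels) {
    mk <- paste0(s$trigger, "|", slotKey(deNumberRole(s$slots$role), s$slots$arg))
    idx[[mk]] <- c(idx[[mk]], s$key)
  }
  idx
}

#' Enumerate event-structure candidates for one trigger's pairs
#'
#' Every non-empty subset of a trigger's positively-classified argument
#' pairs whose de-numbered role/argument-type multiset matches a structure
#' in the (possibly expanded) inventory becomes a candidate. To guard
#' against combinatorial blow-up the \code{pairCap} highest-scoring pairs
#' per trigger are considered (default 10).
#'
#' @param pairs data.frame with columns \code{role}, \code{argType},
#'   \code{argRow}, \code{argToken}, \code{score} for one trigger.
#' @param trigType the trigger's (concrete) type.
#' @param matchIdx index from [structureMatchIndex] over the inventory.
#' @param cfg a [TaskConfig-class].
#' @return list of candidate records (fields \code{rows} (pair row
#'   indices), \code{allowed} (structure keys)).
#' @export
enumerateEventCandidates <- function(pairs, trigType, matchIdx, cfg) {
  out <- list()
  if (nrow(pairs) == 0L) return(out)
  cap <- taskOption(cfg, "pairCap")
  if (nrow(pairs) > cap) {
    keep <- order(-pairs$score)[seq_len(cap)]
    pairs <- pairs[sort(keep), , drop = FALSE]
  }
  tG <- generalizeType(cfg, trigType, "structure_label", "trigger")
  argG <- generalizeType(cfg, pairs$argType, "structure_label", "argument")
  k <- nrow(pairs)
  for (mask in seq_len(2L^k - 1L)) {
    sel <- which(bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0L)
    mk <- paste0(tG, "|", slotKey(pairs$role[sel], argG[sel]))
    keys <- matchIdx[[mk]]
    if (is.null(keys)) next
    out[[length(out) + 1L]] <- list(rows = sel, allowed = sort(keys, method = "radix"))
  }
  out
}

goldStructureKey <- function(goldIdx, cfg, trigTok, trigType, pairSet) {
  ## pairSet: data.frame(role (de-numbered), argToken, argType)
  candKey <- slotKey(pairSet$role,
                     paste0(pairSet$argToken, "/", pairSet$argType))
  for (g in goldIdx) {
    if (g$trigTok != trigTok || g$type != trigType) next
    roles <- vapply(g$args, function(a) deNumberRole(a$role), character(1))
    toks <- vapply(g$args, function(a) as.integer(a$token), integer(1))
    types <- vapply(g$args, function(a) a$type, character(1))
    gKey <- slotKey(roles, paste0(toks, "/", types))
    if (gKey == candKey) {
      tG <- generalizeType(cfg, g$type, "structure_label", "trigger")
      rolesS <- vapply(g$args, function(a)
        generalizeType(cfg, a$role, "structure_label", "role"), character(1))
      argsS <- generalizeType(cfg, types, "structure_label", "argument")
      return(structureKey(tG, rolesS, argsS))
    }
  }
  NULL
}

## ---- assembly --------------------------------------------------------------

## Assign numbered roles from a structure label to concrete pairs: within
## each de-numbered role group, slots ordered by number and pairs by
## argument text order.
assignNumberedRoles <- function(structure, pairSet) {
  slots <- structure$slots
  base <- deNumberRole(slots$role)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", slots$role)))
  num[is.na(num)] <- 1L
  assign <- data.frame(role = character(), row = integer(),
                       stringsAsFactors = FALSE)
  used <- rep(FALSE, nrow(pairSet))
  for (b in unique(base)) {
    sIdx <- which(base == b)
    sIdx <- sIdx[order(num[sIdx])]
    pIdx <- which(pairSet$role == b & !used)
    pIdx <- pIdx[order(pairSet$argStart[pIdx])]
    if (length(sIdx) != length(pIdx)) return(NULL)
    for (t in seq_along(sIdx)) {
      assign <- rbind(assign,
                      data.frame(role = slots$role[sIdx[t]], row = pIdx[t],
                                 stringsAsFactors = FALSE))
      used[pIdx[t]] <- TRUE
    }
  }
  if (!all(used)) return(NULL)
  assign
}
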