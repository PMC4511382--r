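## Scoring: soft-boundary span matching, strict / partial recursive event
## matching, per-category precision/recall/F reports, and the approximate
## randomisation significance test.

#' Soft-boundary span match
#'
#' A predicted span counts as matching a gold span when it lies within the
#' gold span extended by one token on each side (using the document's
#' tokenisation); exact equality always matches.
#'
#' @param gold,pred length-2 integer vectors \code{c(start, end)} (0-based,
#'   half-open).
#' @param doc the [StandoffDocument-class] the spans refer to.
#' @return logical.
#' @export
matchSpanSoft <- function(gold, pred, doc) {
  if (gold[1] == pred[1] && gold[2] == pred[2]) return(TRUE)
  tk <- doc@tokens
  if (nrow(tk) == 0L) return(FALSE)
  over <- which(tk$start < gold[2] & tk$end > gold[1])
  extStart <- gold[1]; extEnd <- gold[2]
  if (length(over)) {
    lo <- min(over); hi <- max(over)
    extStart <- min(extStart, if (lo > 1L) tk$start[lo - 1L] else tk$start[lo])
    extEnd <- max(extEnd, if (hi < nrow(tk)) tk$end[hi + 1L] else tk$end[hi])
  }
  pred[1] >= extStart && pred[2] <= extEnd && pred[1] < pred[2]
}

tbSpan <- function(doc, id) {
  j <- match(id, doc@textbounds$id)
  if (is.na(j)) return(NULL)
  c(doc@textbounds$start[j], doc@textbounds$end[j])
}

tbType <- function(doc, id) {
  j <- match(id, doc@textbounds$id)
  if (is.na(j)) NA_character_ else doc@textbounds$type[j]
}

eventById <- function(doc, id) {
  for (e in doc@events) if (e$id == id) return(e)
  NULL
}

## Spans a gold textbound may present: its own span plus any equivalence
## partners'.
equivSpans <- function(doc, id) {
  spans <- list(list(span = tbSpan(doc, id), type = tbType(doc, id)))
  for (eq in doc@equivalences) {
    if (id %in% eq) {
      for (m in setdiff(eq, id))
        spans[[length(spans) + 1L]] <- list(span = tbSpan(doc, m),
                                            type = tbType(doc, m))
    }
  }
  spans
}

#' Strict or partial-recursive event match
#'
#' Strict: event types equal, triggers soft-match, and the role multisets
#' agree exactly, with entity arguments matched by soft span plus type
#' (equivalence-set members interchangeable) and event arguments matched by
#' strict recursion. Partial recursive: as strict at the top level, but an
#' event-valued argument already matches when its type and trigger
#' soft-match and its Theme-role sub-arguments match recursively
#' (non-Theme sub-arguments are ignored).
#'
#' @param goldE,predE event records from [events()].
#' @param mode \code{"strict"} or \code{"partial"}.
#' @param goldDoc,predDoc the documents the events live in.
#' @return logical.
#' @export
matchEvent <- function(goldE, predE, mode = c("strict", "partial"),
                       goldDoc, predDoc) {
  mode <- match.arg(mode)
  matchEventRec(goldE, predE, goldDoc, predDoc, mode, top = TRUE)
}

matchTrigger <- function(goldE, predE, goldDoc, predDoc) {
  gs <- tbSpan(goldDoc, goldE$trigger)
  ps <- tbSpan(predDoc, predE$trigger)
  !is.null(gs) && !is.null(ps) && matchSpanSoft(gs, ps, goldDoc)
}

matchArgTarget <- function(gTarget, pTarget, goldDoc, predDoc, mode) {
  gEv <- eventById(goldDoc, gTarget)
  pEv <- eventById(predDoc, pTarget)
  if (!is.null(gEv) || !is.null(pEv)) {
    if (is.null(gEv) || is.null(pEv)) return(FALSE)
    if (mode == "strict")
      return(matchEventRec(gEv, pEv, goldDoc, predDoc, mode, top = FALSE))
    ## partial: type + trigger soft-match + Theme-role recursion
    if (gEv$type != pEv$type) return(FALSE)
    if (!matchTrigger(gEv, pEv, goldDoc, predDoc)) return(FALSE)
    gTh <- gEv$args[deNumberRole(gEv$args$role) == "Theme", , drop = FALSE]
    pTh <- pEv$args[deNumberRole(pEv$args$role) == "Theme", , drop = FALSE]
    return(matchArgMultiset(gTh, pTh, goldDoc, predDoc, mode))
  }
  ## entity argument: soft span + type, equivalence members interchangeable
  ps <- tbSpan(predDoc, pTarget)
  pt <- tbType(predDoc, pTarget)
  if (is.null(ps) || is.na(pt)) return(FALSE)
  for (cand in equivSpans(goldDoc, gTarget)) {
    if (!is.null(cand$span) && !is.na(cand$type) && cand$type == pt &&
        matchSpanSoft(cand$span, ps, goldDoc))
      return(TRUE)
  }
  FALSE
}

## One-to-one matching of argument rows with identical role names
## (backtracking; argument lists are small).
matchArgMultiset <- function(gArgs, pArgs, goldDoc, predDoc, mode) {
  if (nrow(gArgs) != nrow(pArgs)) return(FALSE)
  if (nrow(gArgs) == 0L) return(TRUE)
  try1 <- function(gRows, pUsed) {
    if (length(gRows) == 0L) return(TRUE)
    g <- gRows[1]
    for (p in seq_len(nrow(pArgs))) {
      if (pUsed[p]) next
      if (gArgs$role[g] != pArgs$role[p]) next
      if (!matchArgTarget(gArgs$target[g], pArgs$target[p], goldDoc, predDoc,
                          mode)) next
      pUsed[p] <- TRUE
      if (try1(gRows[-1], pUsed)) return(TRUE)
      pUsed[p] <- FALSE
    }
    FALSE
  }
  try1(seq_len(nrow(gArgs)), rep(FALSE, nrow(pArgs)))
}

matchEventRec <- function(goldE, predE, goldDoc, predDoc, mode, top) {
  if (goldE$type != predE$type) return(FALSE)
  if (!matchTrigger(goldE, predE, goldDoc, predDoc)) return(FALSE)
  matchArgMultiset(goldE$args, predE$args, goldDoc, predDoc, mode)
}

prf <- function(gold, matchedGold, pred, matchedPred) {
  gold <- as.numeric(gold); matchedGold <- as.numeric(matchedGold)
  pred <- as.numeric(pred); matchedPred <- as.numeric(matchedPred)
  r <- if (gold == 0) { if (pred == 0) 1 else 0 } else matchedGold / gold
  p <- if (pred == 0) { if (gold == 0) 1 else 0 } else matchedPred / pred
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(recall = r, precision = p, fscore = f)
}

## Per-document matched/total counts per category (events + MOD items).
docCounts <- function(goldDoc, predDoc, categories, mode) {
  catOf <- function(type)
    if (type %in% names(categories)) categories[[type]] else type
  gEvents <- goldDoc@events
  pEvents <- predDoc@events
  matched <- rep(NA_integer_, length(gEvents))   # index into pEvents
  pUsed <- rep(FALSE, length(pEvents))
  for (i in seq_along(gEvents)) {
    for (j in seq_along(pEvents)) {
      if (pUsed[j]) next
      if (matchEvent(gEvents[[i]], pEvents[[j]], mode, goldDoc, predDoc)) {
        matched[i] <- j; pUsed[j] <- TRUE; break
      }
    }
  }
  rows <- list()
  bump <- function(cat, dGold = 0L, dMG = 0L, dPred = 0L, dMP = 0L) {
    cur <- rows[[cat]] %||% c(gold = 0L, matchedGold = 0L, pred = 0L,
                              matchedPred = 0L)
    rows[[cat]] <<- cur + c(dGold, dMG, dPred, dMP)
  }
  for (i in seq_along(gEvents)) {
    bump(catOf(gEvents[[i]]$type), dGold = 1L,
         dMG = as.integer(!is.na(matched[i])))
    for (m in gEvents[[i]]$mods)
      bump("MOD", dGold = 1L,
           dMG = as.integer(!is.na(matched[i]) &&
                              m %in% pEvents[[matched[i]]]$mods))
  }
  gMatchOf <- match(seq_along(pEvents), matched)  # pred j -> gold i
  for (j in seq_along(pEvents)) {
    bump(catOf(pEvents[[j]]$type), dPred = 1L, dMP = as.integer(pUsed[j]))
    for (m in pEvents[[j]]$mods)
      bump("MOD", dPred = 1L,
           dMP = as.integer(!is.na(gMatchOf[j]) &&
                              m %in% gEvents[[gMatchOf[j]]]$mods))
  }
  rows
}

#' Score a predicted corpus against gold
#'
#' Greedy one-to-one matching per document (each gold event consumed by at
#' most one prediction and vice versa), counted per category; hedge
#' modifications are scored as separate MOD items that require the
#' underlying event to match. Conventions: recall is
#' \code{matchedGold/gold} (1 when both gold and predicted are empty, 0
#' when only gold is), precision analogously, and
#' \code{F = 2PR/(P+R)} (0 when both are 0).
#'
#' @param goldDocs,predDocs lists of [StandoffDocument-class] with aligned
#'   ids.
#' @param categories optional named character vector mapping event types to
#'   category names (e.g. [loadCategoryMap()]); unmapped types score under
#'   their own name.
#' @param mode matching mode: \code{"strict"} or \code{"partial"}.
#' @return a [ScoreReport-class].
#' @export
scoreCorpus <- function(goldDocs, predDocs, categories = NULL,
                        mode = c("strict", "partial")) {
  mode <- match.arg(mode)
  gid <- vapply(goldDocs, docId, character(1))
  pid <- vapply(predDocs, docId, character(1))
  if (!setequal(gid, pid) || length(gid) != length(pid))
    stopf("gold and predicted document sets do not align")
  predDocs <- predDocs[match(gid, pid)]
  categories <- categories %||% character()
  total <- list()
  for (d in seq_along(goldDocs)) {
    cnt <- docCounts(goldDocs[[d]], predDocs[[d]], categories, mode)
    for (cat in names(cnt))
      total[[cat]] <- (total[[cat]] %||% c(gold = 0L, matchedGold = 0L,
                                           pred = 0L, matchedPred = 0L)) +
        cnt[[cat]]
  }
  cats <- sort(names(total), method = "radix")
  cats <- c(setdiff(cats, "MOD"), intersect("MOD", cats))
  rows <- lapply(cats, function(cat) {
    v <- total[[cat]]
    m <- prf(v[["gold"]], v[["matchedGold"]], v[["pred"]], v[["matchedPred"]])
    data.frame(category = cat, gold = v[["gold"]],
               matchedGold = v[["matchedGold"]], pred = v[["pred"]],
               matchedPred = v[["matchedPred"]], recall = m[["recall"]],
               precision = m[["precision"]], fscore = m[["fscore"]],
               stringsAsFactors = FALSE)
  })
  tot <- Reduce(`+`, total) %||% c(gold = 0L, matchedGold = 0L, pred = 0L,
                                   matchedPred = 0L)
  m <- prf(tot[["gold"]], tot[["matchedGold"]], tot[["pred"]],
           tot[["matchedPred"]])
  rows[[length(rows) + 1L]] <-
    data.frame(category = "TOTAL", gold = tot[["gold"]],
               matchedGold = tot[["matchedGold"]], pred = tot[["pred"]],
               matchedPred = tot[["matchedPred"]], recall = m[["recall"]],
               precision = m[["precision"]], fscore = m[["fscore"]],
               stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  methods::new("ScoreReport", table = tab, categories = categories,
               mode = mode)
}

## Summed-count F over a subset assignment (internal to the randomisation
## test): counts is a d x 4 matrix per system.
fFromCounts <- function(counts) {
  s <- colSums(counts)
  prf(s[1], s[2], s[3], s[4])[["fscore"]]
}

#' Approximate randomisation test between two systems
#'
#' Stratified shuffling at the document level: in each iteration every
#' document's two system outputs are swapped with probability 1/2 and the
#' absolute F-score difference is recomputed; the p-value is
#' \code{(#iterations with |diff| >= observed + 1) / (iterations + 1)}.
#'
#' @param goldDocs gold documents.
#' @param predA,predB the two systems' predicted documents (ids aligned
#'   with gold).
#' @param iterations number of shuffles (>= 1).
#' @param seed RNG seed; the test is deterministic given it.
#' @param mode matching mode passed to the scorer.
#' @param categories optional category map (F is computed on the TOTAL
#'   row).
#' @return list with elements \code{p}, \code{observed} (F difference
#'   A - B), \code{fA}, \code{fB}.
#' @export
approximateRandomization <- function(goldDocs, predA, predB,
                                     iterations = 1000L, seed = 1L,
                                     mode = c("strict", "partial"),
                                     categories = NULL) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 1L)
  categories <- categories %||% character()
  d <- length(goldDocs)
  perDoc <- function(preds) {
    t(vapply(seq_len(d), function(i) {
      cnt <- docCounts(goldDocs[[i]], preds[[i]], categories, mode)
      Reduce(`+`, cnt) %||% c(gold = 0L, matchedGold = 0L, pred = 0L,
                              matchedPred = 0L)
    }, numeric(4)))
  }
  gid <- vapply(goldDocs, docId, character(1))
  predA <- predA[match(gid, vapply(predA, docId, character(1)))]
  predB <- predB[match(gid, vapply(predB, docId, character(1)))]
  cA <- perDoc(predA)
  cB <- perDoc(predB)
  fA <- fFromCounts(cA); fB <- fFromCounts(cB)
  obs <- abs(fA - fB)
  hits <- withLocalSeed(seed, {
    n <- 0L
    for (it in seq_len(iterations)) {
      swap <- runif(d) < 0.5
      a <- cA; b <- cB
      a[swap, ] <- cB[swap, , drop = FALSE]
      b[swap, ] <- cA[swap, , drop = FALSE]
      if (abs(fFromCounts(a) - fFromCounts(b)) >= obs - 1e-12) n <- n + 1L
    }
    n
  })
  list(p = (hits + 1) / (iterations + 1), observed = fA - fB, fA = fA, fB = fB)
}
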