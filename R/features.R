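## Feature extraction: lexical and dependency-path evidence turned into
## hashed, group-normalised sparse vectors.
##
## Feature groups: char_ngram, word_ngram, path, context_word, context_path,
## stack_score (reserved hook for stacked-model scores). Each candidate's
## features are hashed into 2^hashBits dimensions (MurmurHash2 over
## "group\x1fkey"), each group's sub-vector is scaled to unit Euclidean
## length, and the concatenated vector is scaled to unit length again.

#' Replace gold entity mentions by their type names
#'
#' Returns a copy of the document's token table in which every token run
#' covered by a gold entity is collapsed into a single placeholder token
#' whose surface/base/stem are the entity's type, so classifiers cannot
#' memorise specific entity names. When two gold entities overlap, the
#' longer span masks (ties: the earlier one).
#'
#' @param doc a [StandoffDocument-class].
#' @param goldTypes character vector of the entity types to mask; defaults
#'   to every textbound type never used as an event trigger in `doc`.
#' @return a token data.frame (same layout, possibly fewer rows); masked
#'   rows keep the span of the full entity.
#' @export
maskEntities <- function(doc, goldTypes = NULL) {
  tk <- doc@tokens
  tb <- doc@textbounds
  if (is.null(goldTypes)) {
    trig <- vapply(doc@events, function(e) e$trigger, character(1))
    goldTypes <- setdiff(unique(tb$type), unique(tb$type[tb$id %in% trig]))
  }
  ents <- tb[tb$type %in% goldTypes, , drop = FALSE]
  if (nrow(ents) == 0L || nrow(tk) == 0L) return(tk)
  ents <- ents[cOrder(-(ents$end - ents$start), ents$start), , drop = FALSE]
  owner <- rep(NA_integer_, nrow(tk))
  for (i in seq_len(nrow(ents))) {
    cover <- which(tk$start < ents$end[i] & tk$end > ents$start[i])
    cover <- cover[is.na(owner[cover])]
    owner[cover] <- i
  }
  keep <- list()
  i <- 1L
  while (i <= nrow(tk)) {
    if (is.na(owner[i])) {
      keep[[length(keep) + 1L]] <- tk[i, ]
      i <- i + 1L
    } else {
      o <- owner[i]
      run <- i
      while (run < nrow(tk) && !is.na(owner[run + 1L]) && owner[run + 1L] == o)
        run <- run + 1L
      row <- tk[i, ]
      row$surface <- row$base <- row$stem <- ents$type[o]
      row$start <- min(tk$start[i:run]); row$end <- max(tk$end[i:run])
      keep[[length(keep) + 1L]] <- row
      i <- run + 1L
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Character n-gram features
#'
#' @param s a character string.
#' @param nMin,nMax inclusive n-gram order range (1 <= nMin <= nMax).
#' @return a feature data.frame (\code{group}, \code{key}, \code{value});
#'   repeated n-grams accumulate their counts in \code{value}.
#' @export
charNgrams <- function(s, nMin = 2L, nMax = 4L) {
  stopifnot(nMin >= 1L, nMin <= nMax)
  keys <- character()
  len <- nchar(s)
  for (n in nMin:nMax) {
    if (len < n) next
    keys <- c(keys, substring(s, seq_len(len - n + 1L), seq_len(len - n + 1L) + n - 1L))
  }
  countFeatures("char_ngram", keys)
}

#' Word n-gram features over a token sequence
#'
#' N-grams are taken over the given word forms (conventionally stems of
#' entity-masked tokens).
#'
#' @param words character vector of word forms, in order.
#' @param nMin,nMax inclusive n-gram order range.
#' @param group feature group to emit under (default \code{word_ngram}).
#' @param tag optional prefix folded into every key (used to tag context
#'   bundles by an outside anchor's type).
#' @return a feature data.frame.
#' @export
wordNgrams <- function(words, nMin = 1L, nMax = 3L, group = "word_ngram",
                       tag = NULL) {
  stopifnot(nMin >= 1L, nMin <= nMax)
  keys <- character()
  len <- length(words)
  for (n in nMin:nMax) {
    if (len < n) next
    for (i in seq_len(len - n + 1L))
      keys <- c(keys, paste(words[i:(i + n - 1L)], collapse = " "))
  }
  if (!is.null(tag) && length(keys)) keys <- paste0(tag, "|", keys)
  countFeatures(group, keys)
}

countFeatures <- function(group, keys) {
  if (length(keys) == 0L) return(featureFrame(character(), character()))
  tab <- table(keys)
  featureFrame(group, names(tab), as.numeric(tab))
}

## Lexicographically-smallest shortest undirected path between two tokens
## in the sentence dependency graph, as a sequence of token indices.
## Breadth-first search with parent relaxation: among equal-length paths the
## one with the smallest token-index sequence wins.
shortestTokenPath <- function(tokens, a, b) {
  if (a == b) return(integer())
  sent <- tokens$sentence[a]
  if (tokens$sentence[b] != sent) return(NULL)
  idx <- which(tokens$sentence == sent)
  adj <- lapply(idx, function(i) integer())
  names(adj) <- as.character(idx)
  for (i in idx) {
    h <- tokens$head[i]
    if (h > 0L) {
      adj[[as.character(i)]] <- c(adj[[as.character(i)]], h)
      adj[[as.character(h)]] <- c(adj[[as.character(h)]], i)
    }
  }
  dist <- setNames(rep(NA_integer_, length(idx)), as.character(idx))
  best <- setNames(vector("list", length(idx)), as.character(idx))
  dist[[as.character(a)]] <- 0L
  best[[as.character(a)]] <- a
  frontier <- a
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in sort(adj[[as.character(v)]])) {
        cand <- c(best[[as.character(v)]], w)
        dw <- dist[[as.character(w)]]
        if (is.na(dw)) {
          dist[[as.character(w)]] <- dist[[as.character(v)]] + 1L
          best[[as.character(w)]] <- cand
          nxt <- c(nxt, w)
        } else if (dw == dist[[as.character(v)]] + 1L) {
          cur <- best[[as.character(w)]]
          if (paste(sprintf("%06d", cand), collapse = ",") <
              paste(sprintf("%06d", cur), collapse = ","))
            best[[as.character(w)]] <- cand
        }
      }
    }
    frontier <- sort(unique(nxt))
  }
  if (is.na(dist[[as.character(b)]])) return(NULL)
  best[[as.character(b)]]
}

#' Shortest dependency-path features between two tokens
#'
#' Encodes the label and lemma sequence along the unique shortest
#' undirected path between two tokens of the same sentence (ties broken by
#' the lexicographically smallest token-index sequence). Identical tokens
#' yield no features; tokens in different sentences signal the
#' cross-sentence condition by returning \code{NULL}, and callers emit a
#' distance-bucket fallback instead.
#'
#' @param doc a [StandoffDocument-class] (or any object with a token table).
#' @param a,b 1-based token indices.
#' @param tokens optional token table overriding \code{tokens(doc)} (used
#'   with entity-masked tokens).
#' @return a feature data.frame, empty for \code{a == b}, or \code{NULL}
#'   when the tokens are in different sentences or disconnected.
#' @export
shortestPathFeatures <- function(doc, a, b, tokens = NULL) {
  tk <- tokens %||% doc@tokens
  if (a == b) return(featureFrame(character(), character()))
  path <- shortestTokenPath(tk, a, b)
  if (is.null(path)) return(NULL)
  lem <- tk$base[path]
  rel <- character(length(path) - 1L)
  for (i in seq_len(length(path) - 1L)) {
    u <- path[i]; v <- path[i + 1L]
    rel[i] <- if (tk$head[v] == u) paste0(">", tk$deprel[v])
              else paste0("<", tk$deprel[u])
  }
  keys <- c(paste0("len:", length(path) - 1L),
            paste0("dir:", if (a < b) "fwd" else "bwd"),
            paste0("rels:", paste(rel, collapse = ",")),
            paste0("lems:", paste(lem, collapse = ",")),
            paste0("mix:", paste(lem[-length(lem)], rel, collapse = " ")))
  featureFrame("path", keys)
}

distanceBucket <- function(d) {
  cut(abs(d), breaks = c(-1, 0, 2, 5, 10, 20, Inf),
      labels = c("0", "1-2", "3-5", "6-10", "11-20", ">20"))
}

#' Context features from triggers/entities outside a candidate
#'
#' For every annotation anchor in the document that is not part of the
#' candidate, emits a word-n-gram and path bundle tagged with the
#' outsider's (generalised) type. Outsiders in other sentences degrade to a
#' distance-bucket feature.
#'
#' @param doc a [StandoffDocument-class].
#' @param inside integer token indices of the candidate's participants.
#' @param anchors data.frame with columns \code{token} (index) and
#'   \code{type} (generalised type) for candidate outside anchors.
#' @param tokens optional masked token table.
#' @return a feature data.frame.
#' @export
contextFeatures <- function(doc, inside, anchors, tokens = NULL) {
  tk <- tokens %||% doc@tokens
  out <- list()
  if (nrow(anchors) == 0L || length(inside) == 0L)
    return(featureFrame(character(), character()))
  ref <- inside[1]
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$token[i]
    if (a %in% inside) next
    tag <- anchors$type[i]
    if (tk$sentence[a] == tk$sentence[ref]) {
      lo <- min(a, ref); hi <- max(a, ref)
      out[[length(out) + 1L]] <-
        wordNgrams(tk$stem[lo:hi], 1L, 2L, group = "context_word", tag = tag)
      pf <- shortestPathFeatures(doc, ref, a, tokens = tk)
      if (!is.null(pf) && nrow(pf)) {
        pf$group <- "context_path"
        pf$key <- paste0(tag, "|", pf$key)
        out[[length(out) + 1L]] <- pf
      }
    } else {
      out[[length(out) + 1L]] <-
        featureFrame("context_word",
                     paste0(tag, "|xsent:", distanceBucket(a - ref)))
    }
  }
  do.call(bindFeatures, out)
}

#' Hash features and normalise per group, then overall
#'
#' Indexes each feature at \code{murmur2(group + key) mod 2^hashBits}
#' (collisions sum), scales every feature group's sub-vector to unit
#' Euclidean length, and finally scales the whole concatenated vector to
#' unit length. The result is deterministic across runs and platforms.
#'
#' @param feats a feature data.frame (\code{group}, \code{key},
#'   \code{value}).
#' @param hashBits feature-space exponent (indices lie in
#'   \code{[0, 2^hashBits)}).
#' @return a [Matrix::sparseVector-class] of length \code{2^hashBits}.
#' @export
hashAndNormalize <- function(feats, hashBits = 20L) {
  stopifnot(hashBits >= 1L)
  trip <- hashTriplets(feats, hashBits)
  Matrix::sparseVector(x = trip$x, i = trip$i, length = 2L^hashBits)
}

## Shared worker: returns 1-based indices and normalised values.
hashTriplets <- function(feats, hashBits) {
  if (is.null(feats) || nrow(feats) == 0L)
    return(list(i = integer(), x = numeric()))
  idx <- .murmur32(paste0(feats$group, "\x1f", feats$key), as.integer(hashBits)) + 1L
  val <- feats$value
  grp <- feats$group
  ## collisions within a group sum first
  aggKey <- paste0(grp, "\x1f", idx)
  sums <- rowsum(val, aggKey)
  parts <- strsplit(rownames(sums), "\x1f", fixed = TRUE)
  grp2 <- vapply(parts, `[[`, character(1), 1L)
  idx2 <- as.integer(vapply(parts, `[[`, character(1), 2L))
  x <- as.numeric(sums[, 1])
  ## per-group unit length
  gnorm <- sqrt(rowsum(x^2, grp2))
  x <- x / gnorm[match(grp2, rownames(gnorm)), 1]
  ## cross-group collisions sum after group scaling
  sums <- rowsum(x, idx2)
  i <- as.integer(rownames(sums))
  x <- as.numeric(sums[, 1])
  tot <- sqrt(sum(x^2))
  if (tot > 0) x <- x / tot
  ord <- order(i)
  list(i = i[ord], x = x[ord])
}

#' Build a sparse instance matrix from a list of feature frames
#'
#' Applies [hashAndNormalize()] row-wise and assembles a
#' \code{Matrix::dgCMatrix} with one row per candidate.
#'
#' @param featList list of feature data.frames.
#' @param hashBits feature-space exponent.
#' @return a sparse matrix, \code{length(featList)} x \code{2^hashBits}.
#' @export
featureMatrix <- function(featList, hashBits = 20L) {
  n <- length(featList)
  trips <- lapply(featList, hashTriplets, hashBits = hashBits)
  ii <- unlist(lapply(seq_len(n), function(r) rep.int(r, length(trips[[r]]$i))))
  jj <- unlist(lapply(trips, `[[`, "i"))
  xx <- unlist(lapply(trips, `[[`, "x"))
  Matrix::sparseMatrix(i = ii %||% integer(), j = jj %||% integer(),
                       x = xx %||% numeric(),
                       dims = c(n, 2L^hashBits))
}
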