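## BioNLP shared-task standoff I/O.
##
## Line grammar handled here (tab-separated, UTF-8):
##   T<N> <TAB> Type start end <TAB> text          text-bound (entity/trigger)
##   E<N> <TAB> Type:Ttrig Role:Target ...         event
##   M<N> <TAB> Negation|Speculation E<N>          hedge modification
##   *    <TAB> Equiv T1 T2 ...                    equivalence set
## Offsets are 0-based, half-open. Discontinuous spans ("start end;start end")
## are rejected: the matcher and head-word rules are defined on contiguous
## spans only.

asLines <- function(x) {
  if (is.null(x)) return(character())
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE, encoding = "UTF-8"))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

asText <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(paste(readLines(x, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n"))
  paste(x, collapse = "\n")
}

#' Read a standoff-annotated document
#'
#' Parses a document's text together with its gold (.a1) and, optionally,
#' event (.a2) annotation files into a [StandoffDocument-class]. Annotation
#' references may be forward; they are resolved after all lines are read.
#' M-lines are folded into the referenced event's \code{mods}; Equiv
#' (\code{*}) lines are kept as equivalence sets.
#'
#' @param txt document text: a file path or the literal text.
#' @param a1 gold annotation lines: a file path, a character vector of
#'   lines, or \code{NULL}.
#' @param a2 event annotation lines, same conventions as \code{a1}.
#' @param parse optional pre-tokenised input in the parse interchange format
#'   (see [readParseInterchange()]): a path or character lines. When absent,
#'   \code{tokenizer} supplies tokens and a trivial parse.
#' @param id document identifier.
#' @param tokenizer function(text) -> token data.frame used when
#'   \code{parse} is missing; defaults to [simpleTokenize()].
#' @return a validated [StandoffDocument-class].
#' @examples
#' doc <- readDocument("Overexpression of TGF-beta",
#'   a1 = "T1\tGene_or_gene_product 18 26\tTGF-beta")
#' textbounds(doc)
#' @export
readDocument <- function(txt, a1 = NULL, a2 = NULL, parse = NULL,
                         id = "doc", tokenizer = simpleTokenize) {
  text <- asText(txt)
  ann <- parseStandoffLines(c(asLines(a1), asLines(a2)))
  toks <- if (!is.null(parse)) readParseInterchange(parse, text)
          else tokenizer(text)
  doc <- methods::new("StandoffDocument", id = id, text = text,
                      tokens = toks, textbounds = ann$textbounds,
                      events = ann$events, equivalences = ann$equivalences)
  doc
}

parseStandoffLines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  tb <- emptyTextbounds()
  evs <- list()
  equivs <- list()
  mods <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    lineId <- fields[[1]]
    if (startsWith(lineId, "T")) {
      if (length(fields) < 2L)
        stopf("parse error at annotation line %d: T-line needs >= 2 fields", i)
      head <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
      if (grepl(";", fields[[2]], fixed = TRUE))
        stopf("parse error at annotation line %d: discontinuous spans are not supported", i)
      if (length(head) != 3L)
        stopf("parse error at annotation line %d: expected 'Type start end'", i)
      start <- suppressWarnings(as.integer(head[[2]]))
      end <- suppressWarnings(as.integer(head[[3]]))
      if (is.na(start) || is.na(end))
        stopf("parse error at annotation line %d: non-integer offsets", i)
      tb <- rbind(tb, data.frame(id = lineId, type = head[[1]],
                                 start = start, end = end,
                                 text = if (length(fields) >= 3L) fields[[3]] else "",
                                 stringsAsFactors = FALSE))
    } else if (startsWith(lineId, "E")) {
      if (length(fields) < 2L)
        stopf("parse error at annotation line %d: E-line needs 2 fields", i)
      parts <- strsplit(trimws(fields[[2]]), " +")[[1]]
      tp <- strsplit(parts[[1]], ":", fixed = TRUE)[[1]]
      if (length(tp) != 2L)
        stopf("parse error at annotation line %d: expected 'Type:Trigger'", i)
      args <- data.frame(role = character(), target = character(),
                         stringsAsFactors = FALSE)
      for (p in parts[-1]) {
        rp <- strsplit(p, ":", fixed = TRUE)[[1]]
        if (length(rp) != 2L || !nzchar(rp[[1]]))
          stopf("parse error at annotation line %d: bad argument '%s'", i, p)
        args <- rbind(args, data.frame(role = rp[[1]], target = rp[[2]],
                                       stringsAsFactors = FALSE))
      }
      evs[[lineId]] <- list(id = lineId, type = tp[[1]], trigger = tp[[2]],
                            args = args, mods = character())
    } else if (startsWith(lineId, "M")) {
      head <- strsplit(trimws(fields[[2]]), " +")[[1]]
      if (length(head) != 2L)
        stopf("parse error at annotation line %d: expected 'ModType Event'", i)
      mods[[length(mods) + 1L]] <- head
    } else if (lineId == "*") {
      head <- strsplit(trimws(fields[[2]]), " +")[[1]]
      if (length(head) < 3L || head[[1]] != "Equiv")
        stopf("parse error at annotation line %d: expected 'Equiv T.. T..'", i)
      equivs[[length(equivs) + 1L]] <- head[-1]
    } else {
      stopf("parse error at annotation line %d: unknown line type '%s'",
            i, lineId)
    }
  }
  if (anyDuplicated(tb$id) || anyDuplicated(names(evs)))
    stopf("integrity error: duplicate annotation identifiers")
  for (m in mods) {
    ev <- evs[[m[[2]]]]
    if (is.null(ev))
      stopf("integrity error: modification references unknown event %s", m[[2]])
    ev$mods <- union(ev$mods, m[[1]])
    evs[[m[[2]]]] <- ev
  }
  list(textbounds = tb, events = unname(evs), equivalences = equivs)
}

#' Validate a StandoffDocument
#'
#' Checks every structural invariant of the document data model and returns
#' the violations as a character vector (empty when the document is valid);
#' nothing is raised. Each message names the offending annotation.
#'
#' @param doc a [StandoffDocument-class] (possibly constructed by hand).
#' @return character vector of violation descriptions.
#' @export
validateDocument <- function(doc) validateDocumentImpl(doc)

validateDocumentImpl <- function(doc) {
  msgs <- character()
  n <- nchar(doc@text)
  tk <- doc@tokens
  if (nrow(tk)) {
    if (is.unsorted(tk$start) ||
        any(tk$start[-1] < tk$end[-nrow(tk)]))
      msgs <- c(msgs, "tokens must be sorted and non-overlapping")
    bad <- which(substr(rep(doc@text, nrow(tk)), tk$start + 1L, tk$end) != tk$surface)
    if (length(bad))
      msgs <- c(msgs, paste0("token ", bad[1], " surface does not match the text slice"))
    sent <- tk$sentence
    hd <- tk$head
    bad <- which(hd != 0L & (hd < 1L | hd > nrow(tk) | sent[pmax(pmin(hd, nrow(tk)), 1L)] != sent))
    if (length(bad))
      msgs <- c(msgs, paste0("token ", bad[1], ": dependency head outside its sentence"))
  }
  tb <- doc@textbounds
  if (nrow(tb)) {
    if (anyDuplicated(tb$id))
      msgs <- c(msgs, "duplicate textbound identifiers")
    for (i in seq_len(nrow(tb))) {
      if (!(tb$start[i] >= 0L && tb$start[i] < tb$end[i] && tb$end[i] <= n)) {
        msgs <- c(msgs, paste0(tb$id[i], ": span outside the document text"))
      } else if (nzchar(tb$text[i]) &&
                 substr(doc@text, tb$start[i] + 1L, tb$end[i]) != tb$text[i]) {
        msgs <- c(msgs, paste0(tb$id[i], ": text does not match the document slice"))
      }
      if (!nzchar(tb$type[i]))
        msgs <- c(msgs, paste0(tb$id[i], ": empty type"))
    }
  }
  evIds <- vapply(doc@events, function(e) e$id, character(1))
  if (anyDuplicated(evIds)) msgs <- c(msgs, "duplicate event identifiers")
  known <- c(tb$id, evIds)
  for (e in doc@events) {
    if (!(e$trigger %in% tb$id))
      msgs <- c(msgs, paste0(e$id, ": unresolvable trigger ", e$trigger))
    if (nrow(e$args)) {
      if (any(!nzchar(e$args$role)))
        msgs <- c(msgs, paste0(e$id, ": empty role name"))
      bad <- setdiff(e$args$target, known)
      if (length(bad))
        msgs <- c(msgs, paste0(e$id, ": unresolvable argument target ",
                               paste(bad, collapse = ", ")))
    }
    extra <- setdiff(e$mods, c("Negation", "Speculation"))
    if (length(extra))
      msgs <- c(msgs, paste0(e$id, ": unknown modification ",
                             paste(extra, collapse = ", ")))
  }
  cyc <- findEventCycle(doc@events)
  if (!is.null(cyc))
    msgs <- c(msgs, paste0(cyc, ": argument reference cycle"))
  for (eq in doc@equivalences) {
    bad <- setdiff(eq, tb$id)
    if (length(bad))
      msgs <- c(msgs, paste0("equivalence set references unknown textbound ",
                             paste(bad, collapse = ", ")))
  }
  msgs
}

## Returns the id of an event on a cycle of event-valued argument
## references, or NULL.
findEventCycle <- function(events) {
  ids <- vapply(events, function(e) e$id, character(1))
  adj <- lapply(events, function(e)
    intersect(e$args$target, ids))
  names(adj) <- ids
  state <- setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  hit <- NULL
  visit <- function(v) {
    if (!is.null(hit)) return()
    if (state[[v]] == 1L) { hit <<- v; return() }
    if (state[[v]] == 2L) return()
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in ids) visit(v)
  hit
}

#' Serialise a document back to standoff annotation files
#'
#' Re-emits a document's annotations as .a1 and .a2 bodies. Identifiers are
#' renumbered deterministically in document order (text-bounds by span, then
#' events bottom-up by trigger position), so repeated serialisation of the
#' same document is byte-identical, and \code{readDocument} on the output
#' reproduces the document up to identifier renumbering.
#'
#' @param doc a [StandoffDocument-class].
#' @param config optional [TaskConfig-class]; its GOLD types go to the .a1
#'   body and its PREDICTION types to .a2. Without a config, types never
#'   used as an event trigger go to .a1.
#' @return list with character elements \code{a1} and \code{a2} (newline
#'   separated bodies, possibly empty strings).
#' @export
writeAnnotations <- function(doc, config = NULL) {
  tb <- doc@textbounds
  if (is.null(config)) {
    trigTypes <- unique(tb$type[tb$id %in%
      vapply(doc@events, function(e) e$trigger, character(1))])
    a1Types <- setdiff(unique(tb$type), trigTypes)
    a2Types <- setdiff(unique(tb$type), a1Types)
  } else {
    a1Types <- config@goldTypes
    a2Types <- setdiff(config@predictionTypes, a1Types)
  }
  referenced <- unique(c(vapply(doc@events, function(e) e$trigger, character(1)),
                         unlist(lapply(doc@events, function(e) e$args$target))))
  dropped <- tb$id[!(tb$type %in% c(a1Types, a2Types))]
  lost <- intersect(referenced, dropped)
  if (length(lost))
    stopf("integrity error: event references textbound(s) excluded from both files: %s",
          paste(lost, collapse = ", "))

  ord <- cOrder(tb$start, tb$end, tb$type)
  tb <- tb[ord, , drop = FALSE]
  newT <- setNames(paste0("T", seq_len(nrow(tb))), tb$id)

  ## events bottom-up: dependency depth, then trigger span order
  evs <- doc@events
  evIds <- vapply(evs, function(e) e$id, character(1))
  depth <- setNames(rep(NA_integer_, length(evs)), evIds)
  depthOf <- function(id) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    e <- evs[[match(id, evIds)]]
    sub <- intersect(e$args$target, evIds)
    d <- if (length(sub) == 0L) 0L else 1L + max(vapply(sub, depthOf, integer(1)))
    depth[[id]] <<- d
    d
  }
  if (length(evs)) for (id in evIds) depthOf(id)
  trigStart <- vapply(evs, function(e) tb$start[match(e$trigger, tb$id)],
                      integer(1))
  ## id-free canonical key so ordering is stable across renumbering
  contentKey <- function(id) {
    j <- match(id, tb$id)
    if (!is.na(j)) return(paste0("T@", tb$start[j], "-", tb$end[j], "/", tb$type[j]))
    e <- evs[[match(id, evIds)]]
    paste0(e$type, "(", contentKey(e$trigger),
           paste(vapply(seq_len(nrow(e$args)), function(k)
             paste0(",", e$args$role[k], "=", contentKey(e$args$target[k])),
             character(1)), collapse = ""), ")")
  }
  sortKey <- vapply(evIds, contentKey, character(1))
  ord <- cOrder(as.integer(depth[evIds]), trigStart, sortKey)
  evs <- evs[ord]
  newE <- setNames(paste0("E", seq_along(evs)),
                   vapply(evs, function(e) e$id, character(1)))
  remap <- c(newT, newE)

  a1 <- character(); a2 <- character()
  for (i in seq_len(nrow(tb))) {
    line <- paste0(remap[[tb$id[i]]], "\t", tb$type[i], " ", tb$start[i], " ",
                   tb$end[i], "\t",
                   substr(doc@text, tb$start[i] + 1L, tb$end[i]))
    if (tb$type[i] %in% a1Types) a1 <- c(a1, line)
    else if (tb$type[i] %in% a2Types) a2 <- c(a2, line)
  }
  mline <- 0L
  for (e in evs) {
    argStr <- if (nrow(e$args))
      paste(" ", paste0(e$args$role, ":", remap[e$args$target], collapse = " "),
            sep = "")
    else ""
    a2 <- c(a2, paste0(remap[[e$id]], "\t", e$type, ":", remap[[e$trigger]],
                       argStr))
  }
  for (e in evs) {
    for (m in sort(e$mods, method = "radix")) {
      mline <- mline + 1L
      a2 <- c(a2, paste0("M", mline, "\t", m, " ", remap[[e$id]]))
    }
  }
  for (eq in doc@equivalences) {
    a2 <- c(a2, paste0("*\tEquiv ", paste(remap[eq], collapse = " ")))
  }
  list(a1 = if (length(a1)) paste0(paste(a1, collapse = "\n"), "\n") else "",
       a2 = if (length(a2)) paste0(paste(a2, collapse = "\n"), "\n") else "")
}

#' Write a document's files to a directory
#'
#' Emits \code{<id>.txt}, \code{<id>.a1}, \code{<id>.a2} and (when tokens
#' are present) \code{<id>.parse} in the parse interchange format.
#'
#' @param doc a [StandoffDocument-class].
#' @param dir output directory (created if needed).
#' @param config optional [TaskConfig-class] passed to
#'   [writeAnnotations()].
#' @return invisibly, the paths written.
#' @export
writeDocumentFiles <- function(doc, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- writeAnnotations(doc, config)
  paths <- c(txt = file.path(dir, paste0(doc@id, ".txt")),
             a1 = file.path(dir, paste0(doc@id, ".a1")),
             a2 = file.path(dir, paste0(doc@id, ".a2")))
  writeText(doc@text, paths[["txt"]])
  writeText(ann$a1, paths[["a1"]])
  writeText(ann$a2, paths[["a2"]])
  if (nrow(doc@tokens)) {
    paths <- c(paths, parse = file.path(dir, paste0(doc@id, ".parse")))
    writeText(writeParseInterchange(doc@tokens), paths[["parse"]])
  }
  invisible(paths)
}

#' Read a directory of standoff documents
#'
#' Loads every \code{*.txt} file with its sibling \code{.a1}/\code{.a2}/
#' \code{.parse} files when present.
#'
#' @param dir directory containing aligned standoff files.
#' @inheritParams readDocument
#' @return list of [StandoffDocument-class], named by document id.
#' @export
readCorpusDir <- function(dir, tokenizer = simpleTokenize) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE),
               method = "radix")
  if (length(txts) == 0L) stopf("no .txt files found in %s", dir)
  docs <- lapply(txts, function(p) {
    stem <- sub("\\.txt$", "", p)
    sib <- function(ext) if (file.exists(paste0(stem, ext))) paste0(stem, ext) else NULL
    readDocument(p, a1 = sib(".a1"), a2 = sib(".a2"), parse = sib(".parse"),
                 id = basename(stem), tokenizer = tokenizer)
  })
  names(docs) <- vapply(docs, docId, character(1))
  docs
}
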