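## Parse interchange format: the pluggable bridge between any external
## tokeniser/dependency parser and the pipeline. One record per token,
## tab-separated:
##   index  surface  start  end  lemma  head  deprel
## with `index` and `head` 0-based within the sentence (-1 marks the root)
## and `start`/`end` 0-based half-open character offsets into the document
## text. Sentences are separated by blank lines.

#' Read pre-tokenised, pre-parsed input
#'
#' @param x a file path or character lines in the interchange format.
#' @param text optional document text; when given, each token's surface is
#'   checked against the text slice at its offsets.
#' @return a token data.frame in [StandoffDocument-class] layout.
#' @export
readParseInterchange <- function(x, text = NULL) {
  lines <- asLines(x)
  toks <- emptyTokens()
  sentence <- 1L
  offset <- 0L           # global index of the last token before this sentence
  rows <- list()
  sentRows <- list()
  flush <- function() {
    if (length(sentRows) == 0L) return()
    for (r in sentRows) {
      r$head <- if (r$head < 0L) 0L else r$head + 1L + offset
      r$sentence <- sentence
      rows[[length(rows) + 1L]] <<- r
    }
    offset <<- offset + length(sentRows)
    sentence <<- sentence + 1L
    sentRows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 7L)
      stopf("parse error at interchange line %d: expected 7 fields", i)
    sentRows[[length(sentRows) + 1L]] <-
      list(surface = f[[2]], start = as.integer(f[[3]]), end = as.integer(f[[4]]),
           base = f[[5]], stem = stemWord(f[[2]]), head = as.integer(f[[6]]),
           deprel = f[[7]])
  }
  flush()
  if (length(rows) == 0L) return(toks)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(surface = r$surface, start = r$start, end = r$end,
               base = r$base, stem = r$stem, sentence = r$sentence,
               head = r$head, deprel = r$deprel, stringsAsFactors = FALSE)))
  if (!is.null(text)) {
    got <- substr(rep(text, nrow(out)), out$start + 1L, out$end)
    bad <- which(got != out$surface)
    if (length(bad))
      stopf("integrity error: token %d surface %s does not match text slice %s",
            bad[1], sQuote(out$surface[bad[1]]), sQuote(got[bad[1]]))
  }
  out
}

#' Serialise a token table to the parse interchange format
#'
#' @param tokens a token data.frame in [StandoffDocument-class] layout.
#' @return a single character string (trailing newline included).
#' @export
writeParseInterchange <- function(tokens) {
  if (nrow(tokens) == 0L) return("")
  out <- character()
  offset <- 0L
  for (s in unique(tokens$sentence)) {
    rows <- tokens[tokens$sentence == s, , drop = FALSE]
    idx <- seq_len(nrow(rows)) - 1L
    head0 <- ifelse(rows$head == 0L, -1L, rows$head - 1L - offset)
    out <- c(out, paste(idx, rows$surface, rows$start, rows$end, rows$base,
                        head0, rows$deprel, sep = "\t"), "")
    offset <- offset + nrow(rows)
  }
  paste0(paste(out, collapse = "\n"))
}

#' Fallback tokenizer with a trivial left-branching parse
#'
#' Splits text on whitespace and punctuation, closes a sentence at
#' \code{.}, \code{!} or \code{?}, and attaches each token to the token on
#' its left (the first token of a sentence is the root). It exists so the
#' pipeline can run without an external parser; supply real parses through
#' the interchange format for linguistic fidelity.
#'
#' @param text document text.
#' @return a token data.frame in [StandoffDocument-class] layout.
#' @export
simpleTokenize <- function(text) {
  if (!nzchar(text)) return(emptyTokens())
  m <- gregexpr("[A-Za-z0-9_'-]+|[^A-Za-z0-9_[:space:]]", text)[[1]]
  if (m[1] == -1L) return(emptyTokens())
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  surf <- substring(text, starts + 1L, starts + lens)
  n <- length(surf)
  sentence <- integer(n); head <- integer(n)
  s <- 1L; root <- TRUE
  for (i in seq_len(n)) {
    sentence[i] <- s
    head[i] <- if (root) 0L else i - 1L
    root <- FALSE
    if (surf[i] %in% c(".", "!", "?")) { s <- s + 1L; root <- TRUE }
  }
  data.frame(surface = surf, start = starts, end = starts + lens,
             base = tolower(surf), stem = stemWord(surf),
             sentence = sentence, head = head,
             deprel = ifelse(head == 0L, "root", "dep"),
             stringsAsFactors = FALSE)
}
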