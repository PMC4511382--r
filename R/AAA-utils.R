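## Small shared helpers. Nothing here is exported.

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so library code never perturbs user
## simulations.
withLocalSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Derive a reproducible child seed from a base seed and a stream label,
## kept below 2^31.
childSeed <- function(seed, stream) {
  h <- .murmur32(paste0("seed:", stream), 30L, as.integer(seed %% 1000003L))
  (as.integer(seed) %% 65011 + 1L) * 32749L + h %% 32749L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## A light rule-based English suffix stripper (lower-cases, then removes a
## small fixed set of inflectional endings). It serves the head-word lookup
## tables, where only a stable surface normalisation is required.
stemWord <- function(x) {
  s <- tolower(x)
  s <- sub("'s$", "", s)
  s <- sub("(sses)$", "ss", s)
  s <- sub("([^aeious])ies$", "\\1y", s)
  long <- nchar(s) > 4
  s[long] <- sub("(ing|edly|ely)$", "", s[long])
  long <- nchar(s) > 3
  s[long] <- sub("([^aeiou])(ed|es)$", "\\1", s[long])
  long <- nchar(s) > 3
  s[long] <- sub("([^su])s$", "\\1", s[long])
  s
}

## Deterministic ordering helper: order by multiple character/numeric keys
## using the C locale so results do not depend on the session collation.
cOrder <- function(...) {
  keys <- list(...)
  keys <- lapply(keys, function(k) if (is.character(k)) {
    factor(k, levels = sort(unique(k), method = "radix"))
  } else k)
  do.call(order, keys)
}

emptyTokens <- function() {
  data.frame(surface = character(), start = integer(), end = integer(),
             base = character(), stem = character(), sentence = integer(),
             head = integer(), deprel = character(),
             stringsAsFactors = FALSE)
}

emptyTextbounds <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), text = character(), stringsAsFactors = FALSE)
}

## Canonical string key for a multiset of (role, argument-type) slots.
slotKey <- function(roles, args) {
  if (length(roles) == 0L) return("")
  parts <- paste0(roles, "-", args)
  paste(sort(parts, method = "radix"), collapse = ":")
}

## Strip a trailing number from a role name (Theme2 -> Theme).
deNumberRole <- function(role) sub("[0-9]+$", "", role)

## Write a string byte-for-byte (writeChar warns on empty strings).
writeText <- function(text, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nzchar(text)) writeBin(charToRaw(enc2utf8(text)), con)
  invisible(path)
}

## Coerce any numeric matrix-like to dgCMatrix.
asSparse <- function(X) {
  if (methods::is(X, "dgCMatrix")) return(X)
  if (!methods::is(X, "Matrix")) X <- Matrix::Matrix(as.matrix(X), sparse = TRUE)
  methods::as(methods::as(methods::as(X, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

featureFrame <- function(group, key, value = 1) {
  if (length(key) == 0L)
    return(data.frame(group = character(), key = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  data.frame(group = rep_len(group, length(key)), key = key,
             value = rep_len(value, length(key)), stringsAsFactors = FALSE)
}

bindFeatures <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0L, list(...))
  if (length(dfs) == 0L) return(featureFrame(character(), character()))
  do.call(rbind, dfs)
}
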