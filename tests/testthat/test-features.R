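test_that("gold entity mentions are masked by their types", {
  doc <- tinyDoc()
  masked <- maskEntities(doc, "Gene_or_gene_product")
  expect_false(any(grepl("TGFB", masked$surface)))
  expect_true("Gene_or_gene_product" %in% masked$surface)
  ## no entities -> identity
  noEnt <- readDocument("plain words here .")
  expect_identical(maskEntities(noEnt, "Anything"), tokens(noEnt))
  ## overlapping entities: the longest span masks
  doc2 <- readDocument("alpha beta gamma",
    a1 = c("T1\tShort 6 10\tbeta", "T2\tLong 0 10\talpha beta"))
  masked2 <- maskEntities(doc2, c("Short", "Long"))
  expect_true("Long" %in% masked2$surface)
  expect_false("Short" %in% masked2$surface)
})

test_that("character n-grams enumerate windows and accumulate counts", {
  f <- charNgrams("abc", 2, 2)
  expect_setequal(f$key, c("ab", "bc"))
  expect_equal(nrow(charNgrams("a", 2, 3)), 0L)
  f2 <- charNgrams("aaa", 2, 2)
  expect_equal(f2$value[f2$key == "aa"], 2)
})

test_that("word n-grams follow the same contract", {
  f <- wordNgrams(c("X", "inhibited", "Y"), 1, 2)
  expect_equal(nrow(f), 5L)  # 3 unigrams + 2 bigrams
  expect_equal(nrow(wordNgrams(character(), 1, 2)), 0L)
  f2 <- wordNgrams(c("a", "b", "a", "b"), 2, 2)
  expect_equal(f2$value[f2$key == "a b"], 2)
})

test_that("shortest dependency paths match a graph-library oracle", {
  doc <- tinyDoc()
  ## chain: one arc between adjacent tokens
  f <- shortestPathFeatures(doc, 1, 2)
  expect_true(any(grepl("len:1", f$key)))
  ## identity
  expect_equal(nrow(shortestPathFeatures(doc, 3, 3)), 0L)

  ## star graph: leaves connect through the hub
  star <- data.frame(surface = c("hub", "a", "b", "c"),
                     start = c(0L, 4L, 6L, 8L), end = c(3L, 5L, 7L, 9L),
                     base = c("hub", "a", "b", "c"),
                     stem = c("hub", "a", "b", "c"),
                     sentence = 1L, head = c(0L, 1L, 1L, 1L),
                     deprel = c("root", "dep", "dep", "dep"))
  sdoc <- methods::new("StandoffDocument", id = "star",
                       text = "hub a b c", tokens = star)
  f2 <- shortestPathFeatures(sdoc, 2, 4, tokens = star)
  expect_true(any(grepl("len:2", f2$key)))

  skip_if_not_installed("igraph")
  ## distances agree with igraph on the generator's parses
  for (d in cachedCorpus("round7", 3, 7)) {
    tk <- tokens(d)
    for (s in unique(tk$sentence)) {
      idx <- which(tk$sentence == s)
      edges <- idx[tk$head[idx] > 0]
      if (length(edges) < 2) next
      g <- igraph::graph_from_edgelist(
        cbind(match(edges, idx), match(tk$head[edges], idx)),
        directed = FALSE)
      a <- idx[1]; b <- idx[length(idx)]
      want <- igraph::distances(g, match(a, idx), match(b, idx))[1, 1]
      got <- shortestPathFeatures(d, a, b)
      lenKey <- got$key[grepl("^len:", got$key)]
      expect_equal(as.integer(sub("len:", "", lenKey)), as.integer(want))
    }
  }
})

test_that("cross-sentence pairs signal the fallback condition", {
  doc <- readDocument("One two . Three four .")
  expect_null(shortestPathFeatures(doc, 1, 5))
})

test_that("context features tag outside anchors and bucket cross-sentence", {
  doc <- tinyDoc()
  anchors <- data.frame(token = 5L, type = "ENTITY")
  f <- contextFeatures(doc, inside = 2L, anchors = anchors)
  expect_true(all(grepl("^ENTITY\\|", f$key)))
  expect_true(any(f$group == "context_path"))
  ## no outside anchors
  f0 <- contextFeatures(doc, inside = 2L,
                        anchors = data.frame(token = integer(),
                                             type = character()))
  expect_equal(nrow(f0), 0L)
  ## anchor in another sentence -> distance bucket only
  doc2 <- readDocument("One two . Three four .")
  f2 <- contextFeatures(doc2, inside = 1L,
                        anchors = data.frame(token = 5L, type = "T"))
  expect_true(all(grepl("xsent", f2$key)))
})

test_that("hashing and two-level normalisation follow the closed forms", {
  one <- data.frame(group = "word_ngram", key = "k", value = 3)
  v <- hashAndNormalize(one, 10)
  expect_equal(sum(v@x^2), 1)
  expect_equal(v@x, 1.0)

  two <- data.frame(group = c("word_ngram", "char_ngram"),
                    key = c("k1", "k2"), value = c(5, 0.2))
  v2 <- hashAndNormalize(two, 10)
  expect_equal(sort(abs(v2@x)), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  v0 <- hashAndNormalize(data.frame(group = character(), key = character(),
                                    value = numeric()), 10)
  expect_equal(length(v0@i), 0L)
})

test_that("hashed vectors are bounded, unit-norm, and order-invariant", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(1:30, 1)
      feats <- data.frame(
        group = sample(c("char_ngram", "word_ngram", "path"), n, TRUE),
        key = replicate(n, paste(sample(letters, 5, TRUE), collapse = "")),
        value = runif(n, 0.1, 3))
      bits <- sample(4:20, 1)
      v <- hashAndNormalize(feats, bits)
      expect_true(all(v@i >= 1 & v@i <= 2^bits))
      expect_equal(sum(v@x^2), 1, tolerance = 1e-9)
      perm <- feats[sample(nrow(feats)), ]
      expect_identical(hashAndNormalize(perm, bits), v)
    }
  })
})

test_that("hashing is reproducible across calls", {
  f <- charNgrams("reproducible", 2, 4)
  expect_identical(hashAndNormalize(f, 20), hashAndNormalize(f, 20))
  m1 <- featureMatrix(list(f, charNgrams("again", 2, 3)), 12)
  m2 <- featureMatrix(list(f, charNgrams("again", 2, 3)), 12)
  expect_identical(m1, m2)
})

test_that("after masking, no feature key carries an entity surface", {
  docs <- cachedCorpus("round7", 4, 7)
  cfg <- deriveConfigFromCorpus(docs)
  for (d in docs) {
    ents <- textbounds(d)$text[textbounds(d)$type %in% cfg@goldTypes]
    if (length(ents) == 0L) next
    st <- EventPipe:::docState(d, cfg)
    cands <- enumerateTriggerCandidates(d, collectInventories(list(d),
                                                              cfg)$headTable,
                                        cfg)
    for (cd in cands) {
      f <- EventPipe:::featTrigger(st, cd$token)
      for (ent in ents)
        expect_false(any(grepl(ent, f$key, fixed = TRUE)))
    }
  }
})
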