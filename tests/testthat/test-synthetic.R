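test_that("generated corpora satisfy every standoff invariant", {
  docs <- cachedCorpus("round7", 6, 7)
  for (d in docs) expect_length(validateDocument(d), 0L)
})

test_that("spec edge cases: zero documents and zero nesting", {
  expect_length(generateCorpus(synthSpec(nDocs = 0, seed = 1)), 0L)
  g <- synthSpec(nDocs = 15, seed = 3)
  g@grammar <- lapply(g@grammar, function(r) { r$nesting <- 0; r })
  docs <- generateCorpus(g)
  for (d in docs) {
    evIds <- vapply(events(d), `[[`, character(1), "id")
    for (e in events(d))
      expect_false(any(e$args$target %in% evIds))
  }
})

test_that("invalid specs are rejected", {
  bad <- synthSpec(nDocs = 2, seed = 1)
  bad@distractorRate <- 1.5
  expect_error(generateCorpus(bad), "probabilities")
  bad2 <- synthSpec(nDocs = 2, seed = 1)
  bad2@grammar[[1]]$slots$filler <- "Unknown_type"
  expect_error(generateCorpus(bad2), "filler")
})

test_that("event-sentence counts sit within 3 sigma of the binomial", {
  spec <- synthSpec(nDocs = 100, sentencesPerDoc = c(5L, 5L),
                    distractorRate = 0.5, fillerRate = 0.3, seed = 23)
  docs <- generateCorpus(spec)
  nSent <- 500
  pEvent <- 1 - 0.5 - 0.3
  ## each event sentence carries >= 1 event; count sentences with a trigger
  nEventSent <- sum(vapply(docs, function(d) {
    trig <- vapply(events(d), `[[`, character(1), "trigger")
    tb <- textbounds(d)
    toks <- vapply(trig, function(t)
      EventPipe:::headTokenIndex(d, tb$start[match(t, tb$id)],
                                 tb$end[match(t, tb$id)]), integer(1))
    length(unique(tokens(d)$sentence[toks]))
  }, integer(1)))
  mu <- nSent * pEvent
  sigma <- sqrt(nSent * pEvent * (1 - pEvent))
  expect_lt(abs(nEventSent - mu), 3 * sigma)
})

test_that("generation is a pure function of the spec", {
  s <- synthSpec(nDocs = 8, seed = 41, shift = 0.5)
  p1 <- generateShiftedPair(s)
  p2 <- generateShiftedPair(s)
  expect_identical(p1, p2)
  ## train and target differ under shift
  expect_false(identical(p1$train, p1$target))
})

test_that("the train/target shift is detectable but not separable", {
  ## domain-classifier AUC on candidate-level lexical features: near 0.5
  ## with no shift, strictly between 0.5 and 1 under moderate shift,
  ## near 1 in the disjoint-lexicon limit
  auc <- function(shift, seed) {
    pair <- generateShiftedPair(synthSpec(nDocs = 25, shift = shift,
                                          seed = seed))
    cfg <- deriveConfigFromCorpus(pair$train,
                                  options = list(hashBits = 10L))
    feats <- function(docs) {
      inv <- collectInventories(docs, cfg)
      fl <- list()
      for (d in docs) {
        st <- EventPipe:::docState(d, cfg)
        for (cd in enumerateTriggerCandidates(d, inv$headTable, cfg))
          fl[[length(fl) + 1L]] <- EventPipe:::featTrigger(st, cd$token)
      }
      featureMatrix(fl, 10L)
    }
    Xtr <- feats(pair$train); Xtg <- feats(pair$target)
    ## fit on one half, measure separability on the held-out half so the
    ## no-shift case is not inflated by in-sample optimism
    oddTr <- seq_len(nrow(Xtr)) %% 2 == 1
    oddTg <- seq_len(nrow(Xtg)) %% 2 == 1
    Xfit <- rbind(Xtr[oddTr, ], Xtg[oddTg, ])
    yfit <- c(rep(0, sum(oddTr)), rep(1, sum(oddTg)))
    fit <- glmnet::glmnet(Xfit, yfit, family = "binomial",
                          alpha = 0, lambda = 1 / length(yfit),
                          standardize = FALSE)
    Xev <- rbind(Xtr[!oddTr, ], Xtg[!oddTg, ])
    y <- c(rep(0, sum(!oddTr)), rep(1, sum(!oddTg)))
    p <- as.numeric(predict(fit, Xev, type = "response"))
    r <- rank(p)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  }
  aucNone <- mean(vapply(1:3, function(s) auc(0, s), numeric(1)))
  expect_lt(abs(aucNone - 0.5), 0.1)
  aucMid <- auc(0.8, 4)
  expect_gt(aucMid, 0.55)
  expect_lt(aucMid, 1)
  aucFull <- auc(1, 5)
  expect_gt(aucFull, 0.9)
})

test_that("corpus summaries equal a re-scan of the serialised files", {
  docs <- cachedCorpus("round7", 6, 7)
  sums <- corpusSummary(docs)
  dir <- tempfile("corpus")
  cfg <- deriveConfigFromCorpus(docs)
  for (d in docs) writeDocumentFiles(d, dir, cfg)
  reread <- readCorpusDir(dir)
  sums2 <- corpusSummary(reread)
  expect_equal(sums$entities, sums2$entities)
  expect_equal(sums$events, sums2$events)
  expect_equal(sums$structures, sums2$structures)
  expect_equal(sums$modifications, sums2$modifications)
  ## trivial cases
  expect_equal(corpusSummary(list()),
               list(entities = integer(), events = integer(),
                    structures = integer(), modifications = integer()))
})

test_that("numbered-role events occur in the default grammar", {
  docs <- cachedCorpus("train40", 40, 11)
  roles <- unlist(lapply(docs, function(d)
    unlist(lapply(events(d), function(e) e$args$role))))
  expect_true("Theme2" %in% roles)
})
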