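test_that("soft-boundary matching extends gold spans by one token", {
  doc <- readDocument("alpha beta gamma delta .")
  ## identical spans
  expect_true(matchSpanSoft(c(6, 10), c(6, 10), doc))
  ## pred extended by the single preceding token
  expect_true(matchSpanSoft(c(6, 10), c(0, 10), doc))
  ## pred extended by the following token
  expect_true(matchSpanSoft(c(6, 10), c(6, 16), doc))
  ## two tokens away fails
  expect_false(matchSpanSoft(c(6, 10), c(17, 22), doc))
  ## disjoint far spans fail
  expect_false(matchSpanSoft(c(0, 5), c(17, 22), doc))
})

nestedPair <- function(innerCauseType = "Prot") {
  txt <- "A inhibited GE of B with C ."
  gold <- readDocument(txt,
    a1 = c("T1\tProt 0 1\tA", "T2\tProt 18 19\tB", "T6\tProt 25 26\tC"),
    a2 = c("T3\tRegulation 2 11\tinhibited", "T4\tGene_expression 12 14\tGE",
           "E1\tGene_expression:T4 Theme:T2 Cause:T6",
           "E2\tRegulation:T3 Theme:E1 Cause:T1"), id = "d1")
  pred <- readDocument(txt,
    a1 = c("T1\tProt 0 1\tA", "T2\tProt 18 19\tB", "T6\tProt 25 26\tC"),
    a2 = c("T3\tRegulation 2 11\tinhibited", "T4\tGene_expression 12 14\tGE",
           "E1\tGene_expression:T4 Theme:T2",
           "E2\tRegulation:T3 Theme:E1 Cause:T1"), id = "d1")
  list(gold = gold, pred = pred)
}

test_that("strict and partial recursive matching differ on nested args", {
  p <- nestedPair()
  gE2 <- events(p$gold)[[2]]
  pE2 <- events(p$pred)[[2]]
  ## identical event trees match in both modes
  expect_true(matchEvent(gE2, gE2, "strict", p$gold, p$gold))
  expect_true(matchEvent(gE2, gE2, "partial", p$gold, p$gold))
  ## inner event differs in its Cause: strict fails, partial passes
  expect_false(matchEvent(gE2, pE2, "strict", p$gold, p$pred))
  expect_true(matchEvent(gE2, pE2, "partial", p$gold, p$pred))
  ## differing top-level types fail in both modes
  gAlt <- gE2; gAlt$type <- "Positive_regulation"
  expect_false(matchEvent(gAlt, pE2, "strict", p$gold, p$pred))
  expect_false(matchEvent(gAlt, pE2, "partial", p$gold, p$pred))
})

test_that("equivalence-set members are interchangeable argument fillers", {
  txt <- "X binds A aka B ."
  gold <- readDocument(txt,
    a1 = c("T1\tProt 8 9\tA", "T2\tProt 14 15\tB", "*\tEquiv T1 T2"),
    a2 = c("T3\tBinding 2 7\tbinds", "E1\tBinding:T3 Theme:T1"), id = "d")
  pred <- readDocument(txt,
    a1 = c("T1\tProt 8 9\tA", "T2\tProt 14 15\tB"),
    a2 = c("T3\tBinding 2 7\tbinds", "E1\tBinding:T3 Theme:T2"), id = "d")
  expect_true(matchEvent(events(gold)[[1]], events(pred)[[1]], "strict",
                         gold, pred))
})

test_that("self-evaluation scores ones; empty predictions score zeros", {
  docs <- cachedCorpus("round7", 6, 7)
  rep1 <- scoreCorpus(docs, docs, mode = "strict")
  tab <- scoreTable(rep1)
  expect_true(all(tab$recall == 1 & tab$precision == 1 & tab$fscore == 1))

  stripped <- lapply(docs, function(d) {
    d@events <- list()
    d
  })
  rep0 <- scoreCorpus(docs, stripped, mode = "strict")
  tot <- scoreTable(rep0)[scoreTable(rep0)$category == "TOTAL", ]
  expect_equal(tot$recall, 0)
  expect_equal(tot$precision, 0)
  expect_equal(tot$fscore, 0)
})

test_that("the tiny worked example gives R=1/2, P=1/3, F=0.4", {
  ## entities and triggers separated by spacer tokens so soft-boundary
  ## extension cannot make neighbours interchangeable
  txt <- "aa xx bb cc y1 dd y2 ee ff ."
  mk <- function(evLines, id = "d") readDocument(txt,
    a1 = c("T1\tProt 0 2\taa", "T2\tProt 6 8\tbb"),
    a2 = c("T3\tEv 9 11\tcc", "T4\tEv 15 17\tdd", "T5\tEv 21 23\tee",
           evLines), id = id)
  gold <- mk(c("E1\tEv:T3 Theme:T1", "E2\tEv:T4 Theme:T2"))
  ## 3 predictions, exactly one correct
  pred <- mk(c("E1\tEv:T3 Theme:T1", "E2\tEv:T4 Theme:T1",
               "E3\tEv:T5 Theme:T2"))
  tab <- scoreTable(scoreCorpus(list(gold), list(pred), mode = "strict"))
  tot <- tab[tab$category == "TOTAL", ]
  expect_equal(tot$recall, 0.5)
  expect_equal(tot$precision, 1 / 3)
  expect_equal(tot$fscore, 0.4)
})

test_that("the F identity holds on every report row", {
  model <- cachedSmallModel()
  held <- cachedCorpus("held8", 8, 77)
  preds <- lapply(held, predictPipeline, model = model)
  tab <- scoreTable(scoreCorpus(held, preds, mode = "strict"))
  for (i in seq_len(nrow(tab))) {
    p <- tab$precision[i]; r <- tab$recall[i]
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(tab$fscore[i], f)
  }
})

test_that("modifications are scored as MOD items on matched events", {
  docs <- cachedCorpus("round7", 6, 7)
  nMods <- sum(vapply(docs, function(d)
    sum(lengths(lapply(events(d), `[[`, "mods"))), integer(1)))
  skip_if(nMods == 0)
  tab <- scoreTable(scoreCorpus(docs, docs, mode = "strict"))
  expect_true("MOD" %in% tab$category)
  expect_equal(tab$gold[tab$category == "MOD"], nMods)
})

test_that("identical systems give p = 1 under randomisation", {
  docs <- cachedCorpus("round7", 6, 7)
  res <- approximateRandomization(docs, docs, docs, iterations = 50,
                                  seed = 1)
  expect_equal(res$p, 1)
  res2 <- approximateRandomization(docs, docs, docs, iterations = 50,
                                   seed = 1)
  expect_identical(res, res2)
})

test_that("randomisation p matches exhaustive swap enumeration", {
  ## two synthetic systems over d small documents with known per-document
  ## outputs: compare the Monte-Carlo p with the exact enumeration over
  ## all 2^d swap patterns
  txt <- "aa bb cc ."
  mkDoc <- function(id, withEvent) readDocument(txt,
    a1 = "T1\tProt 0 2\taa",
    a2 = c("T2\tEv 3 5\tbb",
           if (withEvent) "E1\tEv:T2 Theme:T1"), id = id)
  d <- 6
  withr::with_seed(13, {
    gold <- lapply(seq_len(d), function(i) mkDoc(paste0("d", i), TRUE))
    predA <- lapply(seq_len(d), function(i)
      mkDoc(paste0("d", i), runif(1) < 0.8))
    predB <- lapply(seq_len(d), function(i)
      mkDoc(paste0("d", i), runif(1) < 0.4))
  })
  perDoc <- function(preds) t(vapply(seq_len(d), function(i) {
    cnt <- EventPipe:::docCounts(gold[[i]], preds[[i]], character(),
                                 "strict")
    Reduce(`+`, cnt)
  }, numeric(4)))
  cA <- perDoc(predA); cB <- perDoc(predB)
  fOf <- EventPipe:::fFromCounts
  obs <- abs(fOf(cA) - fOf(cB))
  hits <- 0L
  for (m in 0:(2^d - 1)) {
    swap <- bitwAnd(m, 2^(seq_len(d) - 1)) > 0
    a <- cA; b <- cB
    a[swap, ] <- cB[swap, , drop = FALSE]
    b[swap, ] <- cA[swap, , drop = FALSE]
    if (abs(fOf(a) - fOf(b)) >= obs - 1e-12) hits <- hits + 1L
  }
  exact <- hits / 2^d
  res <- approximateRandomization(gold, predA, predB, iterations = 4000,
                                  seed = 5)
  expect_equal(res$p, exact, tolerance = 0.05)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
})
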