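test_that("standoff T/E/M lines parse into the document model", {
  doc <- readDocument("Overexpression of TGF-beta",
                      a1 = "T1\tGene_or_gene_product 18 26\tTGF-beta")
  tb <- textbounds(doc)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$type, "Gene_or_gene_product")
  expect_equal(c(tb$start, tb$end), c(18L, 26L))

  doc2 <- readDocument("Overexpression of TGF-beta",
    a1 = "T1\tGene_or_gene_product 18 26\tTGF-beta",
    a2 = c("T2\tGene_expression 0 14\tOverexpression",
           "E1\tGene_expression:T2 Theme:T1"))
  ev <- events(doc2)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$args$role, "Theme")
  expect_equal(ev[[1]]$args$target, "T1")
})

test_that("modifications fold into events and Equiv lines are stored", {
  doc <- tinyDoc()
  e3 <- events(doc)[[3]]
  expect_equal(e3$id, "E3")
  expect_equal(e3$mods, "Negation")
  doc2 <- readDocument("A B", a1 = c("T1\tProt 0 1\tA", "T2\tProt 2 3\tB",
                                     "*\tEquiv T1 T2"))
  expect_equal(equivalences(doc2), list(c("T1", "T2")))
})

test_that("self-referencing and malformed annotations are rejected", {
  expect_error(
    readDocument("Regulation here",
                 a2 = c("T9\tRegulation 0 10\tRegulation",
                        "E9\tRegulation:T9 Theme:E9")),
    "cycle")
  expect_error(readDocument("abc", a1 = "T1\tFoo 0 2;4 5\tab"),
               "discontinuous")
  expect_error(readDocument("abc", a1 = "Z1\tFoo 0 2\tab"), "unknown line")
  expect_error(readDocument("abc", a1 = c("T1\tFoo 0 1\ta",
                                          "T1\tFoo 1 2\tb")),
               "duplicate")
})

test_that("parsing is insensitive to annotation line order", {
  lines <- c("E1\tGene_expression:T2 Theme:T1",
             "T2\tGene_expression 0 14\tOverexpression",
             "T1\tGene_or_gene_product 18 26\tTGF-beta")
  doc <- readDocument("Overexpression of TGF-beta", a2 = lines)
  expect_length(validateDocument(doc), 0L)
  doc2 <- readDocument("Overexpression of TGF-beta", a2 = rev(lines))
  expect_identical(writeAnnotations(doc), writeAnnotations(doc2))
})

test_that("validateDocument reports violations without raising", {
  doc <- tinyDoc()
  expect_length(validateDocument(doc), 0L)
  bad <- doc
  bad@textbounds$end[1] <- 10000L
  v <- validateDocument(bad)
  expect_true(any(grepl(bad@textbounds$id[1], v)))
  bad2 <- doc
  bad2@events[[1]]$args$target <- "T99"
  v2 <- validateDocument(bad2)
  expect_true(any(grepl("T99", v2)))
})

test_that("write -> read -> write round trips byte-identically", {
  doc <- tinyDoc()
  ann <- writeAnnotations(doc)
  doc2 <- readDocument(docText(doc), a1 = ann$a1, a2 = ann$a2)
  expect_identical(writeAnnotations(doc2), ann)

  ## generator-produced documents, including hedges and numbered roles
  for (d in cachedCorpus("round7", 6, 7)) {
    ann <- writeAnnotations(d)
    d2 <- readDocument(docText(d), a1 = ann$a1, a2 = ann$a2, id = docId(d))
    expect_identical(writeAnnotations(d2), ann)
    expect_identical(writeAnnotations(d), ann)  # repeated call, same bytes
  }
})

test_that("a document with no events serialises an empty a2 body", {
  doc <- readDocument("Only text", a1 = "T1\tProt 0 4\tOnly")
  expect_identical(writeAnnotations(doc)$a2, "")
})

test_that("events referencing textbounds excluded from both files error", {
  doc <- tinyDoc()
  cfg <- taskConfig(goldTypes = "Gene_or_gene_product",
                    predictionTypes = c("Gene_expression",
                                        "Negative_regulation"),
                    triggerTypes = c("Gene_expression",
                                     "Negative_regulation"))
  expect_error(writeAnnotations(doc, cfg), "excluded")
})

test_that("parse interchange format round trips and checks offsets", {
  doc <- tinyDoc()
  txt <- writeParseInterchange(tokens(doc))
  tk <- readParseInterchange(txt, docText(doc))
  expect_equal(tk$surface, tokens(doc)$surface)
  expect_equal(tk$head, tokens(doc)$head)
  expect_equal(tk$sentence, tokens(doc)$sentence)
  expect_error(readParseInterchange("0\tWRONG\t0\t5\twrong\t-1\troot",
                                    "right"),
               "does not match")
})

test_that("the fallback tokenizer yields valid offsets and sentences", {
  tk <- simpleTokenize("One two. Three four!")
  expect_equal(tk$surface, c("One", "two", ".", "Three", "four", "!"))
  expect_equal(tk$sentence, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(tk$head, c(0L, 1L, 2L, 0L, 4L, 5L))
  txt <- "One two. Three four!"
  expect_equal(substring(txt, tk$start + 1, tk$end), tk$surface)
})

test_that("annotation identifiers are unique per document", {
  for (d in cachedCorpus("round7", 6, 7)) {
    ids <- c(textbounds(d)$id, vapply(events(d), `[[`, character(1), "id"))
    expect_false(anyDuplicated(ids) > 0)
  }
})
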