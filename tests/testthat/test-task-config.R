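test_that("config files parse, validate, and round trip", {
  src <- "
GOLD
Gene_or_gene_product
PREDICTION
Gene_expression
TRIGGERS
Gene_expression
ROLES
Theme
OPTIONS
C = 1
"
  cfg <- parseTaskConfig(src)
  expect_s4_class(cfg, "TaskConfig")
  expect_equal(cfg@triggerTypes, "Gene_expression")
  cfg2 <- parseTaskConfig(writeTaskConfig(cfg))
  expect_equal(cfg2@goldTypes, cfg@goldTypes)
  expect_equal(taskOption(cfg2, "C"), 1)

  expect_error(parseTaskConfig("GOLD\nA\nGOLD\nB"), "duplicate section")
  expect_error(parseTaskConfig("GOLD\nA\nMYSTERY_SECTION\nB"),
               "unknown section")
  expect_error(parseTaskConfig("TRIGGERS\nNeverDeclared"),
               "GOLD or PREDICTION")
})

test_that("entity types are GOLD union PREDICTION minus TRIGGERS", {
  cfg <- taskConfig(goldTypes = c("A", "B", "T1"), predictionTypes = "T2",
                    triggerTypes = c("T1", "T2"))
  expect_setequal(entityTypes(cfg), c("A", "B"))
  cfg2 <- taskConfig(goldTypes = c("T1"), predictionTypes = "T2",
                     triggerTypes = c("T1", "T2"))
  expect_length(entityTypes(cfg2), 0L)
  cfg3 <- taskConfig(predictionTypes = "E")
  expect_equal(entityTypes(cfg3), "E")
})

test_that("configuration derivation from a corpus observes all types", {
  doc <- tinyDoc()
  cfg <- deriveConfigFromCorpus(list(doc),
                                a1Types = "Gene_or_gene_product")
  expect_true(all(c("Gene_expression", "Negative_regulation", "Pathway")
                  %in% cfg@triggerTypes))
  expect_equal(cfg@goldTypes, "Gene_or_gene_product")
  expect_setequal(cfg@roleTypes, c("Theme", "Cause", "Participant"))
  expect_length(cfg@labelGen, 0L)

  noEv <- readDocument("Only text", a1 = "T1\tProt 0 4\tOnly")
  cfgE <- deriveConfigFromCorpus(list(noEv))
  expect_length(cfgE@triggerTypes, 0L)

  expect_identical(deriveConfigFromCorpus(list(doc)),
                   deriveConfigFromCorpus(list(doc)))
  expect_error(deriveConfigFromCorpus(list()), "empty")
})

test_that("type generalisation follows the preset rules by position", {
  cg <- loadPresetConfig("cg")
  expect_equal(generalizeType(cg, "Positive_regulation", "argument_label",
                              "trigger"), "REGULATION")
  expect_equal(generalizeType(cg, "Phosphorylation", "argument_label",
                              "trigger"), "PTM")
  ## event and entity catch-alls act in argument position only
  expect_equal(generalizeType(cg, "Gene_expression", "argument_label",
                              "argument"), "EVENT")
  expect_equal(generalizeType(cg, "Cell", "argument_label", "argument"),
               "ENTITY")
  expect_equal(generalizeType(cg, "Gene_expression", "argument_label",
                              "trigger"), "Gene_expression")
  ## numbered roles: de-numbered everywhere except structure labels
  expect_equal(generalizeType(cg, "Participant2", "argument_label", "role"),
               "Participant")
  expect_equal(generalizeType(cg, "Theme2", "structure_label", "role"),
               "Theme2")
  ## refined PC preset maps proteins and complexes to PROTEIN
  pc <- loadPresetConfig("pc-refined")
  expect_equal(generalizeType(pc, "Gene_or_gene_product", "feature",
                              "argument"), "PROTEIN")
  expect_equal(generalizeType(pc, "Complex", "feature", "argument"),
               "PROTEIN")
  expect_equal(generalizeType(pc, "Simple_chemical", "feature", "argument"),
               "Simple_chemical")
})

test_that("generalisation is idempotent over the full preset inventories", {
  for (preset in c("cg", "cg-refined", "pc", "pc-refined")) {
    cfg <- loadPresetConfig(preset)
    names <- c(cfg@goldTypes, cfg@predictionTypes, "REGULATION", "PTM",
               "EVENT", "ENTITY")
    for (ctx in c("argument_label", "structure_label", "feature")) {
      for (pos in c("argument", "trigger")) {
        once <- generalizeType(cfg, names, ctx, pos)
        expect_identical(generalizeType(cfg, once, ctx, pos), once)
      }
    }
    roles <- c(cfg@roleTypes, "Theme")
    onceR <- generalizeType(cfg, roles, "argument_label", "role")
    expect_identical(generalizeType(cfg, onceR, "argument_label", "role"),
                     onceR)
  }
})

test_that("inventories collect the generalised labels observed in training", {
  doc <- readDocument("X binds TGFB now .",
    a1 = "T1\tGene_or_gene_product 8 12\tTGFB",
    a2 = c("T2\tBinding 2 7\tbinds", "E1\tBinding:T2 Theme:T1"))
  cfg <- taskConfig(goldTypes = "Gene_or_gene_product",
                    predictionTypes = "Binding", triggerTypes = "Binding",
                    roleTypes = "Theme")
  inv <- collectInventories(list(doc), cfg)
  expect_equal(inv$roleLabels$key, "Binding:Theme-Gene_or_gene_product")
  expect_equal(names(inv$structureLabels),
               "Binding|Theme-Gene_or_gene_product")
  expect_true("binds" %in% inv$headTable$form)

  empty <- readDocument("Only text", a1 = "T1\tGene_or_gene_product 0 4\tOnly")
  invE <- collectInventories(list(empty), cfg)
  expect_equal(nrow(invE$roleLabels), 0L)
  expect_length(invE$structureLabels, 0L)

  expect_identical(collectInventories(list(doc), cfg),
                   collectInventories(list(doc), cfg))
  badCfg <- taskConfig(goldTypes = "Gene_or_gene_product",
                       predictionTypes = "Binding",
                       triggerTypes = "Binding")
  expect_error(collectInventories(list(tinyDoc()), badCfg), "validation")
})

test_that("instance-generation rules expand structures monotonically", {
  docs <- list(readDocument("A inhibits GE of X .",
    a1 = "T1\tProt 17 18\tX",
    a2 = c("T2\tRegulation 2 10\tinhibits", "T3\tGene_expression 11 13\tGE",
           "E1\tGene_expression:T3 Theme:T1", "E2\tRegulation:T2 Theme:E1")))
  cfg <- taskConfig(goldTypes = "Prot",
                    predictionTypes = c("Regulation", "Positive_regulation",
                                        "Gene_expression"),
                    triggerTypes = c("Regulation", "Positive_regulation",
                                     "Gene_expression"),
                    roleTypes = "Theme",
                    instanceRules = list(c("Regulation",
                                           "Positive_regulation")))
  inv <- collectInventories(docs, cfg)
  out <- expandStructures(cfg, inv$structureLabels)
  expect_true("Positive_regulation|Theme-Gene_expression" %in% names(out))
  expect_true(all(names(inv$structureLabels) %in% names(out)))
  ## idempotent and monotone
  expect_identical(expandStructures(cfg, out), out)
  ## no rules -> identity
  cfg0 <- taskConfig(goldTypes = "Prot",
                     predictionTypes = c("Regulation", "Gene_expression"),
                     triggerTypes = c("Regulation", "Gene_expression"))
  inv0 <- collectInventories(docs[1], cfg0)
  expect_identical(expandStructures(cfg0, inv0$structureLabels),
                   inv0$structureLabels)
})

test_that("derived configs support inventory collection on their corpus", {
  docs <- cachedCorpus("round7", 6, 7)
  cfg <- deriveConfigFromCorpus(docs)
  expect_silent(inv <- collectInventories(docs, cfg))
  expect_gt(nrow(inv$roleLabels), 0L)
})
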