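## Shared fixtures, all built in code.

## A Figure-1-style miniature document: nested regulation over an
## expression event, one gold entity, one hedge.
tinyDoc <- function() {
  readDocument("Overexpression of TGFB inhibited FOO signaling .",
    a1 = c("T1\tGene_or_gene_product 18 22\tTGFB",
           "T5\tGene_or_gene_product 33 36\tFOO"),
    a2 = c("T2\tGene_expression 0 14\tOverexpression",
           "T3\tNegative_regulation 23 32\tinhibited",
           "T4\tPathway 37 46\tsignaling",
           "E1\tGene_expression:T2 Theme:T1",
           "E2\tPathway:T4 Participant:T5",
           "E3\tNegative_regulation:T3 Theme:E2 Cause:E1",
           "M1\tNegation E3"),
    id = "tiny")
}

tinyConfig <- function() {
  taskConfig(goldTypes = "Gene_or_gene_product",
             predictionTypes = c("Gene_expression", "Negative_regulation",
                                 "Pathway"),
             triggerTypes = c("Gene_expression", "Negative_regulation",
                              "Pathway"),
             roleTypes = c("Theme", "Cause", "Participant"))
}

## Small synthetic corpora, cached per session so several test files can
## share them without regenerating.
.fixtureCache <- new.env(parent = emptyenv())

cachedCorpus <- function(key, nDocs, seed, ...) {
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateCorpus(synthSpec(nDocs = nDocs,
                                                     seed = seed, ...))
  .fixtureCache[[key]]
}

## A small trained pipeline shared across pipeline/cli tests.
cachedSmallModel <- function() {
  if (is.null(.fixtureCache$smallModel)) {
    docs <- cachedCorpus("train40", 40, 11)
    cfg <- deriveConfigFromCorpus(docs, options = list(hashBits = 12L))
    .fixtureCache$smallModel <- trainPipeline(docs, cfg, mode = "weighting",
                                              seed = 1)
  }
  .fixtureCache$smallModel
}

## Random sparse-ish training batch for objective/oracle tests.
randomBatch <- function(n = 20, d = 4, seed = 1, posFrac = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    y <- ifelse(seq_len(n) <= max(1, round(posFrac * n)), 1, -1)
    trainingBatch(X, sample(y))
  })
}

randomShiftWeights <- function(batch, seed = 1) {
  withr::with_seed(seed, {
    n <- length(batch@y)
    l <- exp(rnorm(n, sd = 0.5))
    p <- l / (l + 1)
    methods::new("ShiftWeights", l = l, pTrain = 1 - p, pTarget = p,
                 nTrain = as.integer(n), nTarget = as.integer(n),
                 cost = batch@cost, CCS = n * batch@cost / sum(l))
  })
}

## Independent numeric minimiser used as the optimality oracle: a
## different algorithm (BFGS with numerical gradients) from several random
## starts.
oracleMinimum <- function(fn, d, starts = 3, seed = 1) {
  withr::with_seed(seed, {
    best <- Inf
    for (s in seq_len(starts)) {
      par <- if (s == 1) rep(0, d) else rnorm(d)
      fit <- optim(par, fn, method = "BFGS",
                   control = list(maxit = 5000, reltol = 1e-14))
      best <- min(best, fit$value)
    }
    best
  })
}
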