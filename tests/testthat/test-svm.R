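test_that("squared hinge has the textbook values", {
  expect_equal(squaredHinge(1), 0)
  expect_equal(squaredHinge(2), 0)
  expect_equal(squaredHinge(-1), 4)
  expect_equal(squaredHinge(c(0.5, 1.5)), c(0.25, 0))
})

test_that("objectives take closed-form values at zero weights", {
  b <- randomBatch(n = 20, d = 3, seed = 2, posFrac = 0.25)
  np <- nPositive(b); nn <- nNegative(b)
  w0 <- rep(0, 3)
  ## every loss is 1 at w = 0
  expect_equal(objectivePlain(w0, b), b@cost * 20)
  expect_equal(objectiveWeighted(w0, b), 2 * b@cost * nn)
  sw <- unitShiftWeights(20)
  expect_equal(objectiveCovariate(w0, b, sw), b@cost * 20)
  expect_equal(objectiveCombined(w0, b, sw), 2 * b@cost * nn)
})

test_that("a balanced batch makes the weighted objective the plain one", {
  b <- randomBatch(n = 16, d = 3, seed = 5, posFrac = 0.5)
  w <- rnorm(3)
  expect_equal(objectiveWeighted(w, b), objectivePlain(w, b))
})

test_that("objectives match an independent term-by-term summation oracle", {
  for (seed in 1:5) {
    b <- randomBatch(n = 15, d = 4, seed = seed, posFrac = 0.3)
    sw <- randomShiftWeights(b, seed = seed + 100)
    w <- withr::with_seed(seed + 200, rnorm(4))
    X <- as.matrix(b@X); y <- b@y; l <- sw@l; C <- b@cost
    loss <- vapply(seq_len(nrow(X)),
                   function(i) max(0, 1 - y[i] * sum(w * X[i, ]))^2,
                   numeric(1))
    pos <- y > 0
    expect_equal(objectivePlain(w, b), sum(w^2) + C * sum(loss))
    expect_equal(objectiveWeighted(w, b),
                 sum(w^2) + (sum(!pos) / sum(pos)) * C * sum(loss[pos]) +
                   C * sum(loss[!pos]))
    expect_equal(objectiveCovariate(w, b, sw),
                 sum(w^2) + sw@CCS * sum(l * loss))
    expect_equal(objectiveCombined(w, b, sw),
                 sum(w^2) +
                   (sum(l[!pos]) / sum(l[pos])) * sw@CCS * sum(l[pos] * loss[pos]) +
                   sw@CCS * sum(l[!pos] * loss[!pos]))
  }
})

test_that("weighted objective refuses batches without positives", {
  b <- trainingBatch(matrix(rnorm(6), 3, 2), c(-1, -1, -1))
  expect_error(objectiveWeighted(rep(0, 2), b), "positive")
})

test_that("objectives are convex in w", {
  for (seed in 1:10) {
    b <- randomBatch(n = 12, d = 3, seed = seed, posFrac = 0.4)
    sw <- randomShiftWeights(b, seed = seed)
    withr::with_seed(seed + 50, {
      w1 <- rnorm(3); w2 <- rnorm(3); t <- runif(1)
    })
    for (f in list(function(w) objectivePlain(w, b),
                   function(w) objectiveWeighted(w, b),
                   function(w) objectiveCovariate(w, b, sw),
                   function(w) objectiveCombined(w, b, sw))) {
      expect_lte(f(t * w1 + (1 - t) * w2),
                 t * f(w1) + (1 - t) * f(w2) + 1e-9)
    }
  }
})

test_that("the trainer separates trivially separable data", {
  b <- trainingBatch(matrix(c(1, -1), 2, 1), c(1, -1))
  m <- trainBinary(b, "plain")
  expect_gt(m@w[1] * 1, 0)
  expect_lt(m@w[1] * -1, 0)
})

test_that("the trainer attains the oracle optimum in all four modes", {
  for (seed in 1:5) {
    b <- randomBatch(n = 25, d = 4, seed = seed, posFrac = 0.2)
    sw <- randomShiftWeights(b, seed = seed + 7)
    objs <- list(
      plain = function(w) objectivePlain(w, b),
      weighting = function(w) objectiveWeighted(w, b),
      covariate_shift = function(w) objectiveCovariate(w, b, sw),
      combined = function(w) objectiveCombined(w, b, sw))
    for (mode in names(objs)) {
      m <- trainBinary(b, mode, sw = sw)
      mine <- objs[[mode]](m@w)
      oracle <- oracleMinimum(objs[[mode]], 4, seed = seed)
      expect_lte(mine, oracle * (1 + 1e-4) + 1e-8)
    }
  }
})

test_that("combined training with unit weights equals weighting mode", {
  b <- randomBatch(n = 30, d = 4, seed = 3, posFrac = 0.25)
  sw <- unitShiftWeights(30)
  mW <- trainBinary(b, "weighting")
  mC <- trainBinary(b, "combined", sw = sw)
  expect_equal(objectiveWeighted(mC@w, b), objectiveWeighted(mW@w, b),
               tolerance = 1e-6)
})

test_that("trainer refuses empty batches and missing shift weights", {
  empty <- trainingBatch(matrix(numeric(), 0, 2), numeric())
  expect_error(trainBinary(empty, "plain"), "empty")
  b <- randomBatch(10, 2, 1)
  expect_error(trainBinary(b, "covariate_shift"), "ShiftWeights")
})

test_that("density-ratio weights are near one without shift", {
  withr::with_seed(9, {
    tr <- matrix(rnorm(600), ncol = 2)
    tg <- matrix(rnorm(600), ncol = 2)
  })
  sw <- estimateShiftWeights(tr, tg, seed = 4)
  expect_lt(mean(abs(sw@l - 1)), 0.25)
  expect_equal(sw@CCS, 1, tolerance = 0.25)
})

test_that("the ratio formula and clipping are honoured", {
  ## reconstruct l from the classifier probabilities the object reports
  withr::with_seed(10, {
    tr <- matrix(rnorm(200, 0), ncol = 2)
    tg <- matrix(rnorm(200, 0.8), ncol = 2)
  })
  sw <- estimateShiftWeights(tr, tg, seed = 1, clip = c(1e-3, 1e3))
  expected <- pmin(pmax((sw@nTrain / sw@nTarget) * sw@pTarget / sw@pTrain,
                        1e-3), 1e3)
  expect_equal(sw@l, expected)
  ## a classifier probability of 0.8 with equal sizes implies l = 4
  expect_equal((1) * 0.8 / 0.2, 4)
  ## tight clipping bounds bite
  swC <- estimateShiftWeights(tr, tg, seed = 1, clip = c(0.9, 1.1))
  expect_true(all(swC@l >= 0.9 & swC@l <= 1.1))
})

test_that("estimated ratios track the analytic Gaussian density ratio", {
  withr::with_seed(21, {
    tr <- matrix(rnorm(500, 0), ncol = 1)
    tg <- matrix(rnorm(500, 1), ncol = 1)
  })
  sw <- estimateShiftWeights(tr, tg, seed = 2)
  analytic <- exp(tr[, 1] - 0.5)   # N(1,1) / N(0,1)
  expect_gte(cor(sw@l, analytic, method = "spearman"), 0.9)
})

test_that("degenerate shift estimation inputs error", {
  expect_error(estimateShiftWeights(matrix(numeric(), 0, 2),
                                    matrix(rnorm(10), 5, 2)),
               "non-empty")
})

test_that("multi-label decision keeps positives plus the arg-max", {
  model <- methods::new("DetectorModel", stage = "trigger",
                        labels = c("A", "B"),
                        W = cbind(c(0.5, 0), c(0.2, 0)),
                        negativeLabel = "NONE", hashBits = 1L,
                        mode = "none")
  x <- c(1, 0)
  expect_setequal(predictLabels(model, x), c("A", "B"))
  model@W <- cbind(c(-0.5, 0), c(-0.2, 0))
  expect_equal(predictLabels(model, x), "NONE")
  model@W <- cbind(c(0.5, 0), c(-0.2, 0))
  expect_equal(predictLabels(model, x), "A")
})
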