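## L2-regularised squared-hinge linear SVM with three adaptation
## objectives:
##
##   plain:      w'w + C * sum_i loss_i
##   weighting:  w'w + (n_n/n_p) C sum_p loss + C sum_n loss
##   covariate:  w'w + C_CS sum_i l(x_i) loss_i,  C_CS = n C / sum_i l(x_i)
##   combined:   w'w + (sum_n l / sum_p l) C_CS sum_p l loss
##                   + C_CS sum_n l loss
##
## with loss_i = max(0, 1 - y_i w.x_i)^2. Setting all l(x) = 1 reduces
## "covariate" to "plain" and "combined" to "weighting" exactly; those
## identities are asserted in the test suite. The objectives are smooth and
## convex, so the minimiser is an L-BFGS run from the origin with analytic
## gradients — no randomness, no hyper-parameter search (C stays at 1 by
## default).

#' Squared hinge loss
#'
#' @param margin numeric vector of margins \eqn{y_i w x_i}.
#' @return \eqn{\max(0, 1 - margin)^2}, vectorised.
#' @export
squaredHinge <- function(margin) pmax(0, 1 - margin)^2

#' Construct a TrainingBatch
#'
#' @param X instance matrix (rows = instances); coerced to sparse.
#' @param y signed labels in \code{{+1, -1}}.
#' @param C SVM cost constant.
#' @return a [TrainingBatch-class].
#' @export
trainingBatch <- function(X, y, C = 1) {
  methods::new("TrainingBatch", X = asSparse(X), y = as.numeric(y), cost = C)
}

#' @rdname trainingBatch
#' @param batch a [TrainingBatch-class].
#' @export
nPositive <- function(batch) sum(batch@y > 0)

#' @rdname trainingBatch
#' @export
nNegative <- function(batch) sum(batch@y < 0)

batchLosses <- function(w, batch) {
  margins <- as.numeric(batch@X %*% w) * batch@y
  squaredHinge(margins)
}

#' Training objectives for the adaptive SVM
#'
#' \code{objectivePlain} is the ordinary L2-regularised L2-loss SVM
#' objective. \code{objectiveWeighted} up-weights every positive-instance
#' loss by \eqn{n_n/n_p}, making the total cost of positive errors
#' comparable to the total cost of negative errors under class imbalance.
#' \code{objectiveCovariate} weights each instance's loss by its estimated
#' target-to-training density ratio \eqn{l(x_i)} and replaces \eqn{C} with
#' the balancing constant \eqn{C_{CS} = nC/\sum_i l(x_i)}.
#' \code{objectiveCombined} applies both, with the positive losses
#' additionally scaled by \eqn{\sum_n l / \sum_p l}.
#'
#' @param w numeric weight vector.
#' @param batch a [TrainingBatch-class].
#' @param sw a [ShiftWeights-class] covering the batch's instances.
#' @return the objective value (a single number).
#' @export
objectivePlain <- function(w, batch) {
  sum(w^2) + batch@cost * sum(batchLosses(w, batch))
}

#' @rdname objectivePlain
#' @export
objectiveWeighted <- function(w, batch) {
  np <- nPositive(batch)
  if (np == 0L)
    stopf("objectiveWeighted is undefined with no positive instances (n_n/n_p ratio)")
  nn <- nNegative(batch)
  loss <- batchLosses(w, batch)
  pos <- batch@y > 0
  sum(w^2) + (nn / np) * batch@cost * sum(loss[pos]) + batch@cost * sum(loss[!pos])
}

#' @rdname objectivePlain
#' @export
objectiveCovariate <- function(w, batch, sw) {
  stopifnot(length(sw@l) == length(batch@y))
  sum(w^2) + sw@CCS * sum(sw@l * batchLosses(w, batch))
}

#' @rdname objectivePlain
#' @export
objectiveCombined <- function(w, batch, sw) {
  stopifnot(length(sw@l) == length(batch@y))
  pos <- batch@y > 0
  sp <- sum(sw@l[pos]); sn <- sum(sw@l[!pos])
  if (sp <= 0)
    stopf("objectiveCombined is undefined when positive weights sum to zero")
  loss <- batchLosses(w, batch)
  sum(w^2) + (sn / sp) * sw@CCS * sum(sw@l[pos] * loss[pos]) +
    sw@CCS * sum(sw@l[!pos] * loss[!pos])
}

## Per-instance loss multipliers c_i such that every objective is
## w'w + sum_i c_i loss_i. All four modes reduce to this form.
instanceCosts <- function(batch, mode, sw = NULL) {
  n <- length(batch@y)
  pos <- batch@y > 0
  C <- batch@cost
  switch(mode,
    plain = rep(C, n),
    weighting = {
      np <- sum(pos)
      if (np == 0L) stopf("weighting mode needs at least one positive instance")
      ifelse(pos, (sum(!pos) / np) * C, C)
    },
    covariate_shift = {
      if (is.null(sw)) stopf("covariate_shift mode requires ShiftWeights")
      sw@CCS * sw@l
    },
    combined = {
      if (is.null(sw)) stopf("combined mode requires ShiftWeights")
      sp <- sum(sw@l[pos]); sn <- sum(sw@l[!pos])
      if (sp <= 0) stopf("combined mode: positive weights sum to zero")
      ifelse(pos, (sn / sp) * sw@CCS * sw@l, sw@CCS * sw@l)
    },
    stopf("unknown mode '%s'", mode))
}

#' Train one binary squared-hinge SVM
#'
#' Minimises the selected objective by L-BFGS with analytic gradients,
#' started at the origin. The objective is smooth and strictly convex in
#' \code{w}, so the run is deterministic and converges to the global
#' minimum; convergence is controlled by a relative-objective tolerance
#' (default 1e-6 via \code{factr}) with a 10000-iteration cap.
#'
#' @param batch a [TrainingBatch-class].
#' @param mode one of \code{"plain"}, \code{"weighting"},
#'   \code{"covariate_shift"}, \code{"combined"}.
#' @param sw a [ShiftWeights-class]; required for the covariate-shift and
#'   combined modes.
#' @param label label name stored on the returned model.
#' @param maxit iteration cap.
#' @return a [BinaryModel-class].
#' @export
trainBinary <- function(batch, mode = c("plain", "weighting",
                                        "covariate_shift", "combined"),
                        sw = NULL, label = "", maxit = 10000L) {
  mode <- match.arg(mode)
  if (length(batch@y) == 0L) stopf("cannot train on an empty batch")
  costs <- instanceCosts(batch, mode, sw)
  X <- batch@X
  y <- batch@y
  d <- ncol(X)
  Xt <- Matrix::t(X)
  fn <- function(w) {
    h <- pmax(0, 1 - y * as.numeric(X %*% w))
    sum(w^2) + sum(costs * h^2)
  }
  gr <- function(w) {
    h <- pmax(0, 1 - y * as.numeric(X %*% w))
    as.numeric(2 * w - 2 * (Xt %*% (costs * y * h)))
  }
  fit <- optim(rep(0, d), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e4))
  methods::new("BinaryModel", label = label, w = fit$par)
}

#' Multi-label one-vs-rest prediction
#'
#' Scores an instance against every positive-label scorer of a detector.
#' The predicted label set is every label scoring above the separating
#' hyper-plane (score > 0) plus the highest-scoring label, so at least one
#' label is always selected; the negative type participates as an implicit
#' label with fixed score 0. Ties at the maximum return all tied labels.
#'
#' @param model a [DetectorModel-class].
#' @param x a numeric or sparse vector of the model's hashed dimension.
#' @param restrict optional character vector restricting the candidate's
#'   admissible positive labels.
#' @return character vector of predicted labels (possibly just the
#'   negative type).
#' @export
predictLabels <- function(model, x, restrict = NULL) {
  sc <- scoreLabels(model, x, restrict)
  labs <- names(sc)
  sel <- labs[sc > 0]
  top <- labs[sc >= max(sc) - 1e-12]
  out <- union(sel, top)
  if (length(out) == 0L) model@negativeLabel else out
}

#' @rdname predictLabels
#' @return for \code{scoreLabels}: named numeric scores including the
#'   negative type at 0.
#' @export
scoreLabels <- function(model, x, restrict = NULL) {
  labs <- model@labels
  if (!is.null(restrict)) labs <- intersect(labs, restrict)
  xv <- if (methods::is(x, "sparseVector")) as.vector(x) else as.numeric(x)
  sc <- if (length(labs))
    as.numeric(crossprod(model@W[, match(labs, model@labels), drop = FALSE],
                         xv))
  else numeric()
  names(sc) <- labs
  c(sc, setNames(0, model@negativeLabel))
}

## Score a whole candidate matrix at once: rows x labels (negative label
## excluded; it is always 0).
scoreMatrix <- function(model, X) {
  if (length(model@labels) == 0L)
    return(matrix(numeric(), nrow = nrow(X), ncol = 0L))
  out <- as.matrix(X %*% model@W)
  colnames(out) <- model@labels
  out
}
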