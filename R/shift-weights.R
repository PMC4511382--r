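## Covariate-shift importance weights: a regularised logistic regression is
## trained to separate training from target instances; each training
## instance's weight is the implied target-to-training density ratio
##   l(x) = (n_train / n_target) * p_target(x) / p_train(x)
## clipped to configurable bounds (the ratio estimates can overfit), and
## the balancing constant C_CS = n_train * C / sum_i l(x_i) keeps the loss
## term on the same scale as the regulariser after weighting. The domain
## classifier is cross-fitted (5 folds) so every instance's probabilities
## come from a model that never saw it.

#' Estimate covariate-shift importance weights
#'
#' @param train instance matrix of training rows (dense or sparse).
#' @param target instance matrix of target-domain rows (unlabelled).
#' @param C base SVM cost constant the balancing constant refers to.
#' @param clip length-2 lower/upper clipping bounds for l(x).
#' @param seed integer seed for the cross-fitting fold assignment.
#' @param nfolds number of cross-fitting folds.
#' @param lambda ridge penalty for the domain classifier; the default
#'   \code{1/n} corresponds to unit regularisation strength on the summed
#'   log-likelihood scale.
#' @return a [ShiftWeights-class] for the training rows.
#' @export
estimateShiftWeights <- function(train, target, C = 1, clip = c(1e-3, 1e3),
                                 seed = 1L, nfolds = 5L, lambda = NULL) {
  train <- asSparse(train)
  target <- asSparse(target)
  nTr <- nrow(train); nTg <- nrow(target)
  if (nTr == 0L || nTg == 0L)
    stopf("both training and target collections must be non-empty")
  X <- rbind(train, target)
  ## glmnet needs >= 2 columns; pad with an all-zero column if necessary
  if (ncol(X) < 2L)
    X <- cbind(X, Matrix::sparseMatrix(i = integer(), j = integer(),
                                       x = numeric(), dims = c(nrow(X), 2L - ncol(X))))
  y <- c(rep(0, nTr), rep(1, nTg))           # 1 = target domain
  n <- nTr + nTg
  lambda <- lambda %||% 1 / n
  folds <- withLocalSeed(seed, {
    f <- integer(n)
    f[y == 0] <- sample(rep_len(seq_len(nfolds), nTr))
    f[y == 1] <- sample(rep_len(seq_len(nfolds), nTg))
    f
  })
  p <- numeric(n)
  for (k in seq_len(nfolds)) {
    hold <- folds == k
    ytr <- y[!hold]
    if (length(unique(ytr)) < 2L)
      stopf("degenerate domain-classification fold: one class only")
    fit <- glmnet::glmnet(X[!hold, , drop = FALSE], ytr,
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE)
    p[hold] <- as.numeric(predict(fit, X[hold, , drop = FALSE],
                                  type = "response"))
  }
  pTarget <- p[seq_len(nTr)]
  pTrain <- 1 - pTarget
  l <- (nTr / nTg) * pTarget / pTrain
  l <- pmin(pmax(l, clip[1]), clip[2])
  methods::new("ShiftWeights", l = l, pTrain = pTrain, pTarget = pTarget,
               nTrain = nTr, nTarget = nTg, cost = C,
               CCS = nTr * C / sum(l))
}

#' Unit shift weights (no covariate shift)
#'
#' All weights 1, under which the covariate-shift objective is exactly the
#' plain SVM objective and the combined objective is exactly the weighted
#' one; \code{C_CS} equals \code{C}.
#'
#' @param n number of training instances.
#' @param C base SVM cost.
#' @return a [ShiftWeights-class].
#' @export
unitShiftWeights <- function(n, C = 1) {
  methods::new("ShiftWeights", l = rep(1, n), pTrain = rep(0.5, n),
               pTarget = rep(0.5, n), nTrain = as.integer(n),
               nTarget = as.integer(n), cost = C, CCS = C)
}
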