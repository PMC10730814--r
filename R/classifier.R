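# Nuclear-morphology classifiers: treated vs untreated nuclei.

#' The canonical nuclear morphology feature set
#'
#' Column names of the nucleus feature table used as classifier inputs:
#' the four volume variants, the three intensity statistics of the
#' nucleus's own channel, eccentricity, solidity, Euler number and the
#' three inertia tensor eigenvalues.
#'
#' @return character vector of column names.
#' @export
morphologyFeatureSet <- function() {
  c(
    "volume", "volume_filled", "volume_convex", "volume_bbox",
    "intensity_mean", "intensity_max", "intensity_min",
    "eccentricity", "solidity", "euler_number",
    "inertia_tensor_eigvals1", "inertia_tensor_eigvals2",
    "inertia_tensor_eigvals3"
  )
}

#' Stratified train/test split
#'
#' @param features data.frame including a binary label column.
#' @param labelCol name of the label column.
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list of data.frames `train` and `test`; class proportions are
#'   preserved per class (rounded).
#' @export
splitTrainTest <- function(features, labelCol = "label", fraction = 0.8,
                           seed = 1L) {
  y <- features[[labelCol]]
  classes <- unique(y)
  if (length(classes) < 2L) {
    stop("both classes must be present for a split")
  }
  set.seed(seed)
  trainIdx <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    sample(idx, round(fraction * length(idx)))
  }), use.names = FALSE)
  list(
    train = features[sort(trainIdx), , drop = FALSE],
    test = features[-sort(trainIdx), , drop = FALSE]
  )
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic with
#' mid-ranks for ties: the probability that a random positive scores above
#' a random negative (ties counting one half).
#'
#' @param scores numeric decision scores.
#' @param labels logical or 0/1 vector, TRUE/1 = positive.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes needed for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and evaluate a ridge logistic classifier
#'
#' L2-regularized (weak, fixed lambda) logistic regression on standardized
#' features. Standardization statistics are estimated on the training split
#' only and applied to the test split; constant training columns are
#' dropped with a warning. Held-out AUC is computed with the rank
#' statistic.
#'
#' @param train,test data.frames from [splitTrainTest()].
#' @param labelCol name of the binary label column (positive = the
#'   lexicographically larger level, or TRUE/1).
#' @param featureCols feature column names (default: all numeric columns
#'   except the label).
#' @param lambda ridge penalty (default 1e-3).
#' @return list with `auc`, `coefficients` (standardized scale, sorted by
#'   absolute value), `scores` and `labels` of the test split.
#' @export
trainEvalLogistic <- function(train, test, labelCol = "label",
                              featureCols = NULL, lambda = 1e-3) {
  if (is.null(featureCols)) {
    num <- vapply(train, is.numeric, logical(1))
    featureCols <- setdiff(names(train)[num], labelCol)
  }
  yTrain <- asBinary(train[[labelCol]])
  yTest <- asBinary(test[[labelCol]])
  xTrain <- as.matrix(train[, featureCols, drop = FALSE])
  xTest <- as.matrix(test[, featureCols, drop = FALSE])
  mu <- colMeans(xTrain)
  sdv <- apply(xTrain, 2, stats::sd)
  constant <- !is.finite(sdv) | sdv == 0
  if (any(constant)) {
    warning(
      "dropping constant feature column(s): ",
      paste(featureCols[constant], collapse = ", ")
    )
    xTrain <- xTrain[, !constant, drop = FALSE]
    xTest <- xTest[, !constant, drop = FALSE]
    mu <- mu[!constant]
    sdv <- sdv[!constant]
  }
  if (!ncol(xTrain)) stop("no usable feature columns")
  xTrain <- sweep(sweep(xTrain, 2, mu), 2, sdv, "/")
  xTest <- sweep(sweep(xTest, 2, mu), 2, sdv, "/")
  fit <- glmnet::glmnet(xTrain, yTrain,
    family = "binomial", alpha = 0,
    lambda = lambda, standardize = FALSE
  )
  scores <- as.numeric(stats::predict(fit, xTest, type = "link"))
  co <- as.numeric(stats::coef(fit))[-1]
  names(co) <- colnames(xTrain)
  list(
    auc = aucRank(scores, yTest),
    coefficients = co[order(abs(co), decreasing = TRUE)],
    scores = scores, labels = yTest
  )
}

asBinary <- function(y) {
  if (is.logical(y)) {
    return(as.integer(y))
  }
  if (is.numeric(y)) {
    return(as.integer(y != 0))
  }
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stop("label must be binary")
  as.integer(as.character(y) == lev[2])
}

#' ROC curve points
#'
#' @param scores,labels as in [aucRank()].
#' @return data.frame of (fpr, tpr) stepping through score thresholds from
#'   high to low.
#' @export
rocPoints <- function(scores, labels) {
  pos <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  data.frame(
    fpr = c(0, fp / sum(!pos)),
    tpr = c(0, tp / sum(pos))
  )
}
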