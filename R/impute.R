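# Imputation primitives. Observed (non-missing) cells are never altered.

#' Single-statistic imputation
#'
#' Replace each missing cell by the mean, median, or mode of the non-missing
#' cells. Mean and median require a numeric column; mode also serves
#' categorical columns.
#'
#' @param column Vector with at least one non-missing value.
#' @return The column with missing cells filled.
#' @examples
#' meanImpute(c(1, NA, 3))    # 1 2 3
#' medianImpute(c(1, 1, 9, NA))
#' modeImpute(c("a", "a", "b", NA))
#' @export
meanImpute <- function(column) {
  stopIfNot(any(!is.na(column)), "all-missing column")
  stopIfNot(is.numeric(column), "mean imputation requires a numeric column")
  column[is.na(column)] <- mean(column, na.rm = TRUE)
  column
}

#' @rdname meanImpute
#' @export
medianImpute <- function(column) {
  stopIfNot(any(!is.na(column)), "all-missing column")
  stopIfNot(is.numeric(column), "median imputation requires a numeric column")
  column[is.na(column)] <- stats::median(column, na.rm = TRUE)
  column
}

#' @rdname meanImpute
#' @export
modeImpute <- function(column) {
  stopIfNot(any(!is.na(column)), "all-missing column")
  column[is.na(column)] <- statMode(column)
  column
}

# z-score predictors on their observed values; missing predictor cells enter
# the distance at the column mean (z = 0), so on fully observed predictors
# this is plain Euclidean distance on z-scores.
zscorePredictors <- function(table, predictors) {
  z <- matrix(0, nrow(table), length(predictors),
              dimnames = list(NULL, predictors))
  for (j in seq_along(predictors)) {
    x <- table[[predictors[j]]]
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) s <- 1
    zx <- (x - mu) / s
    zx[is.na(zx)] <- 0
    z[, j] <- zx
  }
  z
}

#' K-nearest-neighbour imputation
#'
#' Each missing cell of the target attribute is replaced by the mean (numeric
#' target) or mode (categorical target) of its `k` nearest donor rows, where
#' distance is Euclidean on z-scored numeric predictors and donors are rows
#' with an observed target value. Equal distances are broken by lower row
#' index, making the result deterministic.
#'
#' @param table `data.frame` holding the target and predictor columns.
#' @param target Name of the attribute to impute.
#' @param k Number of neighbours (default 5); at least `k` donor rows must
#'   exist.
#' @return The imputed target column.
#' @examples
#' d <- data.frame(x = c(1, 2, 10), y = c(1.1, 2.2, NA))
#' knnImpute(d, "y", k = 1)
#' @export
knnImpute <- function(table, target, k = 5) {
  y <- table[[target]]
  stopIfNot(!is.null(y), paste("unknown attribute:", target))
  predictors <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        target)
  stopIfNot(length(predictors) > 0, "no numeric predictor attributes")
  donors <- which(!is.na(y))
  stopIfNot(length(donors) >= k,
            sprintf("fewer than k = %d rows with an observed target", k))
  z <- zscorePredictors(table, predictors)
  for (i in which(is.na(y))) {
    d2 <- colSums((t(z[donors, , drop = FALSE]) - z[i, ])^2)
    # order() is stable: ties fall to the lower donor row index
    nn <- donors[order(d2)][seq_len(k)]
    y[i] <- if (is.numeric(y)) mean(table[[target]][nn])
            else statMode(table[[target]][nn])
  }
  y
}

#' Multiple imputation by stochastic regression
#'
#' Proper multiple imputation for a numeric target: fits a linear regression
#' of the target on the z-scored numeric predictors over rows with an
#' observed target, then draws `m` imputations, each with the residual
#' variance drawn from its scaled inverse chi-squared posterior, the
#' coefficients from their sampling distribution, and independent residual
#' noise added to the predictions. The `m` imputed columns are pooled by
#' their mean. Following the principle that more missingness warrants more
#' imputations, `m` defaults to `max(5, round(100 * missingFraction))`.
#' Predictors are mean-completed before the fit, so column-wise missingness
#' in the predictors does not starve the regression of rows.
#'
#' @param table `data.frame` holding the target and predictor columns.
#' @param target Name of the numeric attribute to impute.
#' @param m Number of imputations (`NULL` for the default above).
#' @param seed Integer seed; the same seed reproduces the pooled column
#'   exactly.
#' @param maxPredictors Size cap for the imputation model: when more numeric
#'   predictors are available, the ones most correlated with the target
#'   (pairwise-complete) are kept.
#' @return List with `column` (pooled imputed column), `m`, and `spread`
#'   (per-missing-cell standard deviation across the `m` imputations).
#' @export
multipleImpute <- function(table, target, m = NULL, seed = 1,
                           maxPredictors = 10) {
  y <- table[[target]]
  stopIfNot(!is.null(y), paste("unknown attribute:", target))
  stopIfNot(is.numeric(y), "multiple imputation requires a numeric target")
  obs <- which(!is.na(y))
  stopIfNot(length(obs) >= 10, "need >= 10 rows with an observed target")
  mf <- mean(is.na(y))
  m <- m %||% max(5, round(100 * mf))
  mis <- which(is.na(y))
  if (length(mis) == 0L)
    return(list(column = y, m = m, spread = numeric(0)))

  predictors <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        target)
  # imputation-model predictor selection: keep the columns most correlated
  # with the target (pairwise-complete), so irrelevant predictors do not
  # attenuate the regression
  if (length(predictors) > maxPredictors) {
    r <- vapply(predictors, function(nm) {
      v <- suppressWarnings(stats::cor(table[[nm]], y,
                                       use = "pairwise.complete.obs"))
      if (is.na(v)) 0 else abs(v)
    }, numeric(1))
    predictors <- names(sort(r, decreasing = TRUE))[seq_len(maxPredictors)]
  }
  X <- cbind(1, zscorePredictors(table, predictors))
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  keep <- !is.na(fit$coefficients)
  Xk <- X[, keep, drop = FALSE]
  beta <- fit$coefficients[keep]
  df <- length(obs) - sum(keep)
  stopIfNot(df > 0, "too few observed rows for the predictor count")
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xk[obs, , drop = FALSE])))

  draws <- withSeed(seed, {
    vapply(seq_len(m), function(im) {
      s2 <- sigma2 * df / stats::rchisq(1, df)
      b <- MASS::mvrnorm(1, beta, s2 * XtXinv)
      as.numeric(Xk[mis, , drop = FALSE] %*% b) +
        stats::rnorm(length(mis), 0, sqrt(s2))
    }, numeric(length(mis)))
  })
  draws <- matrix(draws, nrow = length(mis))
  y[mis] <- rowMeans(draws)
  list(column = y, m = m, spread = apply(draws, 1, stats::sd))
}
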