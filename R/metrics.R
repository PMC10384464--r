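# Closed-form data-quality dimension metrics and the per-column statistics
# used by profiling. All fraction-valued metrics return values in [0, 1].

#' Completeness metric
#'
#' `1 - missingCount / totalCount`: the fraction of cells (or tuples) with a
#' value recorded.
#'
#' @param missingCount Non-negative count of null cells.
#' @param totalCount Positive total count.
#' @return Fraction in `[0, 1]`.
#' @examples
#' completenessMetric(3, 10)  # 0.7
#' @export
completenessMetric <- function(missingCount, totalCount) {
  stopIfNot(totalCount > 0, "totalCount must be positive")
  stopIfNot(missingCount >= 0 && missingCount <= totalCount,
            "missingCount must lie in [0, totalCount]")
  1 - missingCount / totalCount
}

#' Timeliness metric
#'
#' `max(1 - currency / volatility, 0)^s`: currency is the elapsed time since
#' the value was created, volatility its shelf life (same units), and the
#' exponent `s > 0` tunes the sensitivity of the decay (set from expert
#' judgment; default 1). The metric is 1 for fresh data, decays as currency
#' approaches volatility, and clamps at 0 once the shelf life is exceeded.
#'
#' @param currency Elapsed time (non-negative).
#' @param volatility Shelf life (positive, same units as `currency`).
#' @param s Positive exponent.
#' @return Fraction in `[0, 1]`.
#' @examples
#' timelinessMetric(1, 2, s = 2)  # 0.25
#' @export
timelinessMetric <- function(currency, volatility, s = 1) {
  stopIfNot(volatility > 0, "volatility must be positive")
  stopIfNot(s > 0, "exponent s must be positive")
  stopIfNot(currency >= 0, "currency must be non-negative")
  max(1 - currency / volatility, 0)^s
}

#' Correctness metric
#'
#' `1 / (d + 1)` for a domain-specific distance `d` between the stored value
#' and the corresponding real-world value: 1 iff the distance is zero,
#' strictly decreasing in the distance.
#'
#' @param distance Non-negative distance `d(w, wm)`.
#' @return Value in `(0, 1]`.
#' @examples
#' correctnessMetric(0)  # 1
#' correctnessMetric(3)  # 0.25
#' @export
correctnessMetric <- function(distance) {
  stopIfNot(distance >= 0, "distance must be non-negative")
  1 / (distance + 1)
}

#' Uniqueness metric
#'
#' Distinct non-missing values divided by the non-missing count: 1 when no
#' value repeats, approaching 0 under heavy duplication.
#'
#' @param column Vector; `NA` cells are dropped first.
#' @return Fraction in `(0, 1]`.
#' @examples
#' uniquenessMetric(c(1, 1, 1, 1))  # 0.25
#' @export
uniquenessMetric <- function(column) {
  x <- column[!is.na(column)]
  stopIfNot(length(x) > 0, "column has no non-missing values")
  length(unique(x)) / length(x)
}

#' Consistency as the coefficient of variation
#'
#' Sample standard deviation divided by the absolute mean, per attribute; a
#' lower CV after repair indicates improved consistency. Dataset-level
#' consistency reports aggregate the per-attribute CVs by their mean, and the
#' tolerance check maps the mean CV to `[0, 1]` as `1 / (1 + CV)` so that
#' higher is better, in line with the other dimensions.
#'
#' @param column Numeric vector with at least 2 non-missing values and
#'   nonzero mean.
#' @return Non-negative CV.
#' @examples
#' consistencyCV(c(1, 3))  # sqrt(2) / 2
#' @export
consistencyCV <- function(column) {
  x <- column[!is.na(column)]
  stopIfNot(length(x) >= 2, "need at least 2 non-missing values")
  m <- mean(x)
  stopIfNot(m != 0, "coefficient of variation undefined for zero mean")
  stats::sd(x) / abs(m)
}

#' Outlier fraction of a column
#'
#' Default method: fraction of non-missing values outside the Tukey fences
#' `[Q1 - k*IQR, Q3 + k*IQR]` (`k = 1.5`). Alternative `"zscore"`: fraction
#' with `|z| > k` (use `k = 3` for the conventional cut).
#'
#' @param column Numeric vector with at least 4 non-missing values for the
#'   IQR method.
#' @param method `"iqr"` (default) or `"zscore"`.
#' @param k Fence multiplier (IQR) or z cut.
#' @return Fraction in `[0, 1]`.
#' @examples
#' outlierFraction(c(1:10, 1000))  # 1/11
#' @export
outlierFraction <- function(column, method = c("iqr", "zscore"), k = NULL) {
  method <- match.arg(method)
  stopIfNot(is.numeric(column), "column must be numeric")
  x <- column[!is.na(column)]
  if (method == "iqr") {
    k <- k %||% 1.5
    stopIfNot(length(x) >= 4, "IQR method needs >= 4 non-missing values")
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    mean(x < q[1] - k * iqr | x > q[2] + k * iqr)
  } else {
    k <- k %||% 3
    stopIfNot(length(x) >= 2, "z-score method needs >= 2 non-missing values")
    s <- stats::sd(x)
    if (s == 0) return(0)
    mean(abs((x - mean(x)) / s) > k)
  }
}

#' Sample skewness
#'
#' Adjusted Fisher-Pearson standardized third moment,
#' `n / ((n-1)(n-2)) * sum((x - mean)^3) / s^3` with the sample (n-1)
#' standard deviation `s` - the estimator spreadsheet software and most
#' statistics packages report. Drives the skewed-vs-symmetric branch of the
#' missing-data rule table.
#'
#' @param column Numeric vector with at least 3 non-missing values and
#'   nonzero variance.
#' @return Dimensionless skewness (0 for a symmetric sample).
#' @examples
#' skewness(c(-1, 0, 1))  # 0
#' @export
skewness <- function(column) {
  x <- column[!is.na(column)]
  n <- length(x)
  stopIfNot(n >= 3, "need at least 3 non-missing values")
  s <- stats::sd(x)
  stopIfNot(s > 0, "skewness undefined for zero variance")
  n / ((n - 1) * (n - 2)) * sum((x - mean(x))^3) / s^3
}
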