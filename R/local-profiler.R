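# Client-side profiling: build an edge profile from an edge dataset and the
# baseline blueprint, and check dataset-level dimension tolerances.

#' Profile one attribute column
#'
#' Computes the full set of per-attribute statistics: observed range, mode,
#' skewness, missing/unique/outlier fractions, completeness, and coefficient
#' of variation. An all-missing column is flagged degenerate
#' (`missingFraction = 1`, numeric statistics undefined) rather than raising,
#' so the rule engine can still decide to drop it.
#'
#' @param column Vector (one dataset column); `NA` marks missing.
#' @param spec The attribute's [AttributeSpec-class] (drives type handling).
#' @return An [AttributeMeasures-class].
#' @examples
#' profileAttribute(c(1, 2, 3, NA), attributeSpec("x"))
#' @export
profileAttribute <- function(column, spec) {
  stopIfNot(length(column) > 0, "empty column")
  n <- length(column)
  x <- column[!is.na(column)]
  mf <- (n - length(x)) / n
  if (length(x) == 0L) {
    return(new("AttributeMeasures", missingFraction = 1, completeness = 0,
               degenerate = TRUE))
  }
  numericCol <- spec@dataType == "numeric" && is.numeric(column)
  m <- new("AttributeMeasures",
    observedMin = if (numericCol) min(x) else NA_real_,
    observedMax = if (numericCol) max(x) else NA_real_,
    mode = statMode(column),
    skewness = if (numericCol && length(x) >= 3 && stats::sd(x) > 0)
      skewness(column) else NA_real_,
    missingFraction = mf,
    uniqueFraction = uniquenessMetric(column),
    outlierFraction = if (numericCol && length(x) >= 4)
      outlierFraction(column) else NA_real_,
    completeness = 1 - mf,
    cv = if (numericCol && length(x) >= 2 && mean(x) != 0)
      consistencyCV(column) else NA_real_)
  validObject(m)
  m
}

#' Flag a column as missing-not-at-random
#'
#' Heuristic MNAR detector: a column is flagged when its missingness
#' indicator correlates (point-biserial `|r|` above `threshold`) with any
#' *other* observed attribute. Under MNAR the unobserved value drives its own
#' missingness, which leaves a correlation footprint on attributes the target
#' is correlated with; under MCAR no such footprint exists.
#'
#' @param table `data.frame` of the edge data.
#' @param attribute Name of the column to test.
#' @param threshold Absolute correlation cut (default 0.3).
#' @return Logical flag.
#' @export
flagMNAR <- function(table, attribute, threshold = 0.3) {
  ind <- as.numeric(is.na(table[[attribute]]))
  if (stats::sd(ind) == 0) return(FALSE)
  others <- setdiff(names(table), attribute)
  for (nm in others) {
    x <- table[[nm]]
    if (!is.numeric(x)) next
    ok <- !is.na(x)
    if (sum(ok) < 10 || stats::sd(x[ok]) == 0 || stats::sd(ind[ok]) == 0) next
    r <- stats::cor(ind[ok], x[ok])
    if (!is.na(r) && abs(r) > threshold) return(TRUE)
  }
  FALSE
}

#' Build an edge data-quality profile
#'
#' Applies the baseline blueprint to one node's data: measures every baseline
#' attribute with [profileAttribute()], flags MNAR columns, and returns an
#' edge-role profile that inherits the baseline's version, weights,
#' tolerances, and rules unchanged. The baseline is never mutated.
#'
#' @param dataset An [EdgeDataset-class] whose attributes cover the
#'   baseline's.
#' @param baseline The baseline [DQProfile-class].
#' @param workload Optional [WorkloadStub-class] to attach.
#' @return A [DQProfile-class] with role `"edge"`.
#' @examples
#' ds <- edgeDataset("n1", data.frame(a = c(1, 2, NA)), c("x", "y", "x"))
#' ep <- buildEdgeProfile(ds, initializeProfile("a"))
#' profileMeasures(ep)$a
#' @export
buildEdgeProfile <- function(dataset, baseline, workload = NULL) {
  stopIfNot(baseline@role == "baseline",
            "baseline profile must have role 'baseline'")
  tab <- edgeTable(dataset)
  absent <- setdiff(attributeNames(baseline), names(tab))
  if (length(absent))
    stop("attribute(s) in baseline but absent from the dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)

  measures <- list()
  for (a in baseline@attributes) {
    m <- profileAttribute(tab[[a@name]], a)
    if (m@missingFraction > 0 && !m@degenerate)
      m@mnar <- flagMNAR(tab[attributeNames(baseline)], a@name)
    measures[[a@name]] <- m
  }

  prof <- baseline
  prof@role <- "edge"
  prof@nodeId <- nodeId(dataset)
  prof@rowCount <- nrow(tab)
  prof@measures <- measures
  if (!is.null(workload)) prof@workload <- workload
  prof
}

# Dataset-level measured value for one dimension, from an edge/federated
# profile's per-attribute measures; NA when the dimension has no measured
# counterpart in the pipeline (accuracy, timeliness, validity).
datasetDimensionValue <- function(profile, dimension) {
  ms <- profile@measures
  switch(dimension,
    completeness = 1 - mean(vapply(ms, function(m) m@missingFraction,
                                   numeric(1))),
    uniqueness = {
      u <- vapply(ms, function(m) m@uniqueFraction, numeric(1))
      if (all(is.na(u))) NA_real_ else mean(u, na.rm = TRUE)
    },
    consistency = {
      cvs <- vapply(ms, function(m) m@cv, numeric(1))
      if (all(is.na(cvs))) NA_real_ else 1 / (1 + mean(cvs, na.rm = TRUE))
    },
    NA_real_)
}

# Dataset-level tolerance for a dimension: mean of the per-attribute
# tolerances that declare it (NA when none does).
datasetDimensionTolerance <- function(profile, dimension) {
  tols <- vapply(profile@attributes, function(a) {
    if (dimension %in% names(a@tolerances)) a@tolerances[[dimension]]
    else NA_real_
  }, numeric(1))
  if (all(is.na(tols))) NA_real_ else mean(tols, na.rm = TRUE)
}

#' Check dataset-level dimension tolerances
#'
#' Compares each profiled dimension's measured dataset-level value against
#' its tolerance. Completeness is `1 -` mean missing fraction, uniqueness the
#' mean unique fraction, and consistency the bounded transform
#' `1 / (1 + mean CV)` so that higher is better for every dimension. A node
#' passes a dimension when the measured value is at or above the tolerance
#' (equality passes, so boundary nodes are not eliminated on float noise);
#' `overallPass` is the conjunction. Dimensions with no configured tolerance
#' or no measurable value are skipped with a warning, not an error.
#'
#' @param edgeProfile A measured [DQProfile-class] (edge or federated role).
#' @param dimensions Dimensions to check (default: the profile's).
#' @return A `ToleranceReport`: list with `table` (dimension, measured,
#'   tolerance, pass) and `overallPass`.
#' @seealso [selectNodes()]
#' @export
checkDimensionTolerances <- function(edgeProfile,
                                     dimensions = profileDimensions(edgeProfile)) {
  stopIfNot(length(edgeProfile@measures) > 0,
            "profile carries no measures; build an edge profile first")
  rows <- list()
  for (d in dimensions) {
    tol <- datasetDimensionTolerance(edgeProfile, d)
    if (is.na(tol)) {
      warning("dimension '", d, "' has no configured tolerance; skipped",
              call. = FALSE)
      next
    }
    val <- datasetDimensionValue(edgeProfile, d)
    if (is.na(val)) {
      warning("dimension '", d, "' has no measured value in this pipeline; ",
              "skipped", call. = FALSE)
      next
    }
    rows[[d]] <- data.frame(dimension = d, measured = val, tolerance = tol,
                            pass = val >= tol, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(dimension = character(), measured = numeric(),
                         tolerance = numeric(), pass = logical())
  rownames(tab) <- NULL
  structure(list(nodeId = edgeProfile@nodeId, table = tab,
                 overallPass = all(tab$pass)),
            class = "ToleranceReport")
}

#' @export
print.ToleranceReport <- function(x, ...) {
  cat(sprintf("ToleranceReport for node '%s': %s\n", x$nodeId,
              if (x$overallPass) "PASS" else "FAIL"))
  print(x$table, row.names = FALSE)
  invisible(x)
}
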