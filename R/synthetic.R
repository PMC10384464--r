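# Synthetic multi-edge cohort generator. Emulates the shape and statistical
# structure of a fetal cardiotocography-style monitoring cohort (about 2100
# rows split over 5 edges, 22 numeric channels, 3 imbalanced outcome
# classes) with controlled missingness (MCAR/MAR/MNAR), outlier injection,
# and deliberate node corruption, so every pipeline stage is testable
# without any data download. All generators are pure functions of
# (spec, seed); injections draw from per-operator substreams.

#' Cohort specification
#'
#' Defaults describe the study conditions the package is exercised under:
#' 5 edges of 425 rows, 22 numeric features, class proportions
#' 0.78/0.14/0.08 (normal/suspect/pathologic), class separation 1.5 standard
#' deviations, and block-exchangeable within-class feature correlation 0.6
#' in blocks of 5 (correlated physiological channels).
#'
#' @param nEdges Number of edge nodes.
#' @param rowsPerEdge Rows per edge.
#' @param nFeatures Numeric feature count.
#' @param classProportions Named fractions summing to 1.
#' @param classSeparation Between-class mean separation in units of the
#'   feature standard deviation.
#' @param featureCorrelation Within-block feature correlation.
#' @param blockSize Features per correlation block.
#' @param seed Master seed.
#' @return A `CohortSpec` list.
#' @examples cohortSpec(seed = 7)
#' @export
cohortSpec <- function(nEdges = 5, rowsPerEdge = 425, nFeatures = 22,
                       classProportions = c(N = 0.78, S = 0.14, P = 0.08),
                       classSeparation = 1.5, featureCorrelation = 0.6,
                       blockSize = 5, seed = 1) {
  stopIfNot(nEdges >= 1 && rowsPerEdge >= 2 && nFeatures >= 1,
            "all counts must be positive")
  stopIfNot(abs(sum(classProportions) - 1) < 1e-9,
            "class proportions must sum to 1")
  stopIfNot(classSeparation >= 0, "classSeparation must be non-negative")
  structure(list(nEdges = nEdges, rowsPerEdge = rowsPerEdge,
                 nFeatures = nFeatures, classProportions = classProportions,
                 classSeparation = classSeparation,
                 featureCorrelation = featureCorrelation,
                 blockSize = blockSize, seed = as.integer(seed)),
            class = "CohortSpec")
}

blockCorrelation <- function(p, rho, blockSize) {
  R <- diag(p)
  for (start in seq(1, p, by = blockSize)) {
    idx <- start:min(start + blockSize - 1, p)
    R[idx, idx] <- rho
  }
  diag(R) <- 1
  R
}

#' Generate a multi-edge labeled cohort
#'
#' Draws class-conditional multivariate Gaussian features: per-feature base
#' means from U(20, 120) and standard deviations from U(1, 10) (positive
#' physiological-scale values, so coefficients of variation are
#' well-defined), class means displaced by `classSeparation` standard
#' deviations along random unit directions, and block-exchangeable
#' within-class correlation. Every edge draws i.i.d. from the same
#' distribution; the whole cohort is reproducible from the seed.
#'
#' @param spec A [cohortSpec()].
#' @return Named list of clean [EdgeDataset-class]s (`node1`, `node2`, ...).
#' @examples
#' edges <- generateCohort(cohortSpec(nEdges = 2, rowsPerEdge = 50,
#'                                    nFeatures = 4, seed = 1))
#' rowCount(edges$node1)
#' @export
generateCohort <- function(spec) {
  stopIfNot(inherits(spec, "CohortSpec"), "spec must be a CohortSpec")
  p <- spec$nFeatures
  classes <- names(spec$classProportions)
  stopIfNot(!is.null(classes), "classProportions must be named")
  withSeed(substreamSeed(spec$seed, "cohort"), {
    mu0 <- stats::runif(p, 20, 120)
    sds <- stats::runif(p, 1, 10)
    dirs <- lapply(classes, function(cl) {
      v <- stats::rnorm(p)
      v / sqrt(sum(v^2))
    })
    names(dirs) <- classes
    R <- blockCorrelation(p, spec$featureCorrelation, spec$blockSize)
    CH <- chol(R)
    featNames <- sprintf("x%02d", seq_len(p))

    edges <- lapply(seq_len(spec$nEdges), function(e) {
      n <- spec$rowsPerEdge
      labels <- sample(classes, n, replace = TRUE,
                       prob = spec$classProportions)
      Z <- matrix(stats::rnorm(n * p), n, p) %*% CH
      X <- Z * rep(sds, each = n)
      for (cl in classes) {
        rows <- labels == cl
        shift <- mu0 + spec$classSeparation * sds * dirs[[cl]]
        X[rows, ] <- X[rows, , drop = FALSE] + rep(shift, each = sum(rows))
      }
      colnames(X) <- featNames
      edgeDataset(paste0("node", e), as.data.frame(X), labels,
                  metadata = list(spec = spec))
    })
    names(edges) <- paste0("node", seq_len(spec$nEdges))
    edges
  })
}

# Solve the logistic intercept so that the mean missingness equals `rate`
# given a standardized driver z and slope b.
logisticIntercept <- function(z, b, rate) {
  f <- function(a) mean(stats::plogis(a + b * z)) - rate
  stats::uniroot(f, c(-50, 50))$root
}

#' Inject missing values
#'
#' Masks cells under one of three mechanisms: `MCAR` (each cell
#' independently missing at its column rate), `MAR` (missing probability
#' logistic in the next observed column, cyclically), `MNAR` (logistic in
#' the cell's own value with a steep slope, so missingness is systematic in
#' the unobserved value). Realized per-column rates are recorded in the
#' dataset metadata.
#'
#' @param dataset An [EdgeDataset-class].
#' @param rates Scalar or per-feature missing rate(s) in `[0, 1]`.
#' @param mechanism `"MCAR"`, `"MAR"`, or `"MNAR"`.
#' @param seed Master seed (substream derived from the node id).
#' @param columns Columns to affect (default: all numeric).
#' @return The dataset with masked cells and updated metadata.
#' @export
injectMissing <- function(dataset, rates, mechanism = c("MCAR", "MAR", "MNAR"),
                          seed = 1, columns = NULL) {
  mechanism <- match.arg(mechanism)
  tab <- edgeTable(dataset)
  columns <- columns %||% names(tab)[vapply(tab, is.numeric, logical(1))]
  stopIfNot(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  rates <- rep_len(rates, length(columns))
  names(rates) <- columns

  realized <- stats::setNames(numeric(length(columns)), columns)
  withSeed(substreamSeed(seed, "missing", nodeId(dataset)), {
    for (j in seq_along(columns)) {
      nm <- columns[j]
      rate <- rates[j]
      if (rate == 0) next
      x <- tab[[nm]]
      n <- length(x)
      pMiss <- switch(mechanism,
        MCAR = rep(rate, n),
        MAR = {
          drv <- tab[[columns[if (j == length(columns)) 1 else j + 1]]]
          z <- as.numeric(scale(drv))
          z[is.na(z)] <- 0
          stats::plogis(logisticIntercept(z, 2, rate) + 2 * z)
        },
        MNAR = {
          z <- as.numeric(scale(x))
          z[is.na(z)] <- 0
          stats::plogis(logisticIntercept(z, 4, rate) + 4 * z)
        })
      mask <- stats::runif(n) < pMiss
      x[mask] <- NA
      tab[[nm]] <- x
      realized[nm] <- mean(is.na(x))
    }
  })
  md <- edgeMetadata(dataset)
  md$missing <- list(mechanism = mechanism, targetRates = rates,
                     realizedRates = realized)
  edgeDataset(nodeId(dataset), tab, edgeLabels(dataset), md)
}

#' Inject outliers
#'
#' Displaces a random fraction of cells to `scale` column-IQRs beyond the
#' nearer Tukey fence (the upper fence for cells above the median, the lower
#' fence otherwise). The displaced cells are logged in the metadata
#' bookkeeping.
#'
#' @param dataset An [EdgeDataset-class] with numeric features.
#' @param rate Fraction of cells to displace per column.
#' @param scale IQR multiples beyond the fence.
#' @param seed Master seed.
#' @param columns Columns to affect (default: all numeric).
#' @return The dataset with displaced cells and a `metadata$outliers` log
#'   (`data.frame`: row, column, old, new).
#' @export
injectOutliers <- function(dataset, rate = 0.03, scale = 3, seed = 1,
                           columns = NULL) {
  stopIfNot(rate >= 0 && rate <= 1, "rate must lie in [0, 1]")
  tab <- edgeTable(dataset)
  columns <- columns %||% names(tab)[vapply(tab, is.numeric, logical(1))]
  log <- list()
  withSeed(substreamSeed(seed, "outliers", nodeId(dataset)), {
    for (nm in columns) {
      if (rate == 0) next
      x <- tab[[nm]]
      obs <- which(!is.na(x))
      nOut <- round(rate * length(obs))
      if (nOut == 0) next
      q <- stats::quantile(x[obs], c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      if (iqr == 0) iqr <- max(stats::sd(x[obs]), 1)
      cells <- sample(obs, nOut)
      old <- x[cells]
      upper <- old >= q[2]
      x[cells] <- ifelse(upper, q[3] + 1.5 * iqr + scale * iqr,
                         q[1] - 1.5 * iqr - scale * iqr)
      log[[nm]] <- data.frame(row = cells, column = nm, old = old,
                              new = x[cells], stringsAsFactors = FALSE)
      tab[[nm]] <- x
    }
  })
  md <- edgeMetadata(dataset)
  md$outliers <- if (length(log)) do.call(rbind, c(log, make.row.names = FALSE))
                 else data.frame(row = integer(), column = character(),
                                 old = numeric(), new = numeric())
  edgeDataset(nodeId(dataset), tab, edgeLabels(dataset), md)
}

#' Corrupt one node
#'
#' Degrades a dataset so that its dataset-level completeness falls below
#' `1 - severity`: every numeric column is masked up to an exact count of
#' `ceiling((severity + 0.05) * n)` missing cells, and Gaussian value noise
#' with standard deviation `2 * severity` column-sd is added to a `severity`
#' fraction of the surviving cells. With a completeness tolerance of 0.70
#' the node is guaranteed to fail whenever `severity >= 0.35`, and the
#' pass/fail decision flips exactly once as severity sweeps upward.
#'
#' @param dataset An [EdgeDataset-class].
#' @param severity Fraction in `(0, 1]`.
#' @param seed Master seed.
#' @return The corrupted dataset (metadata records the severity).
#' @export
corruptNode <- function(dataset, severity, seed = 1) {
  stopIfNot(severity > 0 && severity <= 1, "severity must lie in (0, 1]")
  tab <- edgeTable(dataset)
  columns <- names(tab)[vapply(tab, is.numeric, logical(1))]
  withSeed(substreamSeed(seed, "corrupt", nodeId(dataset)), {
    for (nm in columns) {
      x <- tab[[nm]]
      n <- length(x)
      target <- min(n - 1L, ceiling((severity + 0.05) * n))
      need <- target - sum(is.na(x))
      if (need > 0) {
        obs <- which(!is.na(x))
        x[sample(obs, need)] <- NA
      }
      obs <- which(!is.na(x))
      noisy <- sample(obs, round(severity * length(obs)))
      s <- stats::sd(x[obs])
      if (is.na(s) || s == 0) s <- 1
      x[noisy] <- x[noisy] + stats::rnorm(length(noisy), 0, 2 * severity * s)
      tab[[nm]] <- x
    }
  })
  md <- edgeMetadata(dataset)
  md$corruption <- list(severity = severity)
  edgeDataset(nodeId(dataset), tab, edgeLabels(dataset), md)
}

#' Simulate the standard multi-edge profiling scenario
#'
#' One call that builds the whole test bed: a clean cohort from
#' [generateCohort()], per-column MCAR rates drawn once from
#' U(`rateRange`) and applied identically at every edge, optional outlier
#' injection, optional corruption of one node, and a matching baseline
#' profile (uniform weights; completeness tolerance 0.70, consistency 0.20,
#' uniqueness 0.05).
#'
#' @param seed Master seed.
#' @param spec A [cohortSpec()] (defaults to the standard shape with this
#'   seed).
#' @param rateRange Range the per-column MCAR rates are drawn from.
#' @param outlierRate,outlierScale Outlier injection parameters (rate 0
#'   disables).
#' @param corruptedNode Index of the node to corrupt (`NULL` for none).
#' @param severity Corruption severity.
#' @return List with `edges` (corrupted [EdgeDataset-class]s), `clean` (the
#'   pre-injection cohort), `baseline` (the baseline [DQProfile-class]), and
#'   `rates` (the per-column MCAR rates).
#' @examples
#' sc <- simulateScenario(seed = 1, spec = cohortSpec(nEdges = 2,
#'   rowsPerEdge = 60, nFeatures = 4, seed = 1), corruptedNode = NULL)
#' names(sc$edges)
#' @export
simulateScenario <- function(seed = 1, spec = cohortSpec(seed = seed),
                             rateRange = c(0.05, 0.30), outlierRate = 0.03,
                             outlierScale = 3,
                             corruptedNode = if (spec$nEdges >= 3) 3 else NULL,
                             severity = 0.4) {
  clean <- generateCohort(spec)
  rates <- withSeed(substreamSeed(seed, "rates"),
                    stats::runif(spec$nFeatures, rateRange[1], rateRange[2]))
  edges <- lapply(clean, injectMissing, rates = rates, mechanism = "MCAR",
                  seed = seed)
  if (outlierRate > 0)
    edges <- lapply(edges, injectOutliers, rate = outlierRate,
                    scale = outlierScale, seed = seed)
  if (!is.null(corruptedNode)) {
    stopIfNot(corruptedNode >= 1 && corruptedNode <= length(edges),
              "corruptedNode out of range")
    edges[[corruptedNode]] <- corruptNode(edges[[corruptedNode]], severity,
                                          seed = seed)
  }
  baseline <- initializeProfile(
    attributeNames(clean[[1]]),
    dimensions = c("completeness", "uniqueness", "consistency"),
    tolerances = c(completeness = 0.70, consistency = 0.20,
                   uniqueness = 0.05))
  list(edges = edges, clean = clean, baseline = baseline, rates = rates)
}

#' Write / read an edge dataset as CSV
#'
#' CSV dialect: header row, one `label` column, empty cells or `NA` mark
#' missing values. The same seed therefore produces byte-identical files.
#'
#' @param dataset An [EdgeDataset-class].
#' @param file Path.
#' @param labelColumn Name for the label column.
#' @return `writeEdgeCSV()`: the path, invisibly. `readEdgeCSV()`: an
#'   [EdgeDataset-class].
#' @export
writeEdgeCSV <- function(dataset, file, labelColumn = "label") {
  tab <- edgeTable(dataset)
  stopIfNot(!labelColumn %in% names(tab),
            "label column name collides with a feature")
  tab[[labelColumn]] <- edgeLabels(dataset)
  utils::write.csv(tab, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname writeEdgeCSV
#' @param nodeId Node identifier for the read dataset (default: file name
#'   without extension).
#' @export
readEdgeCSV <- function(file, labelColumn = "label", nodeId = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  stopIfNot(labelColumn %in% names(tab),
            paste("no label column", labelColumn, "in", file))
  labels <- as.character(tab[[labelColumn]])
  tab[[labelColumn]] <- NULL
  edgeDataset(nodeId %||% sub("\\.[^.]*$", "", basename(file)), tab, labels)
}
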