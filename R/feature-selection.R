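# Federated feature selection: per-node quality criteria (feature value,
# outlier percentage, missing percentage) are summed across nodes, ranked,
# and the per-criterion ranks summed into the federated feature rank -
# lower is better.

#' Per-node feature statistics for federated feature selection
#'
#' Computes, for every feature of one edge, the three selection criteria:
#' the feature value (default: ANOVA F statistic of the feature against the
#' class label, computed on observed cells; alternative: a mutual-information
#' estimate on equal-frequency bins), the outlier fraction, and the missing
#' fraction (the latter two from the node's measured profile when given,
#' otherwise from the data).
#'
#' @param dataset An [EdgeDataset-class].
#' @param profile Optional measured [DQProfile-class] for the node.
#' @param scorer `"anova"` (default) or `"mi"`.
#' @param bins Bin count for the mutual-information scorer.
#' @return `data.frame` with columns `feature`, `featureValue`, `outlierPct`,
#'   `missingPct`.
#' @export
featureStats <- function(dataset, profile = NULL,
                         scorer = c("anova", "mi"), bins = 10) {
  scorer <- match.arg(scorer)
  tab <- edgeTable(dataset)
  labels <- edgeLabels(dataset)
  feats <- names(tab)[vapply(tab, is.numeric, logical(1))]
  rows <- lapply(feats, function(nm) {
    x <- tab[[nm]]
    ok <- !is.na(x)
    fv <- if (sum(ok) >= 3 && length(unique(labels[ok])) >= 2 &&
              stats::sd(x[ok]) > 0) {
      if (scorer == "anova") anovaF(x[ok], labels[ok])
      else binnedMI(x[ok], labels[ok], bins)
    } else 0
    m <- if (!is.null(profile)) profile@measures[[nm]] else NULL
    outl <- if (!is.null(m) && !is.na(m@outlierFraction)) m@outlierFraction
            else if (sum(ok) >= 4) outlierFraction(x) else 0
    miss <- if (!is.null(m)) m@missingFraction else mean(is.na(x))
    data.frame(feature = nm, featureValue = fv, outlierPct = outl,
               missingPct = miss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

anovaF <- function(x, g) {
  fit <- stats::lm(x ~ factor(g))
  fv <- stats::anova(fit)[["F value"]][1]
  if (is.na(fv)) 0 else fv
}

# Mutual information between a numeric feature (equal-frequency binned) and
# the class label, in nats.
binnedMI <- function(x, g, bins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  if (length(br) < 2) return(0)
  xb <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(xb, g)
  p <- tab / sum(tab)
  px <- rowSums(p); pg <- colSums(p)
  e <- outer(px, pg)
  sum(p[p > 0] * log(p[p > 0] / e[p > 0]))
}

stableRank <- function(key) {
  # rank 1 = smallest key; ties broken by position (stable), so each rank
  # column is a permutation of 1..N
  r <- integer(length(key))
  r[order(key, seq_along(key))] <- seq_along(key)
  r
}

#' Rank features from aggregated criterion ranks
#'
#' Sums the three per-criterion rank columns into the federated feature rank
#' and orders features ascending by it (lower = more valuable). Equal
#' federated ranks are broken by the feature-value rank, then the outlier
#' rank, then the missing rank. The first `featureTol` features are marked
#' selected.
#'
#' @param valueRank,outlierRank,missingRank Integer rank vectors (1 = best:
#'   most feature value, least outliers, least missing).
#' @param features Feature names.
#' @param featureTol Maximum number of features to select.
#' @return A `FeatureRankTable` `data.frame` with columns `feature`,
#'   `valueRank`, `outlierRank`, `missingRank`, `federatedRank`, `selected`,
#'   ordered best to worst.
#' @examples
#' federatedFeatureRank(c(3, 5, 9, 1, 7), c(1, 4, 8, 2, 23),
#'                      c(8, 7, 2, 5, 13), features = LETTERS[1:5],
#'                      featureTol = 3)
#' @export
federatedFeatureRank <- function(valueRank, outlierRank, missingRank,
                                 features = NULL,
                                 featureTol = length(valueRank)) {
  n <- length(valueRank)
  stopIfNot(length(outlierRank) == n && length(missingRank) == n,
            "rank vectors must have equal length")
  stopIfNot(featureTol >= 1, "featureTol must be at least 1")
  features <- features %||% paste0("f", seq_len(n))
  fed <- as.integer(valueRank) + as.integer(outlierRank) +
    as.integer(missingRank)
  ord <- order(fed, valueRank, outlierRank, missingRank, seq_len(n))
  out <- data.frame(feature = features, valueRank = as.integer(valueRank),
                    outlierRank = as.integer(outlierRank),
                    missingRank = as.integer(missingRank),
                    federatedRank = fed, stringsAsFactors = FALSE)[ord, ]
  out$selected <- seq_len(n) <= featureTol
  rownames(out) <- NULL
  class(out) <- c("FeatureRankTable", "data.frame")
  out
}

#' Federated feature selection across edge nodes
#'
#' Sums each feature's criteria (feature value, outlier fraction, missing
#' fraction) across the participating nodes, ranks the summed criteria
#' (feature value descending - rank 1 is the largest; outliers and missing
#' ascending - rank 1 is the smallest), sums the three ranks into the
#' federated feature rank, and selects the `featureTol` best-ranked features.
#'
#' @param statsList List of per-node `data.frame`s as returned by
#'   [featureStats()]; every node must report all three criteria for the
#'   same feature set.
#' @param featureTol Maximum number of features to select.
#' @return A `FeatureRankTable` (see [federatedFeatureRank()]) with the
#'   aggregated criteria attached as attribute `"aggregated"`.
#' @export
federatedFeatureSelection <- function(statsList, featureTol) {
  stopIfNot(length(statsList) >= 1, "need at least one node's statistics")
  feats <- statsList[[1]]$feature
  for (s in statsList)
    if (!identical(sort(s$feature), sort(feats)))
      stop("inconsistent feature sets across nodes", call. = FALSE)
  agg <- Reduce(`+`, lapply(statsList, function(s) {
    s <- s[match(feats, s$feature), ]
    as.matrix(s[, c("featureValue", "outlierPct", "missingPct")])
  }))
  tab <- federatedFeatureRank(
    valueRank = stableRank(-agg[, "featureValue"]),
    outlierRank = stableRank(agg[, "outlierPct"]),
    missingRank = stableRank(agg[, "missingPct"]),
    features = feats, featureTol = featureTol)
  attr(tab, "aggregated") <- data.frame(feature = feats,
                                        featureValue = agg[, "featureValue"],
                                        outlierPct = agg[, "outlierPct"],
                                        missingPct = agg[, "missingPct"],
                                        row.names = NULL)
  tab
}
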