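# Patient-similarity evaluation harness: Gaussian-kernel similarity, a
# most-similar-patient (leave-one-out 1-NN) label prediction, and the
# federated aggregation of per-edge accuracies. This is the stopping signal
# of the federation loop and the pre/post-profiling comparison surface.

#' Gaussian-kernel patient similarity matrix
#'
#' `S[i, j] = exp(-||z_i - z_j||^2 / (2 * sigma^2))` on z-scored numeric
#' features; zero-variance columns are dropped before scaling. The default
#' bandwidth `sigma` is the median pairwise Euclidean distance, a standard
#' heuristic that keeps the kernel informative across scales.
#'
#' @param table Complete (no missing cells) numeric `data.frame` or matrix
#'   with at least 2 rows.
#' @param bandwidth Kernel bandwidth `sigma` (`NULL` for the median
#'   heuristic).
#' @return A `SimilarityMatrix`: symmetric matrix with unit diagonal and
#'   entries in `[0, 1]`.
#' @examples
#' similarityMatrix(data.frame(a = c(1, 1, 5), b = c(2, 2, 9)))
#' @export
similarityMatrix <- function(table, bandwidth = NULL) {
  m <- as.matrix(table)
  stopIfNot(is.numeric(m), "table must be numeric")
  stopIfNot(nrow(m) >= 2, "need at least 2 rows")
  if (anyNA(m))
    stop("missing cells present; repair the data before similarity",
         call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  keep <- sds > 0
  stopIfNot(any(keep), "all columns have zero variance")
  z <- scale(m[, keep, drop = FALSE])
  d <- as.matrix(stats::dist(z))
  sigma <- bandwidth %||% stats::median(d[upper.tri(d)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  s <- exp(-d^2 / (2 * sigma^2))
  diag(s) <- 1
  class(s) <- c("SimilarityMatrix", class(s))
  attr(s, "bandwidth") <- sigma
  s
}

#' Most-similar-patient label prediction
#'
#' Leave-one-out 1-nearest-neighbour on the similarity matrix: each row is
#' predicted as the label of its most similar *other* row; ties go to the
#' lower row index.
#'
#' @param S Similarity matrix (from [similarityMatrix()]).
#' @param labels One class label per row.
#' @return Character vector of predicted labels.
#' @export
mostSimilarPrediction <- function(S, labels) {
  n <- nrow(S)
  stopIfNot(n >= 2, "need at least 2 rows")
  stopIfNot(length(labels) == n, "labels length must equal the row count")
  labels <- as.character(labels)
  s <- unclass(S)
  diag(s) <- -Inf
  # which.max returns the first maximum: ties break to the lower row index
  labels[apply(s, 1, which.max)]
}

#' Patient-similarity accuracy of one table
#'
#' Convenience wrapper: similarity matrix, most-similar prediction, and the
#' fraction of rows whose predicted label matches their own.
#'
#' @inheritParams similarityMatrix
#' @param labels One class label per row.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
psnAccuracy <- function(table, labels, bandwidth = NULL) {
  S <- similarityMatrix(table, bandwidth)
  mean(mostSimilarPrediction(S, labels) == as.character(labels))
}

#' Federate per-edge accuracies
#'
#' Row-count-weighted mean of the per-edge accuracies; equals the plain mean
#' for equal counts.
#'
#' @param accuracies Per-edge accuracy fractions.
#' @param counts Positive per-edge row counts.
#' @return A `FederatedScore`: list with `perEdge`, `weights`, and
#'   `federatedAccuracy`.
#' @examples
#' federatedAccuracy(c(0.8, 0.9), c(100, 300))$federatedAccuracy  # 0.875
#' @export
federatedAccuracy <- function(accuracies, counts) {
  stopIfNot(length(accuracies) >= 1, "empty input")
  stopIfNot(length(accuracies) == length(counts),
            "accuracies and counts must have equal length")
  stopIfNot(all(counts > 0), "counts must be positive")
  structure(list(perEdge = accuracies, weights = counts,
                 federatedAccuracy = sum(accuracies * counts) / sum(counts)),
            class = "FederatedScore")
}

#' @export
print.FederatedScore <- function(x, ...) {
  cat(sprintf("FederatedScore: %.4f over %d edge(s)\n",
              x$federatedAccuracy, length(x$perEdge)))
  invisible(x)
}

# Naive completion used only to make the *pre-repair* (corrupted) side of a
# comparison PSN-computable: global column-mean fill (mode for categorical).
naiveComplete <- function(table) {
  for (nm in names(table)) {
    x <- table[[nm]]
    if (!anyNA(x)) next
    if (all(is.na(x))) { table[[nm]] <- NULL; next }
    table[[nm]] <- if (is.numeric(x)) meanImpute(x) else modeImpute(x)
  }
  table
}

#' Compare patient-similarity accuracy before and after profiling
#'
#' Evaluates each edge's most-similar-patient accuracy on the raw
#' (corrupted) data and on the quality-enriched data, plus the federated
#' (row-count-weighted) accuracies and their delta. Raw tables are naively
#' column-mean completed so the kernel is computable; enriched tables must
#' already be complete. Enriched edges are matched to raw edges by node id
#' and may be a subset (eliminated nodes contribute to the pre side only,
#' with `NA` in the post column).
#'
#' @param edgesRaw List of raw [EdgeDataset-class]s.
#' @param edgesEnriched List of enriched [EdgeDataset-class]s (matched
#'   subset).
#' @return List with `perEdge` (`data.frame`: nodeId, nPre, nPost, accPre,
#'   accPost, delta), `federatedPre`, `federatedPost`, and `delta`.
#' @export
comparePrePost <- function(edgesRaw, edgesEnriched) {
  rawIds <- vapply(edgesRaw, nodeId, character(1))
  enrIds <- vapply(edgesEnriched, nodeId, character(1))
  stopIfNot(all(enrIds %in% rawIds),
            "every enriched edge must match a raw edge by node id")
  names(edgesRaw) <- rawIds
  names(edgesEnriched) <- enrIds

  rows <- lapply(rawIds, function(id) {
    raw <- edgesRaw[[id]]
    accPre <- psnAccuracy(naiveComplete(edgeTable(raw)), edgeLabels(raw))
    if (id %in% enrIds) {
      enr <- edgesEnriched[[id]]
      stopIfNot(rowCount(enr) == length(edgeLabels(enr)),
                "enriched labels out of step with enriched rows")
      accPost <- psnAccuracy(edgeTable(enr), edgeLabels(enr))
      nPost <- rowCount(enr)
    } else {
      accPost <- NA_real_
      nPost <- NA_integer_
    }
    data.frame(nodeId = id, nPre = rowCount(raw), nPost = nPost,
               accPre = accPre, accPost = accPost, delta = accPost - accPre,
               stringsAsFactors = FALSE)
  })
  perEdge <- do.call(rbind, rows)
  rownames(perEdge) <- NULL
  fedPre <- federatedAccuracy(perEdge$accPre, perEdge$nPre)$federatedAccuracy
  post <- perEdge[!is.na(perEdge$accPost), ]
  fedPost <- federatedAccuracy(post$accPost, post$nPost)$federatedAccuracy
  list(perEdge = perEdge, federatedPre = fedPre, federatedPost = fedPost,
       delta = fedPost - fedPre)
}
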