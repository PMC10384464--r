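# Server side: aggregate edge profiles into the federated profile, compute
# missing-value vectors, decide attribute fate, eliminate low-quality nodes,
# and run the versioned federation loop.

#' Federation run configuration
#'
#' @param qTol Target federated accuracy in `[0, 1]`; the round loop stops
#'   once the federated patient-similarity accuracy reaches it.
#' @param featureTol Maximum number of features retained by federated
#'   feature selection. The default (20) trims only the worst-ranked
#'   channels of the standard 22-feature cohort: rank-aggregation feature
#'   selection is a noise filter here, not aggressive dimensionality
#'   reduction, since every channel carries class signal.
#' @param maxRounds Round cap for the loop.
#' @param aggSpec Named character map, measure field -> aggregation
#'   (`"min"`, `"max"`, `"weighted_mean"`, `"sum"`); defaults: min of minima,
#'   max of maxima, row-count-weighted means for fractions, skewness and CV.
#' @param weightImputeThreshold Attribute weight above which an imputation is
#'   mandated regardless of the missing-value indicator.
#' @param weightInsignificanceThreshold Weight below which an attribute that
#'   fails its missing tolerance is dropped.
#' @param scorer Feature-value scorer (`"anova"` or `"mi"`).
#' @param seed Master seed for all stochastic steps.
#' @return A `FederationConfig` list.
#' @examples
#' federationConfig(qTol = 0.9, featureTol = 10)
#' @export
federationConfig <- function(qTol = 0.9, featureTol = 20, maxRounds = 3,
                             aggSpec = NULL, weightImputeThreshold = 0.5,
                             weightInsignificanceThreshold = 0.1,
                             scorer = c("anova", "mi"), seed = 1) {
  stopIfNot(qTol >= 0 && qTol <= 1, "qTol must lie in [0, 1]")
  stopIfNot(featureTol >= 1, "featureTol must be at least 1")
  stopIfNot(maxRounds >= 1, "maxRounds must be at least 1")
  defaults <- c(observedMin = "min", observedMax = "max",
                skewness = "weighted_mean", missingFraction = "weighted_mean",
                uniqueFraction = "weighted_mean",
                outlierFraction = "weighted_mean", cv = "weighted_mean")
  if (!is.null(aggSpec)) defaults[names(aggSpec)] <- aggSpec
  structure(list(qTol = qTol, featureTol = featureTol, maxRounds = maxRounds,
                 aggSpec = defaults,
                 weightImputeThreshold = weightImputeThreshold,
                 weightInsignificanceThreshold = weightInsignificanceThreshold,
                 scorer = match.arg(scorer), seed = as.integer(seed)),
            class = "FederationConfig")
}

#' Missing-value information vector of a measured profile
#'
#' For every attribute, the missing fraction `mv` and the indicator that it
#' lies within the attribute's acceptable missing-data tolerance `ATol`
#' (taken as `1 -` the attribute's completeness tolerance, so a 70%
#' completeness tolerance admits up to 30% missing). `indicator` is 1 iff
#' `mv < ATol`.
#'
#' @param edgeProfile A measured [DQProfile-class].
#' @return `data.frame` with columns `attribute`, `mv`, `atol`, `indicator`.
#' @export
missingValueVector <- function(edgeProfile) {
  stopIfNot(length(edgeProfile@measures) > 0, "profile carries no measures")
  rows <- lapply(edgeProfile@attributes, function(a) {
    if (!"completeness" %in% names(a@tolerances))
      stop("attribute '", a@name, "' lacks a missing-data tolerance ",
           "(no completeness tolerance configured)", call. = FALSE)
    atol <- 1 - a@tolerances[["completeness"]]
    mv <- edgeProfile@measures[[a@name]]@missingFraction
    data.frame(attribute = a@name, mv = mv, atol = atol,
               indicator = as.integer(mv < atol), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

weightedVote <- function(flags, w) sum(w[flags]) > sum(w) / 2

aggField <- function(vals, w, how) {
  ok <- !is.na(vals)
  if (!any(ok)) return(NA_real_)
  switch(how,
    min = min(vals[ok]),
    max = max(vals[ok]),
    sum = sum(vals[ok]),
    weighted_mean = sum(vals[ok] * w[ok]) / sum(w[ok]),
    stop("unknown aggregation: ", how, call. = FALSE))
}

#' Aggregate edge profiles into the federated profile
#'
#' Group-aggregates the measures of the surviving edge profiles per
#' attribute: minima by min, maxima by max, fraction-valued measures (and
#' skewness/CV) by row-count-weighted mean, the mode by row-count-weighted
#' vote among the node modes, the MNAR flag by weighted vote. The result has
#' role `"federated"`, the maximum input version, the summed row count, and
#' inherits attributes, weights, tolerances and rules from the (identical)
#' edge blueprints.
#'
#' @param edgeProfiles Non-empty list of measured edge [DQProfile-class]s
#'   over identical attribute sets.
#' @param config A [federationConfig()] (supplies `aggSpec`).
#' @return A federated [DQProfile-class].
#' @examples
#' ds <- edgeDataset("n1", data.frame(a = c(1, 2, NA)), c("x", "y", "x"))
#' ep <- buildEdgeProfile(ds, initializeProfile("a"))
#' fed <- aggregateProfiles(list(ep))
#' profileRole(fed)
#' @export
aggregateProfiles <- function(edgeProfiles, config = federationConfig()) {
  stopIfNot(length(edgeProfiles) >= 1, "empty profile list")
  nms <- attributeNames(edgeProfiles[[1]])
  for (p in edgeProfiles) {
    if (!identical(sort(attributeNames(p)), sort(nms)))
      stop("attribute-set mismatch across edge profiles", call. = FALSE)
    stopIfNot(length(p@measures) > 0, "every edge profile needs measures")
  }
  w <- vapply(edgeProfiles, function(p) as.numeric(p@rowCount), numeric(1))
  stopIfNot(all(w > 0), "edge profiles must have positive row counts")

  spec <- config$aggSpec
  measures <- list()
  for (nm in nms) {
    ms <- lapply(edgeProfiles, function(p) p@measures[[nm]])
    num <- function(field) vapply(ms, function(m) slot(m, field), numeric(1))
    mf <- aggField(num("missingFraction"), w, spec[["missingFraction"]])
    modes <- lapply(ms, function(m) m@mode)
    modeOK <- !vapply(modes, isMissingScalar, logical(1))
    aggMode <- if (!any(modeOK)) NA else {
      mv <- unlist(modes[modeOK])
      mw <- w[modeOK]
      agg <- tapply(mw, mv, sum)
      val <- names(agg)[which.max(agg)]
      if (is.numeric(mv)) as.numeric(val) else val
    }
    measures[[nm]] <- new("AttributeMeasures",
      observedMin = aggField(num("observedMin"), w, spec[["observedMin"]]),
      observedMax = aggField(num("observedMax"), w, spec[["observedMax"]]),
      mode = aggMode,
      skewness = aggField(num("skewness"), w, spec[["skewness"]]),
      missingFraction = mf,
      uniqueFraction = aggField(num("uniqueFraction"), w,
                                spec[["uniqueFraction"]]),
      outlierFraction = aggField(num("outlierFraction"), w,
                                 spec[["outlierFraction"]]),
      completeness = 1 - mf,
      cv = aggField(num("cv"), w, spec[["cv"]]),
      mnar = weightedVote(vapply(ms, function(m) isTRUE(m@mnar), logical(1)),
                          w),
      degenerate = mf >= 1 - 1e-12)
  }

  fed <- edgeProfiles[[1]]
  fed@role <- "federated"
  fed@nodeId <- NA_character_
  fed@version <- max(vapply(edgeProfiles, function(p) p@version, integer(1)))
  fed@rowCount <- as.integer(sum(w))
  fed@measures <- measures
  fed@workload <- NULL
  fed
}

#' Decide the fate of one attribute at federation
#'
#' Combines the aggregated missing-value indicator with the attribute's
#' weight: a heavy attribute (weight above `weightImputeThreshold`) must be
#' imputed regardless of the indicator; a failing attribute (indicator 0)
#' with insignificant weight (below `weightInsignificanceThreshold`) is
#' dropped; everything else is retained with whatever action the rule table
#' selects.
#'
#' @param indicator Aggregated missing-value indicator (0 or 1).
#' @param weight Attribute weight in `[0, 1]`.
#' @param config A [federationConfig()].
#' @return `"impute"`, `"drop"`, or `"retain"`.
#' @examples
#' decideAttributeFate(0, 0.6)   # "impute"
#' decideAttributeFate(0, 0.05)  # "drop"
#' decideAttributeFate(1, 0.05)  # "retain"
#' @export
decideAttributeFate <- function(indicator, weight,
                                config = federationConfig()) {
  stopIfNot(weight >= 0 && weight <= 1, "weight must lie in [0, 1]")
  if (weight > config$weightImputeThreshold) return("impute")
  if (indicator == 0 && weight < config$weightInsignificanceThreshold)
    return("drop")
  "retain"
}

#' Select edge nodes by quality tolerances
#'
#' Runs [checkDimensionTolerances()] on every edge profile and partitions
#' the nodes: a node whose report fails any dimension is eliminated from the
#' federation. Raises when no node survives.
#'
#' @param edgeProfiles List of measured edge [DQProfile-class]s.
#' @return List with `selected` and `eliminated` (node-id character
#'   vectors) and `reports` (named list of `ToleranceReport`s).
#' @export
selectNodes <- function(edgeProfiles) {
  stopIfNot(length(edgeProfiles) >= 1, "no edge profiles")
  reports <- lapply(edgeProfiles, checkDimensionTolerances)
  ids <- unname(vapply(edgeProfiles, function(p) p@nodeId, character(1)))
  names(reports) <- ids
  pass <- unname(vapply(reports, function(r) r$overallPass, logical(1)))
  if (!any(pass))
    stop("all nodes eliminated; federation cannot proceed", call. = FALSE)
  list(selected = ids[pass], eliminated = ids[!pass], reports = reports)
}

# Merge rule-table decisions with the attribute-fate overrides from the
# missing-value vector: "drop" forces DROP_COLUMN; "impute" upgrades a drop
# to multiple (numeric) / mode (categorical) imputation.
overrideDecisions <- function(decisions, fed, config) {
  mvv <- missingValueVector(fed)
  wts <- attributeWeights(fed)
  specs <- profileAttributes(fed)
  for (nm in names(decisions)) {
    ind <- mvv$indicator[mvv$attribute == nm]
    fate <- decideAttributeFate(ind, wts[[nm]], config)
    d <- decisions[[nm]]
    if (fate == "drop" && d$action != "DROP_COLUMN" &&
        fed@measures[[nm]]@missingFraction > 0) {
      d$action <- "DROP_COLUMN"
      d$justification <- paste0(d$justification,
        "; overridden: indicator 0 with insignificant weight")
    } else if (fate == "impute" && d$action == "DROP_COLUMN") {
      d$action <- if (specs[[nm]]@dataType == "numeric") "MULTIPLE_IMPUTE"
                  else "MODE_IMPUTE"
      d$justification <- paste0(d$justification,
        "; overridden: heavy attribute, imputation mandated")
    }
    decisions[[nm]] <- d
  }
  decisions
}

#' Run the federated data-quality profiling loop
#'
#' Executes the versioned federation rounds. Each round: the current
#' baseline is broadcast; every (still-connected) edge builds its profile;
#' nodes failing their dimension tolerances are eliminated; the survivors'
#' profiles are aggregated into the federated profile; federated feature
#' selection ranks and trims the features; repair decisions are derived from
#' the federated measures (with attribute-fate overrides) and applied at
#' every surviving edge together with the feature drops; the
#' patient-similarity accuracy of the enriched data is computed per edge and
#' federated by row-count-weighted mean. The profile version increments by
#' one per round, the loop stops once the federated accuracy reaches `qTol`
#' (or after `maxRounds`), and from the second round on only profile deltas
#' are exchanged (recorded in the history).
#'
#' @param edges List of [EdgeDataset-class]s (at least 2).
#' @param baseline The baseline [DQProfile-class].
#' @param config A [federationConfig()].
#' @return List with `profile` (final federated [DQProfile-class]),
#'   `datasets` (named list of enriched [EdgeDataset-class]s for the
#'   surviving nodes), and `history` (one record per round: version,
#'   eliminated node ids, selected features, dataset-level completeness and
#'   mean CV, federated accuracy, and the profile delta from the previous
#'   round).
#' @export
runFederation <- function(edges, baseline, config = federationConfig()) {
  stopIfNot(length(edges) >= 2, "need at least 2 edges")
  viol <- validateProfile(baseline)
  stopIfNot(length(viol) == 0,
            paste("invalid baseline:", paste(viol, collapse = "; ")))

  names(edges) <- vapply(edges, nodeId, character(1))
  eliminated <- character()
  history <- list()
  current <- baseline
  prevFed <- NULL
  fed <- NULL
  datasets <- edges

  for (round in seq_len(config$maxRounds)) {
    active <- setdiff(names(datasets), eliminated)
    edgeProfiles <- lapply(datasets[active], buildEdgeProfile,
                           baseline = current)
    sel <- selectNodes(edgeProfiles)
    eliminated <- union(eliminated, sel$eliminated)
    surv <- edgeProfiles[sel$selected]

    fed <- aggregateProfiles(surv, config)
    fed@version <- baseline@version + round

    stats <- lapply(sel$selected, function(id)
      featureStats(datasets[[id]], profile = edgeProfiles[[id]],
                   scorer = config$scorer))
    ranks <- federatedFeatureSelection(stats, config$featureTol)
    selectedFeats <- ranks$feature[ranks$selected]
    fed@selectedFeatures <- selectedFeats

    decisions <- overrideDecisions(selectRules(fed), fed, config)
    dropped <- names(decisions)[vapply(decisions, function(d)
      d$action == "DROP_COLUMN", logical(1))]
    keepFeats <- setdiff(selectedFeats, dropped)
    stopIfNot(length(keepFeats) > 0, "no features retained")

    accs <- numeric(0)
    sizes <- numeric(0)
    for (id in sel$selected) {
      ds <- datasets[[id]]
      restricted <- edgeDataset(id, edgeTable(ds)[keepFeats],
                                edgeLabels(ds), edgeMetadata(ds))
      out <- applyRules(restricted, decisions[keepFeats],
                        seed = substreamSeed(config$seed, "apply", id, round))
      datasets[[id]] <- out$dataset
      accs[id] <- psnAccuracy(edgeTable(out$dataset),
                              edgeLabels(out$dataset))
      sizes[id] <- rowCount(out$dataset)
    }
    fscore <- federatedAccuracy(accs, sizes)
    acc <- fscore$federatedAccuracy
    if (!is.finite(acc)) stop("non-finite federated accuracy", call. = FALSE)

    history[[round]] <- list(
      round = round, version = fed@version,
      eliminated = sel$eliminated, allEliminated = eliminated,
      selectedFeatures = selectedFeats, droppedAttributes = dropped,
      completeness = mean(vapply(datasets[sel$selected], function(d)
        1 - mean(is.na(as.matrix(edgeTable(d)))), numeric(1))),
      meanCV = mean(vapply(datasets[sel$selected], function(d) {
        cvs <- vapply(edgeTable(d), function(col)
          if (is.numeric(col) && sum(!is.na(col)) >= 2 &&
              mean(col, na.rm = TRUE) != 0) consistencyCV(col) else NA_real_,
          numeric(1))
        mean(cvs, na.rm = TRUE)
      }, numeric(1))),
      accuracy = acc,
      delta = if (!is.null(prevFed)) diffProfiles(prevFed, fed) else NULL)

    prevFed <- fed
    # next round's baseline: the federated profile trimmed to the retained
    # features, weights renormalized over the survivors
    current <- fed
    current@role <- "baseline"
    current@measures <- list()
    current@nodeId <- NA_character_
    keep <- vapply(current@attributes, function(a) a@name %in% keepFeats,
                   logical(1))
    current@attributes <- current@attributes[keep]
    wsum <- sum(vapply(current@attributes, function(a) a@weight, numeric(1)))
    current@attributes <- lapply(current@attributes, function(a) {
      a@weight <- a@weight / wsum
      a
    })
    if (acc >= config$qTol) break
  }

  list(profile = fed, datasets = datasets[setdiff(names(datasets), eliminated)],
       history = history)
}
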