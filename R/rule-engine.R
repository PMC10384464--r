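# Rule engine: map attribute measures to concrete repair actions and apply
# them to produce the quality-enriched dataset.

#' Default missing-data rule table
#'
#' The condition-to-action table the profiler ships with. Rule ids follow the
#' conventional 2.x numbering for missing-data actions:
#'
#' * `2.0` - no missing cells: no action.
#' * `2.2` - missing fraction at or above `columnDropThreshold` (default
#'   0.50): delete the whole column.
#' * `2.4` - MNAR-flagged column: KNN imputation.
#' * `2.5` - categorical column with under 20% missing: mode imputation.
#' * `2.3` - skewed numeric column (|skew| > `skewCut`) with under
#'   `medianMissingMax` (5%) missing: median imputation.
#' * `2.1` - numeric column with under `lowMissingMax` (20%) missing: mean
#'   imputation (also covers the skewed 5-20% band, where the mean remains
#'   the general-purpose low-missingness action).
#' * `2.6` - numeric column with 20% up to the drop threshold missing:
#'   multiple imputation.
#' * `2.7` - row rule: delete rows missing in more than half of the retained
#'   attributes (applied after column decisions, so a column drop can never
#'   be preempted by row removal).
#'
#' Rules are matched in the order listed above; the first match wins. All
#' thresholds are arguments.
#'
#' @param columnDropThreshold Missing fraction at which a column is deleted.
#' @param skewCut |skewness| above which a column counts as skewed.
#' @param medianMissingMax Upper missing fraction for the median rule.
#' @param lowMissingMax Upper missing fraction for the mean/mode rules.
#' @param rowMissingThreshold Row-deletion cut on the fraction of missing
#'   attributes within a row.
#' @param knnK Neighbour count for rule 2.4.
#' @return List of [QualityRule-class] objects in match priority order.
#' @examples
#' vapply(defaultRuleTable(), function(r) r@action, character(1))
#' @export
defaultRuleTable <- function(columnDropThreshold = 0.5, skewCut = 1,
                             medianMissingMax = 0.05, lowMissingMax = 0.20,
                             rowMissingThreshold = 0.5, knnK = 5) {
  list(
    qualityRule("2.2", action = "DROP_COLUMN",
      condition = list(missing = c(columnDropThreshold, 1),
                       closed = c(TRUE, TRUE)),
      params = list(threshold = columnDropThreshold)),
    qualityRule("2.0", action = "NONE",
      condition = list(missing = c(0, 0), closed = c(TRUE, TRUE))),
    qualityRule("2.4", action = "KNN_IMPUTE",
      condition = list(missing = c(0, columnDropThreshold),
                       closed = c(FALSE, FALSE), mnar = TRUE),
      params = list(k = knnK)),
    qualityRule("2.5", action = "MODE_IMPUTE",
      condition = list(missing = c(0, lowMissingMax),
                       closed = c(FALSE, FALSE), dataType = "categorical")),
    qualityRule("2.3", action = "MEDIAN_IMPUTE",
      condition = list(missing = c(0, medianMissingMax),
                       closed = c(FALSE, FALSE), dataType = "numeric",
                       skew = "skewed"),
      params = list(skewCut = skewCut)),
    qualityRule("2.1", action = "MEAN_IMPUTE",
      condition = list(missing = c(0, lowMissingMax),
                       closed = c(FALSE, FALSE), dataType = "numeric"),
      params = list(skewCut = skewCut)),
    qualityRule("2.6", action = "MULTIPLE_IMPUTE",
      condition = list(missing = c(lowMissingMax, columnDropThreshold),
                       closed = c(TRUE, FALSE), dataType = "numeric")),
    qualityRule("2.7", action = "DROP_ROWS",
      condition = list(scope = "row"),
      params = list(rowMissingThreshold = rowMissingThreshold)))
}

matchesCondition <- function(rule, mf, dataType, skewVal, mnarFlag) {
  cc <- canonicalCondition(rule@condition)
  if (cc$scope != "column") return(FALSE)
  if (!is.na(cc$missingMin)) {
    lowOK <- if (cc$closedMin) mf >= cc$missingMin else mf > cc$missingMin
    highOK <- if (cc$closedMax) mf <= cc$missingMax else mf < cc$missingMax
    if (!lowOK || !highOK) return(FALSE)
  }
  if (cc$dataType != "any" && cc$dataType != dataType) return(FALSE)
  if (cc$skew != "any") {
    skewCut <- rule@params$skewCut %||% 1
    skewed <- !is.na(skewVal) && abs(skewVal) > skewCut
    if (cc$skew == "skewed" && !skewed) return(FALSE)
    if (cc$skew == "symmetric" && skewed) return(FALSE)
  }
  if (cc$mnar != "any") {
    if (identical(cc$mnar, "true") && !isTRUE(mnarFlag)) return(FALSE)
    if (identical(cc$mnar, "false") && isTRUE(mnarFlag)) return(FALSE)
  }
  TRUE
}

#' Select the repair rule for one attribute
#'
#' Walks the rule table in priority order and returns the first rule whose
#' condition matches the attribute's measured state (missing fraction, data
#' type, skew class, MNAR flag). When no rule matches, a `NONE` decision is
#' returned with a warning - data are never silently dropped.
#'
#' @param measures The attribute's [AttributeMeasures-class].
#' @param spec The attribute's [AttributeSpec-class].
#' @param ruleTable List of [QualityRule-class] in priority order (default
#'   [defaultRuleTable()]).
#' @return A `RuleDecision`: list with `attribute`, `ruleId`, `action`,
#'   `params`, and a human-readable `justification` naming the matched
#'   condition.
#' @examples
#' m <- profileAttribute(c(1, 2, NA, 3), attributeSpec("x"))
#' selectRule(m, attributeSpec("x"))
#' @export
selectRule <- function(measures, spec, ruleTable = defaultRuleTable()) {
  mf <- measures@missingFraction
  stopIfNot(!is.na(mf), "measures must be populated (missingFraction is NA)")
  dataType <- if (spec@dataType == "numeric") "numeric" else "categorical"
  for (rule in ruleTable) {
    if (matchesCondition(rule, mf, dataType, measures@skewness,
                         measures@mnar)) {
      cc <- canonicalCondition(rule@condition)
      just <- sprintf(
        "rule %s: missing=%.4f in %s%s,%s%s; dataType=%s; skew=%s; mnar=%s",
        rule@ruleId, mf, if (cc$closedMin) "[" else "(", fmtShort(cc$missingMin),
        fmtShort(cc$missingMax), if (cc$closedMax) "]" else ")",
        cc$dataType, cc$skew, cc$mnar)
      return(structure(list(attribute = spec@name, ruleId = rule@ruleId,
                            action = rule@action, params = rule@params,
                            justification = just),
                       class = "RuleDecision"))
    }
  }
  warning("no rule matches attribute '", spec@name, "' (missing fraction ",
          format(mf), "); returning NONE", call. = FALSE)
  structure(list(attribute = spec@name, ruleId = NA_character_,
                 action = "NONE", params = list(),
                 justification = "no rule matched"),
            class = "RuleDecision")
}

fmtShort <- function(x) if (is.na(x)) "?" else format(x)

#' @export
print.RuleDecision <- function(x, ...) {
  cat(sprintf("RuleDecision: %s -> %s (%s)\n", x$attribute, x$action,
              x$justification))
  invisible(x)
}

#' Select rules for every attribute of a measured profile
#'
#' @param profile A measured [DQProfile-class] (edge or federated).
#' @param ruleTable Rule table (default: the profile's own rules).
#' @return Named list of `RuleDecision`s, one per attribute.
#' @export
selectRules <- function(profile, ruleTable = NULL) {
  stopIfNot(length(profile@measures) > 0, "profile carries no measures")
  ruleTable <- ruleTable %||% profile@rules
  specs <- profileAttributes(profile)
  decisions <- lapply(names(specs), function(nm)
    selectRule(profile@measures[[nm]], specs[[nm]], ruleTable))
  stats::setNames(decisions, names(specs))
}

imputeColumn <- function(table, target, decision, seed) {
  switch(decision$action,
    MEAN_IMPUTE = meanImpute(table[[target]]),
    MEDIAN_IMPUTE = medianImpute(table[[target]]),
    MODE_IMPUTE = modeImpute(table[[target]]),
    KNN_IMPUTE = knnImpute(table, target, k = decision$params$k %||% 5),
    MULTIPLE_IMPUTE = multipleImpute(table, target,
      m = decision$params$m %||% NULL,
      seed = substreamSeed(seed, "mi", target))$column,
    table[[target]])
}

#' Apply repair decisions to an edge dataset
#'
#' Executes the per-attribute decisions: column drops first, then imputations
#' (each computed from the pre-repair table, so decision order cannot change
#' the result), then the row rule (rows missing in more than
#' `rowMissingThreshold` of the retained attributes are deleted together with
#' their labels). The returned report reconciles exactly: every missing cell
#' of a retained column is either imputed or removed with its row/column, so
#' repeated application is the identity.
#'
#' @param dataset An [EdgeDataset-class].
#' @param decisions Named list of `RuleDecision`s covering every dataset
#'   attribute (e.g. from [selectRules()]).
#' @param seed Integer seed for the stochastic imputations.
#' @param rowMissingThreshold Row-deletion cut (fraction of retained
#'   attributes missing).
#' @return List with `dataset` (the quality-enriched [EdgeDataset-class])
#'   and `report` (a `RepairReport`: decisions, columnsDropped,
#'   droppedColumns, rowsDropped, droppedRows (input row indices),
#'   cellsImputed, postCompleteness).
#' @examples
#' ds <- edgeDataset("n1", data.frame(a = c(1, 2, NA, 3)), rep("x", 4))
#' ep <- buildEdgeProfile(ds, initializeProfile("a"))
#' out <- applyRules(ds, selectRules(ep))
#' out$report$postCompleteness  # 1
#' @export
applyRules <- function(dataset, decisions, seed = 1,
                       rowMissingThreshold = 0.5) {
  tab <- edgeTable(dataset)
  unknown <- setdiff(names(decisions), names(tab))
  if (length(unknown))
    stop("decision references unknown attribute(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  uncovered <- setdiff(names(tab), names(decisions))
  stopIfNot(length(uncovered) == 0,
            paste("decisions must cover every attribute; missing:",
                  paste(uncovered, collapse = ", ")))

  dropCols <- names(decisions)[vapply(decisions, function(d)
    d$action == "DROP_COLUMN", logical(1))]
  keepCols <- setdiff(names(tab), dropCols)
  stopIfNot(length(keepCols) > 0, "all columns would be dropped")

  # row rule: judged on the pre-repair cells of the retained columns, after
  # column decisions (a column drop can absorb the missingness of a bad
  # column) but before imputation (an imputed row would never look missing)
  rowMissFrac <- rowMeans(is.na(tab[keepCols]))
  keepRows <- rowMissFrac <= rowMissingThreshold
  rowsDropped <- sum(!keepRows)
  tab <- tab[keepRows, , drop = FALSE]
  rownames(tab) <- NULL

  cellsImputed <- 0L
  repaired <- tab[keepCols]
  for (nm in keepCols) {
    d <- decisions[[nm]]
    if (d$action %in% c("NONE", "DROP_ROWS")) next
    nMiss <- sum(is.na(tab[[nm]]))
    if (nMiss == 0L) next
    repaired[[nm]] <- imputeColumn(tab, nm, d, seed)
    cellsImputed <- cellsImputed + nMiss
  }

  enriched <- edgeDataset(nodeId(dataset), repaired,
                          edgeLabels(dataset)[keepRows],
                          metadata = edgeMetadata(dataset))
  post <- if (length(repaired) && nrow(repaired))
    1 - mean(is.na(as.matrix(repaired))) else 1
  report <- structure(list(decisions = decisions,
                           columnsDropped = length(dropCols),
                           droppedColumns = dropCols,
                           rowsDropped = rowsDropped,
                           droppedRows = which(!keepRows),
                           cellsImputed = cellsImputed,
                           postCompleteness = post),
                      class = "RepairReport")
  list(dataset = enriched, report = report)
}

#' @export
print.RepairReport <- function(x, ...) {
  cat(sprintf(paste0("RepairReport: %d column(s) dropped, %d row(s) ",
                     "dropped, %d cell(s) imputed; post-repair completeness ",
                     "%.4f\n"),
              x$columnsDropped, x$rowsDropped, x$cellsImputed,
              x$postCompleteness))
  invisible(x)
}
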