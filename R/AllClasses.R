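#' @import methods
NULL

#' Closed set of data-quality dimensions
#'
#' The six dimension names a profile may measure and bound: completeness,
#' accuracy, timeliness, uniqueness, validity, and consistency.
#'
#' @return Character vector of the six dimension names.
#' @examples qualityDimensions()
#' @export
qualityDimensions <- function() {
  c("completeness", "accuracy", "timeliness", "uniqueness", "validity",
    "consistency")
}

#' Closed set of repair actions
#'
#' Actions a quality rule may prescribe for an attribute.
#'
#' @return Character vector of action names.
#' @examples ruleActions()
#' @export
ruleActions <- function() {
  c("NONE", "MEAN_IMPUTE", "MEDIAN_IMPUTE", "MODE_IMPUTE", "KNN_IMPUTE",
    "MULTIPLE_IMPUTE", "DROP_COLUMN", "DROP_ROWS")
}

profileRoles <- function() c("baseline", "edge", "federated")
attributeDataTypes <- function() c("numeric", "categorical", "datetime")

#' QualityRule: a condition-to-action repair rule
#'
#' A rule maps a condition over an attribute's measured state (missing-fraction
#' interval, data type, skew class, MNAR flag, weight interval) to a repair
#' action (imputation or drop). Rules live inside a [DQProfile] and are
#' referenced by [RuleDecision]s.
#'
#' @slot ruleId Dotted string identifier, e.g. `"2.1"`.
#' @slot dimension One of [qualityDimensions()].
#' @slot condition Named list; see [qualityRule()] for the recognised fields.
#' @slot action One of [ruleActions()].
#' @slot params Named list of action parameters (e.g. `k` for KNN).
#' @name QualityRule-class
#' @rdname QualityRule-class
#' @exportClass QualityRule
setClass("QualityRule",
  representation(ruleId = "character", dimension = "character",
                 condition = "list", action = "character", params = "list"),
  prototype(ruleId = NA_character_, dimension = "completeness",
            condition = list(), action = "NONE", params = list()))

setValidity("QualityRule", function(object) {
  msg <- character()
  if (length(object@ruleId) != 1L) msg <- c(msg, "ruleId must be length 1")
  if (length(object@action) != 1L || !object@action %in% ruleActions())
    msg <- c(msg, "action must be one of ruleActions()")
  if (length(object@dimension) != 1L ||
      !object@dimension %in% qualityDimensions())
    msg <- c(msg, "dimension must be one of qualityDimensions()")
  mi <- object@condition$missing
  if (!is.null(mi) && (length(mi) != 2L || anyNA(mi) || mi[1] > mi[2]))
    msg <- c(msg, "condition$missing must be a well-formed interval (lower <= upper)")
  if (length(msg)) msg else TRUE
})

#' AttributeSpec: declared properties of one dataset attribute
#'
#' @slot name Attribute identifier (no `/` allowed; used as an XML id and a
#'   diff path component).
#' @slot dataType `"numeric"`, `"categorical"`, or `"datetime"`.
#' @slot allowedMin,allowedMax Optional domain bounds in the attribute's units
#'   (`NA` when unbounded).
#' @slot weight Relative importance in `[0, 1]`; weights sum to 1 across a
#'   profile's attributes.
#' @slot tolerances Named numeric vector mapping dimension name to the minimum
#'   acceptable level in `[0, 1]`.
#' @slot ruleIds Identifiers of the profile rules applicable to this attribute.
#' @name AttributeSpec-class
#' @rdname AttributeSpec-class
#' @exportClass AttributeSpec
setClass("AttributeSpec",
  representation(name = "character", dataType = "character",
                 allowedMin = "numeric", allowedMax = "numeric",
                 weight = "numeric", tolerances = "numeric",
                 ruleIds = "character"),
  prototype(name = NA_character_, dataType = "numeric",
            allowedMin = NA_real_, allowedMax = NA_real_, weight = NA_real_,
            tolerances = c(completeness = 0.7), ruleIds = character()))

setValidity("AttributeSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) ||
      grepl("/", object@name, fixed = TRUE))
    msg <- c(msg, "name must be a single identifier without '/'")
  if (!object@dataType %in% attributeDataTypes())
    msg <- c(msg, "dataType must be numeric, categorical, or datetime")
  if (length(object@tolerances) &&
      (is.null(names(object@tolerances)) ||
       !all(names(object@tolerances) %in% qualityDimensions())))
    msg <- c(msg, "tolerances must be named by quality dimensions")
  if (length(msg)) msg else TRUE
})

#' AttributeMeasures: per-attribute profiling statistics
#'
#' Quantities measured from one column of an edge dataset (or aggregated
#' across edges): observed range, mode, skewness, missing/unique/outlier
#' fractions, completeness, coefficient of variation, and an MNAR flag.
#' A column with every cell missing is flagged `degenerate` and carries
#' `missingFraction = 1` with undefined numeric statistics.
#'
#' @slot observedMin,observedMax Observed range in attribute units.
#' @slot mode Most frequent value (numeric or character).
#' @slot skewness Adjusted Fisher-Pearson standardized third moment.
#' @slot missingFraction,uniqueFraction,outlierFraction,completeness
#'   Fractions in `[0, 1]`; `completeness = 1 - missingFraction`.
#' @slot cv Sample coefficient of variation (sd / |mean|), `NA` when undefined.
#' @slot mnar `TRUE` when missingness correlates with another observed
#'   attribute (missing-not-at-random heuristic).
#' @slot degenerate `TRUE` for an all-missing column.
#' @name AttributeMeasures-class
#' @rdname AttributeMeasures-class
#' @exportClass AttributeMeasures
setClass("AttributeMeasures",
  representation(observedMin = "numeric", observedMax = "numeric",
                 mode = "ANY", skewness = "numeric",
                 missingFraction = "numeric", uniqueFraction = "numeric",
                 outlierFraction = "numeric", completeness = "numeric",
                 cv = "numeric", mnar = "logical", degenerate = "logical"),
  prototype(observedMin = NA_real_, observedMax = NA_real_, mode = NA,
            skewness = NA_real_, missingFraction = NA_real_,
            uniqueFraction = NA_real_, outlierFraction = NA_real_,
            completeness = NA_real_, cv = NA_real_, mnar = FALSE,
            degenerate = FALSE))

setValidity("AttributeMeasures", function(object) {
  msg <- character()
  fr <- c(missing = object@missingFraction, unique = object@uniqueFraction,
          outlier = object@outlierFraction, completeness = object@completeness)
  bad <- !is.na(fr) & (fr < 0 | fr > 1)
  if (any(bad))
    msg <- c(msg, paste("fractions out of [0,1]:",
                        paste(names(fr)[bad], collapse = ", ")))
  if (!is.na(object@observedMin) && !is.na(object@observedMax) &&
      object@observedMin > object@observedMax)
    msg <- c(msg, "observedMin must be <= observedMax")
  if (!is.na(object@missingFraction) && !is.na(object@completeness) &&
      abs(object@completeness - (1 - object@missingFraction)) > 1e-12)
    msg <- c(msg, "completeness must equal 1 - missingFraction")
  if (length(msg)) msg else TRUE
})

#' WorkloadStub: opaque edge workload descriptor
#'
#' Carries an edge node's configuration and real-time resource parameters as
#' opaque key-value maps. The profiling pipeline stores and transports it but
#' never interprets its contents.
#'
#' @slot config Named list (values coerced to character on XML write).
#' @slot realtime Named list.
#' @name WorkloadStub-class
#' @rdname WorkloadStub-class
#' @exportClass WorkloadStub
setClass("WorkloadStub",
  representation(config = "list", realtime = "list"),
  prototype(config = list(), realtime = list()))

#' DQProfile: a versioned data-quality profile
#'
#' The central container: the tuple of attributes (with weights and
#' tolerances), quality dimensions, repair rules, and (for edge and federated
#' roles) measured statistics, carried with a version number so that only
#' profile updates need be exchanged between server and edges.
#'
#' @slot version Non-negative integer profile version.
#' @slot role `"baseline"` (server blueprint), `"edge"` (measured locally), or
#'   `"federated"` (server aggregate).
#' @slot nodeId Edge node identifier (`NA` for baseline/federated).
#' @slot rowCount Rows profiled (0 for a baseline).
#' @slot attributes List of [AttributeSpec-class] objects.
#' @slot dimensions Subset of [qualityDimensions()].
#' @slot rules List of [QualityRule-class] objects with unique ids.
#' @slot measures Named list (attribute name ->
#'   [AttributeMeasures-class]); empty for a baseline.
#' @slot selectedFeatures Attribute names retained by federated feature
#'   selection, in rank order (federated role).
#' @slot workload Optional [WorkloadStub-class] or `NULL`.
#' @seealso [initializeProfile()], [validateProfile()], [writeProfileXML()]
#' @name DQProfile-class
#' @rdname DQProfile-class
#' @exportClass DQProfile
setClass("DQProfile",
  representation(version = "integer", role = "character",
                 nodeId = "character", rowCount = "integer",
                 attributes = "list", dimensions = "character",
                 rules = "list", measures = "list",
                 selectedFeatures = "character", workload = "ANY"),
  prototype(version = 0L, role = "baseline", nodeId = NA_character_,
            rowCount = 0L, attributes = list(), dimensions = character(),
            rules = list(), measures = list(),
            selectedFeatures = character(), workload = NULL))

setValidity("DQProfile", function(object) {
  msg <- character()
  if (!object@role %in% profileRoles())
    msg <- c(msg, "role must be baseline, edge, or federated")
  if (length(object@dimensions) &&
      !all(object@dimensions %in% qualityDimensions()))
    msg <- c(msg, "dimensions must be a subset of qualityDimensions()")
  if (!all(vapply(object@attributes, is, logical(1), "AttributeSpec")))
    msg <- c(msg, "attributes must be AttributeSpec objects")
  if (!all(vapply(object@rules, is, logical(1), "QualityRule")))
    msg <- c(msg, "rules must be QualityRule objects")
  if (length(object@measures) &&
      !all(vapply(object@measures, is, logical(1), "AttributeMeasures")))
    msg <- c(msg, "measures must be AttributeMeasures objects")
  if (!is.null(object@workload) && !is(object@workload, "WorkloadStub"))
    msg <- c(msg, "workload must be a WorkloadStub or NULL")
  if (length(msg)) msg else TRUE
})

#' EdgeDataset: one node's labeled tabular data
#'
#' @slot nodeId Node identifier.
#' @slot table `data.frame` of typed values; `NA` marks a missing cell.
#' @slot labels Character class label per row.
#' @slot metadata List of generator/injection bookkeeping (realized missing
#'   rates, outlier displacement log, corruption record).
#' @name EdgeDataset-class
#' @rdname EdgeDataset-class
#' @exportClass EdgeDataset
setClass("EdgeDataset",
  representation(nodeId = "character", table = "data.frame",
                 labels = "character", metadata = "list"),
  prototype(nodeId = NA_character_, table = data.frame(),
            labels = character(), metadata = list()))

setValidity("EdgeDataset", function(object) {
  msg <- character()
  if (nrow(object@table) != length(object@labels))
    msg <- c(msg, "label count must equal row count")
  if (anyDuplicated(names(object@table)))
    msg <- c(msg, "attribute names must be unique")
  if (length(msg)) msg else TRUE
})
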