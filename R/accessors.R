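#' Constructors for profile building blocks
#'
#' `attributeSpec()`, `qualityRule()`, `workloadStub()`, and `edgeDataset()`
#' build validated objects of the corresponding S4 classes.
#'
#' The recognised `condition` fields of a rule are: `missing` (length-2
#' missing-fraction interval), `closed` (length-2 logical, whether each bound
#' is inclusive), `dataType` (`"any"`, `"numeric"`, `"categorical"`), `skew`
#' (`"any"`, `"skewed"`, `"symmetric"`), `mnar` (`NA` = any, or TRUE/FALSE),
#' and `scope` (`"column"` or `"row"`).
#'
#' @param name Attribute identifier.
#' @param dataType One of `"numeric"`, `"categorical"`, `"datetime"`.
#' @param allowedMin,allowedMax Optional domain bounds.
#' @param weight Weight in `[0, 1]` (`NA` to have [initializeProfile()] assign
#'   a uniform default).
#' @param tolerances Named numeric vector, dimension -> tolerance in `[0, 1]`.
#' @param ruleIds Rule identifiers applicable to this attribute.
#' @return The constructed object.
#' @examples
#' attributeSpec("fhr_baseline", tolerances = c(completeness = 0.7))
#' qualityRule("2.2", action = "DROP_COLUMN",
#'             condition = list(missing = c(0.5, 1), closed = c(TRUE, TRUE)))
#' @export
attributeSpec <- function(name, dataType = "numeric", allowedMin = NA_real_,
                          allowedMax = NA_real_, weight = NA_real_,
                          tolerances = c(completeness = 0.7),
                          ruleIds = character()) {
  new("AttributeSpec", name = as.character(name), dataType = dataType,
      allowedMin = as.numeric(allowedMin), allowedMax = as.numeric(allowedMax),
      weight = as.numeric(weight), tolerances = tolerances,
      ruleIds = as.character(ruleIds))
}

#' @rdname attributeSpec
#' @param ruleId Dotted rule identifier (e.g. `"2.1"`).
#' @param dimension Quality dimension the rule guards.
#' @param condition Named list; see Details.
#' @param action One of [ruleActions()].
#' @param params Named list of action parameters.
#' @export
qualityRule <- function(ruleId, dimension = "completeness",
                        condition = list(), action = "NONE", params = list()) {
  new("QualityRule", ruleId = as.character(ruleId), dimension = dimension,
      condition = condition, action = action, params = params)
}

#' @rdname attributeSpec
#' @param config,realtime Opaque named lists.
#' @export
workloadStub <- function(config = list(), realtime = list()) {
  new("WorkloadStub", config = config, realtime = realtime)
}

#' @rdname attributeSpec
#' @param nodeId Node identifier.
#' @param table `data.frame` with `NA` as the missing marker.
#' @param labels Class label per row.
#' @param metadata Bookkeeping list.
#' @export
edgeDataset <- function(nodeId, table, labels, metadata = list()) {
  new("EdgeDataset", nodeId = as.character(nodeId),
      table = as.data.frame(table, stringsAsFactors = FALSE),
      labels = as.character(labels), metadata = metadata)
}

#' Accessors for profiles and edge datasets
#'
#' Small read-only accessors; user code should prefer these over `@` slot
#' access.
#'
#' @param object A [DQProfile-class] or [EdgeDataset-class].
#' @return The requested component.
#' @examples
#' p <- initializeProfile(c("a", "b"))
#' profileVersion(p)
#' attributeNames(p)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profileVersion", function(object) standardGeneric("profileVersion"))
#' @rdname accessors
#' @export
setMethod("profileVersion", "DQProfile", function(object) object@version)

#' @rdname accessors
#' @export
setGeneric("profileRole", function(object) standardGeneric("profileRole"))
#' @rdname accessors
#' @export
setMethod("profileRole", "DQProfile", function(object) object@role)

#' @rdname accessors
#' @export
setGeneric("nodeId", function(object) standardGeneric("nodeId"))
#' @rdname accessors
#' @export
setMethod("nodeId", "DQProfile", function(object) object@nodeId)
#' @rdname accessors
#' @export
setMethod("nodeId", "EdgeDataset", function(object) object@nodeId)

#' @rdname accessors
#' @export
setGeneric("rowCount", function(object) standardGeneric("rowCount"))
#' @rdname accessors
#' @export
setMethod("rowCount", "DQProfile", function(object) object@rowCount)
#' @rdname accessors
#' @export
setMethod("rowCount", "EdgeDataset", function(object) nrow(object@table))

#' @rdname accessors
#' @export
setGeneric("attributeNames", function(object) standardGeneric("attributeNames"))
#' @rdname accessors
#' @export
setMethod("attributeNames", "DQProfile", function(object)
  vapply(object@attributes, function(a) a@name, character(1)))
#' @rdname accessors
#' @export
setMethod("attributeNames", "EdgeDataset", function(object)
  names(object@table))

#' @rdname accessors
#' @export
setGeneric("attributeWeights",
           function(object) standardGeneric("attributeWeights"))
#' @rdname accessors
#' @export
setMethod("attributeWeights", "DQProfile", function(object) {
  w <- vapply(object@attributes, function(a) a@weight, numeric(1))
  names(w) <- attributeNames(object)
  w
})

#' @rdname accessors
#' @export
setGeneric("profileAttributes",
           function(object) standardGeneric("profileAttributes"))
#' @rdname accessors
#' @export
setMethod("profileAttributes", "DQProfile", function(object) {
  a <- object@attributes
  names(a) <- attributeNames(object)
  a
})

#' @rdname accessors
#' @export
setGeneric("profileDimensions",
           function(object) standardGeneric("profileDimensions"))
#' @rdname accessors
#' @export
setMethod("profileDimensions", "DQProfile", function(object) object@dimensions)

#' @rdname accessors
#' @export
setGeneric("profileRules", function(object) standardGeneric("profileRules"))
#' @rdname accessors
#' @export
setMethod("profileRules", "DQProfile", function(object) {
  r <- object@rules
  names(r) <- vapply(r, function(x) x@ruleId, character(1))
  r
})

#' @rdname accessors
#' @export
setGeneric("profileMeasures",
           function(object) standardGeneric("profileMeasures"))
#' @rdname accessors
#' @export
setMethod("profileMeasures", "DQProfile", function(object) object@measures)

#' @rdname accessors
#' @export
setGeneric("selectedFeatures",
           function(object) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "DQProfile",
          function(object) object@selectedFeatures)

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setMethod("edgeTable", "EdgeDataset", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("edgeLabels", function(object) standardGeneric("edgeLabels"))
#' @rdname accessors
#' @export
setMethod("edgeLabels", "EdgeDataset", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("edgeMetadata", function(object) standardGeneric("edgeMetadata"))
#' @rdname accessors
#' @export
setMethod("edgeMetadata", "EdgeDataset", function(object) object@metadata)

setMethod("show", "DQProfile", function(object) {
  cat(sprintf("DQProfile (%s) version %d\n", object@role, object@version))
  if (!is.na(object@nodeId)) cat("  node:      ", object@nodeId, "\n")
  cat("  attributes:", length(object@attributes),
      sprintf("(rows profiled: %d)\n", object@rowCount))
  cat("  dimensions:", paste(object@dimensions, collapse = ", "), "\n")
  cat("  rules:     ", length(object@rules), "\n")
  cat("  measures:  ",
      if (length(object@measures)) sprintf("%d attributes",
                                           length(object@measures))
      else "none", "\n")
  if (length(object@selectedFeatures))
    cat("  selected features:",
        paste(utils::head(object@selectedFeatures, 8), collapse = ", "),
        if (length(object@selectedFeatures) > 8) "..." else "", "\n")
  invisible(object)
})

setMethod("show", "EdgeDataset", function(object) {
  cat(sprintf("EdgeDataset '%s': %d rows x %d attributes\n",
              object@nodeId, nrow(object@table), ncol(object@table)))
  tab <- table(object@labels)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  miss <- mean(is.na(as.matrix(object@table)))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(object)
})

setMethod("show", "AttributeMeasures", function(object) {
  cat(sprintf(paste0("AttributeMeasures: range [%s, %s], missing %.3f, ",
                     "unique %.3f, outlier %.3f, skew %s\n"),
              format(object@observedMin), format(object@observedMax),
              object@missingFraction, object@uniqueFraction,
              object@outlierFraction, format(object@skewness, digits = 4)))
  invisible(object)
})
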