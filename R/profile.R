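#' Normalize attribute weights to sum to one
#'
#' Divides by the total so the weights sum to 1; idempotent.
#'
#' @param w Non-negative numeric weights with positive sum.
#' @return Weights rescaled to sum to 1.
#' @examples normalizeWeights(c(2, 1, 1))
#' @export
normalizeWeights <- function(w) {
  stopIfNot(is.numeric(w) && length(w) > 0 && !anyNA(w),
            "weights must be numeric and non-missing")
  stopIfNot(all(w >= 0) && sum(w) > 0,
            "weights must be non-negative with positive sum")
  w / sum(w)
}

#' Create a baseline data-quality profile
#'
#' Builds the version-0 baseline profile (the server's blueprint) from
#' attribute specifications, the quality dimensions to monitor, and the rule
#' table. When no weights are supplied, each attribute receives the uniform
#' weight `1/D`. Supplied weights must already sum to 1 (within 1e-9) unless
#' `normalize = TRUE` requests rescaling.
#'
#' @param attributes Character vector of attribute names, or a list of
#'   [AttributeSpec-class] objects.
#' @param dimensions Subset of [qualityDimensions()] to monitor.
#' @param rules List of [QualityRule-class] objects (default:
#'   [defaultRuleTable()]).
#' @param weights Optional numeric weights, one per attribute; overrides any
#'   weights carried by the specs.
#' @param normalize If `TRUE`, rescale supplied weights to sum to 1 instead of
#'   erroring on a bad sum.
#' @param tolerances Default per-dimension tolerances applied to attributes
#'   constructed from bare names.
#' @param workload Optional [WorkloadStub-class].
#' @return A [DQProfile-class] with role `"baseline"`, version 0, no measures.
#' @examples
#' p <- initializeProfile(c("fhr", "accel", "decel"))
#' attributeWeights(p)
#' @export
initializeProfile <- function(attributes,
                              dimensions = qualityDimensions(),
                              rules = defaultRuleTable(),
                              weights = NULL, normalize = FALSE,
                              tolerances = c(completeness = 0.7),
                              workload = NULL) {
  if (is.character(attributes)) {
    attributes <- lapply(attributes, function(nm)
      attributeSpec(nm, tolerances = tolerances))
  }
  stopIfNot(length(attributes) > 0, "at least one attribute is required")
  nms <- vapply(attributes, function(a) a@name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate attribute names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  rids <- vapply(rules, function(r) r@ruleId, character(1))
  if (anyDuplicated(rids))
    stop("duplicate rule ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)

  w <- if (!is.null(weights)) as.numeric(weights)
       else vapply(attributes, function(a) a@weight, numeric(1))
  if (all(is.na(w))) {
    w <- rep(1 / length(attributes), length(attributes))
  } else {
    stopIfNot(!anyNA(w), "weights must be supplied for all attributes or none")
    if (any(w < 0 | w > 1))
      stop("every weight must lie in [0, 1]", call. = FALSE)
    if (abs(sum(w) - 1) > 1e-9) {
      if (normalize) w <- normalizeWeights(w)
      else stop("attribute weights must sum to 1 (got ", format(sum(w)),
                "); pass normalize = TRUE to rescale", call. = FALSE)
    }
  }
  attributes <- Map(function(a, wi) { a@weight <- wi; a }, attributes, w)

  prof <- new("DQProfile", version = 0L, role = "baseline",
              attributes = attributes, dimensions = dimensions,
              rules = rules, workload = workload)
  viol <- validateProfile(prof)
  stopIfNot(length(viol) == 0,
            paste("invalid profile:", paste(viol, collapse = "; ")))
  prof
}

#' Validate a data-quality profile
#'
#' Checks every profile invariant and returns the violations as messages
#' (empty when the profile is valid); nothing is raised, so callers can
#' inspect a broken profile.
#'
#' Checked: weight range and sum (must be 1 within 1e-9), tolerance ranges,
#' bound ordering, version sign, unique attribute and rule names, measure
#' coverage, dimension membership, and per-measure invariants.
#'
#' @param profile A [DQProfile-class].
#' @return Character vector of violation messages; `character(0)` if valid.
#' @examples
#' validateProfile(initializeProfile(c("a", "b")))
#' @export
validateProfile <- function(profile) {
  v <- character()
  nms <- attributeNames(profile)
  if (anyDuplicated(nms))
    v <- c(v, "attributes: duplicate attribute names")
  w <- vapply(profile@attributes, function(a) a@weight, numeric(1))
  if (anyNA(w)) {
    v <- c(v, "weight: missing attribute weight")
  } else {
    if (any(w < 0 | w > 1))
      v <- c(v, "weight: attribute weight outside [0, 1]")
    if (length(w) && abs(sum(w) - 1) > 1e-9)
      v <- c(v, sprintf("weight: sum of attribute weights is %s, not 1",
                        format(sum(w))))
  }
  for (a in profile@attributes) {
    if (length(a@tolerances) && any(a@tolerances < 0 | a@tolerances > 1))
      v <- c(v, sprintf("tolerances[%s]: tolerance outside [0, 1]", a@name))
    if (!is.na(a@allowedMin) && !is.na(a@allowedMax) &&
        a@allowedMin > a@allowedMax)
      v <- c(v, sprintf("allowedMin/allowedMax[%s]: allowedMin > allowedMax",
                        a@name))
  }
  if (profile@version < 0L)
    v <- c(v, "version: must be non-negative")
  if (length(profile@dimensions) &&
      !all(profile@dimensions %in% qualityDimensions()))
    v <- c(v, "dimensions: unknown quality dimension")
  rids <- vapply(profile@rules, function(r) r@ruleId, character(1))
  if (anyDuplicated(rids))
    v <- c(v, "rules: duplicate rule ids")
  for (r in profile@rules) {
    mi <- r@condition$missing
    if (!is.null(mi) && (length(mi) != 2L || anyNA(mi) || mi[1] > mi[2]))
      v <- c(v, sprintf("rules[%s]: malformed missing-fraction interval",
                        r@ruleId))
  }
  if (length(profile@measures)) {
    missing_m <- setdiff(nms, names(profile@measures))
    if (length(missing_m))
      v <- c(v, paste("measures: no measures for attribute(s)",
                      paste(missing_m, collapse = ", ")))
    for (nm in names(profile@measures)) {
      ok <- validObject(profile@measures[[nm]], test = TRUE)
      if (!isTRUE(ok))
        v <- c(v, sprintf("measures[%s]: %s", nm,
                          paste(ok, collapse = "; ")))
    }
  }
  v
}

#' Compare two profiles for structural equality
#'
#' Field-by-field comparison on the flattened profile representation; numeric
#' fields compare within `tol` (default 1e-9, matching decimal XML
#' serialization), everything else exactly.
#'
#' @param a,b [DQProfile-class] objects.
#' @param tol Numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @examples
#' p <- initializeProfile(c("a", "b"))
#' profilesEqual(p, p)
#' @export
profilesEqual <- function(a, b, tol = 1e-9) {
  fa <- flattenProfile(a)
  fb <- flattenProfile(b)
  if (!identical(names(fa), names(fb))) return(FALSE)
  for (k in names(fa)) {
    x <- fa[[k]]; y <- fb[[k]]
    if (is.numeric(x) && is.numeric(y)) {
      if (xor(is.na(x), is.na(y))) return(FALSE)
      if (!is.na(x) && abs(x - y) > tol) return(FALSE)
    } else if (!identical(x, y)) return(FALSE)
  }
  TRUE
}
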