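# Versioned profile diffs: a profile flattens to an ordered map of
# path -> atomic scalar; a delta is the exact key-level difference of two such
# maps, so that apply(old, diff(old, new)) reproduces new. Only deltas need be
# transmitted between server and edges after the first round.

collapseCSV <- function(x) paste(x, collapse = ",")
splitCSV <- function(s) if (identical(s, "")) character() else
  strsplit(s, ",", fixed = TRUE)[[1]]

canonicalCondition <- function(cond) {
  mi <- cond$missing
  cl <- cond$closed %||% c(TRUE, TRUE)
  list(missingMin = if (is.null(mi)) NA_real_ else as.numeric(mi[1]),
       missingMax = if (is.null(mi)) NA_real_ else as.numeric(mi[2]),
       closedMin = as.logical(cl[1]), closedMax = as.logical(cl[2]),
       dataType = as.character(cond$dataType %||% "any"),
       skew = as.character(cond$skew %||% "any"),
       mnar = if (isMissingScalar(cond$mnar)) "any"
              else tolower(as.character(cond$mnar)),
       scope = as.character(cond$scope %||% "column"))
}

conditionFromCanonical <- function(cc) {
  cond <- list()
  if (!is.na(cc$missingMin))
    cond$missing <- c(cc$missingMin, cc$missingMax)
  cond$closed <- c(cc$closedMin, cc$closedMax)
  if (cc$dataType != "any") cond$dataType <- cc$dataType
  if (cc$skew != "any") cond$skew <- cc$skew
  if (cc$mnar != "any") cond$mnar <- identical(cc$mnar, "true")
  if (cc$scope != "column") cond$scope <- cc$scope
  cond
}

# Ordered map of path -> atomic scalar. Rule params and workload entries must
# be atomic scalars; tolerance/param/workload keys are canonically sorted.
flattenProfile <- function(profile) {
  out <- list()
  put <- function(path, value) out[[path]] <<- value

  put("version", profile@version)
  put("role", profile@role)
  put("nodeId", profile@nodeId)
  put("rowCount", profile@rowCount)
  put("dimensions", collapseCSV(profile@dimensions))
  put("selectedFeatures", collapseCSV(profile@selectedFeatures))

  nms <- attributeNames(profile)
  put("attrOrder", collapseCSV(nms))
  for (a in profile@attributes) {
    p <- paste0("attributes/", a@name, "/")
    put(paste0(p, "dataType"), a@dataType)
    put(paste0(p, "weight"), a@weight)
    put(paste0(p, "allowedMin"), a@allowedMin)
    put(paste0(p, "allowedMax"), a@allowedMax)
    put(paste0(p, "ruleIds"), collapseCSV(a@ruleIds))
    for (d in sort(names(a@tolerances)))
      put(paste0(p, "tolerances/", d), unname(a@tolerances[d]))
  }

  rids <- vapply(profile@rules, function(r) r@ruleId, character(1))
  put("ruleOrder", collapseCSV(rids))
  for (r in profile@rules) {
    p <- paste0("rules/", r@ruleId, "/")
    put(paste0(p, "dimension"), r@dimension)
    put(paste0(p, "action"), r@action)
    cc <- canonicalCondition(r@condition)
    for (k in names(cc)) put(paste0(p, "condition/", k), cc[[k]])
    for (k in sort(names(r@params))) {
      stopIfNot(is.atomic(r@params[[k]]) && length(r@params[[k]]) == 1L,
                "rule params must be atomic scalars")
      put(paste0(p, "params/", k), r@params[[k]])
    }
  }

  put("measureOrder", collapseCSV(names(profile@measures)))
  for (nm in names(profile@measures)) {
    m <- profile@measures[[nm]]
    p <- paste0("measures/", nm, "/")
    put(paste0(p, "observedMin"), m@observedMin)
    put(paste0(p, "observedMax"), m@observedMax)
    put(paste0(p, "modeType"),
        if (isMissingScalar(m@mode)) "na"
        else if (is.numeric(m@mode)) "numeric" else "character")
    put(paste0(p, "mode"),
        if (isMissingScalar(m@mode)) NA_character_
        else if (is.numeric(m@mode)) fmtNum(m@mode) else as.character(m@mode))
    put(paste0(p, "skewness"), m@skewness)
    put(paste0(p, "missingFraction"), m@missingFraction)
    put(paste0(p, "uniqueFraction"), m@uniqueFraction)
    put(paste0(p, "outlierFraction"), m@outlierFraction)
    put(paste0(p, "completeness"), m@completeness)
    put(paste0(p, "cv"), m@cv)
    put(paste0(p, "mnar"), m@mnar)
    put(paste0(p, "degenerate"), m@degenerate)
  }

  put("workload/present", !is.null(profile@workload))
  if (!is.null(profile@workload)) {
    for (k in sort(names(profile@workload@config)))
      put(paste0("workload/config/", k),
          as.character(profile@workload@config[[k]]))
    for (k in sort(names(profile@workload@realtime)))
      put(paste0("workload/realtime/", k),
          as.character(profile@workload@realtime[[k]]))
  }
  out
}

unflattenProfile <- function(flat) {
  get1 <- function(path, default = NULL) flat[[path]] %||% default
  prefixed <- function(prefix) {
    keys <- names(flat)[startsWith(names(flat), prefix)]
    stats::setNames(flat[keys], substring(keys, nchar(prefix) + 1L))
  }

  attrs <- lapply(splitCSV(get1("attrOrder", "")), function(nm) {
    p <- paste0("attributes/", nm, "/")
    tolv <- prefixed(paste0(p, "tolerances/"))
    attributeSpec(nm,
      dataType = get1(paste0(p, "dataType"), "numeric"),
      allowedMin = get1(paste0(p, "allowedMin"), NA_real_),
      allowedMax = get1(paste0(p, "allowedMax"), NA_real_),
      weight = get1(paste0(p, "weight"), NA_real_),
      tolerances = if (length(tolv))
        stats::setNames(vapply(tolv, as.numeric, numeric(1)), names(tolv))
        else stats::setNames(numeric(0), character(0)),
      ruleIds = splitCSV(get1(paste0(p, "ruleIds"), "")))
  })

  rules <- lapply(splitCSV(get1("ruleOrder", "")), function(rid) {
    p <- paste0("rules/", rid, "/")
    cc <- prefixed(paste0(p, "condition/"))
    qualityRule(rid,
      dimension = get1(paste0(p, "dimension"), "completeness"),
      action = get1(paste0(p, "action"), "NONE"),
      condition = conditionFromCanonical(cc),
      params = prefixed(paste0(p, "params/")))
  })

  measures <- list()
  for (nm in splitCSV(get1("measureOrder", ""))) {
    p <- paste0("measures/", nm, "/")
    modeType <- get1(paste0(p, "modeType"), "na")
    modeRaw <- get1(paste0(p, "mode"), NA_character_)
    measures[[nm]] <- new("AttributeMeasures",
      observedMin = get1(paste0(p, "observedMin"), NA_real_),
      observedMax = get1(paste0(p, "observedMax"), NA_real_),
      mode = switch(modeType, na = NA, numeric = as.numeric(modeRaw),
                    character = as.character(modeRaw)),
      skewness = get1(paste0(p, "skewness"), NA_real_),
      missingFraction = get1(paste0(p, "missingFraction"), NA_real_),
      uniqueFraction = get1(paste0(p, "uniqueFraction"), NA_real_),
      outlierFraction = get1(paste0(p, "outlierFraction"), NA_real_),
      completeness = get1(paste0(p, "completeness"), NA_real_),
      cv = get1(paste0(p, "cv"), NA_real_),
      mnar = get1(paste0(p, "mnar"), FALSE),
      degenerate = get1(paste0(p, "degenerate"), FALSE))
  }

  workload <- NULL
  if (isTRUE(get1("workload/present", FALSE))) {
    workload <- workloadStub(config = prefixed("workload/config/"),
                             realtime = prefixed("workload/realtime/"))
  }

  new("DQProfile",
      version = as.integer(get1("version", 0L)),
      role = get1("role", "baseline"),
      nodeId = get1("nodeId", NA_character_),
      rowCount = as.integer(get1("rowCount", 0L)),
      attributes = attrs,
      dimensions = splitCSV(get1("dimensions", "")),
      rules = rules,
      measures = measures,
      selectedFeatures = splitCSV(get1("selectedFeatures", "")),
      workload = workload)
}

#' Diff and patch versioned profiles
#'
#' `diffProfiles()` computes the exact field-level delta between two profiles
#' on the flattened path representation; `applyDelta()` patches a profile with
#' a delta. The pair forms an exact patch algebra:
#' `applyDelta(old, diffProfiles(old, new))` equals `new`, and the diff of a
#' profile with itself has no changed fields. After the first federation
#' round, only these deltas need be exchanged.
#'
#' @param old,new [DQProfile-class] objects with `old` at a version no later
#'   than `new`.
#' @return `diffProfiles()`: a `ProfileDelta` (list with `versionFrom`,
#'   `versionTo`, and `changed`, a list of `(path, old, new)` records where
#'   `NULL` marks an added/removed field). `applyDelta()`: the patched
#'   [DQProfile-class].
#' @examples
#' p <- initializeProfile(c("a", "b"))
#' q <- p; q@version <- 1L
#' d <- diffProfiles(p, q)
#' profilesEqual(applyDelta(p, d), q, tol = 0)
#' @export
diffProfiles <- function(old, new) {
  stopIfNot(old@version <= new@version,
            "old profile version must not exceed the new version")
  fo <- flattenProfile(old)
  fn <- flattenProfile(new)
  changed <- list()
  for (k in union(names(fo), names(fn))) {
    ov <- fo[[k]]; nv <- fn[[k]]
    if (!identical(ov, nv))
      changed[[length(changed) + 1L]] <- list(path = k, old = ov, new = nv)
  }
  structure(list(versionFrom = old@version, versionTo = new@version,
                 changed = changed),
            class = "ProfileDelta")
}

#' @rdname diffProfiles
#' @param delta A `ProfileDelta` whose `versionFrom` matches `old`'s version.
#' @export
applyDelta <- function(old, delta) {
  stopIfNot(inherits(delta, "ProfileDelta"), "delta must be a ProfileDelta")
  if (!identical(as.integer(delta$versionFrom), old@version))
    stop("version mismatch: delta starts at version ", delta$versionFrom,
         " but the profile is at version ", old@version, call. = FALSE)
  flat <- flattenProfile(old)
  for (ch in delta$changed) {
    if (is.null(ch$new)) flat[[ch$path]] <- NULL
    else flat[[ch$path]] <- ch$new
  }
  unflattenProfile(flat)
}

#' @export
print.ProfileDelta <- function(x, ...) {
  cat(sprintf("ProfileDelta: version %d -> %d, %d changed field(s)\n",
              x$versionFrom, x$versionTo, length(x$changed)))
  for (ch in utils::head(x$changed, 20))
    cat("  ", ch$path, "\n")
  if (length(x$changed) > 20) cat("  ...\n")
  invisible(x)
}
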