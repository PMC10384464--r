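# XML dialect for data-quality profiles. Element names:
# Profile / Dimensions / Attributes / Attribute / Tolerances / RuleRefs /
# Measures / Rules / Rule / Condition / Params / FederatedFeatures / Workload,
# with attributes id, version, action, threshold. An XSD for the dialect ships
# in inst/extdata/dqprofile.xsd. Numeric fields serialize with 17 significant
# digits so that read(write(p)) is the identity on valid profiles.

actionXMLNames <- c(
  NONE = "None", MEAN_IMPUTE = "MeanImputation",
  MEDIAN_IMPUTE = "MedianImputation", MODE_IMPUTE = "ModeImputation",
  KNN_IMPUTE = "KNNImputation", MULTIPLE_IMPUTE = "MultipleImputation",
  DROP_COLUMN = "DeleteColumn", DROP_ROWS = "DeleteRows")

actionFromXML <- function(x) {
  hit <- names(actionXMLNames)[actionXMLNames == x]
  if (length(hit) != 1L)
    stop("unknown rule action in XML: ", x, call. = FALSE)
  hit
}

xmlBool <- function(x) if (isTRUE(x)) "true" else "false"

addNumChild <- function(parent, name, value) {
  if (!is.na(value)) xml2::xml_add_child(parent, name, fmtNum(value))
}

#' Write a data-quality profile to XML
#'
#' Serializes a valid [DQProfile-class] to the package's XML dialect. The
#' document round-trips: `readProfileXML(writeProfileXML(p))` structurally
#' equals `p`, including rule parameters and measures.
#'
#' @param profile A [DQProfile-class] passing [validateProfile()].
#' @param file Optional path; when given the document is also written there
#'   (UTF-8).
#' @return An `xml2::xml_document`, invisibly when `file` is given.
#' @examples
#' p <- initializeProfile(c("a", "b"))
#' doc <- writeProfileXML(p)
#' profilesEqual(readProfileXML(doc), p)
#' @export
writeProfileXML <- function(profile, file = NULL) {
  viol <- validateProfile(profile)
  stopIfNot(length(viol) == 0,
            paste("profile fails validation:", paste(viol, collapse = "; ")))

  doc <- xml2::xml_new_root("Profile",
    version = as.character(profile@version), role = profile@role)
  if (!is.na(profile@nodeId))
    xml2::xml_set_attr(doc, "nodeId", profile@nodeId)
  xml2::xml_set_attr(doc, "rowCount", as.character(profile@rowCount))

  dims <- xml2::xml_add_child(doc, "Dimensions")
  for (d in profile@dimensions)
    xml2::xml_add_child(dims, "Dimension", name = d)

  attrs <- xml2::xml_add_child(doc, "Attributes")
  for (a in profile@attributes) {
    an <- xml2::xml_add_child(attrs, "Attribute", id = a@name,
                              dataType = a@dataType,
                              weight = fmtNum(a@weight))
    if (!is.na(a@allowedMin))
      xml2::xml_set_attr(an, "allowedMin", fmtNum(a@allowedMin))
    if (!is.na(a@allowedMax))
      xml2::xml_set_attr(an, "allowedMax", fmtNum(a@allowedMax))
    tn <- xml2::xml_add_child(an, "Tolerances")
    for (d in names(a@tolerances))
      xml2::xml_add_child(tn, "Tolerance", dimension = d,
                          value = fmtNum(unname(a@tolerances[d])))
    rn <- xml2::xml_add_child(an, "RuleRefs")
    for (rid in a@ruleIds)
      xml2::xml_add_child(rn, "RuleRef", id = rid)
    m <- profile@measures[[a@name]]
    if (!is.null(m)) {
      mn <- xml2::xml_add_child(an, "Measures")
      addNumChild(mn, "Min", m@observedMin)
      addNumChild(mn, "Max", m@observedMax)
      if (!isMissingScalar(m@mode)) {
        if (is.numeric(m@mode))
          xml2::xml_add_child(mn, "Mode", fmtNum(m@mode), type = "numeric")
        else
          xml2::xml_add_child(mn, "Mode", as.character(m@mode),
                              type = "character")
      }
      addNumChild(mn, "Skewness", m@skewness)
      addNumChild(mn, "MissingFraction", m@missingFraction)
      addNumChild(mn, "UniqueFraction", m@uniqueFraction)
      addNumChild(mn, "OutlierFraction", m@outlierFraction)
      addNumChild(mn, "Completeness", m@completeness)
      addNumChild(mn, "CV", m@cv)
      xml2::xml_add_child(mn, "MNAR", xmlBool(m@mnar))
      xml2::xml_add_child(mn, "Degenerate", xmlBool(m@degenerate))
    }
  }

  rules <- xml2::xml_add_child(doc, "Rules")
  for (r in profile@rules) {
    rn <- xml2::xml_add_child(rules, "Rule", id = r@ruleId,
                              dimension = r@dimension,
                              action = unname(actionXMLNames[r@action]))
    cc <- canonicalCondition(r@condition)
    if (r@action %in% c("DROP_COLUMN", "DROP_ROWS") && !is.na(cc$missingMin))
      xml2::xml_set_attr(rn, "threshold", fmtNum(cc$missingMin))
    cn <- xml2::xml_add_child(rn, "Condition",
      dataType = cc$dataType, skew = cc$skew, mnar = cc$mnar,
      scope = cc$scope)
    if (!is.na(cc$missingMin)) {
      xml2::xml_set_attr(cn, "missingMin", fmtNum(cc$missingMin))
      xml2::xml_set_attr(cn, "missingMax", fmtNum(cc$missingMax))
      xml2::xml_set_attr(cn, "closedMin", xmlBool(cc$closedMin))
      xml2::xml_set_attr(cn, "closedMax", xmlBool(cc$closedMax))
    }
    if (length(r@params)) {
      pn <- xml2::xml_add_child(rn, "Params")
      for (k in names(r@params)) {
        v <- r@params[[k]]
        xml2::xml_add_child(pn, "Param", key = k,
          value = if (is.numeric(v)) fmtNum(v) else as.character(v),
          type = class(v)[1])
      }
    }
  }

  if (length(profile@selectedFeatures)) {
    fn <- xml2::xml_add_child(doc, "FederatedFeatures")
    for (i in seq_along(profile@selectedFeatures))
      xml2::xml_add_child(fn, "Feature", rank = as.character(i),
                          name = profile@selectedFeatures[i])
  }

  if (!is.null(profile@workload)) {
    wn <- xml2::xml_add_child(doc, "Workload")
    for (k in names(profile@workload@config))
      xml2::xml_add_child(wn, "Config", key = k,
                          value = as.character(profile@workload@config[[k]]))
    for (k in names(profile@workload@realtime))
      xml2::xml_add_child(wn, "RealTime", key = k,
                          value = as.character(profile@workload@realtime[[k]]))
  }

  if (!is.null(file)) {
    xml2::write_xml(doc, file, encoding = "UTF-8")
    return(invisible(doc))
  }
  doc
}

checkChildren <- function(node, allowed) {
  kids <- xml2::xml_name(xml2::xml_children(node))
  unknown <- setdiff(kids, allowed)
  if (length(unknown))
    stop("unknown element(s) under <", xml2::xml_name(node), ">: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
}

strAttr <- function(node, name, default) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

numAttr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_real_ else as.numeric(v)
}

numChild <- function(node, name) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing")) NA_real_
  else as.numeric(xml2::xml_text(ch))
}

#' Read a data-quality profile from XML
#'
#' @param x An `xml2::xml_document`, a path to an XML file, or an XML string.
#' @return A [DQProfile-class].
#' @seealso [writeProfileXML()], [validateProfileXML()]
#' @export
readProfileXML <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  stopIfNot(identical(xml2::xml_name(root), "Profile"),
            "root element must be <Profile>")
  checkChildren(root, c("Dimensions", "Attributes", "Rules",
                        "FederatedFeatures", "Workload"))
  version <- xml2::xml_attr(root, "version")
  if (is.na(version))
    stop("version attribute missing on <Profile>", call. = FALSE)

  dims <- xml2::xml_attr(
    xml2::xml_find_all(root, "./Dimensions/Dimension"), "name")

  measures <- list()
  attrNodes <- xml2::xml_find_all(root, "./Attributes/Attribute")
  attrs <- lapply(attrNodes, function(an) {
    checkChildren(an, c("Tolerances", "RuleRefs", "Measures"))
    nm <- xml2::xml_attr(an, "id")
    tolNodes <- xml2::xml_find_all(an, "./Tolerances/Tolerance")
    tol <- stats::setNames(
      vapply(tolNodes, numAttr, numeric(1), name = "value"),
      xml2::xml_attr(tolNodes, "dimension"))
    mn <- xml2::xml_find_first(an, "./Measures")
    if (!inherits(mn, "xml_missing")) {
      modeNode <- xml2::xml_find_first(mn, "./Mode")
      modeVal <- if (inherits(modeNode, "xml_missing")) NA
        else if (identical(xml2::xml_attr(modeNode, "type"), "numeric"))
          as.numeric(xml2::xml_text(modeNode))
        else xml2::xml_text(modeNode)
      mnarNode <- xml2::xml_find_first(mn, "./MNAR")
      degNode <- xml2::xml_find_first(mn, "./Degenerate")
      measures[[nm]] <<- new("AttributeMeasures",
        observedMin = numChild(mn, "./Min"),
        observedMax = numChild(mn, "./Max"),
        mode = modeVal,
        skewness = numChild(mn, "./Skewness"),
        missingFraction = numChild(mn, "./MissingFraction"),
        uniqueFraction = numChild(mn, "./UniqueFraction"),
        outlierFraction = numChild(mn, "./OutlierFraction"),
        completeness = numChild(mn, "./Completeness"),
        cv = numChild(mn, "./CV"),
        mnar = !inherits(mnarNode, "xml_missing") &&
          identical(xml2::xml_text(mnarNode), "true"),
        degenerate = !inherits(degNode, "xml_missing") &&
          identical(xml2::xml_text(degNode), "true"))
    }
    attributeSpec(nm,
      dataType = strAttr(an, "dataType", "numeric"),
      allowedMin = numAttr(an, "allowedMin"),
      allowedMax = numAttr(an, "allowedMax"),
      weight = numAttr(an, "weight"),
      tolerances = tol,
      ruleIds = xml2::xml_attr(
        xml2::xml_find_all(an, "./RuleRefs/RuleRef"), "id"))
  })

  rules <- lapply(xml2::xml_find_all(root, "./Rules/Rule"), function(rn) {
    checkChildren(rn, c("Condition", "Params"))
    cn <- xml2::xml_find_first(rn, "./Condition")
    cond <- list()
    if (!inherits(cn, "xml_missing")) {
      cond <- conditionFromCanonical(list(
        missingMin = numAttr(cn, "missingMin"),
        missingMax = numAttr(cn, "missingMax"),
        closedMin = !identical(xml2::xml_attr(cn, "closedMin"), "false"),
        closedMax = !identical(xml2::xml_attr(cn, "closedMax"), "false"),
        dataType = strAttr(cn, "dataType", "any"),
        skew = strAttr(cn, "skew", "any"),
        mnar = strAttr(cn, "mnar", "any"),
        scope = strAttr(cn, "scope", "column")))
    }
    pNodes <- xml2::xml_find_all(rn, "./Params/Param")
    params <- stats::setNames(lapply(pNodes, function(p) {
      v <- xml2::xml_attr(p, "value")
      switch(strAttr(p, "type", "character"),
             numeric = as.numeric(v), integer = as.integer(v),
             logical = as.logical(v), v)
    }), xml2::xml_attr(pNodes, "key"))
    qualityRule(xml2::xml_attr(rn, "id"),
                dimension = strAttr(rn, "dimension", "completeness"),
                action = actionFromXML(xml2::xml_attr(rn, "action")),
                condition = cond, params = params)
  })

  featNodes <- xml2::xml_find_all(root, "./FederatedFeatures/Feature")
  feats <- character()
  if (length(featNodes)) {
    ord <- order(as.integer(xml2::xml_attr(featNodes, "rank")))
    feats <- xml2::xml_attr(featNodes, "name")[ord]
  }

  workload <- NULL
  wn <- xml2::xml_find_first(root, "./Workload")
  if (!inherits(wn, "xml_missing")) {
    cfgNodes <- xml2::xml_find_all(wn, "./Config")
    rtNodes <- xml2::xml_find_all(wn, "./RealTime")
    workload <- workloadStub(
      config = stats::setNames(as.list(xml2::xml_attr(cfgNodes, "value")),
                               xml2::xml_attr(cfgNodes, "key")),
      realtime = stats::setNames(as.list(xml2::xml_attr(rtNodes, "value")),
                                 xml2::xml_attr(rtNodes, "key")))
  }

  nid <- xml2::xml_attr(root, "nodeId")
  new("DQProfile",
      version = as.integer(version),
      role = strAttr(root, "role", "baseline"),
      nodeId = if (is.na(nid)) NA_character_ else nid,
      rowCount = as.integer(strAttr(root, "rowCount", "0")),
      attributes = attrs, dimensions = dims, rules = rules,
      measures = measures, selectedFeatures = feats, workload = workload)
}

#' Validate profile XML against the shipped XSD
#'
#' @param x An `xml2::xml_document` or path to a profile XML file.
#' @param xsd Path to the schema (defaults to the XSD shipped with the
#'   package).
#' @return Logical; attribute `"errors"` carries any validation messages.
#' @export
validateProfileXML <- function(x,
    xsd = system.file("extdata", "dqprofile.xsd", package = "fdqp")) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  schema <- xml2::read_xml(xsd)
  xml2::xml_validate(doc, schema)
}
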