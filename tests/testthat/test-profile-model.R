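test_that("initializeProfile assigns and checks weights", {
  p <- initializeProfile(c("a", "b", "c"))
  expect_equal(unname(attributeWeights(p)), rep(1 / 3, 3))
  expect_equal(profileVersion(p), 0L)
  expect_identical(profileRole(p), "baseline")
  expect_length(profileMeasures(p), 0)

  p2 <- initializeProfile(c("a", "b", "c"), weights = c(0.5, 0.3, 0.2))
  expect_equal(unname(attributeWeights(p2)), c(0.5, 0.3, 0.2))

  expect_error(initializeProfile(c("a", "b", "c"),
                                 weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
  p3 <- initializeProfile(c("a", "b", "c"), weights = c(0.5, 0.5, 0.5),
                          normalize = TRUE)
  expect_equal(sum(attributeWeights(p3)), 1)

  expect_error(initializeProfile(c("a", "a", "b")), "duplicate attribute")
  expect_error(initializeProfile("a", rules = list(
    qualityRule("2.1"), qualityRule("2.1"))), "duplicate rule")
  expect_error(initializeProfile(c("a", "b"), weights = c(1.5, -0.5)),
               "\\[0, 1\\]")
})

test_that("weight normalization is idempotent", {
  w <- c(2, 3, 5)
  expect_equal(normalizeWeights(normalizeWeights(w)), normalizeWeights(w))
})

test_that("validateProfile reports violations instead of raising", {
  expect_identical(validateProfile(tinyProfile()), character(0))

  p <- tinyProfile()
  p@attributes[[1]]@weight <- 0.4  # weights now sum to ~0.8 + 1/3...
  p@attributes[[2]]@weight <- 0.2
  p@attributes[[3]]@weight <- 0.2
  v <- validateProfile(p)
  expect_length(v, 1)
  expect_match(v, "weight")
  expect_match(v, "sum")

  q <- tinyProfile()
  q@attributes[[2]]@tolerances <- c(completeness = 1.3)
  v2 <- validateProfile(q)
  expect_match(v2, "tolerance")

  r <- tinyProfile()
  r@attributes[[1]]@allowedMin <- 10
  r@attributes[[1]]@allowedMax <- 5
  expect_match(validateProfile(r), "allowedMin")
})

test_that("XML round trip is the identity on valid profiles", {
  for (p in list(tinyProfile(), richProfile())) {
    doc <- writeProfileXML(p)
    expect_true(profilesEqual(readProfileXML(doc), p, tol = 0))
  }
  # file round trip
  f <- tempfile(fileext = ".xml")
  writeProfileXML(richProfile(), f)
  expect_true(profilesEqual(readProfileXML(f), richProfile(), tol = 0))
})

test_that("XML dialect serializes actions and validates against the XSD", {
  p <- tinyProfile()
  doc <- writeProfileXML(p)
  rule22 <- xml2::xml_find_first(doc, "//Rule[@id='2.2']")
  expect_identical(xml2::xml_attr(rule22, "action"), "DeleteColumn")
  expect_equal(as.numeric(xml2::xml_attr(rule22, "threshold")), 0.5)
  expect_true(validateProfileXML(doc))
  expect_true(validateProfileXML(writeProfileXML(richProfile())))
})

test_that("XML reader rejects malformed and unknown input", {
  expect_error(readProfileXML("<Profile role='baseline'/>"),
               "version attribute missing")
  expect_error(readProfileXML("<Profile version='1'><Bogus/></Profile>"),
               "unknown element")
  expect_error(readProfileXML("<Profile version='1'"), "")
  expect_error(readProfileXML("<NotAProfile/>"), "Profile")
})

test_that("hand-written per-attribute measure XML parses field by field", {
  xml <- paste0(
    '<Profile version="2" role="edge" nodeId="node1" rowCount="500">',
    '<Dimensions><Dimension name="completeness"/></Dimensions>',
    '<Attributes>',
    '<Attribute id="fhr_baseline" dataType="numeric" weight="1">',
    '<Tolerances><Tolerance dimension="completeness" value="0.7"/>',
    '</Tolerances><RuleRefs/>',
    '<Measures><Min>106</Min><Max>160</Max>',
    '<Mode type="numeric">133</Mode><Skewness>0.42</Skewness>',
    '<MissingFraction>0.12</MissingFraction>',
    '<UniqueFraction>0.3</UniqueFraction>',
    '<OutlierFraction>0.02</OutlierFraction>',
    '<Completeness>0.88</Completeness>',
    '</Measures></Attribute></Attributes><Rules/></Profile>')
  p <- readProfileXML(xml)
  expect_identical(profileVersion(p), 2L)
  expect_identical(nodeId(p), "node1")
  expect_identical(rowCount(p), 500L)
  m <- profileMeasures(p)$fhr_baseline
  expect_equal(m@observedMin, 106)
  expect_equal(m@observedMax, 160)
  expect_equal(m@mode, 133)
  expect_equal(m@skewness, 0.42)
  expect_equal(m@missingFraction, 0.12)
  expect_equal(m@uniqueFraction, 0.3)
  expect_equal(m@outlierFraction, 0.02)
  expect_equal(m@completeness, 0.88)
})

test_that("diff/apply form an exact patch algebra", {
  p <- tinyProfile()
  expect_length(diffProfiles(p, p)$changed, 0)

  q <- p
  q@version <- 1L
  d <- diffProfiles(p, q)
  expect_length(d$changed, 1)
  expect_identical(d$changed[[1]]$path, "version")
  expect_true(profilesEqual(applyDelta(p, d), q, tol = 0))

  # bit-identical after an XML round trip of both endpoints
  pR <- readProfileXML(writeProfileXML(p))
  qR <- readProfileXML(writeProfileXML(q))
  expect_true(profilesEqual(applyDelta(pR, diffProfiles(pR, qR)), qR,
                            tol = 0))

  # version mismatch is rejected
  expect_error(applyDelta(q, d), "version mismatch")
})

test_that("apply(old, diff(old, new)) holds over randomized profile pairs", {
  for (s in 1:12) {
    old <- randomProfile(s)
    new <- randomProfile(s + 100)
    new@version <- old@version + 1L
    d <- diffProfiles(old, new)
    expect_true(profilesEqual(applyDelta(old, d), new, tol = 0),
                info = paste("seed", s))
  }
})
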