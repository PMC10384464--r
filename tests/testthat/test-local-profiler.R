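test_that("profileAttribute counts and ranges directly", {
  m <- profileAttribute(c(1, 2, 3, NA), attributeSpec("x"))
  expect_equal(m@missingFraction, 0.25)
  expect_equal(m@observedMin, 1)
  expect_equal(m@observedMax, 3)
  expect_equal(m@completeness, 0.75)

  # a 70%-missing column profiles cleanly and later maps to column deletion
  x <- c(rep(NA_real_, 7), 1, 2, 3)
  m2 <- profileAttribute(x, attributeSpec("x"))
  expect_equal(m2@missingFraction, 0.7)
  dec <- selectRule(m2, attributeSpec("x"))
  expect_identical(dec$action, "DROP_COLUMN")
  expect_identical(dec$ruleId, "2.2")

  # all-missing column: degenerate, not an error
  m3 <- profileAttribute(rep(NA_real_, 5), attributeSpec("x"))
  expect_true(m3@degenerate)
  expect_equal(m3@missingFraction, 1)
  expect_error(profileAttribute(numeric(0), attributeSpec("x")), "empty")
})

test_that("every profiled statistic equals an independent recomputation", {
  set.seed(11)
  for (i in 1:8) {
    x <- rnorm(60, mean = 20, sd = 4)
    x[sample(60, 9)] <- NA
    m <- profileAttribute(x, attributeSpec("x"))
    obs <- x[!is.na(x)]
    expect_equal(m@observedMin, min(obs))
    expect_equal(m@observedMax, max(obs))
    expect_equal(m@missingFraction, mean(is.na(x)))
    expect_equal(m@completeness, 1 - mean(is.na(x)))
    expect_equal(m@uniqueFraction, length(unique(obs)) / length(obs))
    q <- quantile(obs, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    expect_equal(m@outlierFraction,
                 mean(obs < q[1] - 1.5 * iqr | obs > q[2] + 1.5 * iqr))
    n <- length(obs)
    expect_equal(m@skewness,
                 n / ((n - 1) * (n - 2)) * sum((obs - mean(obs))^3) /
                   sd(obs)^3)
    expect_equal(m@cv, sd(obs) / abs(mean(obs)))
    tab <- table(obs)
    expect_equal(m@mode, as.numeric(names(tab)[which.max(tab)]))
  }
})

test_that("buildEdgeProfile inherits the blueprint and measures the data", {
  sc <- smallScenario(seed = 3, corrupt = FALSE)
  baseline <- sc$baseline
  baseline@version <- 3L
  ep <- buildEdgeProfile(sc$edges[[1]], baseline)
  expect_identical(profileRole(ep), "edge")
  expect_identical(profileVersion(ep), 3L)   # version inherited
  expect_identical(nodeId(ep), "node1")
  expect_identical(rowCount(ep), 80L)
  expect_identical(names(profileMeasures(ep)), attributeNames(baseline))
  expect_equal(attributeWeights(ep), attributeWeights(baseline))

  # clean edge: completeness 1 everywhere
  epClean <- buildEdgeProfile(sc$clean[[1]], baseline)
  comp <- vapply(profileMeasures(epClean), function(m) m@completeness,
                 numeric(1))
  expect_true(all(comp == 1))

  # measured missing fractions equal the generator's bookkeeping exactly
  realized <- edgeMetadata(sc$edges[[1]])$missing$realizedRates
  measured <- vapply(profileMeasures(ep), function(m) m@missingFraction,
                     numeric(1))
  expect_equal(measured[names(realized)], realized)

  # the baseline is never mutated
  expect_identical(profileRole(baseline), "baseline")
  expect_length(profileMeasures(baseline), 0)

  expect_error(buildEdgeProfile(
    edgeDataset("n", data.frame(zz = 1:3), rep("N", 3)), baseline),
    "absent from the dataset")
})

test_that("profiling is invariant to row permutation", {
  sc <- smallScenario(seed = 4, corrupt = FALSE)
  ds <- sc$edges[[1]]
  perm <- sample(rowCount(ds))
  shuffled <- edgeDataset(nodeId(ds), edgeTable(ds)[perm, ],
                          edgeLabels(ds)[perm])
  a <- buildEdgeProfile(ds, sc$baseline)
  b <- buildEdgeProfile(shuffled, sc$baseline)
  expect_true(profilesEqual(a, b, tol = 1e-12))
})

test_that("measured fractions converge to injected rates at n = 2000", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 2000, nFeatures = 5, seed = 9)
  ds <- injectMissing(generateCohort(sp)[[1]], rates = 0.2, seed = 9)
  baseline <- initializeProfile(attributeNames(ds))
  ep <- buildEdgeProfile(ds, baseline)
  mf <- vapply(profileMeasures(ep), function(m) m@missingFraction,
               numeric(1))
  expect_true(all(abs(mf - 0.2) <= 0.02))
})

test_that("dimension tolerance checks pass at and above the tolerance", {
  sc <- smallScenario(seed = 5)
  base <- sc$baseline
  # corrupted node fails completeness at the 0.70 tolerance
  repBad <- checkDimensionTolerances(buildEdgeProfile(sc$edges[[2]], base))
  compRow <- repBad$table[repBad$table$dimension == "completeness", ]
  expect_false(compRow$pass)
  expect_equal(compRow$tolerance, 0.7)
  expect_lt(compRow$measured, 0.7)
  expect_false(repBad$overallPass)

  # a clean node passes everything
  repOK <- checkDimensionTolerances(buildEdgeProfile(sc$clean[[1]], base))
  expect_true(repOK$overallPass)
  expect_true(all(repOK$table$pass))

  # overallPass is the conjunction of the per-dimension flags
  expect_identical(repBad$overallPass, all(repBad$table$pass))

  # a measured value exactly at the tolerance passes
  ep <- buildEdgeProfile(sc$clean[[1]], base)
  tolHere <- 1 - mean(vapply(profileMeasures(ep),
                             function(m) m@missingFraction, numeric(1)))
  base2 <- initializeProfile(attributeNames(sc$clean[[1]]),
                             dimensions = "completeness",
                             tolerances = c(completeness = tolHere))
  rep2 <- checkDimensionTolerances(buildEdgeProfile(sc$clean[[1]], base2))
  expect_true(rep2$table$pass[rep2$table$dimension == "completeness"])

  # unconfigured dimension: warning, not error
  base3 <- initializeProfile(attributeNames(sc$clean[[1]]),
                             dimensions = c("completeness", "timeliness"),
                             tolerances = c(completeness = 0.7))
  expect_warning(checkDimensionTolerances(
    buildEdgeProfile(sc$clean[[1]], base3)), "no configured tolerance")
})
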