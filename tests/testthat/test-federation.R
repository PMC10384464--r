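test_that("missing-value vector indicators follow the tolerance", {
  mkProfile <- function(mf) {
    ds <- edgeDataset("n1", data.frame(x = c(rep(NA_real_, round(mf * 100)),
                                             rnorm(100 - round(mf * 100)))),
                      rep("N", 100))
    buildEdgeProfile(ds, initializeProfile("x",
                                           tolerances = c(completeness = 0.7)))
  }
  v1 <- missingValueVector(mkProfile(0.10))
  expect_equal(v1$mv, 0.10)
  expect_equal(v1$indicator, 1L)         # 0.10 < ATol 0.30
  expect_equal(missingValueVector(mkProfile(0.40))$indicator, 0L)
  expect_equal(missingValueVector(mkProfile(0.70))$indicator, 0L)

  p <- mkProfile(0.1)
  p@attributes[[1]]@tolerances <- c(consistency = 0.2)
  expect_error(missingValueVector(p), "lacks a missing-data tolerance")
})

test_that("profile aggregation follows the per-field aggregation map", {
  mkEdge <- function(id, x, nrep) {
    ds <- edgeDataset(id, data.frame(x = x), rep("N", length(x)))
    p <- buildEdgeProfile(ds, initializeProfile("x"))
    p
  }
  # single edge: aggregation of one is the identity on the measures
  e1 <- mkEdge("n1", c(3, 5, 7, 9, NA, 4, 6, 5, 8, 7), 1)
  fed1 <- aggregateProfiles(list(e1))
  expect_identical(profileRole(fed1), "federated")
  m1 <- profileMeasures(e1)$x
  f1 <- profileMeasures(fed1)$x
  for (f in c("observedMin", "observedMax", "missingFraction",
              "uniqueFraction", "skewness", "completeness", "cv"))
    expect_equal(slot(f1, f), slot(m1, f))

  # min of minima and max of maxima across two edges
  e2 <- mkEdge("n2", c(5, 6, 7, 7, 6, 5, 6, 7, 6, 5), 1)
  fed <- aggregateProfiles(list(e1, e2))
  expect_equal(profileMeasures(fed)$x@observedMin, 3)
  expect_equal(profileMeasures(fed)$x@observedMax, 9)
  expect_equal(rowCount(fed), 20L)

  # row-count-weighted mean of missing fractions: edges of 100 and 300 rows
  # at 0.1 and 0.3 missing federate to 0.25
  big1 <- edgeDataset("b1", data.frame(x = c(rep(NA_real_, 10), rnorm(90))),
                      rep("N", 100))
  big2 <- edgeDataset("b2", data.frame(x = c(rep(NA_real_, 90), rnorm(210))),
                      rep("N", 300))
  base <- initializeProfile("x")
  fedW <- aggregateProfiles(list(buildEdgeProfile(big1, base),
                                 buildEdgeProfile(big2, base)))
  expect_equal(profileMeasures(fedW)$x@missingFraction, 0.25)
  expect_equal(profileMeasures(fedW)$x@completeness, 0.75)

  # permutation invariance in the edge order
  fedRev <- aggregateProfiles(list(e2, e1))
  expect_true(profilesEqual(fed, fedRev, tol = 1e-12))

  # attribute-set mismatch and empty list are rejected
  eBad <- buildEdgeProfile(edgeDataset("n3", data.frame(z = rnorm(5)),
                                       rep("N", 5)),
                           initializeProfile("z"))
  expect_error(aggregateProfiles(list(e1, eBad)), "mismatch")
  expect_error(aggregateProfiles(list()), "empty")
})

test_that("attribute fate combines indicator and weight", {
  expect_identical(decideAttributeFate(0, 0.6), "impute")
  expect_identical(decideAttributeFate(0, 0.05), "drop")
  expect_identical(decideAttributeFate(1, 0.05), "retain")
  expect_identical(decideAttributeFate(1, 0.3), "retain")
  expect_error(decideAttributeFate(1, 1.5), "\\[0, 1\\]")
})

test_that("node selection eliminates exactly the corrupted node", {
  sc <- simulateScenario(seed = 2)
  profiles <- lapply(sc$edges, buildEdgeProfile, baseline = sc$baseline)
  sel <- selectNodes(profiles)
  expect_identical(sel$eliminated, "node3")
  expect_setequal(sel$selected, paste0("node", c(1, 2, 4, 5)))
  expect_false(sel$reports$node3$overallPass)

  # all clean: nothing eliminated
  selClean <- selectNodes(lapply(sc$clean, buildEdgeProfile,
                                 baseline = sc$baseline))
  expect_length(selClean$eliminated, 0)
})

test_that("elimination flips exactly once along a severity sweep", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 120, nFeatures = 5, seed = 13)
  clean <- generateCohort(sp)[[1]]
  base <- initializeProfile(attributeNames(clean),
                            dimensions = "completeness",
                            tolerances = c(completeness = 0.7))
  passes <- vapply(seq(0.05, 0.6, by = 0.05), function(sev) {
    ds <- corruptNode(clean, sev, seed = 13)
    checkDimensionTolerances(buildEdgeProfile(ds, base))$overallPass
  }, logical(1))
  expect_true(passes[1])                      # near-zero severity passes
  expect_false(passes[length(passes)])        # heavy corruption fails
  expect_equal(sum(diff(passes) != 0), 1)     # a single flip
  # guaranteed failure at severity >= 0.35 under the 0.70 tolerance
  expect_false(checkDimensionTolerances(
    buildEdgeProfile(corruptNode(clean, 0.35, seed = 13), base))$overallPass)
})

test_that("worsening a node's completeness never rescues it", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 150, nFeatures = 4, seed = 14)
  clean <- generateCohort(sp)[[1]]
  base <- initializeProfile(attributeNames(clean),
                            dimensions = "completeness",
                            tolerances = c(completeness = 0.7))
  sev <- seq(0.1, 0.6, by = 0.1)
  passFlags <- vapply(sev, function(s)
    checkDimensionTolerances(buildEdgeProfile(
      corruptNode(clean, s, seed = 14), base))$overallPass, logical(1))
  # monotone: once failing, failing forever
  expect_true(all(diff(as.integer(passFlags)) <= 0))
})

test_that("the federation loop is versioned, seeded, and converges", {
  sc <- smallScenario(seed = 7)

  # qTol = 0 stops after exactly one round
  res0 <- runFederation(sc$edges, sc$baseline,
                        federationConfig(qTol = 0, seed = 7))
  expect_length(res0$history, 1)
  expect_identical(res0$history[[1]]$version, 1L)

  # determinism under a fixed seed
  resA <- runFederation(sc$edges, sc$baseline,
                        federationConfig(qTol = 1, maxRounds = 2, seed = 7))
  resB <- runFederation(sc$edges, sc$baseline,
                        federationConfig(qTol = 1, maxRounds = 2, seed = 7))
  expect_equal(vapply(resA$history, `[[`, numeric(1), "accuracy"),
               vapply(resB$history, `[[`, numeric(1), "accuracy"))
  expect_true(profilesEqual(resA$profile, resB$profile, tol = 0))

  # versions increment by one per round; the corrupted node is absent from
  # every aggregation round; deltas are exchanged from round 2 on
  expect_equal(vapply(resA$history, `[[`, integer(1), "version"), 1:2)
  for (h in resA$history)
    expect_true("node2" %in% h$allEliminated)
  expect_null(resA$history[[1]]$delta)
  expect_s3_class(resA$history[[2]]$delta, "ProfileDelta")
  expect_false("node2" %in% names(resA$datasets))

  # enriched survivors are fully complete
  for (d in resA$datasets)
    expect_equal(mean(is.na(as.matrix(edgeTable(d)))), 0)
})
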