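test_that("generation is a pure function of the spec and seed", {
  sp <- cohortSpec(nEdges = 2, rowsPerEdge = 50, nFeatures = 4, seed = 5)
  a <- generateCohort(sp)
  b <- generateCohort(sp)
  expect_identical(lapply(a, edgeTable), lapply(b, edgeTable))
  expect_identical(lapply(a, edgeLabels), lapply(b, edgeLabels))

  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeEdgeCSV(a[[1]], f1); writeEdgeCSV(b[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))

  # CSV round trip preserves values and missing markers
  masked <- injectMissing(a[[1]], rates = 0.2, seed = 5)
  f3 <- tempfile(fileext = ".csv")
  writeEdgeCSV(masked, f3)
  back <- readEdgeCSV(f3, nodeId = nodeId(masked))
  expect_equal(edgeTable(back), edgeTable(masked), tolerance = 1e-12)
  expect_identical(edgeLabels(back), edgeLabels(masked))
})

test_that("empirical class proportions match the spec at n = 10000", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 10000, nFeatures = 4, seed = 6)
  labs <- edgeLabels(generateCohort(sp)[[1]])
  emp <- table(labs) / length(labs)
  for (cl in names(sp$classProportions))
    expect_lt(abs(emp[[cl]] - sp$classProportions[[cl]]), 0.02)
})

test_that("zero class separation yields chance-level similarity accuracy", {
  # 1-NN chance level under exchangeable labels is sum(p^2), the
  # probability that a random neighbour carries the same label
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 1000, classSeparation = 0,
                   seed = 11)
  ds <- generateCohort(sp)[[1]]
  chance <- sum(sp$classProportions^2)
  expect_lt(abs(psnAccuracy(edgeTable(ds), edgeLabels(ds)) - chance), 0.05)
})

test_that("missing injection hits its target rates", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 2000, nFeatures = 5, seed = 12)
  clean <- generateCohort(sp)[[1]]

  # rate 0: unchanged
  same <- injectMissing(clean, rates = 0, seed = 12)
  expect_identical(edgeTable(same), edgeTable(clean))

  for (mech in c("MCAR", "MAR", "MNAR")) {
    ds <- injectMissing(clean, rates = 0.2, mechanism = mech, seed = 12)
    realized <- edgeMetadata(ds)$missing$realizedRates
    expect_true(all(abs(realized - 0.2) <= 0.02), info = mech)
    # bookkeeping equals the data
    measured <- vapply(edgeTable(ds), function(x) mean(is.na(x)), numeric(1))
    expect_equal(unname(realized), unname(measured))
  }
  expect_error(injectMissing(clean, rates = 1.2), "\\[0, 1\\]")
})

test_that("outlier injection displaces exactly the logged cells", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 2000, nFeatures = 5, seed = 13)
  clean <- generateCohort(sp)[[1]]
  expect_identical(edgeTable(injectOutliers(clean, rate = 0, seed = 1)),
                   edgeTable(clean))

  ds <- injectOutliers(clean, rate = 0.05, scale = 3, seed = 13)
  log <- edgeMetadata(ds)$outliers
  expect_gt(nrow(log), 0)
  # displaced cells are exactly those logged
  for (nm in unique(log$column)) {
    changed <- which(edgeTable(ds)[[nm]] != edgeTable(clean)[[nm]])
    expect_setequal(changed, log$row[log$column == nm])
  }
  # the detector sees at least (almost) the injected rate
  fracs <- vapply(names(edgeTable(ds)), function(nm)
    outlierFraction(edgeTable(ds)[[nm]]), numeric(1))
  expect_true(all(fracs >= 0.04))
})

test_that("node corruption degrades completeness below 1 - severity", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 400, nFeatures = 5, seed = 14)
  clean <- generateCohort(sp)[[1]]
  ds <- corruptNode(clean, severity = 0.4, seed = 14)
  completeness <- 1 - mean(is.na(as.matrix(edgeTable(ds))))
  expect_lt(completeness, 1 - 0.4)
  expect_error(corruptNode(clean, severity = 0), "\\(0, 1\\]")
  expect_error(corruptNode(clean, severity = 1.4), "\\(0, 1\\]")
})

test_that("injection commutes with row permutation in distribution", {
  sp <- cohortSpec(nEdges = 1, rowsPerEdge = 2000, nFeatures = 4, seed = 15)
  clean <- generateCohort(sp)[[1]]
  set.seed(15)
  perm <- sample(rowCount(clean))
  permuted <- edgeDataset(nodeId(clean), edgeTable(clean)[perm, ],
                          edgeLabels(clean)[perm])
  a <- injectMissing(clean, rates = 0.2, seed = 15)
  b <- injectMissing(permuted, rates = 0.2, seed = 16)
  ra <- edgeMetadata(a)$missing$realizedRates
  rb <- edgeMetadata(b)$missing$realizedRates
  # same Binomial(n, 0.2) law either way: realized rates agree within a
  # 99%-level binomial band (~2.58 * sqrt(p(1-p)/n) ~ 0.023)
  expect_true(all(abs(ra - rb) < 2 * 2.58 * sqrt(0.2 * 0.8 / 2000)))
})

test_that("the standard scenario wires everything together", {
  sc <- simulateScenario(seed = 3, spec = cohortSpec(nEdges = 3,
                                                     rowsPerEdge = 60,
                                                     nFeatures = 5, seed = 3),
                         corruptedNode = 2, severity = 0.4)
  expect_length(sc$edges, 3)
  expect_identical(attributeNames(sc$baseline),
                   attributeNames(sc$edges[[1]]))
  expect_true(all(sc$rates >= 0.05 & sc$rates <= 0.30))
  # only the designated node is corrupted
  miss <- vapply(sc$edges, function(e) mean(is.na(as.matrix(edgeTable(e)))),
                 numeric(1))
  expect_gt(miss[["node2"]], 0.4)
  expect_true(all(miss[c("node1", "node3")] < 0.35))
})
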