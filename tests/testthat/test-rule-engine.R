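test_that("the rule table maps measured states to the documented actions", {
  spec <- attributeSpec("x")
  cases <- list(
    list(m = measuresWith(0.70), action = "DROP_COLUMN", id = "2.2"),
    list(m = measuresWith(0.03, skewness = 2.4), action = "MEDIAN_IMPUTE",
         id = "2.3"),
    list(m = measuresWith(0), action = "NONE", id = "2.0"),
    list(m = measuresWith(0.25, skewness = 0), action = "MULTIPLE_IMPUTE",
         id = "2.6"),
    list(m = measuresWith(0.10, skewness = 0), action = "MEAN_IMPUTE",
         id = "2.1"),
    list(m = measuresWith(0.10, skewness = 3), action = "MEAN_IMPUTE",
         id = "2.1"),  # skewed 5-20% band falls to the general mean rule
    list(m = measuresWith(0.10, mnar = TRUE), action = "KNN_IMPUTE",
         id = "2.4"))
  for (cs in cases) {
    d <- selectRule(cs$m, spec)
    expect_identical(d$action, cs$action)
    expect_identical(d$ruleId, cs$id)
    expect_match(d$justification, cs$id, fixed = TRUE)
  }
  # categorical branches
  catSpec <- attributeSpec("c", dataType = "categorical")
  expect_identical(selectRule(measuresWith(0.10), catSpec)$action,
                   "MODE_IMPUTE")
  expect_warning(dNone <- selectRule(measuresWith(0.30), catSpec),
                 "no rule matches")
  expect_identical(dNone$action, "NONE")
  # thresholds are configurable
  rt <- defaultRuleTable(columnDropThreshold = 0.8)
  expect_identical(selectRule(measuresWith(0.70), spec, rt)$action,
                   "MULTIPLE_IMPUTE")
})

test_that("single-statistic imputations fill with the right statistic", {
  expect_equal(meanImpute(c(1, NA, 3)), c(1, 2, 3))
  # median of {1, 1, 9} is 1 (sort oracle)
  expect_equal(medianImpute(c(1, 1, 9, NA)), c(1, 1, 9, 1))
  expect_identical(modeImpute(c("a", "a", "b", NA)), c("a", "a", "b", "a"))
  expect_error(meanImpute(c(NA_real_, NA_real_)), "all-missing")
  # observed cells untouched
  x <- c(5, NA, 7, 11)
  expect_equal(meanImpute(x)[-2], x[-2])
})

test_that("KNN imputation matches hand-enumerated neighbour sets", {
  # with k = 1 the imputed value is the nearest donor's value
  d <- data.frame(p = c(1, 2, 3.2, 4), y = c(10, 20, NA, 40))
  expect_equal(knnImpute(d, "y", k = 1)[3], 40)

  # k = all donor rows: imputation equals the global mean of observed
  expect_equal(knnImpute(d, "y", k = 3)[3], mean(c(10, 20, 40)))

  # 6-row fixture with an exhaustive distance table
  fix <- data.frame(a = c(0, 1, 4, 9, 2, 0.5),
                    b = c(0, 1, 4, 9, 2, 0.5),
                    y = c(100, 110, 200, 300, NA, NA))
  za <- as.numeric(scale(fix$a))
  donors <- which(!is.na(fix$y))
  for (i in which(is.na(fix$y))) {
    d2 <- (za[donors] - za[i])^2 * 2  # both predictors identical
    nn <- donors[order(d2)][1:2]
    expect_equal(knnImpute(fix, "y", k = 2)[i], mean(fix$y[nn]))
  }
  # deterministic tie-break: equidistant donors resolve to lower row index
  tie <- data.frame(p = c(-1, 1, 0), y = c(7, 9, NA))
  expect_equal(knnImpute(tie, "y", k = 1)[3], 7)

  expect_error(knnImpute(d, "y", k = 5), "fewer than k")
})

test_that("multiple imputation is seeded, sized by missingness, and beats
           the global mean on a linear target", {
  set.seed(21)
  n <- 500
  X <- data.frame(p1 = rnorm(n), p2 = rnorm(n))
  truth <- 3 + 2 * X$p1 - X$p2
  y <- truth + rnorm(n, 0, 0.5)
  ymiss <- y
  mis <- sample(n, 125)  # 25% missing
  ymiss[mis] <- NA
  tab <- cbind(X, y = ymiss)

  r1 <- multipleImpute(tab, "y", seed = 99)
  r2 <- multipleImpute(tab, "y", seed = 99)
  expect_identical(r1$column, r2$column)   # determinism under seed
  expect_equal(r1$m, 25)                   # m = round(100 * 0.25)
  expect_equal(r1$column[-mis], y[-mis])   # observed cells untouched

  rmseMI <- sqrt(mean((r1$column[mis] - truth[mis])^2))
  rmseMean <- sqrt(mean((mean(ymiss, na.rm = TRUE) - truth[mis])^2))
  expect_lt(rmseMI, rmseMean)
  expect_error(multipleImpute(tab, "nope"), "unknown attribute")
})

test_that("applyRules repairs to full completeness and reconciles counts", {
  # one 70%-missing column is deleted wholesale; the rest are imputed
  set.seed(22)
  tab <- data.frame(bad = c(rep(NA_real_, 7), 1, 2, 3),
                    ok = c(1, 2, NA, 3, 4, 5, 6, 7, 8, 9),
                    full = rnorm(10))
  ds <- edgeDataset("n1", tab, rep(c("N", "S"), 5))
  ep <- buildEdgeProfile(ds, initializeProfile(names(tab)))
  out <- applyRules(ds, selectRules(ep))
  expect_equal(ncol(edgeTable(out$dataset)), 2)
  expect_false("bad" %in% attributeNames(out$dataset))
  expect_equal(out$report$columnsDropped, 1)
  expect_equal(out$report$cellsImputed, 1)
  expect_equal(out$report$postCompleteness, 1.0)
  expect_equal(edgeTable(out$dataset)$ok[3], mean(tab$ok, na.rm = TRUE))

  # clean dataset, all NONE: identity with zero counts
  clean <- edgeDataset("n2", data.frame(a = 1:6 / 2, b = rnorm(6)),
                       rep("N", 6))
  ep2 <- buildEdgeProfile(clean, initializeProfile(c("a", "b")))
  out2 <- applyRules(clean, selectRules(ep2))
  expect_identical(edgeTable(out2$dataset), edgeTable(clean))
  expect_equal(out2$report$cellsImputed + out2$report$rowsDropped +
                 out2$report$columnsDropped, 0)

  expect_error(applyRules(clean, list(zz = selectRules(ep2)[[1]])),
               "unknown attribute")
})

test_that("applyRules is idempotent and never alters observed cells", {
  sc <- smallScenario(seed = 6, corrupt = FALSE)
  ds <- sc$edges[[1]]
  ep <- buildEdgeProfile(ds, sc$baseline)
  out1 <- applyRules(ds, selectRules(ep), seed = 5)

  # observed cells unchanged (cell-level diff over the surviving rows)
  raw <- edgeTable(ds)
  if (length(out1$report$droppedRows))
    raw <- raw[-out1$report$droppedRows, , drop = FALSE]
  rep1 <- edgeTable(out1$dataset)
  expect_equal(nrow(rep1), nrow(raw))
  for (nm in names(rep1)) {
    obs <- !is.na(raw[[nm]])
    expect_equal(rep1[[nm]][obs], raw[[nm]][obs], ignore_attr = TRUE)
  }

  # second pass is the identity with an all-zero report
  ep2 <- buildEdgeProfile(out1$dataset, sc$baseline)
  out2 <- applyRules(out1$dataset, selectRules(ep2), seed = 5)
  expect_identical(edgeTable(out2$dataset), edgeTable(out1$dataset))
  expect_equal(out2$report$cellsImputed, 0)
  expect_equal(out2$report$rowsDropped, 0)
  expect_equal(out2$report$columnsDropped, 0)

  # drops strictly reduce size; imputations preserve shape
  expect_equal(dim(rep1), dim(raw))
})

test_that("the MNAR heuristic fires under MNAR and stays quiet under MCAR", {
  hits <- vapply(1:50, function(s) {
    sp <- cohortSpec(nEdges = 1, rowsPerEdge = 2000, nFeatures = 8, seed = s)
    ds <- injectMissing(generateCohort(sp)[[1]], rates = 0.2,
                        mechanism = "MNAR", seed = s, columns = "x03")
    flagMNAR(edgeTable(ds), "x03")
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  quiet <- vapply(1:20, function(s) {
    sp <- cohortSpec(nEdges = 1, rowsPerEdge = 425, nFeatures = 8, seed = s)
    ds <- injectMissing(generateCohort(sp)[[1]], rates = 0.2,
                        mechanism = "MCAR", seed = s, columns = "x03")
    flagMNAR(edgeTable(ds), "x03")
  }, logical(1))
  expect_lte(mean(quiet), 0.1)
})
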