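# Fixtures shared across the suite. Everything is built in code.

# Three-attribute baseline with the full rule table.
tinyProfile <- function(weights = NULL) {
  initializeProfile(c("hr", "sp", "rr"), weights = weights,
                    tolerances = c(completeness = 0.7, consistency = 0.2))
}

# A measured profile with measures, workload, selected features and custom
# rule params - exercises every XML element.
richProfile <- function() {
  ds <- edgeDataset("nodeA",
                    data.frame(hr = c(120, 130, NA, 125, 1000, 128),
                               sp = c(97, 96, 98, NA, 95, 97),
                               rr = c(14, 15, 14, 14, 16, NA)),
                    labels = c("N", "N", "S", "N", "P", "N"))
  p <- buildEdgeProfile(ds, tinyProfile(),
                        workload = workloadStub(config = list(cpu = "4"),
                                                realtime = list(load = "0.3")))
  p@selectedFeatures <- c("hr", "rr")
  p
}

# Random valid profile for property tests (seeded).
randomProfile <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  nms <- paste0("a", seq_len(n))
  w <- normalizeWeights(runif(n))
  p <- initializeProfile(nms, weights = w)
  p@version <- sample(0:5, 1)
  if (runif(1) < 0.5) {
    ds <- edgeDataset("nX", as.data.frame(matrix(rnorm(20 * n), 20,
                                                 dimnames = list(NULL, nms))),
                      labels = sample(c("N", "S"), 20, replace = TRUE))
    p <- buildEdgeProfile(ds, p)
  }
  p
}

# Small-scale standard scenario for fast pipeline tests.
smallScenario <- function(seed = 1, corrupt = TRUE) {
  simulateScenario(seed = seed,
                   spec = cohortSpec(nEdges = 3, rowsPerEdge = 80,
                                     nFeatures = 6, seed = seed),
                   corruptedNode = if (corrupt) 2 else NULL)
}

# Build AttributeMeasures directly (for rule-selection tests).
measuresWith <- function(missingFraction, skewness = 0, mnar = FALSE) {
  new("AttributeMeasures", missingFraction = missingFraction,
      completeness = 1 - missingFraction, skewness = skewness, mnar = mnar)
}
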