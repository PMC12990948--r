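test_that("enumerated distributions recover the generator parameters exactly", {
  # closed form under the independence model: FI = 100 pF, GI = 100 pGal,
  # SI = 100 pSial, untouched by high-mannose dilution
  grid <- c(0.1, 0.5, 0.9)
  for (pf in grid) for (pg in grid) for (ps in grid) for (hm in c(0, 0.2)) {
    d <- enumerateDistribution(GlycanSimParams(
      pFucose = pf, pGal = pg, pSial = ps, highMannoseFraction = hm))
    expect_equal(sum(abundances(d)), 100, tolerance = 1e-12)
    v <- indexValues(computeIndexSet(d))
    expect_equal(unname(v["FI"]), 100 * pf, tolerance = 1e-9)
    expect_equal(unname(v["GI"]), 100 * pg, tolerance = 1e-9)
    expect_equal(unname(v["SI"]), 100 * ps, tolerance = 1e-9)
  }
})

test_that("enumerated species are valid and degenerate cases collapse", {
  d <- enumerateDistribution(GlycanSimParams(pFucose = 0.9, pGal = 0.5,
                                             pSial = 0.2))
  # every name round-trips through the parser
  for (nm in names(abundances(d))) {
    expect_identical(formatGlycan(parseGlycan(nm)), nm)
  }
  expect_identical(length(abundances(d)), 12L)

  deg <- enumerateDistribution(GlycanSimParams(pFucose = 1, pGal = 0,
                                               pSial = 0.7))
  expect_identical(abundances(deg), c(FA2G0 = 100))

  tri <- enumerateDistribution(GlycanSimParams(antennarity = 3L, pGal = 0.4))
  expect_true(all(grepl("A3", setdiff(names(abundances(tri)), "M5"))))
  expect_equal(galactosylationIndex(tri), 40, tolerance = 1e-9)
})

test_that("sampled distributions are seed-deterministic and consistent", {
  p <- GlycanSimParams(pFucose = 0.9, pGal = 0.5, pSial = 0.2,
                       nMolecules = 1e6, seed = 7L)
  d1 <- sampleDistribution(p)
  d2 <- sampleDistribution(p)
  expect_identical(abundances(d1), abundances(d2))

  # FI within 3 binomial standard errors of its closed form
  se3 <- 3 * sqrt(0.9 * 0.1 / 1e6) * 100
  expect_lt(abs(fucosylationIndex(d1) - 90), se3)

  one <- sampleDistribution(GlycanSimParams(nMolecules = 1L, seed = 3L))
  expect_identical(length(abundances(one)), 1L)
  expect_equal(unname(abundances(one)), 100)

  # sampling must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sampleDistribution(p)); after <- runif(1)
  expect_identical(before, after)
})

test_that("makeSyntheticStudy attaches ground-truth deltas", {
  st <- makeSyntheticStudy(GlycanSimParams(pGal = 0.30),
                           list(GlycanSimParams(pGal = 0.20)))
  td <- S4Vectors::metadata(st)$trueDelta
  expect_equal(td$trueDeltaGI, 10)
  expect_equal(td$trueDeltaFI, 0)
  expect_identical(ncol(st), 2L)

  solo <- makeSyntheticStudy(GlycanSimParams())
  expect_identical(ncol(solo), 1L)
  expect_null(S4Vectors::metadata(solo)$trueDelta)

  two <- makeSyntheticStudy(GlycanSimParams(),
                            list(GlycanSimParams(pGal = 0.25),
                                 GlycanSimParams(pGal = 0.30)))
  expect_identical(ncol(two), 3L)
  expect_identical(sum(SummarizedExperiment::colData(two)$role == "control"), 1L)
})

test_that("synthetic cohorts emulate the compiled corpus", {
  cohort <- makeSyntheticCohort(nPairs = 15, seed = 5)
  pairs <- pairConditions(cohort)
  expect_identical(nrow(pairs), 15L)
  cd <- SummarizedExperiment::colData(cohort)
  # reported-only studies carry their indices instead of distributions
  if (any(!cd$suitable)) {
    expect_true(all(!is.na(cd$reported_GI[!cd$suitable])))
  }
  # generator manifest covers every condition
  gen <- S4Vectors::metadata(cohort)$generator
  expect_setequal(gen$condition_id, cd$condition_id)
  # determinism
  cohort2 <- makeSyntheticCohort(nPairs = 15, seed = 5)
  expect_identical(as.data.frame(SummarizedExperiment::colData(cohort2)),
                   as.data.frame(cd))
  expect_identical(SummarizedExperiment::assay(cohort2),
                   SummarizedExperiment::assay(cohort))
})

test_that("logit jitter perturbs probabilities reproducibly", {
  p <- GlycanSimParams(pFucose = 0.95, pGal = 0.2, pSial = 0.05)
  j1 <- jitterParams(p, sd = 0.2, seed = 4L)
  j2 <- jitterParams(p, sd = 0.2, seed = 4L)
  expect_identical(j1, j2)
  expect_false(identical(j1@pGal, p@pGal))
  expect_true(j1@pGal > 0 && j1@pGal < 1)
  # structural 0/1 probabilities stay put
  fixed <- jitterParams(GlycanSimParams(pFucose = 1, pSial = 0), seed = 4L)
  expect_identical(fixed@pFucose, 1)
  expect_identical(fixed@pSial, 0)
})
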