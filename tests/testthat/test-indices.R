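test_that("normalization rescales within tolerance and guards outside", {
  d <- GlycanDistribution(c(FA2G0 = 49.5, FA2G1 = 30.0, FA2G2 = 19.5))
  expect_equal(sum(abundances(d)), 100)
  expect_equal(rawTotal(d), 99)
  expect_equal(unname(abundances(d)["FA2G0"]), 49.5 * 100 / 99)

  ident <- GlycanDistribution(c(FA2G0 = 100))
  expect_identical(unname(abundances(ident)), 100)
  expect_false(ident@normalized)

  expect_error(GlycanDistribution(c(FA2G0 = 60)), "60 outside \\[95, 105\\]")
  expect_error(GlycanDistribution(c(FA2G0 = -1, FA2G1 = 101)), "negative")
  expect_error(GlycanDistribution(c(FA2G9 = 100)), "galactose count")
  # widened tolerance admits the same total
  expect_s4_class(GlycanDistribution(c(FA2G0 = 60), tolerance = 45),
                  "GlycanDistribution")
})

test_that("non-structural categories are dropped before normalization", {
  expect_message(
    d <- GlycanDistribution(c(FA2G0 = 90, Other = 8, FA2G1 = 10)),
    "non-structural")
  expect_setequal(names(abundances(d)), c("FA2G0", "FA2G1"))
  expect_equal(rawTotal(d), 100)
})

test_that("galactosylation index matches hand-expanded weighted sums", {
  expect_equal(galactosylationIndex(
    GlycanDistribution(c(FA2G0 = 50, FA2G1 = 30, FA2G2 = 20))), 35)
  expect_equal(galactosylationIndex(GlycanDistribution(c(FA2G2 = 100))), 100)
  # sialyl-capped galactose still occupies its antenna
  expect_equal(galactosylationIndex(
    GlycanDistribution(c(A2G0 = 40, FA2G2S2 = 60))), 60)
  expect_warning(gi <- galactosylationIndex(GlycanDistribution(c(M5 = 100))),
                 "galactose-capable")
  expect_true(is.na(gi))
  expect_error(galactosylationIndex(GlycanDistribution(c(M5 = 100)),
                                    strict = TRUE),
               "galactose-capable")
})

test_that("sialylation index counts NeuAc over galactoses", {
  expect_equal(sialylationIndex(GlycanDistribution(c(FA2G2S1 = 100))), 50)
  expect_equal(sialylationIndex(
    GlycanDistribution(c(A2G0 = 40, FA2G2S2 = 60))), 100)
  expect_warning(si <- sialylationIndex(GlycanDistribution(c(FA2G0 = 100))),
                 "sialylatable")
  expect_true(is.na(si))
  # galactose present but uncapped: SI is a true zero, not missing
  expect_equal(sialylationIndex(
    GlycanDistribution(c(FA2G0 = 50, FA2G1 = 30, FA2G2 = 20))), 0)
})

test_that("fucosylation index excludes high-mannose from both sums", {
  expect_equal(fucosylationIndex(
    GlycanDistribution(c(FA2G0 = 80, A2G0 = 20))), 80)
  expect_equal(fucosylationIndex(
    GlycanDistribution(c(M5 = 20, FA2G0 = 80))), 100)
  expect_equal(fucosylationIndex(GlycanDistribution(c(A2G2 = 100))), 0)
  expect_warning(fi <- fucosylationIndex(GlycanDistribution(c(M5 = 100))),
                 "fucosylatable")
  expect_true(is.na(fi))
})

test_that("summative indices are motif-membership abundance sums", {
  s <- summativeIndices(GlycanDistribution(c(FA2G0 = 50, FA2G1 = 30, FA2G2 = 20)))
  expect_equal(unname(s), c(100, 50, 0))
  s2 <- summativeIndices(GlycanDistribution(c(A2G0 = 40, FA2G2S2 = 60)))
  expect_equal(unname(s2), c(60, 60, 60))
  s3 <- summativeIndices(GlycanDistribution(c(M5 = 100)))
  expect_equal(unname(s3), c(0, 0, 0))
})

test_that("computeIndexSet composes the five index operations", {
  is1 <- computeIndexSet(GlycanDistribution(c(FA2G0 = 50, FA2G1 = 30, FA2G2 = 20)))
  v <- indexValues(is1)
  expect_equal(unname(v[c("FI", "GI", "SI")]), c(100, 35, 0))
  expect_equal(unname(v[c("summFucose", "summGalactose", "summSialic")]),
               c(100, 50, 0))
  expect_identical(provenance(is1), "computed_from_distribution")

  is2 <- computeIndexSet(GlycanDistribution(c(FA2G2 = 100)))
  expect_equal(unname(indexValues(is2)), c(100, 100, 0, 100, 100, 0))

  rep <- reportedIndexSet(FI = 95, GI = 20)
  expect_identical(provenance(rep), "reported_in_source")
  expect_true(all(is.na(indexValues(rep)[4:6])))
  expect_error(new("GlycanIndexSet", FI = 1, GI = 1, SI = 1,
                   summFucose = 50, summGalactose = NA_real_,
                   summSialic = NA_real_, provenance = "reported_in_source"),
               "summative")
})

test_that("indices are scale- and permutation-invariant and bounded", {
  set.seed(71)
  for (i in 1:25) {
    counts <- random_population(500, k_species = sample(3:10, 1L))
    raw <- 100 * counts / sum(counts)
    d1 <- GlycanDistribution(raw)
    d2 <- GlycanDistribution(raw * 0.97)          # scale then renormalize
    d3 <- GlycanDistribution(sample(raw))          # permute species order
    for (fun in list(galactosylationIndex, sialylationIndex,
                     fucosylationIndex)) {
      v1 <- suppressWarnings(fun(d1))
      expect_equal(suppressWarnings(fun(d2)), v1)
      expect_equal(suppressWarnings(fun(d3)), v1)
      if (!is.na(v1)) {
        expect_gte(v1, 0)
        expect_lte(v1, 100)
      }
    }
  }
})

test_that("moving mass from FA2G0 to FA2G2 raises GI and fixes FI", {
  base <- c(FA2G0 = 60, FA2G1 = 20, FA2G2 = 20)
  gi_prev <- -Inf
  for (shift in c(0, 10, 20, 30)) {
    d <- GlycanDistribution(base + c(-shift, 0, shift))
    gi <- galactosylationIndex(d)
    expect_gt(gi, gi_prev)
    gi_prev <- gi
    expect_equal(fucosylationIndex(d), 100)
  }
})

test_that("SI, GI and the antenna pool are mutually consistent", {
  set.seed(72)
  for (i in 1:25) {
    counts <- random_population(1000)
    d <- GlycanDistribution(100 * counts / sum(counts))
    si <- suppressWarnings(sialylationIndex(d))
    gi <- suppressWarnings(galactosylationIndex(d))
    if (is.na(si) || is.na(gi)) next
    w <- speciesWeights(names(abundances(d)))
    p <- abundances(d) / 100
    expect_equal(sum(w$sialResidues * p),
                 (si / 100) * (gi / 100) * sum(w$antennaSites * p))
  }
})

test_that("weighted-sum indices equal the per-molecule site census", {
  set.seed(73)
  for (i in 1:50) {
    counts <- random_population(sample(50:2000, 1L),
                                k_species = sample(2:12, 1L))
    d <- GlycanDistribution(100 * counts / sum(counts))
    ref <- oracle_census(counts)
    expect_equal(suppressWarnings(galactosylationIndex(d)), ref$GI,
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(sialylationIndex(d)), ref$SI,
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(fucosylationIndex(d)), ref$FI,
                 tolerance = 1e-12)
  }
})
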