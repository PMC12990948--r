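test_that("readStudyTable builds validated records with derived suitability", {
  fx <- write_demo_tables()
  gss <- readStudyTable(fx$meta, fx$dist)
  expect_s4_class(gss, "GlycanStudySet")
  expect_identical(ncol(gss), 5L)
  cd <- SummarizedExperiment::colData(gss)
  # suitability derived from the presence of a distribution, never trusted
  expect_identical(unname(cd$suitable),
                   c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # reported-only condition carries its indices with source provenance
  idx <- conditionIndexSets(gss)
  expect_identical(provenance(idx$kimA_rep), "reported_in_source")
  expect_equal(unname(indexValues(idx$kimA_rep)[c("FI", "GI", "SI")]),
               c(96.5, 18.2, 2.1))
  expect_true(all(is.na(indexValues(idx$kimA_rep)[4:6])))
  expect_identical(provenance(idx$kimA_ctrl), "computed_from_distribution")
  # experiment_group defaults to the parameter category
  expect_identical(unname(cd$experiment_group[1L]), "temperature")
})

test_that("readStudyTable reports violations with row locators", {
  fx <- write_demo_tables()
  dist <- utils::read.csv(fx$dist)

  bad <- rbind(dist, data.frame(condition_id = "nobody", glycan = "FA2G0",
                                relative_abundance_percent = 1))
  p <- file.path(fx$dir, "bad1.csv"); utils::write.csv(bad, p, row.names = FALSE)
  expect_error(readStudyTable(fx$meta, p), "unknown condition_id 'nobody' \\(distributions row 15\\)")

  bad <- rbind(dist, dist[1L, ])
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(readStudyTable(fx$meta, p), "duplicate \\(condition_id, glycan\\)")

  bad <- dist; bad$glycan[4L] <- "FA2G9"
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(readStudyTable(fx$meta, p), "galactose count 9.*row 4")

  meta <- utils::read.csv(fx$meta)
  meta$culture_mode[2L] <- "chemostat"
  mp <- file.path(fx$dir, "badmeta.csv"); utils::write.csv(meta, mp, row.names = FALSE)
  expect_error(readStudyTable(mp, fx$dist), "invalid culture_mode 'chemostat' \\(metadata row 2\\)")

  meta <- utils::read.csv(fx$meta)
  meta$role[1L] <- "manipulated"   # breaks role <-> manipulation_type 'control'
  utils::write.csv(meta, mp, row.names = FALSE)
  expect_error(readStudyTable(mp, fx$dist), "control")
})

test_that("study-table read/write/read is field-identical", {
  fx <- write_demo_tables()
  gss <- readStudyTable(fx$meta, fx$dist)
  mp2 <- file.path(fx$dir, "meta2.csv")
  dp2 <- file.path(fx$dir, "dist2.csv")
  writeStudyTable(gss, mp2, dp2)
  gss2 <- readStudyTable(mp2, dp2)
  expect_identical(as.data.frame(SummarizedExperiment::colData(gss2)),
                   as.data.frame(SummarizedExperiment::colData(gss)))
  m1 <- SummarizedExperiment::assay(gss, "abundance")
  m2 <- SummarizedExperiment::assay(gss2, "abundance")
  expect_identical(m2[rownames(m1), colnames(m1)], m1)
})

test_that("pairing matches each manipulated condition to its group control", {
  fx <- write_demo_tables()
  gss <- readStudyTable(fx$meta, fx$dist)
  pairs <- pairConditions(gss)
  expect_identical(nrow(pairs), 3L)
  expect_setequal(pairs$manipulated_id, c("kimA_low", "kimA_rep", "taitB_shift"))
  expect_identical(unique(pairs$control_id[pairs$study_id == "kimA"]), "kimA_ctrl")
  expect_identical(attr(pairs, "unpaired"), character(0))

  # one control shared by several manipulation levels: one pair per level
  st <- makeSyntheticStudy(GlycanSimParams(),
                           list(GlycanSimParams(pGal = 0.25),
                                GlycanSimParams(pGal = 0.30),
                                GlycanSimParams(pGal = 0.35)))
  expect_identical(nrow(pairConditions(st)), 3L)

  # manipulated without any control: reported unpaired, excluded
  cd <- as.data.frame(SummarizedExperiment::colData(gss))
  cd$role[cd$condition_id == "taitB_ctrl"] <- "manipulated"
  cd$manipulation_type[cd$condition_id == "taitB_ctrl"] <- "shift"
  gss_orphan <- GlycanStudySet(SummarizedExperiment::assay(gss), cd)
  expect_message(p2 <- pairConditions(gss_orphan), "without a control")
  expect_setequal(attr(p2, "unpaired"), c("taitB_ctrl", "taitB_shift"))
  expect_identical(nrow(p2), 2L)

  # two controls in one experiment group is an error
  cd2 <- as.data.frame(SummarizedExperiment::colData(gss))
  cd2$role[cd2$condition_id == "kimA_low"] <- "control"
  cd2$manipulation_type[cd2$condition_id == "kimA_low"] <- "control"
  gss_two <- GlycanStudySet(SummarizedExperiment::assay(gss), cd2)
  expect_error(pairConditions(gss_two), "has 2 controls")
})

test_that("grouping partitions pairs deterministically", {
  cohort <- makeSyntheticCohort(nPairs = 20, seed = 11)
  pairs <- pairConditions(cohort)
  tree <- groupPairs(pairs)
  expect_setequal(names(tree), unique(pairs$parameter_category))
  # leaves cover every pair exactly once
  leaves <- function(x) {
    if (is.data.frame(x)) return(list(x))
    unlist(lapply(x, leaves), recursive = FALSE)
  }
  got <- do.call(rbind, leaves(tree))
  expect_identical(sort(got$manipulated_id), sort(pairs$manipulated_id))
  expect_identical(anyDuplicated(got$manipulated_id), 0L)

  flat <- groupPairs(pairs, keys = "culture_mode")
  expect_setequal(names(flat), unique(pairs$culture_mode))
  all_in_one <- groupPairs(pairs, keys = character(0))
  expect_identical(nrow(all_in_one), nrow(pairs))
  expect_error(groupPairs(pairs, keys = "product"), "unknown grouping key")
})
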