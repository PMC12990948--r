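.INDEX_NAMES <- c("FI", "GI", "SI",
                  "summFucose", "summGalactose", "summSialic")

#' Classify an index change into effect-magnitude bins
#'
#' Bins an absolute index difference (percentage points) into the
#' effect-magnitude classes used throughout the cross-study comparison:
#' negligible below 1.5, minor from 1.5 to below 5, moderate from 5 to
#' below 10, and major at 10 or above. Intervals are left-closed; missing
#' deltas map to \code{not_evaluable}.
#'
#' @param deltaAbs numeric vector of absolute differences (>= 0 or NA)
#' @param edges increasing bin edges, default \code{c(1.5, 5, 10)}
#' @return factor with levels negligible, minor, moderate, major,
#'   not_evaluable
#' @examples
#' classifyEffect(c(0.7, 2.32, 10, NA))
#' @export
classifyEffect <- function(deltaAbs, edges = c(1.5, 5, 10)) {
  if (length(edges) != 3L || is.unsorted(edges)) {
    stop("edges must be three increasing thresholds")
  }
  if (any(deltaAbs < 0, na.rm = TRUE)) {
    stop("absolute deltas must be non-negative")
  }
  lev <- .EFFECT_BINS
  out <- cut(deltaAbs, breaks = c(0, edges, Inf), labels = lev[1:4],
             right = FALSE, include.lowest = TRUE)
  out <- factor(ifelse(is.na(deltaAbs), "not_evaluable", as.character(out)),
                levels = lev)
  out
}

#' Signed and absolute index differences for one condition pair
#'
#' Computes manipulated-minus-control differences, in percentage points,
#' for the three glycan indices and the three summative indices, together
#' with per-index direction (increase/decrease/none) and effect-magnitude
#' bin. An index missing on either side is \code{not_evaluable}.
#'
#' @param control,manipulated [GlycanIndexSet-class] objects
#' @param edges bin edges passed to [classifyEffect()]
#' @return a one-row data.frame with, per index \code{<ix>}, columns
#'   \code{delta_<ix>} (signed), \code{delta_<ix>_abs}, \code{dir_<ix>}
#'   and \code{bin_<ix>}
#' @examples
#' a <- reportedIndexSet(GI = 30)
#' b <- reportedIndexSet(GI = 20)
#' deltaIndices(a, b)$delta_GI_abs
#' @export
deltaIndices <- function(control, manipulated, edges = c(1.5, 5, 10)) {
  stopifnot(is(control, "GlycanIndexSet"), is(manipulated, "GlycanIndexSet"))
  cv <- indexValues(control)
  mv <- indexValues(manipulated)
  out <- list()
  for (ix in .INDEX_NAMES) {
    signed <- unname(mv[ix] - cv[ix])
    out[[paste0("delta_", ix)]] <- signed
    out[[paste0("delta_", ix, "_abs")]] <- abs(signed)
    out[[paste0("dir_", ix)]] <-
      if (is.na(signed)) NA_character_
      else if (signed > 0) "increase"
      else if (signed < 0) "decrease"
      else "none"
    out[[paste0("bin_", ix)]] <- as.character(classifyEffect(abs(signed), edges))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param groupingKeys ordered grouping keys for the aggregate report
#' @param binEdges effect-magnitude bin edges (percentage points)
#' @param tolerance normalization tolerance (percentage points)
#' @param strict error on non-evaluable indices instead of NA
#' @return a list usable as the \code{config} of [runPipeline()]
#' @export
pipelineConfig <- function(groupingKeys = c("parameter_category",
                                            "manipulation_type",
                                            "culture_mode", "cell_line"),
                           binEdges = c(1.5, 5, 10),
                           tolerance = 5, strict = FALSE) {
  list(groupingKeys = groupingKeys, binEdges = binEdges,
       tolerance = tolerance, strict = strict)
}

# Largest per-species abundance shift between two distribution columns of
# the raw assay (normalized first); NA when either side lacks a
# distribution. This is the "distribution layer" of the dual report: index
# deltas can be ~0 while individual glycoforms move a lot.
.maxSpeciesDelta <- function(mat, ctrl_id, manip_id, tolerance) {
  a <- mat[, ctrl_id]
  b <- mat[, manip_id]
  if (all(is.na(a)) || all(is.na(b))) return(NA_real_)
  pa <- abundances(GlycanDistribution(a[!is.na(a)], tolerance = tolerance))
  pb <- abundances(GlycanDistribution(b[!is.na(b)], tolerance = tolerance))
  species <- union(names(pa), names(pb))
  va <- ifelse(species %in% names(pa), pa[species], 0)
  vb <- ifelse(species %in% names(pb), pb[species], 0)
  max(abs(vb - va))
}

#' Run the full comparison pipeline
#'
#' End-to-end analysis of a study corpus: computes a
#' [GlycanIndexSet-class] per condition (averaging batch replicates at the
#' index level where a \code{replicate_group} is declared), pairs every
#' manipulated condition with its control, derives signed and absolute
#' index differences with direction and effect-magnitude bins, records the
#' largest per-species abundance shift of each pair (the distribution
#' layer of the dual glycan report), and aggregates the comparisons over
#' the configured grouping keys. Every normalization rescaling, replicate
#' averaging, unpaired condition and non-evaluable index is logged.
#'
#' @param x a [GlycanStudySet-class]
#' @param config a list from [pipelineConfig()]
#' @return a list with elements \code{comparisons} (data.frame, one row
#'   per pair), \code{report} (aggregate data.frame from
#'   [aggregateComparisons()]), \code{log} (character vector)
#' @examples
#' st <- makeSyntheticStudy(GlycanSimParams(pGal = 0.30),
#'                          list(GlycanSimParams(pGal = 0.20)))
#' res <- runPipeline(st)
#' res$comparisons[, c("delta_GI_abs", "bin_GI")]
#' @export
runPipeline <- function(x, config = pipelineConfig()) {
  stopifnot(is(x, "GlycanStudySet"))
  log <- character()
  cd <- as.data.frame(colData(x))
  mat <- assay(x, "abundance")
  idx <- withCallingHandlers(
    conditionIndexSets(x, tolerance = config$tolerance, strict = config$strict),
    warning = function(w) {
      log <<- c(log, paste("index warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  for (j in seq_len(nrow(cd))) {
    if (cd$suitable[j]) {
      tot <- sum(mat[, j], na.rm = TRUE)
      if (abs(tot - 100) > 1e-9) {
        log <- c(log, sprintf("normalized '%s': raw total %.6g rescaled to 100",
                              cd$condition_id[j], tot))
      }
    }
  }

  # replicate collapse: average IndexSets within declared replicate groups
  repkey <- ifelse(is.na(cd$replicate_group) | cd$replicate_group == "",
                   paste0("\r", cd$condition_id),
                   paste(cd$study_id, cd$experiment_group, cd$role,
                         cd$replicate_group, sep = "\r"))
  keep <- !duplicated(repkey)
  for (k in unique(repkey[duplicated(repkey)])) {
    members <- which(repkey == k)
    vals <- vapply(idx[cd$condition_id[members]], indexValues, numeric(6L))
    avg <- rowMeans(vals, na.rm = TRUE)
    avg[is.nan(avg)] <- NA_real_
    spread <- apply(vals, 1L, function(v) diff(range(v, na.rm = TRUE)))
    rep_id <- cd$condition_id[members[1L]]
    prov <- if (all(vapply(idx[cd$condition_id[members]], provenance,
                           character(1L)) == "computed_from_distribution"))
      "computed_from_distribution" else "reported_in_source"
    avg_set <- new("GlycanIndexSet",
                   FI = avg[["FI"]], GI = avg[["GI"]], SI = avg[["SI"]],
                   summFucose = if (prov == "reported_in_source") NA_real_ else avg[["summFucose"]],
                   summGalactose = if (prov == "reported_in_source") NA_real_ else avg[["summGalactose"]],
                   summSialic = if (prov == "reported_in_source") NA_real_ else avg[["summSialic"]],
                   provenance = prov)
    idx[[rep_id]] <- avg_set
    log <- c(log, sprintf(
      "averaged %d replicates into '%s' (max index spread %.3g pp)",
      length(members), rep_id, max(spread[is.finite(spread)], 0)))
  }
  cd_red <- cd[keep, , drop = FALSE]

  pairs <- withCallingHandlers(
    .pairConditionsDF(cd_red),
    message = function(m) {
      log <<- c(log, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  if (nrow(pairs) == 0L) {
    comparisons <- cbind(pairs, deltaIndices(reportedIndexSet(),
                                             reportedIndexSet())[0, ])
    comparisons$max_species_delta <- numeric(0)
  } else {
    deltas <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      deltaIndices(idx[[pairs$control_id[i]]], idx[[pairs$manipulated_id[i]]],
                   edges = config$binEdges)
    }))
    msd <- vapply(seq_len(nrow(pairs)), function(i) {
      .maxSpeciesDelta(mat, pairs$control_id[i], pairs$manipulated_id[i],
                       config$tolerance)
    }, numeric(1L))
    comparisons <- cbind(pairs, deltas, max_species_delta = msd)
  }
  for (ix in c("FI", "GI", "SI")) {
    ne <- comparisons[[paste0("bin_", ix)]] == "not_evaluable"
    if (any(ne)) {
      log <- c(log, sprintf("%s not evaluable for pair(s): %s", ix,
                            paste(comparisons$manipulated_id[ne], collapse = ", ")))
    }
  }
  report <- aggregateComparisons(comparisons, keys = config$groupingKeys)
  list(comparisons = comparisons, report = report, log = log)
}

#' Aggregate comparisons over grouping keys
#'
#' Summarizes a comparisons table per group: pair count, per-index bin
#' counts (which sum to the pair count), minimum/median/maximum absolute
#' index difference, and the pairs whose FI, GI or SI change is major.
#'
#' @param comparisons data.frame from [runPipeline()]
#' @param keys grouping columns (subset of \code{parameter_category},
#'   \code{manipulation_type}, \code{culture_mode}, \code{cell_line});
#'   empty for a single overall group
#' @return data.frame with one row per group
#' @export
aggregateComparisons <- function(comparisons,
                                 keys = c("parameter_category",
                                          "manipulation_type",
                                          "culture_mode", "cell_line")) {
  allowed <- c("parameter_category", "manipulation_type", "culture_mode",
               "cell_line")
  bad <- setdiff(keys, allowed)
  if (length(bad)) {
    stop(sprintf("unknown grouping key(s): %s", paste(bad, collapse = ", ")))
  }
  if (nrow(comparisons) == 0L) {
    return(data.frame(n_pairs = integer(0)))
  }
  grp <- if (length(keys)) {
    interaction(comparisons[, keys, drop = FALSE], drop = TRUE, sep = " / ")
  } else {
    factor(rep("all", nrow(comparisons)))
  }
  rows <- lapply(levels(grp), function(g) {
    sub <- comparisons[grp == g, , drop = FALSE]
    row <- if (length(keys)) sub[1L, keys, drop = FALSE] else data.frame(group = "all")
    row$n_pairs <- nrow(sub)
    for (ix in c("FI", "GI", "SI")) {
      bins <- factor(sub[[paste0("bin_", ix)]], levels = .EFFECT_BINS)
      cnt <- table(bins)
      for (b in .EFFECT_BINS) row[[paste0("n_", b, "_", ix)]] <- unname(cnt[b])
      ab <- sub[[paste0("delta_", ix, "_abs")]]
      row[[paste0("min_d", ix)]] <- if (all(is.na(ab))) NA_real_ else min(ab, na.rm = TRUE)
      row[[paste0("median_d", ix)]] <- if (all(is.na(ab))) NA_real_ else stats::median(ab, na.rm = TRUE)
      row[[paste0("max_d", ix)]] <- if (all(is.na(ab))) NA_real_ else max(ab, na.rm = TRUE)
    }
    major <- sub$bin_FI == "major" | sub$bin_GI == "major" | sub$bin_SI == "major"
    row$major_pairs <- paste(sub$manipulated_id[major], collapse = "; ")
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Human-readable summary of an aggregate report
#'
#' Prints a compact per-group table with pair counts and the span of
#' absolute index differences, rounded to one decimal place (the
#' granularity at which glycan indices are conventionally reported).
#'
#' @param report data.frame from [aggregateComparisons()]
#' @return the formatted data.frame, invisibly
#' @export
formatReport <- function(report) {
  if (nrow(report) == 0L) {
    cat("no pairs\n")
    return(invisible(report))
  }
  shown <- report
  num <- vapply(shown, is.numeric, logical(1L)) &
    grepl("^(min|median|max)_d", colnames(shown))
  shown[num] <- lapply(shown[num], round, 1L)
  print(shown, row.names = FALSE)
  invisible(shown)
}
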