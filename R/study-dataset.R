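.METADATA_COLS <- c("study_id", "condition_id", "experiment_group", "role",
                    "parameter_category", "manipulation_type", "cell_line",
                    "product", "culture_mode", "reference", "replicate_group",
                    "reported_FI", "reported_GI", "reported_SI")

#' Construct a GlycanStudySet
#'
#' Assembles the compiled-study container from a raw abundance matrix
#' (species x conditions, percent, NA where a species was not reported)
#' and a condition-metadata table. The per-condition suitability flag --
#' whether the full glycoform distribution is available so that indices
#' can be computed rather than taken as reported -- is always derived from
#' the abundance matrix, never trusted from the input.
#'
#' @param abundance numeric matrix, rownames = glycan names, colnames =
#'   condition ids; all-NA columns are reported-only conditions
#' @param conditions data.frame with columns \code{study_id},
#'   \code{condition_id}, \code{role}, \code{parameter_category},
#'   \code{manipulation_type}, \code{cell_line}, \code{product},
#'   \code{culture_mode}, \code{reference}; optional
#'   \code{experiment_group} (defaults to the parameter category),
#'   \code{replicate_group}, \code{reported_FI}/\code{_GI}/\code{_SI}
#' @return a [GlycanStudySet-class]
#' @seealso [readStudyTable()] to build one from CSV files
#' @export
GlycanStudySet <- function(abundance, conditions) {
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  if (!"experiment_group" %in% colnames(conditions)) {
    conditions$experiment_group <- NA_character_
  }
  eg <- as.character(conditions$experiment_group)
  conditions$experiment_group <- ifelse(is.na(eg) | eg == "",
                                        conditions$parameter_category, eg)
  if (!"replicate_group" %in% colnames(conditions)) {
    conditions$replicate_group <- NA_character_
  }
  conditions$replicate_group <- as.character(conditions$replicate_group)
  for (col in c("reported_FI", "reported_GI", "reported_SI")) {
    if (!col %in% colnames(conditions)) conditions[[col]] <- NA_real_
    conditions[[col]] <- as.numeric(conditions[[col]])
  }
  missing_cols <- setdiff(.METADATA_COLS, colnames(conditions))
  if (length(missing_cols)) {
    stop(sprintf("condition metadata lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  conditions <- conditions[, .METADATA_COLS]
  abundance <- as.matrix(abundance)
  if (is.null(colnames(abundance)) ||
      !identical(sort(colnames(abundance)), sort(conditions$condition_id))) {
    stop("abundance columns must match condition_id values")
  }
  abundance <- abundance[, conditions$condition_id, drop = FALSE]
  .parseFields(rownames(abundance))  # every species name must be valid
  suitable <- colSums(!is.na(abundance)) > 0L
  no_data <- !suitable & is.na(conditions$reported_FI) &
    is.na(conditions$reported_GI) & is.na(conditions$reported_SI)
  if (any(no_data)) {
    stop(sprintf("conditions with neither distribution nor reported indices: %s",
                 paste(conditions$condition_id[no_data], collapse = ", ")))
  }
  cd <- S4Vectors::DataFrame(conditions, suitable = unname(suitable))
  rownames(cd) <- conditions$condition_id
  se <- SummarizedExperiment(assays = list(abundance = abundance), colData = cd)
  new("GlycanStudySet", se)
}

.checkEnum <- function(values, allowed, what, rows) {
  bad <- !values %in% allowed
  if (any(bad)) {
    stop(sprintf("invalid %s '%s' (metadata row %d); allowed: %s",
                 what, values[which(bad)[1L]], rows[which(bad)[1L]],
                 paste(allowed, collapse = ", ")))
  }
}

#' Read a compiled study table from CSV files
#'
#' Loads the two-file representation of a study corpus: a condition
#' metadata CSV (one row per culture condition) and a long-format
#' distributions CSV with columns \code{condition_id}, \code{glycan},
#' \code{relative_abundance_percent}. Both files are UTF-8,
#' comma-separated with a header row. Every distribution row must
#' reference a known condition and parse as a valid glycan; duplicate
#' (condition, glycan) rows are rejected. Violations are reported with
#' their row number.
#'
#' @param metadataPath path to the condition metadata CSV
#' @param distributionsPath path to the long-format distributions CSV
#' @return a [GlycanStudySet-class]
#' @seealso [writeStudyTable()] for the inverse
#' @export
readStudyTable <- function(metadataPath, distributionsPath) {
  meta <- utils::read.csv(metadataPath, stringsAsFactors = FALSE)
  dist <- utils::read.csv(distributionsPath, stringsAsFactors = FALSE)
  required <- c("study_id", "condition_id", "role", "parameter_category",
                "manipulation_type", "cell_line", "product", "culture_mode",
                "reference")
  missing_cols <- setdiff(required, colnames(meta))
  if (length(missing_cols)) {
    stop(sprintf("metadata CSV lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  rows <- seq_len(nrow(meta))
  .checkEnum(meta$role, c("control", "manipulated"), "role", rows)
  .checkEnum(meta$parameter_category, .PARAMETER_CATEGORIES,
             "parameter_category", rows)
  .checkEnum(meta$culture_mode, .CULTURE_MODES, "culture_mode", rows)
  if (anyDuplicated(meta$condition_id)) {
    stop(sprintf("duplicated condition_id '%s' in metadata",
                 meta$condition_id[anyDuplicated(meta$condition_id)]))
  }
  needed <- c("condition_id", "glycan", "relative_abundance_percent")
  missing_cols <- setdiff(needed, colnames(dist))
  if (length(missing_cols)) {
    stop(sprintf("distributions CSV lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  unknown <- !dist$condition_id %in% meta$condition_id
  if (any(unknown)) {
    stop(sprintf("unknown condition_id '%s' (distributions row %d)",
                 dist$condition_id[which(unknown)[1L]], which(unknown)[1L]))
  }
  dup <- duplicated(dist[, c("condition_id", "glycan")])
  if (any(dup)) {
    stop(sprintf("duplicate (condition_id, glycan) pair '%s'/'%s' (distributions row %d)",
                 dist$condition_id[which(dup)[1L]], dist$glycan[which(dup)[1L]],
                 which(dup)[1L]))
  }
  for (i in seq_len(nrow(dist))) {
    ok <- tryCatch({ .parseFields(dist$glycan[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop(sprintf("%s (distributions row %d)", ok, i))
  }
  species <- unique(dist$glycan)
  mat <- matrix(NA_real_, nrow = length(species), ncol = nrow(meta),
                dimnames = list(species, meta$condition_id))
  mat[cbind(match(dist$glycan, species), match(dist$condition_id, meta$condition_id))] <-
    dist$relative_abundance_percent
  GlycanStudySet(mat, meta)
}

.fmtNum <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Write a study table back to CSV files
#'
#' Inverse of [readStudyTable()]: emits the condition metadata and the
#' long-format distributions (non-NA entries only). Abundances and
#' reported indices are written with 17 significant digits so that a
#' read/write/read cycle is value-exact.
#'
#' @param x a [GlycanStudySet-class]
#' @param metadataPath,distributionsPath output CSV paths
#' @return invisibly, the two paths
#' @export
writeStudyTable <- function(x, metadataPath, distributionsPath) {
  stopifnot(is(x, "GlycanStudySet"))
  cd <- as.data.frame(colData(x))
  meta <- cd[, .METADATA_COLS]
  for (col in c("reported_FI", "reported_GI", "reported_SI")) {
    meta[[col]] <- .fmtNum(meta[[col]])
  }
  utils::write.csv(meta, metadataPath, row.names = FALSE, na = "")
  mat <- assay(x, "abundance")
  idx <- which(!is.na(mat), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  long <- data.frame(
    condition_id = colnames(mat)[idx[, "col"]],
    glycan = rownames(mat)[idx[, "row"]],
    relative_abundance_percent = .fmtNum(mat[idx]),
    stringsAsFactors = FALSE)
  utils::write.csv(long, distributionsPath, row.names = FALSE)
  invisible(c(metadataPath, distributionsPath))
}

#' Per-condition index sets
#'
#' Computes a [GlycanIndexSet-class] for every condition: from its
#' normalized glycoform distribution when one is available (suitability
#' flag), otherwise from the reported FI/GI/SI values with provenance
#' \code{"reported_in_source"}.
#'
#' @param x a [GlycanStudySet-class]
#' @param tolerance normalization tolerance, percentage points (default 5)
#' @param strict error on non-evaluable indices instead of NA
#' @return named list of [GlycanIndexSet-class], one per condition
#' @export
conditionIndexSets <- function(x, tolerance = 5, strict = FALSE) {
  stopifnot(is(x, "GlycanStudySet"))
  mat <- assay(x, "abundance")
  cd <- colData(x)
  out <- vector("list", ncol(mat))
  names(out) <- colnames(mat)
  for (j in seq_len(ncol(mat))) {
    if (cd$suitable[j]) {
      col <- mat[, j]
      d <- GlycanDistribution(col[!is.na(col)], tolerance = tolerance)
      out[[j]] <- computeIndexSet(d, strict = strict)
    } else {
      out[[j]] <- reportedIndexSet(FI = cd$reported_FI[j],
                                   GI = cd$reported_GI[j],
                                   SI = cd$reported_SI[j])
    }
  }
  out
}

#' Pair manipulated conditions with their controls
#'
#' Within each (study, experiment group) the single control condition is
#' matched to every manipulated condition, one pair per manipulation
#' level. A group holding more than one control is an error; manipulated
#' conditions without any control in their group are excluded and listed
#' in the \code{"unpaired"} attribute of the result.
#'
#' @param x a [GlycanStudySet-class]
#' @param ... unused
#' @return data.frame of pairs (study, group, control and manipulated
#'   condition ids, shared metadata), ordered by study then condition;
#'   attribute \code{"unpaired"}: character vector of unpaired manipulated
#'   condition ids
#' @rdname pairConditions
#' @export
setMethod("pairConditions", "GlycanStudySet", function(x, ...) {
  .pairConditionsDF(as.data.frame(colData(x)))
})

.pairConditionsDF <- function(cd) {
  key <- paste(cd$study_id, cd$experiment_group, sep = "\r")
  pairs <- list()
  unpaired <- character()
  for (k in unique(key)) {
    grp <- cd[key == k, , drop = FALSE]
    ctrl <- grp[grp$role == "control", , drop = FALSE]
    manip <- grp[grp$role == "manipulated", , drop = FALSE]
    if (nrow(ctrl) > 1L) {
      stop(sprintf("study '%s', experiment group '%s' has %d controls",
                   grp$study_id[1L], grp$experiment_group[1L], nrow(ctrl)))
    }
    if (nrow(ctrl) == 0L) {
      unpaired <- c(unpaired, manip$condition_id)
      next
    }
    if (nrow(manip) == 0L) next
    pairs[[k]] <- data.frame(
      study_id = manip$study_id,
      experiment_group = manip$experiment_group,
      control_id = ctrl$condition_id,
      manipulated_id = manip$condition_id,
      parameter_category = manip$parameter_category,
      manipulation_type = manip$manipulation_type,
      culture_mode = manip$culture_mode,
      cell_line = manip$cell_line,
      product = manip$product,
      reference = manip$reference,
      stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else data.frame(
    study_id = character(), experiment_group = character(),
    control_id = character(), manipulated_id = character(),
    parameter_category = character(), manipulation_type = character(),
    culture_mode = character(), cell_line = character(),
    product = character(), reference = character(),
    stringsAsFactors = FALSE)
  out <- out[order(out$study_id, out$manipulated_id), , drop = FALSE]
  rownames(out) <- NULL
  if (length(unpaired)) {
    message(sprintf("%d manipulated condition(s) without a control: %s",
                    length(unpaired), paste(unpaired, collapse = ", ")))
  }
  attr(out, "unpaired") <- unpaired
  out
}

#' Hierarchical grouping of condition pairs
#'
#' Clusters pairs by operational parameter, then perturbation type,
#' culture mode and CHO cell lineage (the default key order), returning a
#' nested named list whose leaves are data.frames of pairs ordered by
#' study id. An empty key set returns the single all-pairs group.
#'
#' @param pairs data.frame of pairs from [pairConditions()] or the
#'   comparisons table of [runPipeline()]
#' @param keys ordered character vector among \code{parameter_category},
#'   \code{manipulation_type}, \code{culture_mode}, \code{cell_line}
#' @return nested named list of data.frames (or a single data.frame when
#'   \code{keys} is empty)
#' @export
groupPairs <- function(pairs,
                       keys = c("parameter_category", "manipulation_type",
                                "culture_mode", "cell_line")) {
  allowed <- c("parameter_category", "manipulation_type", "culture_mode",
               "cell_line")
  bad <- setdiff(keys, allowed)
  if (length(bad)) {
    stop(sprintf("unknown grouping key(s): %s", paste(bad, collapse = ", ")))
  }
  ord <- pairs[order(pairs$study_id), , drop = FALSE]
  rownames(ord) <- NULL
  if (length(keys) == 0L) return(ord)
  first <- keys[[1L]]
  lapply(split(ord, factor(ord[[first]], levels = sort(unique(ord[[first]])))),
         groupPairs, keys = keys[-1L])
}

setMethod("show", "GlycanStudySet", function(object) {
  cd <- colData(object)
  cat(sprintf("GlycanStudySet: %d conditions (%d studies), %d glycoform species\n",
              ncol(object), length(unique(cd$study_id)), nrow(object)))
  cat(sprintf("  roles: %d control, %d manipulated | suitable for index calculation: %d\n",
              sum(cd$role == "control"), sum(cd$role == "manipulated"),
              sum(cd$suitable)))
  cats <- table(cd$parameter_category)
  cat("  parameter categories:",
      paste(sprintf("%s (%d)", names(cats), cats), collapse = ", "), "\n")
})
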