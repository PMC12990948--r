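#' Independent-site generator parameters
#'
#' Constructor for [GlycanSimParams-class]. The defaults are a typical-CHO
#' preset landing inside the literature-typical index ranges for IgG
#' produced in CHO systems (FI above 85\%, GI in the 10--30\% band, SI
#' below 10\%): core fucosylation 0.95, per-antenna galactosylation 0.20,
#' per-galactose sialylation 0.05, biantennary, no high-mannose.
#'
#' @param pFucose probability of core fucosylation
#' @param pGal per-antenna galactosylation probability
#' @param pSial per-galactose sialylation probability
#' @param antennarity fixed antennarity of the complex species
#' @param highMannoseFraction probability mass assigned to M5
#' @param nMolecules population size for [sampleDistribution()]
#' @param seed RNG seed for [sampleDistribution()]
#' @return a [GlycanSimParams-class]
#' @examples
#' GlycanSimParams(pGal = 0.30)
#' @export
GlycanSimParams <- function(pFucose = 0.95, pGal = 0.20, pSial = 0.05,
                            antennarity = 2L, highMannoseFraction = 0,
                            nMolecules = 1e6, seed = 1L) {
  new("GlycanSimParams",
      pFucose = unname(as.numeric(pFucose)), pGal = unname(as.numeric(pGal)),
      pSial = unname(as.numeric(pSial)),
      antennarity = as.integer(antennarity),
      highMannoseFraction = unname(as.numeric(highMannoseFraction)),
      nMolecules = as.integer(nMolecules), seed = as.integer(seed))
}

#' Exact expected glycoform distribution under the independent-site model
#'
#' Enumerates every complex species reachable at the fixed antennarity A:
#' with probability \code{pGal} per antenna a galactose is attached, with
#' probability \code{pSial} per galactose a NeuAc caps it, and with
#' probability \code{pFucose} the core is fucosylated, all independently.
#' A species with k galactoses and m NeuAc thus has expected abundance
#' \deqn{(1-hm)\,C(A,k)\,pGal^k(1-pGal)^{A-k}\,C(k,m)\,pSial^m(1-pSial)^{k-m}}
#' split between the fucosylated and afucosylated arms, plus M5 at the
#' high-mannose fraction hm. Zero-probability species are dropped. The
#' resulting pool has closed-form indices FI = 100 pFucose,
#' GI = 100 pGal, SI = 100 pSial, unaffected by hm.
#'
#' @param params a [GlycanSimParams-class]
#' @param ... unused
#' @return a [GlycanDistribution-class] summing to 100
#' @examples
#' enumerateDistribution(GlycanSimParams(pFucose = 0.9, pGal = 0.5, pSial = 0.2))
#' @rdname enumerateDistribution
#' @export
setMethod("enumerateDistribution", "GlycanSimParams", function(params, ...) {
  A <- params@antennarity
  hm <- params@highMannoseFraction
  p <- c()
  for (k in 0:A) {
    pk <- stats::dbinom(k, A, params@pGal)
    for (m in 0:k) {
      pm <- stats::dbinom(m, k, params@pSial)
      base <- paste0("A", A, "G", k, if (m > 0) paste0("S", m) else "")
      mass <- (1 - hm) * pk * pm
      p[paste0("F", base)] <- params@pFucose * mass
      p[base] <- (1 - params@pFucose) * mass
    }
  }
  if (hm > 0) p["M5"] <- hm
  p <- p[p > 0]
  GlycanDistribution(p * 100, tolerance = 1e-6)
})

#' Finite-population draw from the independent-site model
#'
#' Draws \code{nMolecules} glycans from the enumerated expected
#' distribution (multinomial) and converts counts to percent. Identical
#' seeds give identical output; the caller's RNG state is left untouched.
#'
#' @param params a [GlycanSimParams-class] with \code{nMolecules} and
#'   \code{seed} set
#' @param ... unused
#' @return a [GlycanDistribution-class]
#' @examples
#' sampleDistribution(GlycanSimParams(nMolecules = 1000, seed = 42))
#' @rdname sampleDistribution
#' @export
setMethod("sampleDistribution", "GlycanSimParams", function(params, ...) {
  exact <- abundances(enumerateDistribution(params))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params@seed)
  counts <- stats::rmultinom(1L, params@nMolecules, exact / 100)[, 1L]
  counts <- counts[counts > 0L]
  GlycanDistribution(100 * counts / params@nMolecules, tolerance = 1e-6)
})

#' Jitter generator probabilities on the logit scale
#'
#' Emulates batch-to-batch variability under a nominally identical
#' condition: each of the three occupancy probabilities receives
#' independent Gaussian noise on the logit scale. Probabilities exactly 0
#' or 1 are left untouched (they are structural, not noisy).
#'
#' @param params a [GlycanSimParams-class]
#' @param sd standard deviation of the logit-scale noise
#' @param seed RNG seed
#' @return a new [GlycanSimParams-class]
#' @export
jitterParams <- function(params, sd = 0.1, seed = 1L) {
  stopifnot(is(params, "GlycanSimParams"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  jit <- function(p) {
    if (p <= 0 || p >= 1) return(p)
    stats::plogis(stats::qlogis(p) + stats::rnorm(1L, 0, sd))
  }
  GlycanSimParams(pFucose = jit(params@pFucose), pGal = jit(params@pGal),
                  pSial = jit(params@pSial), antennarity = params@antennarity,
                  highMannoseFraction = params@highMannoseFraction,
                  nMolecules = params@nMolecules, seed = params@seed)
}

.defaultStudyMeta <- list(parameter_category = "other",
                          cell_line = "CHO-K1", product = "IgG1",
                          culture_mode = "batch", reference = "synthetic")

#' Build one synthetic study
#'
#' Assembles a control condition and any number of manipulated conditions
#' into a [GlycanStudySet-class] ready for the comparison pipeline, using
#' either the exact enumerated distributions (\code{mode = "exact"}) or
#' finite multinomial draws (\code{mode = "sampled"}). The ground-truth
#' index differences implied by the parameter changes
#' (100 |Delta p| per index) are stored in
#' \code{metadata(x)$trueDelta} for validation, and the full generator
#' parameters per condition in \code{metadata(x)$generator}.
#'
#' @param control a [GlycanSimParams-class] for the control condition
#' @param manipulated a list of [GlycanSimParams-class] (possibly empty)
#' @param metadata named list overriding the study metadata defaults
#'   (\code{parameter_category}, \code{manipulation_type},
#'   \code{cell_line}, \code{product}, \code{culture_mode},
#'   \code{reference})
#' @param mode \code{"exact"} or \code{"sampled"}
#' @param studyId study identifier
#' @return a [GlycanStudySet-class] with 1 + length(manipulated) conditions
#' @examples
#' st <- makeSyntheticStudy(GlycanSimParams(pGal = 0.30),
#'                          list(GlycanSimParams(pGal = 0.20)))
#' S4Vectors::metadata(st)$trueDelta
#' @export
makeSyntheticStudy <- function(control, manipulated = list(),
                               metadata = list(), mode = c("exact", "sampled"),
                               studyId = "SYN1") {
  mode <- match.arg(mode)
  if (is(manipulated, "GlycanSimParams")) manipulated <- list(manipulated)
  stopifnot(is(control, "GlycanSimParams"),
            all(vapply(manipulated, is, logical(1L), "GlycanSimParams")))
  meta <- utils::modifyList(.defaultStudyMeta, metadata)
  manip_type <- meta$manipulation_type %||% "synthetic manipulation"
  all_params <- c(list(control), manipulated)
  ids <- c(paste0(studyId, "_ctrl"),
           if (length(manipulated))
             paste0(studyId, "_manip", seq_along(manipulated)))
  dists <- lapply(all_params, function(pp) {
    if (mode == "exact") enumerateDistribution(pp) else sampleDistribution(pp)
  })
  species <- unique(unlist(lapply(dists, function(d) names(abundances(d)))))
  mat <- matrix(NA_real_, length(species), length(ids),
                dimnames = list(species, ids))
  for (j in seq_along(dists)) {
    ab <- abundances(dists[[j]])
    mat[names(ab), j] <- ab
  }
  conditions <- data.frame(
    study_id = studyId,
    condition_id = ids,
    role = c("control", rep("manipulated", length(manipulated))),
    parameter_category = meta$parameter_category,
    manipulation_type = c("control", rep(manip_type, length(manipulated))),
    cell_line = meta$cell_line, product = meta$product,
    culture_mode = meta$culture_mode, reference = meta$reference,
    stringsAsFactors = FALSE)
  x <- GlycanStudySet(mat, conditions)
  pslot <- function(pp) c(pp@pFucose, pp@pGal, pp@pSial)
  gen <- data.frame(
    condition_id = ids,
    pFucose = vapply(all_params, function(p) p@pFucose, 0),
    pGal = vapply(all_params, function(p) p@pGal, 0),
    pSial = vapply(all_params, function(p) p@pSial, 0),
    antennarity = vapply(all_params, function(p) p@antennarity, 0L),
    highMannoseFraction = vapply(all_params, function(p) p@highMannoseFraction, 0),
    seed = vapply(all_params, function(p) p@seed, 0L),
    mode = mode, stringsAsFactors = FALSE)
  metadata(x)$generator <- gen
  if (length(manipulated)) {
    ctrl_p <- pslot(control)
    td <- t(vapply(manipulated, function(pp) 100 * abs(pslot(pp) - ctrl_p),
                   numeric(3L)))
    metadata(x)$trueDelta <- data.frame(
      condition_id = ids[-1L],
      trueDeltaFI = td[, 1L], trueDeltaGI = td[, 2L], trueDeltaSI = td[, 3L],
      stringsAsFactors = FALSE)
  }
  x
}

#' Generate a synthetic multi-study cohort
#'
#' Builds a corpus of synthetic studies emulating a compiled literature
#' dataset: each study has one control drawn from the literature-typical
#' regime (FI > 85\%, GI 10--30\%, SI < 10\%) and one to three manipulated
#' conditions whose occupancy probabilities are perturbed, with metadata
#' drawn over the parameter categories, culture modes and common CHO
#' lineages. Roughly one study in six is reported-only: its distributions
#' are withheld and only the closed-form FI/GI/SI are carried, emulating
#' sources that publish indices without glycoform tables.
#'
#' @param nPairs total number of control/manipulated pairs (default 78)
#' @param seed RNG seed governing every random choice
#' @param mode \code{"exact"} or \code{"sampled"} distributions
#' @return a [GlycanStudySet-class]; generator parameters in
#'   \code{metadata(x)$generator}
#' @examples
#' cohort <- makeSyntheticCohort(nPairs = 6, seed = 1)
#' @export
makeSyntheticCohort <- function(nPairs = 78L, seed = 1L,
                                mode = c("exact", "sampled")) {
  mode <- match.arg(mode)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  cell_lines <- c("CHO-K1", "CHO DG44", "CHO GS", "CHO DUXB")
  products <- c("IgG1", "IgG4", "IgG", "Fc-fusion")
  manin <- c("constant lower setpoint", "shift to lower setpoint",
             "constant higher setpoint", "oscillatory", "additive supplementation")
  studies <- list()
  pair_count <- 0L
  s <- 0L
  while (pair_count < nPairs) {
    s <- s + 1L
    n_manip <- min(sample(1:3, 1L), nPairs - pair_count)
    theta <- c(pFucose = stats::runif(1, 0.85, 0.99),
               pGal = stats::runif(1, 0.10, 0.30),
               pSial = stats::runif(1, 0.01, 0.10))
    hm <- sample(c(0, 0.05), 1L, prob = c(0.8, 0.2))
    ctrl <- GlycanSimParams(pFucose = theta["pFucose"], pGal = theta["pGal"],
                            pSial = theta["pSial"], highMannoseFraction = hm,
                            nMolecules = 1e5, seed = 1000L * s)
    manip <- lapply(seq_len(n_manip), function(i) {
      GlycanSimParams(
        pFucose = min(1, max(0, theta["pFucose"] + stats::runif(1, -0.10, 0.05))),
        pGal = min(1, max(0, theta["pGal"] + stats::runif(1, -0.12, 0.12))),
        pSial = min(1, max(0, theta["pSial"] + stats::runif(1, -0.03, 0.03))),
        highMannoseFraction = hm, nMolecules = 1e5, seed = 1000L * s + i)
    })
    meta <- list(
      parameter_category = sample(.PARAMETER_CATEGORIES, 1L),
      manipulation_type = sample(manin, 1L),
      cell_line = sample(cell_lines, 1L),
      product = sample(products, 1L),
      culture_mode = sample(.CULTURE_MODES, 1L),
      reference = sprintf("Synthetic et al. %d", 2000L + s))
    st <- makeSyntheticStudy(ctrl, manip, metadata = meta, mode = mode,
                             studyId = sprintf("SYN%02d", s))
    if (stats::runif(1) < 1 / 6) st <- .withholdDistributions(st)
    studies[[s]] <- st
    pair_count <- pair_count + n_manip
  }
  .bindStudySets(studies)
}

# Reported-only variant of a synthetic study: drop the distributions and
# carry the computed FI/GI/SI as if published by the source.
.withholdDistributions <- function(x) {
  idx <- conditionIndexSets(x)
  cd <- as.data.frame(colData(x))
  cd$reported_FI <- vapply(idx, function(s) s@FI, 0)
  cd$reported_GI <- vapply(idx, function(s) s@GI, 0)
  cd$reported_SI <- vapply(idx, function(s) s@SI, 0)
  mat <- assay(x, "abundance")
  mat[] <- NA_real_
  out <- GlycanStudySet(mat[1L, , drop = FALSE] * NA, cd)
  # keep a single placeholder row to preserve matrix shape
  metadata(out) <- metadata(x)
  out
}

# rbind-like union of several GlycanStudySets over the species universe
.bindStudySets <- function(studies) {
  species <- unique(unlist(lapply(studies, rownames)))
  mats <- lapply(studies, function(st) {
    m <- matrix(NA_real_, length(species), ncol(st),
                dimnames = list(species, colnames(st)))
    m[rownames(st), ] <- assay(st, "abundance")
    m
  })
  mat <- do.call(cbind, mats)
  conds <- do.call(rbind, lapply(studies, function(st) as.data.frame(colData(st))))
  conds$suitable <- NULL
  rownames(conds) <- NULL
  # drop species rows never observed
  seen <- rowSums(!is.na(mat)) > 0L
  if (any(seen)) mat <- mat[seen, , drop = FALSE]
  out <- GlycanStudySet(mat, conds)
  gens <- do.call(rbind, lapply(studies, function(st) metadata(st)$generator))
  tds <- do.call(rbind, lapply(studies, function(st) metadata(st)$trueDelta))
  metadata(out)$generator <- gens
  metadata(out)$trueDelta <- tds
  out
}

#' Write the generator manifest as JSON
#'
#' Records the generator parameters and seeds of every synthetic
#' condition, so a fixture can be regenerated exactly.
#'
#' @param x a synthetic [GlycanStudySet-class]
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeGeneratorManifest <- function(x, path) {
  gen <- metadata(x)$generator
  if (is.null(gen)) stop("no generator manifest attached to this study set")
  jsonlite::write_json(gen, path, dataframe = "rows", digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
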