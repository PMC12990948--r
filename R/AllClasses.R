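#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.PARAMETER_CATEGORIES <- c("temperature", "pH", "dissolved_oxygen", "pCO2",
                           "osmolality", "chemical_additive", "other")
.CULTURE_MODES <- c("batch", "fed_batch", "perfusion")
.EFFECT_BINS <- c("negligible", "minor", "moderate", "major", "not_evaluable")
.PROVENANCE <- c("computed_from_distribution", "reported_in_source")

#' GlycanSpecies: structural record of one glycoform
#'
#' Parsed representation of a single released N-glycan in Oxford-style
#' shorthand. Complex-type species carry a core-fucose flag, an antennarity
#' (number of GlcNAc antennae on the trimannosyl core), an optional
#' bisecting-GlcNAc flag, and counts of galactose and N-acetylneuraminic
#' acid (NeuAc) residues. High-mannose species (M5--M9) carry only their
#' mannose degree; the trimannosyl core alone (M3) is encoded as a
#' complex-type record with zero antennae and degree zero.
#'
#' @slot name canonical shorthand, e.g. \code{"FA2G1S1"}
#' @slot coreFucose logical; alpha-1,6 fucose on the innermost GlcNAc
#' @slot antennarity integer; number of GlcNAc antennae (0 for M3 and
#'   high-mannose, otherwise 1--4)
#' @slot bisecting logical; bisecting GlcNAc (never counted as an antenna)
#' @slot galactoseCount integer; total galactose residues, including
#'   sialylated ones
#' @slot sialicCount integer; NeuAc residues
#' @slot highMannoseDegree integer; 0 for complex-type, else 5--9
#'
#' @seealso [parseGlycan()], [formatGlycan()], [speciesWeights()]
#' @exportClass GlycanSpecies
setClass("GlycanSpecies",
  representation(
    name = "character",
    coreFucose = "logical",
    antennarity = "integer",
    bisecting = "logical",
    galactoseCount = "integer",
    sialicCount = "integer",
    highMannoseDegree = "integer"
  )
)

setValidity("GlycanSpecies", function(object) {
  msg <- character()
  a <- object@antennarity
  g <- object@galactoseCount
  s <- object@sialicCount
  hm <- object@highMannoseDegree
  if (s < 0 || g < s) {
    msg <- c(msg, sprintf("sialic count %d exceeds galactose count %d", s, g))
  }
  if (g > a) {
    msg <- c(msg, sprintf("galactose count %d exceeds antennarity %d", g, a))
  }
  if (a > 4L) {
    msg <- c(msg, sprintf("antennarity %d exceeds 4", a))
  }
  if (hm > 0L) {
    if (!(hm %in% 5:9)) {
      msg <- c(msg, sprintf("high-mannose degree %d not in 5..9", hm))
    }
    if (object@coreFucose || a != 0L || g != 0L || s != 0L || object@bisecting) {
      msg <- c(msg, "high-mannose species cannot carry fucose, antennae, galactose, NeuAc or bisecting GlcNAc")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GlycanDistribution: normalized glycoform relative abundances
#'
#' Mapping from canonical species name to relative abundance as percent of
#' the released-glycan pool of one culture condition. Abundances are
#' strictly positive and sum to 100 after normalization; the
#' pre-normalization total is retained for audit.
#'
#' @slot abundances named numeric; percent per species, all > 0, sum 100
#' @slot normalized logical; whether rescaling was applied
#' @slot rawTotal numeric; sum of the input abundances before rescaling
#'
#' @seealso [GlycanDistribution()] constructor, [computeIndexSet()]
#' @exportClass GlycanDistribution
setClass("GlycanDistribution",
  representation(
    abundances = "numeric",
    normalized = "logical",
    rawTotal = "numeric"
  )
)

setValidity("GlycanDistribution", function(object) {
  p <- object@abundances
  msg <- character()
  if (is.null(names(p)) || anyNA(names(p)) || any(names(p) == "")) {
    msg <- c(msg, "abundances must be a named numeric vector")
  }
  if (any(p <= 0)) msg <- c(msg, "all abundances must be > 0")
  if (abs(sum(p) - 100) > 1e-9) {
    msg <- c(msg, sprintf("abundances sum to %.12g, not 100", sum(p)))
  }
  if (anyDuplicated(names(p))) msg <- c(msg, "duplicated species names")
  if (length(msg)) msg else TRUE
})

#' GlycanIndexSet: glycan indices for one culture condition
#'
#' The three site-occupancy glycan indices -- fucosylation (FI),
#' galactosylation (GI) and sialylation (SI) -- plus the three summative
#' motif indices, each in percent or \code{NA} when not evaluable.
#' Provenance records whether the values were computed from a full
#' glycoform distribution or taken as reported by the source study; in the
#' latter case summative indices cannot be calculated and are \code{NA}.
#'
#' @slot FI,GI,SI numeric; site-occupancy indices in percent (or NA)
#' @slot summFucose,summGalactose,summSialic numeric; summative indices
#'   (total abundance of species carrying the motif) in percent (or NA)
#' @slot provenance either \code{"computed_from_distribution"} or
#'   \code{"reported_in_source"}
#'
#' @seealso [computeIndexSet()], [reportedIndexSet()]
#' @exportClass GlycanIndexSet
setClass("GlycanIndexSet",
  representation(
    FI = "numeric",
    GI = "numeric",
    SI = "numeric",
    summFucose = "numeric",
    summGalactose = "numeric",
    summSialic = "numeric",
    provenance = "character"
  )
)

setValidity("GlycanIndexSet", function(object) {
  msg <- character()
  vals <- c(object@FI, object@GI, object@SI,
            object@summFucose, object@summGalactose, object@summSialic)
  if (length(vals) != 6L) msg <- c(msg, "all index slots must have length 1")
  bad <- !is.na(vals) & (vals < -1e-9 | vals > 100 + 1e-9)
  if (any(bad)) msg <- c(msg, "index values must lie in [0, 100]")
  if (!(object@provenance %in% .PROVENANCE)) {
    msg <- c(msg, sprintf("unknown provenance '%s'", object@provenance))
  }
  if (object@provenance == "reported_in_source" &&
      !all(is.na(c(object@summFucose, object@summGalactose, object@summSialic)))) {
    msg <- c(msg, "summative indices cannot be present for reported-only records")
  }
  if (length(msg)) msg else TRUE
})

#' GlycanStudySet: compiled culture conditions with distributions
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' column per culture condition and one row per glycoform species. The
#' \code{"abundance"} assay stores raw (as-published) relative abundances in
#' percent, \code{NA} where a species was not reported for a condition;
#' columns that are entirely \code{NA} are reported-only conditions whose
#' indices live in \code{colData}. Condition metadata (study, role,
#' parameter category, manipulation, cell line, product, culture mode,
#' reference, optional reported FI/GI/SI) is kept in \code{colData}.
#'
#' @seealso [readStudyTable()], [pairConditions()], [runPipeline()]
#' @exportClass GlycanStudySet
setClass("GlycanStudySet", contains = "SummarizedExperiment")

setValidity("GlycanStudySet", function(object) {
  msg <- character()
  cd <- colData(object)
  required <- c("study_id", "condition_id", "role", "parameter_category",
                "manipulation_type", "cell_line", "product", "culture_mode",
                "reference", "experiment_group")
  missing_cols <- setdiff(required, colnames(cd))
  if (length(missing_cols)) {
    return(sprintf("colData lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"abundance" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'abundance' is required")
  }
  if (anyDuplicated(cd$condition_id)) msg <- c(msg, "duplicated condition_id")
  bad_role <- !cd$role %in% c("control", "manipulated")
  if (any(bad_role)) msg <- c(msg, "role must be 'control' or 'manipulated'")
  bad_cat <- !cd$parameter_category %in% .PARAMETER_CATEGORIES
  if (any(bad_cat)) {
    msg <- c(msg, sprintf("unknown parameter_category: %s",
                          paste(unique(cd$parameter_category[bad_cat]), collapse = ", ")))
  }
  bad_mode <- !cd$culture_mode %in% .CULTURE_MODES
  if (any(bad_mode)) {
    msg <- c(msg, sprintf("unknown culture_mode: %s",
                          paste(unique(cd$culture_mode[bad_mode]), collapse = ", ")))
  }
  mism <- (cd$role == "control") != (cd$manipulation_type == "control")
  if (any(mism)) {
    msg <- c(msg, sprintf(
      "role 'control' must coincide with manipulation_type 'control' (conditions: %s)",
      paste(cd$condition_id[mism], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' GlycanSimParams: independent-site generator parameters
#'
#' Parameters of the independent-site occupancy model used to generate
#' synthetic biantennary glycoform distributions: core fucosylation,
#' per-antenna galactosylation and per-galactose sialylation are
#' independent Bernoulli events, antennae are i.i.d., and an optional
#' probability mass is diverted to the high-mannose species M5. Under this
#' model the enumerated distribution has closed-form indices
#' FI = 100 pFucose, GI = 100 pGal, SI = 100 pSial.
#'
#' @slot pFucose probability of core fucosylation
#' @slot pGal per-antenna galactosylation probability
#' @slot pSial per-galactose sialylation probability
#' @slot antennarity fixed antennarity of the complex species (default 2)
#' @slot highMannoseFraction probability mass assigned to M5
#' @slot nMolecules population size for sampled mode
#' @slot seed RNG seed for sampled mode
#'
#' @seealso [GlycanSimParams()], [enumerateDistribution()],
#'   [sampleDistribution()]
#' @exportClass GlycanSimParams
setClass("GlycanSimParams",
  representation(
    pFucose = "numeric",
    pGal = "numeric",
    pSial = "numeric",
    antennarity = "integer",
    highMannoseFraction = "numeric",
    nMolecules = "integer",
    seed = "integer"
  )
)

setValidity("GlycanSimParams", function(object) {
  msg <- character()
  probs <- c(object@pFucose, object@pGal, object@pSial, object@highMannoseFraction)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@antennarity < 1L || object@antennarity > 4L) {
    msg <- c(msg, "antennarity must be 1..4")
  }
  if (object@nMolecules < 1L) msg <- c(msg, "nMolecules must be >= 1")
  if (length(msg)) msg else TRUE
})
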