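# Site-occupancy ratio with abundance weights; NA + warning (or error in
# strict mode) when no site of the kind exists anywhere in the pool.
.occupancyRatio <- function(num_w, den_w, p, what, strict) {
  den <- sum(den_w * p)
  if (den <= 0) {
    if (strict) stop(sprintf("no %s in the distribution", what))
    warning(sprintf("no %s in the distribution; index not evaluable", what),
            call. = FALSE)
    return(NA_real_)
  }
  100 * sum(num_w * p) / den
}

#' Galactosylation index (GI)
#'
#' Net percentage of galactose-capable sites occupied by galactose across
#' the glycan pool: the abundance-weighted sum of galactose residues over
#' the abundance-weighted sum of antennae. Sialyl-capped galactoses count
#' as occupied; high-mannose species carry no galactose-capable sites and
#' enter neither sum.
#'
#' @param dist a [GlycanDistribution-class] object
#' @param strict error instead of returning NA when no site exists
#' @return percent in [0, 100], or NA with a warning when the pool has no
#'   galactose-capable site
#' @examples
#' galactosylationIndex(GlycanDistribution(c(FA2G0 = 50, FA2G1 = 30, FA2G2 = 20)))
#' @rdname galactosylationIndex
#' @export
setMethod("galactosylationIndex", "GlycanDistribution",
  function(dist, strict = FALSE) {
    p <- dist@abundances / 100
    w <- .weightFields(.parseFields(names(p)))
    .occupancyRatio(w$galResidues, w$antennaSites, p,
                    "galactose-capable sites", strict)
  })

#' Sialylation index (SI)
#'
#' Net percentage of sialylatable sites occupied by NeuAc. NeuAc attaches
#' only to galactose, so the available sites are the galactose residues;
#' SI is total NeuAc over total galactose, abundance-weighted.
#'
#' @inheritParams galactosylationIndex
#' @return percent in [0, 100], or NA with a warning when the pool carries
#'   no galactose
#' @examples
#' sialylationIndex(GlycanDistribution(c(FA2G2S1 = 100)))
#' @rdname sialylationIndex
#' @export
setMethod("sialylationIndex", "GlycanDistribution",
  function(dist, strict = FALSE) {
    p <- dist@abundances / 100
    w <- .weightFields(.parseFields(names(p)))
    .occupancyRatio(w$sialResidues, w$sialylatableSites, p,
                    "sialylatable sites (galactoses)", strict)
  })

#' Fucosylation index (FI)
#'
#' Net percentage of core-fucosylatable glycans carrying core fucose.
#' Membership of the fucosylatable pool is restricted to complex-type
#' species with at least one antenna; M3 and the high-mannose series are
#' excluded from numerator and denominator alike, so diluting a pool with
#' M5 leaves FI unchanged.
#'
#' @inheritParams galactosylationIndex
#' @return percent in [0, 100], or NA with a warning when no complex-type
#'   species is present
#' @examples
#' fucosylationIndex(GlycanDistribution(c(FA2G0 = 80, A2G0 = 20)))
#' @rdname fucosylationIndex
#' @export
setMethod("fucosylationIndex", "GlycanDistribution",
  function(dist, strict = FALSE) {
    p <- dist@abundances / 100
    w <- .weightFields(.parseFields(names(p)))
    .occupancyRatio(w$fucosylated, w$fucosylatable, p,
                    "core-fucosylatable species", strict)
  })

#' Summative motif indices
#'
#' Total relative abundance of glycoforms carrying at least one residue of
#' each motif -- a whole-glycan membership sum, as opposed to the
#' site-weighted occupancy of FI/GI/SI. The afucosylated share is the
#' complement of the summative fucose index to 100\%.
#'
#' @inheritParams galactosylationIndex
#' @return named numeric: \code{summFucose}, \code{summGalactose},
#'   \code{summSialic}, each in percent
#' @examples
#' summativeIndices(GlycanDistribution(c(FA2G0 = 50, FA2G1 = 30, FA2G2 = 20)))
#' @rdname summativeIndices
#' @export
setMethod("summativeIndices", "GlycanDistribution", function(dist) {
  p <- dist@abundances
  w <- .weightFields(.parseFields(names(p)))
  c(summFucose = sum(p[w$fucosylated >= 1L]),
    summGalactose = sum(p[w$galResidues >= 1L]),
    summSialic = sum(p[w$sialResidues >= 1L]))
})

#' Compute all glycan indices for one condition
#'
#' Bundles the three site-occupancy indices and the three summative
#' indices into a [GlycanIndexSet-class] with provenance
#' \code{"computed_from_distribution"}. Indices whose site pool is empty
#' come back NA (with a warning, or an error under \code{strict}).
#'
#' @inheritParams galactosylationIndex
#' @return a [GlycanIndexSet-class]
#' @examples
#' computeIndexSet(GlycanDistribution(c(FA2G0 = 50, FA2G1 = 30, FA2G2 = 20)))
#' @rdname computeIndexSet
#' @export
setMethod("computeIndexSet", "GlycanDistribution", function(dist, strict = FALSE) {
  summ <- summativeIndices(dist)
  new("GlycanIndexSet",
      FI = fucosylationIndex(dist, strict = strict),
      GI = galactosylationIndex(dist, strict = strict),
      SI = sialylationIndex(dist, strict = strict),
      summFucose = unname(summ["summFucose"]),
      summGalactose = unname(summ["summGalactose"]),
      summSialic = unname(summ["summSialic"]),
      provenance = "computed_from_distribution")
})

#' Index set from values reported by a source study
#'
#' Some studies publish glycan indices without the underlying glycoform
#' distribution; their values are carried through as reported. Summative
#' indices cannot be calculated without the distribution and stay NA.
#'
#' @param FI,GI,SI reported index values in percent, NA where not reported
#' @return a [GlycanIndexSet-class] with provenance
#'   \code{"reported_in_source"}
#' @examples
#' reportedIndexSet(FI = 95.2, GI = 21.0)
#' @export
reportedIndexSet <- function(FI = NA_real_, GI = NA_real_, SI = NA_real_) {
  new("GlycanIndexSet",
      FI = as.numeric(FI), GI = as.numeric(GI), SI = as.numeric(SI),
      summFucose = NA_real_, summGalactose = NA_real_, summSialic = NA_real_,
      provenance = "reported_in_source")
}

#' Extract index values and provenance
#'
#' \code{indexValues()} returns the six indices as a named numeric vector
#' (\code{FI}, \code{GI}, \code{SI}, \code{summFucose},
#' \code{summGalactose}, \code{summSialic}); \code{provenance()} reports
#' whether they were computed from a distribution or taken as reported.
#'
#' @param x a [GlycanIndexSet-class]
#' @return named numeric of length 6, or a single string
#' @rdname indexValues
#' @export
setMethod("indexValues", "GlycanIndexSet", function(x) {
  c(FI = x@FI, GI = x@GI, SI = x@SI,
    summFucose = x@summFucose, summGalactose = x@summGalactose,
    summSialic = x@summSialic)
})

#' @rdname indexValues
#' @export
setMethod("provenance", "GlycanIndexSet", function(x) x@provenance)

setMethod("show", "GlycanIndexSet", function(object) {
  fmt <- function(v) ifelse(is.na(v), "  NA", sprintf("%5.1f", v))
  cat(sprintf("GlycanIndexSet (%s)\n", object@provenance))
  cat(sprintf("  FI %s%%  GI %s%%  SI %s%%\n",
              fmt(object@FI), fmt(object@GI), fmt(object@SI)))
  cat(sprintf("  summative: fucose %s%%  galactose %s%%  sialic %s%%\n",
              fmt(object@summFucose), fmt(object@summGalactose),
              fmt(object@summSialic)))
})
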