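# Oxford-style shorthand grammar: F? A<d> B? G<d> (S<d>)?  or  M<d>
# Case-sensitive, no whitespace. M3 is the bare trimannosyl core and is
# encoded as complex-type with zero antennae; M5-M9 are high-mannose.

.COMPLEX_RE <- "^(F?)A([0-9])(B?)G([0-9])(?:S([0-9]))?$"
.MANNOSE_RE <- "^M([0-9])$"

# Vectorized structural parse; one row per name, stop on first bad name.
# Columns mirror the GlycanSpecies slots.
.parseFields <- function(names) {
  if (!is.character(names) || anyNA(names)) {
    stop("glycan names must be a character vector without NA")
  }
  n <- length(names)
  out <- data.frame(
    name = names,
    coreFucose = logical(n),
    antennarity = integer(n),
    bisecting = logical(n),
    galactoseCount = integer(n),
    sialicCount = integer(n),
    highMannoseDegree = integer(n),
    stringsAsFactors = FALSE
  )
  is_man <- grepl(.MANNOSE_RE, names)
  is_cpx <- !is_man & grepl(.COMPLEX_RE, names, perl = TRUE)
  bad <- !(is_man | is_cpx)
  if (any(bad)) {
    stop(sprintf("cannot parse glycan name '%s': expected F?A<d>B?G<d>(S<d>)? or M<d>",
                 names[which(bad)[1L]]))
  }
  if (any(is_man)) {
    d <- as.integer(sub(.MANNOSE_RE, "\\1", names[is_man]))
    bad_d <- !(d == 3L | (d >= 5L & d <= 9L))
    if (any(bad_d)) {
      stop(sprintf("invalid mannose degree in '%s': M3 or M5..M9 expected",
                   names[is_man][which(bad_d)[1L]]))
    }
    # M3: trimannosyl core, no antennae -- degree slot stays 0
    out$highMannoseDegree[is_man] <- ifelse(d == 3L, 0L, d)
  }
  if (any(is_cpx)) {
    m <- regmatches(names[is_cpx], regexec(.COMPLEX_RE, names[is_cpx], perl = TRUE))
    m <- do.call(rbind, m)
    a <- as.integer(m[, 3L])
    g <- as.integer(m[, 5L])
    s <- ifelse(m[, 6L] == "", 0L, suppressWarnings(as.integer(m[, 6L])))
    nm <- names[is_cpx]
    if (any(a < 1L | a > 4L)) {
      i <- which(a < 1L | a > 4L)[1L]
      stop(sprintf("invalid antennarity in '%s': A1..A4 expected", nm[i]))
    }
    if (any(g > a)) {
      i <- which(g > a)[1L]
      stop(sprintf("invalid species '%s': galactose count %d exceeds antennarity %d",
                   nm[i], g[i], a[i]))
    }
    if (any(s > g)) {
      i <- which(s > g)[1L]
      stop(sprintf("invalid species '%s': NeuAc count %d exceeds galactose count %d",
                   nm[i], s[i], g[i]))
    }
    out$coreFucose[is_cpx] <- m[, 2L] == "F"
    out$antennarity[is_cpx] <- a
    out$bisecting[is_cpx] <- m[, 4L] == "B"
    out$galactoseCount[is_cpx] <- g
    out$sialicCount[is_cpx] <- s
  }
  out
}

# Canonical shorthand from parsed fields (vectorized).
.formatFields <- function(fields) {
  ifelse(fields$highMannoseDegree > 0L,
         paste0("M", fields$highMannoseDegree),
  ifelse(fields$antennarity == 0L,
         "M3",
         paste0(ifelse(fields$coreFucose, "F", ""),
                "A", fields$antennarity,
                ifelse(fields$bisecting, "B", ""),
                "G", fields$galactoseCount,
                ifelse(fields$sialicCount > 0L,
                       paste0("S", fields$sialicCount), ""))))
}

# Index-equation weights from parsed fields (vectorized).
#   galResidues       GI numerator: all galactoses, sialyl-capped included
#   antennaSites      GI denominator: galactose-capable sites = antennae
#   sialResidues      SI numerator: NeuAc residues
#   sialylatableSites SI denominator: NeuAc attaches only to galactose
#   fucosylated       FI numerator membership (binary core fucose)
#   fucosylatable     FI denominator membership: complex species with
#                     antennae; M3 and high-mannose contribute nowhere
.weightFields <- function(fields) {
  complex_arm <- fields$highMannoseDegree == 0L & fields$antennarity > 0L
  data.frame(
    name = fields$name,
    galResidues = ifelse(complex_arm, fields$galactoseCount, 0L),
    antennaSites = ifelse(complex_arm, fields$antennarity, 0L),
    sialResidues = ifelse(complex_arm, fields$sialicCount, 0L),
    sialylatableSites = ifelse(complex_arm, fields$galactoseCount, 0L),
    fucosylated = as.integer(complex_arm & fields$coreFucose),
    fucosylatable = as.integer(complex_arm),
    stringsAsFactors = FALSE
  )
}

#' Parse an Oxford-style glycoform name
#'
#' Parses shorthand such as \code{"FA2G1S1"} (core-fucosylated biantennary,
#' one galactose, one NeuAc), \code{"A2G0"} (afucosylated agalactosylated
#' biantennary) or \code{"M5"} (high-mannose) into a [GlycanSpecies-class]
#' record. The grammar is \code{F? A<d> B? G<d> (S<d>)?} or \code{M<d>}
#' with \code{d} a digit: \code{F} marks core fucose, \code{A} the number
#' of GlcNAc antennae (1--4), \code{B} a bisecting GlcNAc (accepted but
#' never counted as an antenna), \code{G} galactoses, \code{S} NeuAc
#' residues, and \code{M3}/\code{M5}--\code{M9} the oligomannose series.
#' Parsing is case-sensitive; structurally impossible names (more
#' galactoses than antennae, more NeuAc than galactose, mannose degrees
#' outside \{3, 5..9\}) are rejected.
#'
#' @param name a single shorthand string
#' @return a [GlycanSpecies-class] object
#' @examples
#' parseGlycan("FA2G1S1")
#' parseGlycan("M5")
#' @export
parseGlycan <- function(name) {
  if (length(name) != 1L) stop("parseGlycan() expects a single name")
  f <- .parseFields(name)
  new("GlycanSpecies",
      name = .formatFields(f),
      coreFucose = f$coreFucose,
      antennarity = f$antennarity,
      bisecting = f$bisecting,
      galactoseCount = f$galactoseCount,
      sialicCount = f$sialicCount,
      highMannoseDegree = f$highMannoseDegree)
}

#' Canonical shorthand for a glycan species
#'
#' Inverse of [parseGlycan()]: renders the canonical name in the fixed
#' order \code{F A B G S}, omitting \code{S0}. \code{parseGlycan(formatGlycan(sp))}
#' recovers \code{sp} for every valid record.
#'
#' @param sp a [GlycanSpecies-class] object
#' @return a single string
#' @examples
#' formatGlycan(parseGlycan("A2G2S2"))
#' @export
formatGlycan <- function(sp) {
  stopifnot(is(sp, "GlycanSpecies"))
  .formatFields(data.frame(
    name = sp@name,
    coreFucose = sp@coreFucose,
    antennarity = sp@antennarity,
    bisecting = sp@bisecting,
    galactoseCount = sp@galactoseCount,
    sialicCount = sp@sialicCount,
    highMannoseDegree = sp@highMannoseDegree))
}

#' Per-species weights of the glycan-index equations
#'
#' Returns the coefficients with which one glycoform enters the three
#' site-occupancy index equations. The galactosylation index counts all
#' galactose residues (sialyl-capped included) over galactose-capable
#' sites (= antennae); the sialylation index counts NeuAc residues over
#' sialylatable sites (= galactoses, since NeuAc attaches only to
#' galactose); the fucosylation index is the binary core-fucose flag over
#' membership of the fucosylatable pool (complex-type species with at
#' least one antenna; M3 and high-mannose species contribute to no index).
#'
#' @param sp a [GlycanSpecies-class] object or a character vector of names
#' @return a one-row (or \code{length(sp)}-row) data.frame with columns
#'   \code{name}, \code{galResidues}, \code{antennaSites},
#'   \code{sialResidues}, \code{sialylatableSites}, \code{fucosylated},
#'   \code{fucosylatable}
#' @examples
#' speciesWeights("FA2G2S1")
#' speciesWeights(c("A1G0", "M5"))
#' @export
speciesWeights <- function(sp) {
  if (is(sp, "GlycanSpecies")) {
    fields <- data.frame(
      name = sp@name, coreFucose = sp@coreFucose, antennarity = sp@antennarity,
      bisecting = sp@bisecting, galactoseCount = sp@galactoseCount,
      sialicCount = sp@sialicCount, highMannoseDegree = sp@highMannoseDegree)
  } else {
    fields <- .parseFields(sp)
  }
  .weightFields(fields)
}

#' Species vocabulary of the compiled study tables
#'
#' The glycoform vocabulary used across the compiled CHO bioprocess
#' studies, with the index weights of every species -- a machine-readable
#' companion to the index equations.
#'
#' @return a data.frame with one row per species: the structural fields
#'   and the six index weights
#' @examples
#' glycanVocabulary()
#' @export
glycanVocabulary <- function() {
  vocab <- c("FA2G0", "FA2G1", "FA2G2", "A2G0", "A2G1", "A2G2",
             "FA2G1S1", "FA2G2S1", "FA2G2S2", "A1G0", "M3", "M5")
  fields <- .parseFields(vocab)
  cbind(fields, .weightFields(fields)[, -1L])
}

setMethod("show", "GlycanSpecies", function(object) {
  kind <- if (object@highMannoseDegree > 0L) {
    sprintf("high-mannose (M%d)", object@highMannoseDegree)
  } else if (object@antennarity == 0L) {
    "trimannosyl core (M3)"
  } else {
    sprintf("complex-type, %d antenna(e)", object@antennarity)
  }
  cat(sprintf("GlycanSpecies '%s' [%s]\n", object@name, kind))
  if (object@highMannoseDegree == 0L && object@antennarity > 0L) {
    cat(sprintf("  core fucose: %s%s | galactose: %d | NeuAc: %d\n",
                if (object@coreFucose) "yes" else "no",
                if (object@bisecting) " | bisecting GlcNAc" else "",
                object@galactoseCount, object@sialicCount))
  }
})
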