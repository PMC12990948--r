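#' Build a normalized glycoform distribution
#'
#' Validates and normalizes a vector of relative abundances. Published
#' glycan tables carry rounding error and often omit trace species, so the
#' raw total is allowed to deviate from 100\% within \code{tolerance}
#' percentage points; within that band the values are rescaled to sum
#' exactly 100 and the raw total is kept for audit. Non-structural
#' "Other"/"Unassigned" categories are dropped (with a message) before
#' normalization; zero abundances are dropped silently.
#'
#' @param abundances named numeric vector, percent per species name
#' @param tolerance maximal allowed deviation of the raw total from 100
#'   (percentage points, default 5)
#' @param dropOther drop names matching Other/Unassigned/Unknown before
#'   normalization (default TRUE)
#' @return a [GlycanDistribution-class] object
#' @examples
#' GlycanDistribution(c(FA2G0 = 49.5, FA2G1 = 30, FA2G2 = 19.5))
#' @export
GlycanDistribution <- function(abundances, tolerance = 5, dropOther = TRUE) {
  if (!is.numeric(abundances) || is.null(names(abundances))) {
    stop("abundances must be a named numeric vector")
  }
  if (anyNA(abundances)) stop("abundances must not contain NA")
  if (any(abundances < 0)) {
    stop(sprintf("negative abundance for '%s'",
                 names(abundances)[which(abundances < 0)[1L]]))
  }
  if (dropOther) {
    other <- grepl("^(other|unassigned|unknown)$", names(abundances),
                   ignore.case = TRUE)
    if (any(other)) {
      message(sprintf("dropping %d non-structural categor%s (%s, %.4g%%) before normalization",
                      sum(other), if (sum(other) == 1L) "y" else "ies",
                      paste(names(abundances)[other], collapse = ", "),
                      sum(abundances[other])))
      abundances <- abundances[!other]
    }
  }
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0L) stop("no positive abundances left")
  if (anyDuplicated(names(abundances))) {
    stop(sprintf("duplicated species '%s'",
                 names(abundances)[anyDuplicated(names(abundances))]))
  }
  fields <- .parseFields(names(abundances))
  canon <- .formatFields(fields)
  if (anyDuplicated(canon)) {
    stop("two input names canonicalize to the same species")
  }
  raw_total <- sum(abundances)
  if (raw_total < 100 - tolerance || raw_total > 100 + tolerance) {
    stop(sprintf("total abundance %.6g outside [%g, %g]",
                 raw_total, 100 - tolerance, 100 + tolerance))
  }
  p <- abundances * (100 / raw_total)
  names(p) <- canon
  new("GlycanDistribution",
      abundances = p,
      normalized = abs(raw_total - 100) > 0,
      rawTotal = raw_total)
}

#' Accessors for glycan distributions
#'
#' \code{abundances()} returns the normalized percent-per-species vector;
#' \code{rawTotal()} the pre-normalization sum.
#'
#' @param x a [GlycanDistribution-class] object
#' @return named numeric vector (percent), or a single number
#' @rdname abundances
#' @export
setMethod("abundances", "GlycanDistribution", function(x) x@abundances)

#' @rdname abundances
#' @export
rawTotal <- function(x) {
  stopifnot(is(x, "GlycanDistribution"))
  x@rawTotal
}

setMethod("show", "GlycanDistribution", function(object) {
  p <- sort(object@abundances, decreasing = TRUE)
  cat(sprintf("GlycanDistribution with %d species (raw total %.4g%%%s)\n",
              length(p), object@rawTotal,
              if (object@normalized) ", rescaled to 100" else ""))
  shown <- utils::head(p, 8L)
  cat(paste(sprintf("  %-10s %6.1f%%", names(shown), shown), collapse = "\n"), "\n")
  if (length(p) > 8L) cat(sprintf("  ... and %d more\n", length(p) - 8L))
})
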