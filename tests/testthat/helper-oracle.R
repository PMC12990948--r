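# Independent structural parse of Oxford shorthand, deliberately written
# with character-walking instead of the package's regex path so it can
# serve as an oracle. Returns f (0/1), a, g, s per name; high-mannose and
# M3 come back all-zero with complex = FALSE.
oracle_parse <- function(nm) {
  if (substring(nm, 1L, 1L) == "M") {
    return(list(f = 0L, a = 0L, g = 0L, s = 0L, complex = FALSE))
  }
  f <- 0L
  pos <- 1L
  if (substring(nm, 1L, 1L) == "F") {
    f <- 1L
    pos <- 2L
  }
  stopifnot(substring(nm, pos, pos) == "A")
  a <- as.integer(substring(nm, pos + 1L, pos + 1L))
  pos <- pos + 2L
  if (substring(nm, pos, pos) == "B") pos <- pos + 1L
  stopifnot(substring(nm, pos, pos) == "G")
  g <- as.integer(substring(nm, pos + 1L, pos + 1L))
  pos <- pos + 2L
  s <- 0L
  if (substring(nm, pos, pos) == "S") {
    s <- as.integer(substring(nm, pos + 1L, pos + 1L))
  }
  list(f = f, a = a, g = g, s = s, complex = TRUE)
}

# Brute-force per-molecule site census over a finite population given as
# per-species molecule counts. Expands to one entry per molecule and
# counts occupied over available sites for each motif.
oracle_census <- function(counts) {
  species <- rep(names(counts), counts)
  parsed <- lapply(species, oracle_parse)
  f <- vapply(parsed, `[[`, integer(1L), "f")
  a <- vapply(parsed, `[[`, integer(1L), "a")
  g <- vapply(parsed, `[[`, integer(1L), "g")
  s <- vapply(parsed, `[[`, integer(1L), "s")
  cx <- vapply(parsed, `[[`, logical(1L), "complex") & a > 0L
  list(
    GI = if (sum(a[cx]) > 0) 100 * sum(g[cx]) / sum(a[cx]) else NA_real_,
    SI = if (sum(g[cx]) > 0) 100 * sum(s[cx]) / sum(g[cx]) else NA_real_,
    FI = if (sum(cx) > 0) 100 * sum(f[cx]) / sum(cx) else NA_real_
  )
}

# Species vocabulary of the compiled study tables
vocab_species <- c("FA2G0", "FA2G1", "FA2G2", "A2G0", "A2G1", "A2G2",
                   "FA2G1S1", "FA2G2S1", "FA2G2S2", "A1G0", "M3", "M5")

# Random finite population over the vocabulary (counts per species)
random_population <- function(n_molecules, k_species = NULL) {
  sp <- if (is.null(k_species)) vocab_species else sample(vocab_species, k_species)
  w <- stats::runif(length(sp))
  counts <- stats::rmultinom(1L, n_molecules, w)[, 1L]
  names(counts) <- sp
  counts[counts > 0L]
}
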