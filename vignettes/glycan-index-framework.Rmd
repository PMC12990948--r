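---
title: "The glycan-index framework: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The glycan-index framework: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanIndices)
```

## Why indices

IgG Fc N-glycans are overwhelmingly biantennary complex-type
structures. A released-glycan measurement gives the relative abundance
of each glycoform in the pool; two studies rarely report the same
species set, which makes distributions hard to compare across
laboratories. The site-occupancy indices compress a distribution into
three numbers with a physical meaning: of all the sites that *could*
carry a given monosaccharide, what fraction actually does?

* **GI** — galactoses over galactose-capable sites. Each GlcNAc antenna
  can accept exactly one galactose, so the available sites per glycan
  equal its antennarity. A galactose that is itself capped by NeuAc
  still occupies its antenna, so it counts in the numerator; otherwise a
  fully sialylated glycan such as `FA2G2S2` would absurdly score zero
  galactosylation while carrying two galactoses.
* **SI** — NeuAc over sialylatable sites. NeuAc attaches only to
  galactose, so the available sites are the galactose residues. This
  makes SI conditional on galactosylation: a pool with galactose but no
  NeuAc has a true SI of 0 %, while a pool with no galactose at all has
  no defined SI (returned as `NA` with a warning; `strict = TRUE`
  raises instead). The two cases are deliberately kept distinct.
* **FI** — core fucose is binary per glycan, so FI is a population
  fraction over the glycans able to receive it. We restrict that pool
  to complex-type species with at least one antenna: core fucosylation
  requires the GlcNAc-initiated (complex/hybrid) processing pathway, so
  M3 and the high-mannose series M5–M9 are excluded from numerator
  *and* denominator. A practical consequence, exploited by the tests:
  diluting a pool with M5 changes no index.

The **summative indices** answer a coarser question — what fraction of
glycans carry the motif at all — and are the total abundance of
species with ≥ 1 residue of the motif. Summative fucose plus the
afucosylated share is identically 100 %, a conservation law the test
suite checks on 1,000 random distributions.

Because every index is a ratio of abundance-weighted site counts, the
values are invariant under rescaling of the raw abundances and under
species reordering, and they equal a brute-force per-molecule site
census on any finite population — the suite verifies this equivalence
against an independently written census on 1,000 random populations of
up to 10⁴ molecules.

## Nomenclature

`parseGlycan()` accepts the Oxford-style grammar
`F? A<d> B? G<d> (S<d>)?` or `M<d>`, case-sensitive, and enforces
structural feasibility (S ≤ G ≤ A ≤ 4; mannose degree in {3, 5..9}).
Choices worth stating:

* `M3` — the bare trimannosyl core — is encoded as a complex-type
  record with zero antennae rather than as high-mannose: it appears in
  compiled study tables and must parse, but it has no galactose-capable
  site and is not fucosylatable, so it carries zero weight in every
  index.
* Bisecting GlcNAc (`B`) is accepted and flagged because it is common
  in this notation dialect, but it is never counted as an antenna or a
  site; supporting it costs nothing and avoids spurious parse failures.
* Hybrid structures and antennarity > 4 are rejected: they are absent
  from the compiled tables of the IgG/CHO literature this package
  targets, and silently mis-weighting them would be worse than failing.
* The canonical order `F A B G S` with `S0` omitted makes
  `parseGlycan(formatGlycan(x))` an identity, tested over the full
  enumerated grammar.

## Normalization

Published distribution tables round to 0.1 % and often drop trace
species, so raw totals hover near but not at 100 %.
`GlycanDistribution()` rescales to exactly 100 when the raw total is
within ± `tolerance` percentage points (default 5, configurable) and
refuses otherwise; the raw total is retained in the object and every
rescaling is recorded in the pipeline log. Non-structural catch-all
rows ("Other", "Unassigned") carry no site information and are dropped
before normalization, with a message; the drop is auditable through
the raw total. Zero-abundance species are dropped silently. Internally
all values are kept at full double precision; only printed summaries
round to one decimal, the granularity at which indices are
conventionally reported.

## Pairing, deltas and bins

The unit of comparison is a control/manipulated pair within one
study's experiment group. Groups are scoped by an explicit
`experiment_group` column defaulting to the parameter category, because
one study may contribute independent series (a temperature series and
a pH series) each with its own control; a multi-level manipulation
(e.g. three temperature setpoints against one 37 °C control) yields
one pair per level sharing the control. More than one control in a
group is an error; a group with no control sends its manipulated
conditions to the unpaired report rather than failing the whole run.

Deltas are *absolute percentage points* (manipulated − control),
never relative percent. The signed value and a direction label are
kept alongside, since compiled tables conventionally report direction
arrows. Magnitude bins use fixed left-closed edges {1.5, 5, 10}:
[0, 1.5) negligible, [1.5, 5) minor, [5, 10) moderate, [10, ∞) major.
The literature narrative that motivates these thresholds never fixes
boundary membership, so the left-closed convention — and the edges
themselves — are configurable via `pipelineConfig(binEdges = ...)`. The
same bins are applied to summative deltas for uniformity. No
inferential statistics are attached: a ΔGIx is a difference of two
measured values, typically without dispersion information in the
source.

Batch replicates of one condition (declared through
`replicate_group`) are averaged **at the index level**, not the
distribution level, before pairing: index-level averaging makes the
order of operations explicit and keeps the replicate spread (logged)
interpretable in index units. Conditions published as indices only are
carried through with provenance `reported_in_source`; their ΔGIx is
computed but their summative deltas are structurally `not_evaluable`,
since summatives require the full distribution.

Every pair additionally records the largest per-species abundance
shift between its two distributions. This is the second layer of the
dual report: because indices are weighted sums, mass can move between
species at constant site occupancy — redistributing `FA2G1` and
`FA2G2` at constant total galactose moves individual glycoforms by
tens of percentage points while ΔGI stays at zero. Reporting both
layers keeps such masked rearrangements visible.

## The synthetic generator

No public corpus ships with the package, so all end-to-end validation
runs on synthetic studies from an independent-site occupancy model:
at fixed antennarity *A* (default 2, the dominant IgG case), each
antenna is galactosylated with probability `pGal`, each galactose
capped with probability `pSial`, and the core fucosylated with
probability `pFucose`, all independently; an optional mass fraction is
diverted to M5. The species probabilities are products of binomials,
and the enumerated distribution has closed-form indices

FI = 100 · pFucose, GI = 100 · pGal, SI = 100 · pSial,

unaffected by the M5 fraction. This closed form is what makes the
generator useful: every pipeline stage can be checked against known
truth, exactly in enumerated mode (the suite uses a 5×5×5 probability
grid × two high-mannose levels, tolerance 10⁻⁹) and statistically in
sampled mode (multinomial populations of 10⁶ molecules, each index
within 0.5 points of truth in ≥ 99/100 seeds). A logit-scale Gaussian
jitter (`jitterParams()`) emulates batch-to-batch parameter wobble;
it is off by default.

The default preset (pFucose = 0.95, pGal = 0.20, pSial = 0.05) was
chosen once to sit inside the literature-typical ranges for
CHO-produced IgG — FI above 85 %, GI in the 10–30 % band, SI below
10 % — and is not tuned thereafter. `makeSyntheticCohort()` scales
this up to a corpus (default 78 pairs, the size of the compiled
literature dataset the package mirrors) with randomized metadata, and
withholds the distributions of roughly one study in six to emulate
sources that publish indices without glycoform tables.

What the model does **not** capture: real glycosylation couples its
steps (galactosylation and sialylation compete for residence time in
the Golgi; fucosylation correlates with lineage), antennarity varies
within a pool, and measurement noise is not multinomial. Passing the
synthetic tests therefore demonstrates correctness of the *index
arithmetic and pipeline plumbing*, not fidelity of any biological
model; the generator is a test harness, not a simulator of CHO
biology, and fitting its parameters to real data is out of scope.

## Problem sizes and numerics

The shipped suite uses 1,000 random populations (≤ 10⁴ molecules) for
the census equivalence, 250 probability-grid points for exact
recovery, 100 seeds × 10⁶ molecules for sampled recovery, and a
78-pair cohort for the I/O round trip — sizes chosen to exercise the
properties convincingly while keeping the default run in minutes on
one core. Distribution sums are validated to 10⁻⁹; CSV output writes
17 significant digits so a read/write/read cycle is value-exact;
sampled-mode draws restore the caller's RNG state.

## Known limitations

* The mannose index (occupancy of the oligomannose series) is not
  implemented: most compiled sources do not report the data needed for
  it.
* Site-occupancy statistics of the glycosylation site itself
  (glycosylated vs. aglycosylated Fc) and asymmetric-Fc pairing are out
  of scope, as are O-glycans, mass computation and spectra
  interpretation.
* Grouped aggregation is descriptive (counts, bin tallies, ΔGIx
  spans); no pooling or significance testing is performed, matching
  the descriptive character of the underlying cross-study comparison.
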