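---
title: "Methods: positional composition of transmembrane helices and their flanks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional composition of transmembrane helices and their flanks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmhflanks)
```

## The problem

Transmembrane helices (TMHs) sit in a strongly anisotropic environment: a
hydrophobic bilayer core, charged lipid head groups, and an electrical
potential across the membrane. These constraints leave statistical
fingerprints in sequence — a hydrophobic core, lysine/arginine clustering
on the cytoplasmic flank (positive-inside rule), aspartate/glutamate
depletion on the cytoplasmic flank and/or enrichment outside
(negative-not-inside/negative-outside), tryptophan/tyrosine at the
water–lipid interface (the aromatic belt), and a leucine excess in the
cytoplasmic-side leaflet of the helix itself. The acidic skew is easy to
miss: D and E are among the rarest residues near membranes (of order 1% of
residues in single-pass helix neighbourhoods), so their signal is drowned
by fluctuations of abundant types unless the alignment and the
normalisation are chosen carefully. This package implements that analysis
as a reusable, fully tested pipeline.

## Orientation and coordinate conventions

Every helix is mapped onto a single axis running cytoplasmic ("inside",
negative positions) to non-cytoplasmic ("outside", positive positions).
Orientation uses the topological-domain annotation: if the nearest domain
preceding the TRANSMEM span carries the keyword "cytoplasmic"
(case-insensitively), the source direction is kept; if the nearest
following domain carries it, the segment is reversed; helices with the
keyword on neither side are omitted, and the keyword on both sides is
flagged as an annotation inconsistency. The keyword rule is applied
literally: domains whose labels merely resemble cytoplasm-facing
compartments do not orient a helix. Orientation is resolved independently
per helix in multi-pass proteins; a warning fires when the resulting
orientations do not alternate along a protein.

Internally all coordinates are 1-based inclusive — the natural convention
for R string handling — and the on-disk formats (flat file, segment table)
are 1-based inclusive as well, so no conversion happens at the boundary.

Helix cores shorter than 16 or longer than 38 residues are filtered out
(inclusive bounds): annotated lengths outside that range are dominated by
fragment and re-entrant artefacts rather than genuine membrane-spanning
helices. Both bounds are configurable in `flank_config()`.

## Flank extraction regimes

Loops between helices are often shorter than the flank depth being
analysed, so the package implements four regimes:

* **`db_no_overlap`** (default): flanks extend up to `max_flank` residues
  beyond the database helix boundary; a loop of length L shared by two
  membrane features contributes floor(L/2) residues to each adjoining
  flank, and the middle residue of an odd loop belongs to neither.
  INTRAMEM features truncate flanks by exactly the same half-loop rule —
  they are membrane-resident neighbours even though they are never counted
  as helices.
* **`db_overlap`**: flanks run to `max_flank` regardless of neighbouring
  helices (residues may then be counted twice across helices) but never
  into a membrane core.
* **`db_viable`**: as `db_no_overlap`, but the helix is kept only if both
  flanks reach at least `ceiling(viable_fraction × max_flank)` residues
  (default fraction 0.5 — viable length 5 at a 10-residue flank). This is
  the subset on which flank statistics are meaningful: no flanks, no
  flank bias.
* **`central`**: all helices are gaplessly aligned on their central
  residue (position 0) and a window of ±`central_half_width` positions is
  read off, with positions beyond the database-defined flank limit or the
  protein termini recorded as absent. The flank windows on this axis are
  −20..−10 and +10..+20 (inclusive), i.e. the positions beyond a
  standardised 21-residue core.

Two conventions were genuinely open and are exposed as configuration:

* the central residue of an even-length core is the earlier (cytoplasmic
  side) of the two middle residues by default (`even_center = "lower"`);
* the odd central residue of a core is excluded from both leaflet halves
  in `split_leaflets()` (the symmetric choice), with assignment to the
  inner half available (`center = "inner"`).

A flank clipped by the protein terminus is recorded as truncated, never
skipped — single-pass tails are often short and dropping them would bias
the single-pass statistics. Whether the length filter runs before or after
orientation-based omission affects only the ordering of ledger reasons,
not the kept set; the length filter runs first here. Every decision is
logged per helix in the extraction ledger
(`extraction_ledger()`: kept/skipped/omitted, reason, flank lengths), and
kept + skipped + omitted always equals the number of annotated helices.

## Normalisations

With a_{i,r} the count of residue type i at aligned position r over N
segments:

* **absolute relative occurrence** p_{i,r} = a_{i,r} / max_r(a_r), the
  denominator being the fullest alignment column (the number of sequences
  at full coverage). p is bounded by [0, 1] and dominated by abundant
  types.
* **relative percentage** q_{i,r} = 100·a_{i,r} / a_i, where a_i counts
  residues of type i over the entire analysed region (helix plus both
  flanks under central alignment). Each curve sums to 100; this is the
  normalisation that makes rare-residue skews visible.

Positions never covered by any segment are reported as missing rather than
zero — zero-filling would fabricate suppression at long offsets where
simply no data exist. Residue types absent from a region yield flagged NA
curves for the same reason. For boundary-anchored flank distributions the
natural a_i is per side (each flank is its own region); this is the
`per_side` switch of `relative_percentage()`, left off for central
alignment.

Reference levels for q: the **background** is the unweighted mean over
positions −30..−25 and 25..30 (12 positions, inclusive — far enough out to
escape membrane influence), and the **flank averages** are the inclusive
means over −20..−10 and +10..+20 (11 positions each). Inclusivity at both
endpoints is this package's reading of the written ranges.

The **net charge profile** is c_r = ((a_{K,r}+a_{R,r}) −
(a_{D,r}+a_{E,r}))/N with N the number of segments: +1 for K/R, −1 for
D/E, 0 for everything else including histidine, whose protonation state
near membranes is too context-dependent to assign a fixed charge.

**Hydrophobicity** uses unweighted sliding windows (default length 3,
partial windows at segment ends averaged over the residues available) over
per-residue scale values. Four scales ship as data with their literature
sources: Kyte–Doolittle (default), White–Wimley water–octanol whole
residue, the Hessa translocon ("biological") scale and the Eisenberg
consensus. Note the sign conventions differ: the two transfer-energy
scales decrease with hydrophobicity. Profiles can be stratified by the
number of helices per protein (classes 1, 2, …, 14, 15+).

## Statistics

Inside/outside skew is a two-group Kruskal–Wallis test on per-helix counts
(inside-flank sample vs outside-flank sample), with the standard tie
correction. Below nine observations per group the p value comes from the
exhaustive permutation null — the rank multiset is fixed, so the statistic
depends only on the group rank sum and full enumeration is cheap. Although
H is nonnegative by construction, the reported statistic carries the sign
of (mean outside − mean inside), which is how skew tables are read:
positive = outside excess. A degenerate sample (all counts identical) is
reported as no-skew with an undefined p value rather than a fabricated 1.

Distribution comparisons between helix groups (single- vs multi-pass,
simple vs complex vs multi) treat **each residue occurrence as one
observation valued by its aligned position**. That choice fixes N — and
with it the Bahadur slope B = |ln P|/N — at the residue-type count, which
is the scale on which slope tables are comparable across residue types;
the per-position-summary alternative (one value per position) is available
via `observation_unit = "per_position"`. Three tests probe different
alternatives: Kolmogorov–Smirnov (maximal curve difference),
Kruskal–Wallis (location skew) and χ² on the 2×R per-position count table,
with adjacent sparse positions pooled greedily until every expected count
reaches 1 (the pooling map is returned with the result). p = 0 cannot be
fed to the Bahadur slope; the implementation errors and asks for a lower
bound instead.

The per-position hydrophobicity comparison between single-pass and
multi-pass helices supports both the Welch two-sample t test and the
Kruskal–Wallis test — the two conventions in circulation for this
comparison — with neither privileged; `run_config(hydro_test =)` selects.
Raw p values are reported throughout (that is what skew tables
conventionally print); a Benjamini–Hochberg column can be added by the
caller from the tidy output, and is deliberately not emitted by default.

The leaflet test splits each core into inner/outer halves, counts the
residue of interest (leucine by default), and compares the per-helix
inner/outer samples; the headline number is 100 × total inner / total
outer. Per-helix is the default unit, per-protein aggregation an option —
the two readings of "per unit" both appear in practice.

## The complexity classifier

Helices that are mere anchors are hydrophobic and low-entropy; helices
with roles beyond anchorage are more polar and more complex. The
classifier used in the original literature is an external web service
whose decision parameters are not published, so this package ships an
explicit approximation: the decision score is mean hydrophobicity −
(intercept + slope × Shannon entropy), with a twilight band of ±margin
(defaults: intercept 2.0 Kyte–Doolittle units, slope −0.25 units/bit,
margin 0.5). The defaults were chosen once so that poly-leucine-like
anchors fall deep on the simple side and polar alternating cores on the
complex side; they are not calibrated against the external service, and
counts derived from them are not comparable with published simple/complex
counts. Externally produced calls can be imported as TSV and used for
stratification instead, which is the recommended route when fidelity to
the published classification matters.

## The synthetic cohort generator

`generate_cohort()` draws annotated proteins with the statistical
structure the analysis assumes: helix counts from a configurable
distribution (1..15+), core lengths concentrated at 20–22 within 16..38
(discretised Laplace weights, scale 2.2), loop lengths spanning 0 to 40
(geometric-like decay, mean ≈ 9, so short, odd and overlapping flanks all
occur), and terminal tails of 5–60 residues. Residues are drawn i.i.d.
within region classes (inside/outside flank within 10 residues of a helix,
distal loop, inner leaflet / centre / outer leaflet of the core) from a
curated-database background composition; core classes tilt that background
by exp(KD/2), which concentrates mass on L/I/V/F/A the way annotated cores
do. Bias knobs multiply the affected residue weights before
renormalisation: K/R inside (`k_pos_in`), D/E inside/outside
(`k_neg_in`, `k_neg_out`), leucine in the core with a leaflet skew
(`k_leu_core`, `s_leu`), and W/Y at the three interfacial positions each
side of each boundary (`k_aromatic_belt`) — the region where aromatic-belt
hotspots are reported. All knobs at 1 give a null cohort.

`preset_canonical()` fixes the knobs at k_pos_in = 2.8, k_neg_in = 0.4,
k_neg_out = 1.2, k_leu_core = 1.8, s_leu = 1.25, k_aromatic_belt = 2.5,
with 5% orientation noise: the resulting q-profiles show the inside
positive enrichment at roughly 2–3× background, acidic inside suppression
at roughly 2–3× below background with a mild outside excess, and a
leucine inner-leaflet surplus — the qualitative geometry of the real
skews at realistic magnitudes.

What the generator deliberately does **not** emulate: positional
autocorrelation, homology and redundancy structure, composition drift
between taxa, or genuinely atypical topologies. Passing tests on synthetic
cohorts therefore validate the counting, extraction and statistical
machinery — not the biological conclusions one would draw from real data.

## Calibration and problem sizes

The test suite checks type-I calibration by running the inside/outside
acidic test on 500 independent null cohorts of 200 single-pass helices
each (flanks fully 10 residues long) and requiring the rejection rate at
α = 0.05 to stay within the Monte-Carlo binomial band around the nominal
level; skew recovery uses the canonical-skew preset at 2000 single-pass
helices over 20 seeds. Other property tests run on cohorts of 15–50
proteins, which is ample for exact bookkeeping oracles. These sizes are
the package's chosen trade-off between statistical resolution and a test
suite that runs in minutes.

## Numerical and degenerate-input choices

* Rank ties use the standard tie correction; a tie correction of zero
  (all observations equal) is reported as a degenerate no-skew result.
* χ² pooling merges an offending column with its smaller neighbour,
  repeatedly; if two columns remain and still violate the expected-count
  floor, the test errors with advice to coarsen bins.
* Nonstandard residue letters (B, Z, X, U, O, J) count towards position
  coverage but towards no residue type, no window mean and no entropy
  term; strict mode rejects such records at parse time instead. The
  permissive default keeps records rather than silently shrinking
  datasets.
* Empty flanks, zero-length loops and helices at protein termini are all
  legal inputs with defined outputs (empty strings, truncation notes).
* Report bundles are deterministic: identical records and config produce
  byte-identical TSVs, stamped with a content hash of the configuration.

## Known limitations

* The flat-file dialect is a documented minimal subset (ID/AC, FT
  TRANSMEM/INTRAMEM/TOPO_DOM with a `/note` qualifier, SQ); other line
  types are ignored, not round-tripped.
* The complexity boundary is an approximation (see above).
* The segment-table format cannot express INTRAMEM features; records
  containing them should travel as flat files.
* Histidine is treated as neutral in all charge computations.
* The generator's i.i.d. residue model understates the variance that
  homologous redundancy induces in real cohorts; significance levels on
  real data should be read with that in mind.
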