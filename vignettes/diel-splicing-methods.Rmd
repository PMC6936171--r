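---
title: "Methods: diel alternative-splicing analysis from fragment data"
author: "dielsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel alternative-splicing analysis from fragment data}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circadian-clock transcripts in field-grown crops are extensively
alternatively spliced, and the balance between a gene's fully spliced (FS)
isoform and its alternative (AS) isoforms shifts with organ, season and —
for some genes — ambient temperature. High-resolution RT-PCR (HR RT-PCR)
measures this balance: fluorescently labelled amplicons spanning an AS
event are separated on a capillary sequencer, and the relative peak areas
of the FS and AS products give the splicing ratio. `dielsplice`
implements the full desk-side analysis of such an experiment: event
annotation and consequence classification on gene models, fragment sizing
and reference-gene normalization, zeitgeber-time normalization of field
sampling times across seasons, LOESS peak-phase estimation for diel
rhythms, log(AS/FS) splicing-ratio rhythms, and the regression of those
ratios on ambient temperature. A seeded synthetic-study generator
reproduces the sampling design so every stage is testable end to end.

## Gene models and event consequences

A `gene_model()` is an exon/intron layout on a genomic sequence with an
annotated CDS. Coordinates are 1-based inclusive as stored; exported BED
is 0-based half-open (rtracklayer does the conversion), GFF3 stays
1-based. Minus-strand genes are stored as given and every transcript
operation works on the reverse complement, so downstream code reasons
only 5'→3' on the coding strand. Construction validates the invariants:
non-overlapping exons, GT..AG introns, CDS length divisible by three,
terminal stop codon.

AS events are sets of primitive edits — retain an intron, skip an exon,
move a 5'/3' splice site by a signed number of nucleotides, include an
alternative exon. Composite events apply their parts 5'→3'; edits whose
retained segments overlap or invert are rejected. `classify_event()`
translates the edited transcript from the annotated start codon with the
standard genetic code and reports:

* `ptc` — a stop codon at least one codon upstream of the position
  homologous to the annotated stop. This is a purely positional
  definition; no NMD prediction (e.g. the 50-nt rule) is attempted,
  because the classification of record is "inserts a PTC", not NMD fate.
* `frame_preserved` — length change divisible by three *and* no new
  upstream in-frame stop.
* `aa_delta` — amino acids lost relative to wild type, defined only for
  frame-preserving events.

The packaged catalogue (`clock_gene_models()`, `clock_as_events()`)
carries five clock genes with seventeen events. Real sequences for these
loci are not publicly deposited, so the fixture uses synthetic toy
sequences engineered so that each event's classified consequence matches
the documented one exactly: every intron-retention event inserts a PTC,
one combined alternative-splice-site event removes 246 nt (82 aa) in
frame, and one alternative 3' splice site removes 30 nt (10 aa) in frame.
Exon/intron counts are inferred from the published gene-structure
diagrams and marked as such; two retained-intron events (ScPRR95 I3R,
ScTOC1 I3R) come from the structure survey rather than the printed event
table and are flagged `inferred`. Within the fixture, PTC positions are
approximate: a retained intron carries its stop either in the intron
itself or, via a frameshift, in the following exon; which of the two a
given event uses is a construction choice, not data.

## Zeitgeber-time normalization

Field harvests in different seasons are made comparable by mapping hours
since dawn `T` onto a reference 12 h/12 h day. With day length `P_d` and
night length `P_n = 24 − P_d`:

* day (`0 ≤ T < P_d`): `ZT = 12 · T / P_d`
* night (`P_d ≤ T < 24`): `ZT = 12 + 12 · (T − P_d) / P_n`

The two branches agree at dusk (both give 12) and at the day boundary
(24 ≡ 0); a symmetric photoperiod is the identity; the map is strictly
increasing and analytically invertible (`zt_inverse()`, used by the
round-trip tests at 1e-9 h). Sampling times beyond 24 h — the course runs
26 h — wrap into [0, 24) with the cycle counter kept in `day_index`, so
duplicated early-morning points can be plotted at either position.
Display labels such as "ZT22" use round-half-up (`zt_label()`); all
computation stays in decimal hours. Dawn and dusk are fixed per season:
the drift across a 26-h course (< 1 min at subtropical latitudes) is far
below the 2-h sampling interval.

## Fragment quantification

Sizing maps migration (scan units) to bp against the in-lane ladder.
The default is piecewise-linear interpolation between flanking ladder
points — simple, monotone and accurate to well under 1 bp at typical
ladder density and mobility curvature. The classic local Southern method
(reciprocal mobility model `L = c + k/(m − m0)` fitted to the two
flanking triplets and averaged) is available as an option and is more
accurate where the ladder is sparse. Targets outside the ladder span are
sized by extending the terminal fit and flagged `extrapolated`, because
assays can include amplicons beyond the ladder's top fragment.

Assignment takes each sized peak to the nearest panel amplicon within a
tolerance (default ±2 bp, typical capillary resolution); panels with two
expected sizes closer than twice the tolerance are rejected as ambiguous
at load time. Every defined isoform yields a record per sample; absent
peaks become zero with a `below_detection` flag. Normalization divides by
the geometric mean of the sample's reference-gene areas — the standard
multi-reference rule; the underlying assay names two reference genes but
not a combination rule, so the geometric mean is this package's choice.
Zeros propagate; how they enter ratios is decided once, at the
pseudo-count (below). A simple peak caller (`call_peaks()`: moving-average
smoothing, local maxima above 5% of the trace maximum, trapezoidal area
between flanking minima) supports the simulator's raw-trace path; real
inputs normally arrive as peak-table exports.

## Rhythms and peaks

`fit_loess()` fits a local-linear LOESS (tricube weights) over all
replicate points — replicates enter individually, not as means, matching
how such data are plotted — and evaluates it on a 0.1-h grid covering
[0, 24); the fit is not extrapolated beyond the observed time span. The
span default is 0.5: the source analysis states LOESS but neither span
nor degree, and 0.5 with 42 points gives each local fit about 21 points.
Standard errors come from a seeded bootstrap over replicate points
(default 200 resamples); the reference analysis shows "± SE" bands
without stating a method. The rhythm peak is the maximum of the fitted
curve between ZT0 and ZT22 (`find_peak()`, ties to the earliest grid
point) — the stated peak rule of the assay.

An AS isoform is called expressed when its fitted peak reaches 5% of its
paired FS isoform's peak (and an optional absolute floor). **This 5% rule
is an operational definition of this package**: the original study
reports expression calls without stating a criterion.

Group comparisons use the study's tests: a two-sided paired Student's
t-test (FS vs AS within replicate-timepoint) and one-way ANOVA with
Tukey's HSD across organs, both at α = 0.05. Raw p-values are reported by
default — the reference analysis reports uncorrected p < 0.05 — with
Benjamini–Hochberg available via `p.adjust` on the output if desired.
Degenerate inputs (zero variance) are flagged rather than raised.

## Splicing ratios and temperature

`ratio_series()` aligns an AS series with its FS counterpart — by
`sample_id` when available, since a 26-h course duplicates wrapped ZT
values — and computes `log10((AS + pseudo)/(FS + pseudo))`. Log base 10
is the default and is recorded; the linear-scale fold reporting makes
results base-independent. The pseudo-count defaults to half the smallest
nonzero normalized abundance in the dataset, applied symmetrically, so
below-detection zeros stay in the analysis without dominating it. Points
where both isoforms are below detection are dropped and counted.

The fold range of a ratio rhythm is `base^(max − min)` of the
(optionally LOESS-smoothed) log ratios, i.e. the max/min ratio on the
linear AS/FS scale. The literal ratio-of-log-values reading is available
behind `literal_log_ratio = TRUE`, but the linear reading is the default
because it is the only one invariant to the log base. Note that LOESS
smoothing attenuates the extremes of a diel wave, so a smoothed fold is
systematically below the raw-point fold; order-of-magnitude statements
("more than 10-fold") are robust to this, exact folds should be read from
the unsmoothed series.

`temp_regression()` fits OLS of the log ratio on ambient temperature over
a pooled group — by default per (gene, event, organ, season), mirroring
how such regressions are reported per panel — with temperature linearly
interpolated from the weather log to each sampling instant (stations log
at fixed intervals). A significant negative correlation requires a
negative slope with a two-sided p < α. Fewer than three matched points is
an error, not a silent NA.

## The synthetic study

`sim_config()` fixes the study conditions: two seasons with dawn/dusk at
6:30/18:00 (11.5 h day) and 5:45/19:00 (13.25 h day); sampling every 2 h
for 26 h starting 2 h before dawn (14 points); three pooled replicates;
leaf only in winter, leaf plus two internodes in summer; two constant
reference genes. FS transcripts follow truncated-cosine diel rhythms
(`max(0, cos)`) — clock transcripts are sharply peaked, and the peak is
the target statistic, so a pure sinusoid would be too easy. Each AS
isoform is derived from its FS level through
`log10(AS/FS) = mean + amplitude·cos(2π(zt − peak)/24) +
slope·(temp − 22 °C)`. The defaults encode the qualitative structure of
the system being emulated: the LHY-like gene's events peak at the end of
the night with a −0.05 /°C temperature coupling; the PRR-like gene's
events peak mid-morning with no direct coupling, because in the emulated
system only the LHY-like events showed a significant negative temperature
correlation. Replicate scatter is lognormal (fluorescence areas are
positive with multiplicative error; default sdlog 0.15), reference genes
tighter (0.05). Temperature is a seasonal mean (18 °C winter, 26 °C
summer) plus a diel cosine (amplitude 4–5 °C, warmest at 14:00) plus
AR(1) noise (φ = 0.6, sd 0.5 °C) — plausible subtropical field values.
Peak tables add a per-sample lognormal gain (sdlog 0.2) and a quadratic
mobility model unknown to the sizing code. All randomness flows from the
single config seed.

Two deliberate properties of this generator matter when reading test
results. First, because the ratio rhythm and temperature are both diel,
they are correlated regressors: the measured OLS slope of a
temperature-coupled event is steeper than the configured coupling (the
end-of-night ratio peak coincides with the coldest hours), and an
uncoupled event can show a small spurious positive slope. That is a
property of the field design itself, not a bug; recovery is therefore
asserted as "coupled events flagged significant-negative, uncoupled
events not", not as numeric slope equality. Second, the generator does
not emulate electropherogram artifacts (stutter, pull-up, saturation),
primer competition, partial splicing, or real genome sequence — passing
tests show the analysis chain is correct and well calibrated under the
stated noise model, not that it is robust to every artifact of real
capillary data.

## Problem sizes and numerical choices

The test suite runs the recovery studies at: 500 seeded series for peak
phase (assert ≤ 2 h error in ≥ 95%), 500 seeded runs for the −0.05 /°C
slope at noise sd 0.15 and 42 points (≥ 95% detected), 10,000 null
replicates for the ANOVA type-I error (0.05 ± 0.01), and one full
pipeline round trip (log-ratio recovery within |Δ| < 0.1, AS-before-FS
peak ordering, FS phases within ±2 h). These sizes give Monte-Carlo
standard errors well below the asserted margins while keeping the default
`R CMD check`-style run short.

Numerical conventions: peak ties resolve to the earliest ZT; sizing
enforces strictly monotone ladders; the local Southern fit falls back to
linear interpolation for exactly collinear triplets; constant series fit
to the constant with zero SE and no error; all-zero reference samples are
excluded with a record rather than poisoning the geometric mean.

## Limitations

The consequence classifier does bookkeeping on intervals and codons; it
does not predict NMD, protein-domain disruption or translation
reinitiation. The ZT map assumes a single dawn/dusk per season. The
expression-call threshold is an artifact definition. The pipeline's
synthetic mode is the only wired end-to-end path; file-based inputs go
through the stage functions (`quantify_peak_tables()`, `fit_loess()`,
`ratio_series()`, `temp_regression()`) directly, as the `analysis/`
scripts demonstrate.
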