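# dielsplice

Analysis toolkit for **diel (day/night) dynamics of alternative splicing
(AS) in plant circadian-clock genes**, as measured in field time courses
by high-resolution RT-PCR (HR RT-PCR) fragment analysis.

In this kind of experiment, plants are harvested every 2 h for 26 h
(starting 2 h before dawn, 14 time points, 3 pooled biological
replicates) in different seasons; fluorescently labelled RT-PCR amplicons
spanning each AS event are separated on a capillary sequencer; and the
relative peak areas of the fully spliced (FS) and alternative (AS)
products quantify the splicing ratio. `dielsplice` covers the entire
desk-side analysis:

* **Gene models & consequences** — annotate AS events (intron retention,
  exon skipping, alternative 5'/3' splice sites, alternative exons,
  composites) on exon/intron gene models, build the edited transcripts,
  and classify each event as PTC-inserting or in-frame
  (`gene_model()`, `build_transcript()`, `classify_event()`).
* **Fragment quantification** — size capillary peaks against the in-lane
  ladder (piecewise linear or local Southern), assign them to an amplicon
  panel, and normalize by the geometric mean of two reference genes
  (`size_peaks()`, `assign_isoforms()`, `normalize_abundances()`).
* **Zeitgeber time** — normalize clock times across seasonal photoperiods
  to a reference 12 h/12 h day: day `ZT = 12·T/P_d`, night
  `ZT = 12 + 12·(T − P_d)/P_n`, with `T` hours since dawn, `P_d`/`P_n`
  day/night length (`photoperiod()`, `zt_normalize()`,
  `sampling_schedule()`).
* **Rhythms** — LOESS trends over replicate points with bootstrap SE; the
  rhythm peak is the curve maximum on ZT0–ZT22; paired t-tests and
  one-way ANOVA + Tukey HSD for group comparisons (`fit_loess()`,
  `find_peak()`, `compare_groups()`).
* **Splicing ratios & temperature** — `log10(AS/FS)` series with a
  data-driven pseudo-count, linear-scale fold range, and OLS regression
  of ratios on interpolated ambient temperature with R² and p
  (`ratio_series()`, `ratio_fold_range()`, `temp_regression()`).
* **Synthetic studies** — a fully seeded generator emulating the sampling
  design, truncated-cosine rhythms, temperature-coupled splicing ratios,
  reference genes, and GeneMapper-style peak tables, used as ground truth
  throughout the test suite (`sim_config()`, `simulate_abundances()`,
  `simulate_peak_tables()`, `simulate_temperature()`).

A packaged catalogue (`clock_gene_models()`, `clock_as_events()`)
provides five clock genes (ScLHY, ScPRR37, ScPRR73, ScPRR95, ScTOC1)
with seventeen AS events on synthetic toy sequences engineered to
reproduce the documented consequence of every event.

## Worked example

The `analysis/` directory holds the numbered workflow. Running it end to
end on the default synthetic study:

```sh
Rscript analysis/01_simulate.R 1       # seed 1
Rscript analysis/02_annotate_events.R
Rscript analysis/03_quantify.R
Rscript analysis/04_rhythms.R
Rscript analysis/05_ratio_temperature.R
```

prints, stage by stage:

```
seed 1: 168 sample pools (42 winter, 126 summer), 5208 peak rows
temperature: winter mean 18.1 C, summer mean 25.7 C

all introns carry canonical GT..AG splice sites
17 events on 5 genes: 10 intron retentions (all PTC: TRUE)
in-frame: ScPRR37 Alt3ssE4 removes 30 nt (10 aa)
in-frame: ScPRR73 Alt5ssE4.Alt3ssE5 removes 246 nt (82 aa)

1008 abundance records across 168 samples (0 below detection)
log-abundance correlation with generator truth: r = 0.9998

24 rhythm fits; AS peaked earlier than FS in 16 of 16 conditions

pseudo-count 0.000163; 16 ratio groups
significant negative temperature coupling in 8/16 groups (genes: clockA)
```

Reading this: the annotation stage reproduces the event catalogue's
consequences (all retained introns insert premature termination codons;
the two alternative-splice-site events are in-frame deletions of 10 and
82 amino acids). The quantification stage recovers the generator's
abundances from raw peak tables almost exactly. The rhythm stage finds
every AS isoform peaking earlier than its fully spliced partner, and the
ratio stage flags a significant negative temperature coupling exactly in
the LHY-like gene's events — the structure the generator encodes. Each
stage writes tidy CSVs under `results/`.

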