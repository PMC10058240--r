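# etiofoot

DNase-seq footprinting and cis-regulatory dynamics for de-etiolation time
courses, with cross-species (C4 vs C3) comparison.

## The problem

When a dark-grown (etiolated) seedling first sees light, chromatin
reorganises within hours: promoter-proximal regions open, transcription
factors bind light-responsive elements (LREs — G-, GT-, E- and I-boxes
bound by bZIP, GT-trihelix, bHLH and MYB-related factors), and thousands of
genes switch state. Comparing this response between a C4 species and its C3
relative asks which cis-regulatory differences underlie the stronger
induction of C4 pathway genes. `etiofoot` provides the computational side
of such a study for researchers working with DNase-seq accessibility
profiles and RNA-seq time courses:

* **DHS set algebra** — peaks per time point; *hyperconserved* DHSs (open at
  every time point of the course) and *light-specific* DHSs (open at all
  light points, closed in the dark) by per-base interval algebra; SPOT
  scores, TSS-centred accessibility and log-ratio profiles, feature
  distributions and densities, locus-level accessibility fold changes.
* **Digital genomic footprinting** — a strand-aware binomial statistic: for
  a window W with shoulders S of length s, each strand contributes the
  exact upper-tail probability of the observed shoulder cut excess,
  `P(X ≥ obs), X ~ Bin(n, s/(s+|W|))`, and the footprint score is
  `log10 p_fw + log10 p_rv` (cutoff < −10).
* **Hexamer bias correction (FLR)** — relative cutting rates per 6-mer
  context estimated from deproteinated DNA; per footprint the depletion
  statistic `x = log((o_in/e_in)/(o_out/e_out))`; a two-component Gaussian
  mixture over x fitted by EM gives each footprint a posterior log-odds
  `FLR = log(π_f f_f(x)) − log(π_b f_b(x))`, and footprints with FLR < 0
  (depletion explained by sequence bias) are discarded.
* **Motif analysis** — PWM scanning with *exact* p-values (dynamic
  programme over the null score distribution, verified against exhaustive
  enumeration), semi-redundant motif grouping, non-overlapping occurrence
  counting, and an LRE census over gene windows (1.5 kb upstream of the TSS
  to the CDS end).
* **Enrichment and binding trajectories** — motif-group log2 ratios against
  backgrounds built from hyperconserved DHSs in gene loci;
  depth-compensated per-time-point motif proportions, mean-centred
  trajectories, and dark-vs-light Pearson correlations.
* **Expression dynamics** — quantile normalisation + sample-mean scaling,
  pseudo-3'UTR annotation fix, a robust DEG set as the intersection of two
  independent tests, and per-orthogroup induction contrasts
  `log2(induction_A / induction_B)`.
* **Synthetic data** — a seeded generator planting genomes, gene models,
  motifs, footprints with time-varying occupancy, hexamer cutting bias,
  bias-only controls and two-species expression, with full ground truth for
  parameter-recovery validation.

## Worked example

```r
library(etiofoot)
sc <- synthetic_scenario(seed = 7, genome_length = 1e6, n_genes = 75,
                         n_footprints = 100, n_decoys = 50)
data <- generate_scenario_data(sc)

peaks <- call_peaks(data$profiles[["0"]])
spot_score(data$profiles[["0"]], peaks)
#> [1] 0.709

fp   <- detect_footprints(data$profiles[["0"]], peaks)
bias <- estimate_hexamer_bias(data$control, data$genome_a)
bias
#> HexamerBiasTable: 999071 control cuts, rate range [0.149, 5.788], 0 absent hexamer(s)

flr <- footprint_flr(fp, data$profiles[["0"]], bias, data$genome_a)
flr$fit
#> MixtureFit: pi = (0.361, 0.639), mu = (-1.587, -0.035), sd = (0.086, 0.073), converged

filt <- filter_footprints(flr$footprints)
filt$report
#>   time total removed reduction
#> 1    0   277     177 0.6389892

mean(IRanges::overlapsAny(data$truth_a$footprints, filt$retained))
#> [1] 1
```

Reading the output: the SPOT score says 71% of the dark sample's cuts fall
inside called peaks. The mixture fit has found a protected component at
mean x ≈ −1.59 — close to `log(0.2)`, the planted protection factor — and a
background component at x ≈ 0 holding the decoys and noise detections; the
FLR filter removes 64% of raw detections (bias traps and spurious dips)
while every one of the 100 planted footprints survives.

`run_pipeline(scenario, outdir)` chains every stage (peaks → DHS sets →
bias → footprints → FLR → motif scan → enrichment → trajectories →
expression → species contrast), persists BED/TSV intermediates and writes a
schema-versioned JSON report; rerunning with the same seed reproduces the
report byte for byte.

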