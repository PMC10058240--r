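---
title: "Methods: footprinting and cis-regulatory dynamics in etiofoot"
author: "etiofoot authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprinting and cis-regulatory dynamics in etiofoot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`etiofoot` implements an integrated analysis of chromatin accessibility and
transcription-factor footprints across a de-etiolation (dark-to-light) time
course, with a cross-species comparison between a C4 plant and a C3
relative. The package covers six analysis layers — peak calling and DHS set
algebra, digital genomic footprinting with hexamer cutting-bias correction,
PWM scanning with exact p-values, motif-group enrichment and binding
trajectories, expression normalisation with a two-method DEG intersection,
and ortholog induction comparison — plus a seeded synthetic-data generator
that emulates the statistical structure such a study assumes. This vignette
explains the models, the parameters that matter, and the design choices made
where the design was genuinely open.

# Data model and coordinates

All intervals are 1-based closed `GenomicRanges`, the Bioconductor
convention; `rtracklayer` converts on BED/bedGraph/GFF3 I/O, so no manual
off-by-one handling exists anywhere in the package. A DNase sample is a
`CutProfile`: per-chromosome integer vectors of 5' cut counts, one per
strand. A cut is assigned to the base immediately 3' of the nick on the
strand of the read, and its hexamer context is the 3 bases either side of
the nick — for a forward-strand cut at base *i* this is plus-strand bases
*(i−3)..(i+2)*; for a reverse-strand cut, the reverse complement of
*(i−2)..(i+3)*. This register is a package convention (the underlying
protocol does not fix one); it is used identically in simulation, bias
estimation and expected-rate computation, so it cancels in every ratio the
analysis forms.

# Peak calling and DHS set algebra

`call_peaks()` is deliberately simple: both strands are pooled, per-base
rates are smoothed with a centred window (default 101 bp), and maximal runs
exceeding `fold_threshold` (default 5) times the global rate are merged
within `merge_gap` (100 bp) and filtered to `min_width` (100 bp). Peak
calling is commodity infrastructure here — the pipeline accepts externally
produced narrowPeak files equally — while the bespoke content is the set
algebra: `classify_dhs_sets()` computes, per base, the *hyperconserved* set
(open at all five time points) and the *light-specific* set (open at all
four light points and closed in the dark), as merged disjoint interval
sets. Both are validated against a brute-force per-base boolean oracle on
randomised instances.

`spot_score()` (fraction of cuts inside peaks) is the standard
signal-to-noise QC. `tss_profile()` averages depth-normalised cuts (cuts
per million per base; a per-sample normalisation analogous to RPKM at
single-base bins) over ±2 kb windows around TSSs, reflecting minus-strand
genes so negative offsets are always upstream; in log-ratio mode it
averages `log2((a+ε)/(b+ε))` per base with ε = 0.5 counts (the pseudocount
is unstated in the protocols this follows; 0.5 counts is the smallest value
that stabilises empty bases without visibly biasing covered ones).

Feature assignment uses the interval midpoint (ties toward the lower
coordinate) under the precedence promoter (2 kb upstream) > 5'UTR > CDS >
intron > 3'UTR > intergenic; densities divide counts by summed (unmerged)
feature lengths, so duplicating an annotation scales numerator and
denominator together.

# Digital genomic footprinting

`detect_footprints()` implements a Wellington-style strand-aware statistic.
For a candidate window W inside a DHS with shoulders of `shoulder` bases:
the forward-strand evidence is the exact binomial upper-tail probability of
seeing at least the observed forward cuts in the *left* shoulder out of all
forward cuts in (left shoulder + W), with success probability
`shoulder/(shoulder+|W|)`; the reverse strand is scored against the *right*
shoulder symmetrically. The footprint score is the sum of the two log10
p-values; per window start the best width is kept, and non-overlapping
candidates scoring below the threshold are selected greedily by ascending
score, ties to the leftmost start. Defaults: widths 11–25 step 2, shoulder
35, threshold −10 (the log10 p cutoff conventionally used with this
statistic). Bit-parity with any particular footprinting tool is a non-goal;
the statistic's contract is what downstream stages consume, and it is
tested against an independent direct-summation tail oracle to 1e-10 in
log10 space.

## Cutting-bias correction (FLR)

DNase I has strong sequence preferences, so some "footprints" are sequence
artifacts. `estimate_hexamer_bias()` estimates relative cutting rates per
hexamer from a deproteinated-DNA control:
`rate(h) = (cuts in context h + pc) / (genomic occurrences of h + pc)`,
normalised to mean 1 over hexamers observed in the genome (absent hexamers
are pinned at 1 and flagged). For each footprint a bias-corrected depletion
statistic is computed, `x = log((o_in/e_in)/(o_out/e_out))`, observed vs
bias-expected cuts inside vs in the shoulders (pseudocount 0.5 on observed
counts). A two-component Gaussian mixture over x is fitted by EM
(deterministic k-means initialisation from the 20%/80% quantiles; scale
floor 1e-3; footprint component = lower mean), and the footprint likelihood
ratio is the posterior log-odds
`FLR = log(π_f f_f(x)) − log(π_b f_b(x))`. A genuine protein-protected
footprint depletes cuts beyond what its sequence explains (x well below 0,
FLR ≥ 0); a bias trap is equally depleted in the control (x ≈ 0, FLR < 0)
and is removed by `filter_footprints()`. Degenerate single-component data
yields all-negative FLR with a flag rather than an arbitrary split. The
posterior log-odds formalisation is this package's design; only the
two-component mixture idea is inherited from the upstream method.

Before motif scanning, retained footprints are extended by 4 bp each side
(`extend_footprints()`, no merging), so edge-clipped motif instances remain
detectable.

# Motif scanning with exact p-values

`pwm_from_counts()` builds standard PWMs (pseudocount-regularised column
probabilities, log2 likelihood-ratio scores against a background
composition). `scan_sequence()` assigns each hit the probability that a
background-random sequence of the motif's width scores at least as high.
That null distribution is computed by a dynamic programme over columns. For
motifs whose distinct-score count stays below ~7e4 (always true up to width
8) the DP is *exact*: partial sums are accumulated in the same
left-to-right order as a per-sequence summation, so score values are
bitwise identical to scanned scores, and tail lookups use a 1e-9 tolerance
purely to group values that are mathematically tied but differ in final
float bits between summation paths. Wider motifs fall back to a binned DP
at 0.001 bits per bin, bounding the p-value error by the probability mass
within half a bin of the hit score. Exactness for widths ≤ 8 is verified
against exhaustive enumeration over all 4^w sequences.

Default scan threshold is p ≤ 1e-4 (the conventional FIMO default; the
choice is exposed). Note a consequence of exact p-values: a 6-bp site can
never reach 1e-4 (its best possible p is ≈ 2.4e-4 under a uniform
background), which is why the synthetic motif library uses 8–9 bp sites,
matching real plant light-responsive element PWMs.

Non-overlapping occurrence counting (`count_nonoverlapping()`) is greedy by
ascending p-value with fixed tie-breaks (leftmost start, then motif id),
making it order-independent; the LRE census (`count_lres()`) applies it
per motif family over the window from 1.5 kb upstream of the TSS to the CDS
end, reflected for minus-strand genes. `cluster_pwms()` offers a
single-linkage stand-in for motif-family clustering (best-offset Pearson
correlation of probability columns, reverse complement considered).

# Enrichment, trajectories, correlations

Motif-group enrichment compares a query hit set against background
proportions built from hits in hyperconserved DHSs restricted to
(expression-filtered) gene loci — gene body plus 1.5 kb promoter. The
statistic is `log2((obs + ε)/(exp + ε))` per group with
ε = pseudocount/total observed hits (log base 2 chosen and documented;
pseudocount 1 hit keeps zero-observed groups finite). Per-time-point motif
proportions divide by that time point's total grouped hits, cancelling
sequencing depth and footprint-count differences; trajectories are
mean-centred per group across the five time points, and each light time
point is correlated (Pearson by default, Spearman by flag) with the dark
column across groups. A negative correlation means groups bound in the dark
lose binding at that light time point.

# Expression dynamics

The normalisation chain mirrors the cross-species protocol: quantile
normalisation (via `limma::normalizeQuantiles`, whose tie handling — tied
entries receive the mean of the spanned order-statistic means — matches the
stated rule) followed by sample-mean scaling, after which a value of 1 is
the sample average and species become comparable. Heatmap transforms
(`row_mean_log_transform()`, `zscore_rows()`) and the pseudo-3'UTR fix
(`extend_pseudo_utr()`, default 339 bp — the mean annotated 3'UTR length in
the genome this convention comes from) are exact elementwise operations.

`detect_de_genes()` honours the two-method intersection contract: after a
low-expression filter (mean count ≥ 5), method A is an exact conditional
Poisson test on replicate-summed counts; method B is a Welch t-test on
log2(count+1) applied within its candidate set, the genes passing a
1.5-fold floor. p-values are BH-adjusted within each method — for method B
among its candidates, the floor acting as the method's filtering step — and
the robust set is the intersection of both calls at α. At n = 3 replicates
a Welch t is variance-starved; filtering by effect size before FDR
adjustment is what makes the method usable at that depth while the
intersection with the exact test keeps the null false-robust rate far below
α (measured ≈ 0.001 at α = 0.05 under negative-binomial noise).

`induction_comparison()` takes sample-mean-scaled matrices, aligns time
courses by nearest label, and reports per orthogroup the induction ratio
(last vs first time point, pseudocount 0.01 on the relative scale) per
species and the species contrast `log2(induction_A/induction_B)`.
Relative-abundance scaling carries a compositional caveat: strongly induced
modules inflate the sample mean and deflate everyone's relative values. On
a transcriptome-scale universe this distortion is small and stable; on a
toy universe where the induced module is a large mass fraction it is not —
which is why the validation evaluates the contrast on a 2000-gene
expression design (`expression_design()`) rather than the compact
DNase-arm genome.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the validation runs under.

**Genome and annotation.** A single random chromosome (GC 0.40, plant-like)
carrying evenly spaced gene models — 100 bp 5'UTR, two 300-bp CDS exons
split by a 100-bp intron, and for 70% of genes a 200-bp 3'UTR (the rest
exercise the pseudo-UTR fix) — on both strands. Each gene gets a planted
600-bp accessible region spanning [−150, +449] around its TSS. Classes
(`c4` 5%, `induced` 20%, `repressed` 20%, `flat` 55%) and orthogroups are
assigned from the master seed only, so species A and B (generated
separately) pair gene-by-gene. The C4 module is kept a small fraction, as
in real transcriptomes where such modules are a few percent of genes.

**Motif landscape.** Eight light-signalling motifs (G-box/bZIP,
GT-trihelix, I-box/MYB-related, E-box/bHLH, TCP, WRKY, AP2/ERF, CCA1-like;
8–9 bp consensus, 85% dominant base). Footprint sites (default 200) are
planted at motif instances inside DHSs, up to four slots per DHS; slots may
fall in coding sequence, as real duon sites do. Decoy dips (default 100)
tile the hexamer whose repetition has the lowest intrinsic two-strand
cutting rate under the scenario's bias table — depleted without any bound
protein, they exist to challenge the FLR filter. C4-class promoters receive
planted LREs 0.5–1.25 kb upstream of the TSS, species A getting 3× more
instances than species B (6 vs 2), mirroring a C4 promoter's enriched LRE
content.

**Cut profiles.** Per-base, per-strand Poisson counts with rate = depth ×
accessibility(t, position) × hexamer bias × (φ inside an occupied
footprint). Accessibility is 0.02 genome-wide, 1 across DHSs with 50-bp
linear shoulders; at 0.5–4 h the 500 bp upstream of each TSS gains ×1.5
while the 500 bp downstream loses ×0.81 — the paired gain/loss reproduces
the observed promoter reorganisation *and* keeps library composition
stable, so depth normalisation does not manufacture spurious far-field log
ratios (with gain alone the library grows ~25% and the far field sits at
−0.3 instead of 0). Default protection φ = 0.2, DHS depth 30 cuts/bp
(deep-footprinting scale; the real study's depths are unpublished, so depth
is a free scenario parameter). The deproteinated control is uniform
accessibility × bias at 1 cut/bp — 2M cuts on the 2-Mb standard genome. The
hexamer bias table itself is log-normal (sdlog 0.5, mean 1), a heavy-tailed
shape consistent with measured DNase preference spectra.

**Occupancy designs.** By default all footprints are constitutively bound
(the standard recovery scenario). The inversion design
(`occupancy_fractions = c(constitutive=.2, dark=.4, light=.4)`) binds
dark-class footprints (AP2/ERF, CCA1-like motifs) at 0 and 24 h and
light-class footprints (G-box, I-box, GT, E-box) at 0.5–4 h, producing the
anticorrelated dark-vs-light binding trajectories the trajectory analysis
must recover.

**Expression.** Negative-binomial counts (size 20, i.e. ~22% biological
CV; Poisson by config), log-normal baseline means shared within an
orthogroup. Induced genes jump ~4× by 0.5 h (fast light response),
repressed genes drop to ~0.4×, and the C4-like module ramps to its species
amplitude by 24 h — ×4 in species A, ×2 in species B.

**What the generator does not emulate:** read-level artifacts
(mappability, duplicates, fragment-length effects), diploid variation,
isoform structure, replicate-specific batch effects, and dependence between
neighbouring cut counts beyond the shared rate surface. Passing the
validation therefore demonstrates that the estimators recover the
generating model's structure at realistic depths — not that they are robust
to every failure mode of real libraries.

# Validation problem sizes and numerical choices

The standard recovery scenario is a 2-Mb genome, 150 genes, 200 footprints
at φ = 0.2, 100 decoys, depth 30 cuts/bp, fixed seed — small enough to run
in about a minute yet deep enough that every recovery criterion has clear
margin (recall 1.0, decoy removal 1.0, bias Spearman ≈ 0.99). Oracle checks
use widths ≤ 8 for enumeration (4^8 sequences) and totals ≤ 200 for the
binomial statistic. DE calibration uses 1000 null genes; power uses 100
simulated universes of 312 genes with 12 genes planted at 4-fold, mean 100,
n = 3. The species contrast uses 2000 genes with 100 C4 orthogroups.
End-to-end determinism is checked by running the full pipeline twice on a
1-Mb scenario and requiring identical reports.

Numerical conventions worth knowing: binomial tails come from `pbinom` on
the log scale (k = 0 gives exactly 0); EM stops on a relative
log-likelihood change of 1e-8 with a 500-iteration cap and returns the best
fit with a flag if unconverged; the exact-p DP's 1e-9 tie tolerance is
smaller than any mathematically distinct score gap a count-based PWM
produces; all randomness flows through per-component sub-seeds derived
deterministically from one master seed, so every artefact is byte-stable
under a fixed seed.

# Known limitations

The peak caller is a windowed fold-over-global scanner, not a model-based
caller; replicate-overlap QC and IDR are out of scope. The FLR mixture
assumes two Gaussian components over x, adequate for protection-vs-bias
separation but not for multi-modal occupancy. The DE stand-ins honour the
intersection contract but are not substitutes for moderated count models
when real data are available. Cross-species DNase comparison is limited to
the LRE census and expression contrast; footprint profiles are simulated
for species A only.
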