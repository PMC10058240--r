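#' Define a synthetic de-etiolation scenario
#'
#' A `SyntheticScenario` fixes every parameter of the synthetic data
#' generator: genome size and composition, gene and DHS layout, the
#' dark-to-light time course, footprint protection, hexamer cutting bias,
#' sequencing depths, and the induction design for the two species.  The
#' scenario plus its seed fully determine every generated artefact.
#'
#' The defaults describe the standard validation scenario: a 2-Mb genome,
#' 150 genes each carrying a promoter-proximal DHS, five harvest points at
#' 0, 0.5, 2, 4 and 24 hours, 200 planted transcription-factor footprints
#' at protection `phi = 0.2`, 100 cutting-bias decoy dips, 30 cuts/bp of
#' DNase signal inside DHSs, and a C4-like gene module induced 4-fold in
#' species A but only 2-fold in its species-B orthologs.
#'
#' @param seed Integer master seed; all component sub-seeds derive from it.
#' @param genome_length Genome size in bases (single chromosome).
#' @param gc_fraction GC content in `[0, 1]`.
#' @param n_genes Number of gene models.
#' @param time_points Harvest times in hours, strictly increasing; the
#'   first is the dark sample.
#' @param n_replicates RNA-seq replicates per time point (must be >= 1).
#' @param footprint_protection `phi` in `[0, 1]`: fraction of expected cuts
#'   remaining inside an occupied footprint (0 = full protection).
#' @param bias_profile Named numeric vector of 4096 relative hexamer
#'   cutting rates (mean 1).  `NULL` draws a log-normal table
#'   (`sdlog = 0.5`) from the seed.
#' @param peak_depth Mean cuts per base (both strands) inside a DHS.
#' @param background_fraction Accessibility outside DHSs relative to inside.
#' @param control_depth Mean cuts per base (both strands) of the
#'   deproteinated control.
#' @param n_footprints,n_decoys Number of planted footprints and of
#'   sequence-composition decoy dips (at most 2 per DHS in total).
#' @param frac_no_utr3 Fraction of gene models lacking an annotated 3'UTR.
#' @param induction_design Named list of per-class fold-change trajectories
#'   (one value per time point, first = 1).
#' @param species_pair_design List with `amplitude_a`, `amplitude_b`
#'   (24-h induction of C4-like genes in species A and B) and `lre_ratio`
#'   (ratio of planted LRE instances in A vs B promoters of C4-like genes).
#' @param occupancy_fractions Named numeric, fractions of footprints that
#'   are `constitutive` (bound at all times), `dark` (bound at 0 and 24 h)
#'   and `light` (bound at 0.5/2/4 h only); must sum to 1.
#' @param upstream_gain Multiplier applied to accessibility over the 500 bp
#'   upstream of each TSS at the 0.5-4 h time points (light-induced
#'   promoter opening).
#' @param downstream_loss Multiplier applied to accessibility over the
#'   500 bp downstream of each TSS at the same time points.  The default
#'   0.81 approximately balances the cut mass added by `upstream_gain`
#'   under the default layout, reproducing the observed pattern of
#'   upstream regions gaining and downstream regions losing accessibility
#'   while keeping library composition stable.
#' @param count_model `"nb"` or `"poisson"` for expression counts.
#' @param nb_size Negative-binomial size (inverse dispersion) when
#'   `count_model = "nb"`.
#' @param class_fractions Named fractions of genes per expression class
#'   (`c4`, `induced`, `repressed`, `flat`), summing to 1.
#'
#' @return An object of class `SyntheticScenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               genome_length = 2e6,
                               gc_fraction = 0.4,
                               n_genes = 150L,
                               time_points = c(0, 0.5, 2, 4, 24),
                               n_replicates = 3L,
                               footprint_protection = 0.2,
                               bias_profile = NULL,
                               peak_depth = 30,
                               background_fraction = 0.02,
                               control_depth = 1.0,
                               n_footprints = 200L,
                               n_decoys = 100L,
                               frac_no_utr3 = 0.3,
                               induction_design = NULL,
                               species_pair_design = list(amplitude_a = 4,
                                                          amplitude_b = 2,
                                                          lre_ratio = 3L),
                               occupancy_fractions = c(constitutive = 1, dark = 0, light = 0),
                               upstream_gain = 1.5,
                               downstream_loss = 0.81,
                               count_model = c("nb", "poisson"),
                               nb_size = 20,
                               class_fractions = c(c4 = 0.05, induced = 0.2,
                                                   repressed = 0.2, flat = 0.55)) {
  count_model <- match.arg(count_model)
  .assert(length(seed) == 1 && is.finite(seed), "seed must be a single integer")
  .assert(gc_fraction >= 0 && gc_fraction <= 1, "gc_fraction must lie in [0,1]")
  .assert(footprint_protection >= 0 && footprint_protection <= 1,
          "footprint_protection must lie in [0,1]")
  .assert(all(diff(time_points) > 0), "time points must be strictly increasing")
  .assert(n_replicates >= 1, "at least one replicate per time point is required")
  .assert(peak_depth > 0 && control_depth > 0 && background_fraction > 0,
          "all depths and rates must be positive")
  .assert(n_footprints + n_decoys <= 4L * n_genes,
          "at most four footprint/decoy slots fit per gene DHS")
  .assert(abs(sum(occupancy_fractions) - 1) < 1e-9, "occupancy fractions must sum to 1")
  .assert(abs(sum(class_fractions) - 1) < 1e-9, "class fractions must sum to 1")

  if (is.null(bias_profile)) {
    set.seed(component_seed(seed, "bias_table"))
    bias_profile <- stats::rlnorm(4096, meanlog = 0, sdlog = 0.5)
    bias_profile <- bias_profile / mean(bias_profile)
    names(bias_profile) <- .kmer_strings(6L)
  }
  .assert(length(bias_profile) == 4096 && all(bias_profile > 0),
          "bias_profile must give a positive rate for every hexamer")

  if (is.null(induction_design)) {
    # light-responsive genes switch fast: strong induction/repression by
    # 0.5 h, settling later; the C4-like module instead ramps up to its
    # species amplitude by 24 h (see species_pair_design)
    induction_design <- list(
      flat = rep(1, length(time_points)),
      induced = c(1, 4, 6, 5, 4)[seq_along(time_points)],
      repressed = c(1, 0.4, 0.3, 0.3, 0.35)[seq_along(time_points)]
    )
  }
  .assert(all(vapply(induction_design, function(f) all(f > 0), logical(1))),
          "fold changes must be positive")

  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
    time_points = time_points, n_replicates = as.integer(n_replicates),
    footprint_protection = footprint_protection, bias_profile = bias_profile,
    peak_depth = peak_depth, background_fraction = background_fraction,
    control_depth = control_depth, n_footprints = as.integer(n_footprints),
    n_decoys = as.integer(n_decoys), frac_no_utr3 = frac_no_utr3,
    induction_design = induction_design, species_pair_design = species_pair_design,
    occupancy_fractions = occupancy_fractions, upstream_gain = upstream_gain,
    downstream_loss = downstream_loss,
    count_model = count_model, nb_size = nb_size, class_fractions = class_fractions
  ), class = "SyntheticScenario")
}

#' @export
print.SyntheticScenario <- function(x, ...) {
  cat(sprintf(paste0("SyntheticScenario: %.2g Mb genome, %d genes, %d time points, ",
                     "%d footprints (phi=%.2f) + %d decoys, seed %d\n"),
              x$genome_length / 1e6, x$n_genes, length(x$time_points),
              x$n_footprints, x$footprint_protection, x$n_decoys, x$seed))
  invisible(x)
}

# Draw expression-class labels for n genes at the scenario's fractions
# (exact counts, remainder to flat); caller controls the RNG state.
.assign_classes <- function(scenario, n) {
  cf <- scenario$class_fractions
  n_per <- round(cf * n)
  n_per["flat"] <- n - sum(n_per[setdiff(names(n_per), "flat")])
  sample(rep(names(n_per), times = n_per))
}

#' Expression-only gene design for a scenario
#'
#' Builds the per-gene table (ids, expression classes, orthogroups) that
#' [simulate_expression()] needs, without generating a genome.  This
#' allows the expression arm to use a transcriptome-scale gene universe
#' (thousands of genes, so that relative-abundance normalisation behaves
#' as it does on real data) while the DNase arm keeps its compact genome.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_genes Number of genes in the expression universe (defaults to
#'   the scenario's `n_genes`).
#' @return `data.frame` with columns `gene_id`, `class`, `orthogroup`,
#'   usable as the `annotation` argument of [simulate_expression()].
#' @export
expression_design <- function(scenario, n_genes = scenario$n_genes) {
  set.seed(component_seed(scenario$seed, "classes"))
  classes <- .assign_classes(scenario, n_genes)
  data.frame(gene_id = sprintf("ga_%03d", seq_len(n_genes)),
             class = classes,
             orthogroup = sprintf("OG%04d", seq_len(n_genes)),
             stringsAsFactors = FALSE)
}

# Fixed gene model geometry used by the generator (bases).
.GENE_GEOM <- list(utr5 = 100L, cds1 = 300L, intron = 100L, cds2 = 300L, utr3 = 200L)

.gene_span <- function(has_utr3) {
  g <- .GENE_GEOM
  g$utr5 + g$cds1 + g$intron + g$cds2 + if (has_utr3) g$utr3 else 0L
}
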