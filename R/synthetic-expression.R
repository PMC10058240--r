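.c4_trajectory <- function(time_points, amplitude) {
  ramp <- c(0, 0.125, 0.25, 0.5, 1)[seq_along(time_points)]
  1 + (amplitude - 1) * ramp
}

# Per-gene expected expression across the time course for one species.
.design_means <- function(scenario, genes, base_means, species) {
  tp <- scenario$time_points
  amp <- if (species == "A") scenario$species_pair_design$amplitude_a else
    scenario$species_pair_design$amplitude_b
  folds <- matrix(1, nrow(genes), length(tp))
  for (i in seq_len(nrow(genes))) {
    folds[i, ] <- switch(genes$class[i],
                         c4 = .c4_trajectory(tp, amp),
                         flat = rep(1, length(tp)),
                         scenario$induction_design[[genes$class[i]]])
  }
  base_means * folds
}

#' Simulate the two-species expression experiment
#'
#' Draws negative-binomial (or Poisson) counts for every gene, time point
#' and replicate in both species.  Ortholog pairs share the same baseline
#' mean and expression class; genes of the C4-like class are induced to
#' `amplitude_a`-fold (species A) versus `amplitude_b`-fold (species B)
#' by 24 h, while `induced`/`repressed`/`flat` classes follow the
#' scenario's induction design identically in both species.
#'
#' @param scenario A [synthetic_scenario()].
#' @param annotation Species-A `GeneAnnotation` (gene table must carry
#'   `class` and `orthogroup`, as produced by
#'   [generate_genome_and_annotation()]) or a plain gene `data.frame`
#'   from [expression_design()].
#' @param annotation_b Optional species-B annotation (or gene table);
#'   when omitted, species-B gene ids are derived from the orthogroup
#'   pairing.
#' @return List with `expr_a`, `expr_b` (two [expression_matrix()]s),
#'   `ortholog_map` (`data.frame`: `orthogroup`, `gene_a`, `gene_b`) and
#'   `truth` (per-gene class and designed fold change per species).
#' @export
simulate_expression <- function(scenario, annotation, annotation_b = NULL) {
  .assert(scenario$n_replicates >= 1, "at least one replicate is required")
  genes <- if (is.data.frame(annotation)) annotation else annotation$genes
  .assert(all(c("class", "orthogroup") %in% names(genes)),
          "annotation gene table must carry class and orthogroup")
  tp <- scenario$time_points
  nrep <- scenario$n_replicates

  set.seed(component_seed(scenario$seed, "expr_means"))
  base_means <- stats::rlnorm(nrow(genes), meanlog = log(150), sdlog = 0.6)

  genes_b <- if (is.data.frame(annotation_b)) annotation_b else
    if (!is.null(annotation_b)) annotation_b$genes else
      transform(genes, gene_id = sub("^ga_", "gb_", gene_id))
  ortholog_map <- data.frame(orthogroup = genes$orthogroup,
                             gene_a = genes$gene_id, gene_b = genes_b$gene_id,
                             stringsAsFactors = FALSE)

  draw <- function(species, g) {
    mu <- .design_means(scenario, g, base_means, species)
    set.seed(component_seed(scenario$seed, paste0("expr_counts_", species)))
    cols <- list(); meta <- list()
    for (k in seq_along(tp)) for (r in seq_len(nrep)) {
      m <- mu[, k]
      cnt <- if (scenario$count_model == "nb") {
        stats::rnbinom(length(m), mu = m, size = scenario$nb_size)
      } else stats::rpois(length(m), m)
      nm <- sprintf("%s_t%s_r%d", species, as.character(tp[k]), r)
      cols[[nm]] <- cnt
      meta[[nm]] <- data.frame(sample = nm, species = species, time = tp[k],
                               replicate = r, stringsAsFactors = FALSE)
    }
    values <- do.call(cbind, cols)
    rownames(values) <- g$gene_id
    expression_matrix(values, do.call(rbind, meta))
  }

  expr_a <- draw("A", genes)
  expr_b <- draw("B", genes_b)

  truth <- data.frame(
    orthogroup = genes$orthogroup, class = genes$class, base_mean = base_means,
    fold24_a = .design_means(scenario, genes, rep(1, nrow(genes)), "A")[, length(tp)],
    fold24_b = .design_means(scenario, genes, rep(1, nrow(genes)), "B")[, length(tp)],
    stringsAsFactors = FALSE)
  list(expr_a = expr_a, expr_b = expr_b, ortholog_map = ortholog_map, truth = truth)
}
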