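#' Generate a synthetic genome and gene annotation
#'
#' Draws a random single-chromosome genome at the scenario's GC content and
#' lays out non-overlapping gene models (5'UTR, two CDS exons separated by
#' an intron, and for a configurable fraction of genes a 3'UTR) on both
#' strands, evenly spaced so that every gene carries a 2-kb promoter.
#' Each gene receives a promoter-proximal accessible region (the planted
#' DHS, 600 bp spanning `[-150, +449]` around the TSS in gene orientation)
#' and an expression class (`c4`, `induced`, `repressed`, `flat`); class
#' and orthogroup assignments depend only on the master seed, so the same
#' gene index in species A and B forms an ortholog pair of the same class.
#'
#' @param scenario A [synthetic_scenario()].
#' @param species `"A"` (the C4-like species) or `"B"` (the C3-like
#'   relative).  The genome sequence and exact gene placement differ
#'   between species; gene order, classes and orthogroups correspond.
#' @return A list with elements `genome` (named `DNAStringSet`),
#'   `annotation` (a [gene_annotation()] whose gene table carries `class`
#'   and `orthogroup` columns) and `truth` (list with the gene table and
#'   the planted `dhs` ranges).
#' @export
generate_genome_and_annotation <- function(scenario, species = c("A", "B")) {
  species <- match.arg(species)
  L <- scenario$genome_length
  n <- scenario$n_genes
  max_span <- .gene_span(TRUE)
  if (L < 10 * n * max_span) {
    stop(sprintf("genome of %d bases is too short for %d genes (need >= %d)",
                 L, n, 10 * n * max_span), call. = FALSE)
  }

  # Class / orthogroup design is species-independent by construction.
  set.seed(component_seed(scenario$seed, "classes"))
  classes <- .assign_classes(scenario, n)
  n_no_utr <- round(scenario$frac_no_utr3 * n)
  no_utr_idx <- sample.int(n, n_no_utr)

  set.seed(component_seed(scenario$seed, paste0("genome_", species)))
  gc <- scenario$gc_fraction
  seq_chr <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                          prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                   collapse = "")

  slot <- L %/% n
  geom <- .GENE_GEOM
  strands <- sample(c("+", "-"), n, replace = TRUE)
  has_utr3 <- !(seq_len(n) %in% no_utr_idx)
  spans <- vapply(has_utr3, .gene_span, integer(1))
  margin <- 2500L
  offsets <- vapply(seq_len(n), function(i) {
    hi <- slot - spans[i] - margin
    as.integer(sample(seq.int(margin, max(margin + 1L, hi)), 1L))
  }, integer(1))
  starts <- (seq_len(n) - 1L) * slot + offsets
  ends <- starts + spans - 1L

  gene_id <- sprintf("g%s_%03d", tolower(species), seq_len(n))
  tss <- ifelse(strands == "+", starts, ends)

  feat_list <- vector("list", n)
  cds_start <- integer(n); cds_end <- integer(n)
  for (i in seq_len(n)) {
    # feature widths in transcription order
    widths <- c(five_prime_UTR = geom$utr5, CDS1 = geom$cds1, intron = geom$intron,
                CDS2 = geom$cds2)
    if (has_utr3[i]) widths <- c(widths, three_prime_UTR = geom$utr3)
    types <- sub("[0-9]+$", "", names(widths))
    if (strands[i] == "+") {
      fe <- cumsum(widths) + starts[i] - 1L
      fs <- fe - widths + 1L
    } else {
      fs <- ends[i] - cumsum(widths) + 1L
      fe <- fs + widths - 1L
    }
    feat_list[[i]] <- data.frame(chrom = "chr1", start = fs, end = fe,
                                 strand = strands[i], type = types,
                                 gene_id = gene_id[i], stringsAsFactors = FALSE)
    cds_rows <- types == "CDS"
    cds_start[i] <- min(fs[cds_rows]); cds_end[i] <- max(fe[cds_rows])
  }
  feats <- do.call(rbind, feat_list)
  seqlengths <- c(chr1 = L)
  features <- GenomicRanges::GRanges(feats$chrom, IRanges::IRanges(feats$start, feats$end),
                                     strand = feats$strand, type = feats$type,
                                     gene_id = feats$gene_id, seqlengths = seqlengths)

  genes <- data.frame(gene_id = gene_id, chrom = "chr1", strand = strands,
                      start = starts, end = ends, tss = tss,
                      cds_start = cds_start, cds_end = cds_end,
                      has_utr3 = has_utr3, class = classes,
                      orthogroup = sprintf("OG%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
  annotation <- gene_annotation(genes, features, seqlengths)

  # Planted accessible region: [-150, +449] around the TSS in gene orientation.
  dhs_start <- ifelse(strands == "+", tss - 150L, tss - 449L)
  dhs_end <- ifelse(strands == "+", tss + 449L, tss + 150L)
  dhs <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(pmax(dhs_start, 1L), pmin(dhs_end, L)),
                                gene_id = gene_id, seqlengths = seqlengths)

  genome <- Biostrings::DNAStringSet(setNames(seq_chr, "chr1"))
  list(genome = genome, annotation = annotation,
       truth = list(genes = genes, dhs = dhs, species = species))
}

#' Write a genome to FASTA
#' @param genome A named `DNAStringSet`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
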