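#' Gene annotation container
#'
#' Holds gene models as a per-gene table plus a `GRanges` of sub-gene
#' features (5'UTR, CDS, intron, 3'UTR).  Coordinates are 1-based closed
#' throughout, the Bioconductor convention; GFF3 import/export goes through
#' rtracklayer so no manual off-by-one handling is needed.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, `tss`, `cds_start`, `cds_end` (genomic
#'   coordinates; `cds_start <= cds_end`), `has_utr3` (logical).
#' @param features `GRanges` with metadata columns `type` (one of
#'   `five_prime_UTR`, `CDS`, `intron`, `three_prime_UTR`) and `gene_id`.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return An object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(genes, features, seqlengths) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "tss",
            "cds_start", "cds_end", "has_utr3")
  .assert(all(need %in% names(genes)), "genes table is missing required columns")
  .assert(all(genes$strand %in% c("+", "-")), "gene strand must be '+' or '-'")
  tss_ok <- ifelse(genes$strand == "+", genes$tss == genes$start, genes$tss == genes$end)
  .assert(all(tss_ok), "TSS must equal the 5' gene boundary")
  .assert(all(genes$end <= seqlengths[genes$chrom]), "gene beyond chromosome end")
  structure(list(genes = genes, features = features, seqlengths = seqlengths),
            class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf("GeneAnnotation: %d genes, %d features on %d chromosome(s)\n",
              nrow(x$genes), length(x$features), length(x$seqlengths)))
  invisible(x)
}

#' Promoter intervals upstream of each TSS
#'
#' @param annotation A `GeneAnnotation`.
#' @param width Promoter width in bases upstream of the TSS (default 2000).
#' @return `GRanges` of promoters (clipped at chromosome ends) with a
#'   `gene_id` column.
#' @export
promoter_ranges <- function(annotation, width = 2000L) {
  g <- annotation$genes
  start <- ifelse(g$strand == "+", g$tss - width, g$tss + 1L)
  end <- ifelse(g$strand == "+", g$tss - 1L, g$tss + width)
  start <- pmax(start, 1L)
  end <- pmin(end, annotation$seqlengths[g$chrom])
  keep <- start <= end
  GenomicRanges::GRanges(g$chrom[keep], IRanges::IRanges(start[keep], end[keep]),
                         strand = g$strand[keep], gene_id = g$gene_id[keep],
                         seqlengths = annotation$seqlengths)
}

#' Gene locus windows (gene body plus upstream promoter)
#'
#' The window used when building motif backgrounds: the gene body together
#' with `upstream` bases of promoter.
#'
#' @param annotation A `GeneAnnotation`.
#' @param upstream Bases upstream of the TSS to include (default 1500).
#' @return `GRanges` with a `gene_id` column.
#' @export
gene_locus_windows <- function(annotation, upstream = 1500L) {
  g <- annotation$genes
  start <- ifelse(g$strand == "+", g$start - upstream, g$start)
  end <- ifelse(g$strand == "+", g$end, g$end + upstream)
  start <- pmax(start, 1L)
  end <- pmin(end, annotation$seqlengths[g$chrom])
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(start, end),
                         strand = g$strand, gene_id = g$gene_id,
                         seqlengths = annotation$seqlengths)
}

# GRanges of all features of one type, empty GRanges when absent.
.features_of_type <- function(annotation, type) {
  f <- annotation$features
  f[f$type == type]
}

#' Write a gene annotation as GFF3
#' @param annotation A `GeneAnnotation`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  gene_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                    strand = g$strand,
                                    seqlengths = annotation$seqlengths)
  gene_gr$type <- "gene"
  gene_gr$ID <- g$gene_id
  if (!is.null(g$class)) gene_gr$locus_class <- g$class
  if (!is.null(g$orthogroup)) gene_gr$orthogroup <- g$orthogroup
  feat <- annotation$features
  feat_gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(feat),
                                    IRanges::ranges(feat),
                                    strand = GenomicRanges::strand(feat),
                                    seqlengths = annotation$seqlengths)
  feat_gr$type <- feat$type
  feat_gr$ID <- paste0(feat$gene_id, ":", feat$type, ":", seq_along(feat))
  feat_gr$Parent <- feat$gene_id
  all <- c(gene_gr, feat_gr)
  all <- all[order(as.character(GenomeInfoDb::seqnames(all)), IRanges::start(all))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Expects `gene` records plus `five_prime_UTR`/`CDS`/`intron`/
#' `three_prime_UTR` children carrying a `Parent` attribute.
#'
#' @param path GFF3 file.
#' @param seqlengths Named chromosome lengths; inferred from the file's
#'   maxima when omitted.
#' @return A `GeneAnnotation`.
#' @export
read_annotation_gff3 <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (any(is.na(sl))) {
      sl <- tapply(IRanges::end(gr), as.character(GenomeInfoDb::seqnames(gr)), max)
      sl <- setNames(as.integer(sl), names(sl))
    }
    seqlengths <- sl
  }
  is_gene <- gr$type == "gene"
  genes_gr <- gr[is_gene]
  feats <- gr[!is_gene & gr$type %in% c("five_prime_UTR", "CDS", "intron", "three_prime_UTR")]
  parent <- vapply(feats$Parent, function(p) as.character(p)[1], character(1))
  features <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(feats), IRanges::ranges(feats),
                                     strand = GenomicRanges::strand(feats),
                                     type = as.character(feats$type), gene_id = parent)
  gid <- as.character(genes_gr$ID)
  strand_chr <- as.character(GenomicRanges::strand(genes_gr))
  cds <- features[features$type == "CDS"]
  cds_by <- split(data.frame(s = IRanges::start(cds), e = IRanges::end(cds)), cds$gene_id)
  utr3 <- unique(features$gene_id[features$type == "three_prime_UTR"])
  genes <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomeInfoDb::seqnames(genes_gr)),
    strand = strand_chr,
    start = IRanges::start(genes_gr),
    end = IRanges::end(genes_gr),
    tss = ifelse(strand_chr == "+", IRanges::start(genes_gr), IRanges::end(genes_gr)),
    cds_start = vapply(gid, function(g) min(cds_by[[g]]$s), numeric(1)),
    cds_end = vapply(gid, function(g) max(cds_by[[g]]$e), numeric(1)),
    has_utr3 = gid %in% utr3,
    stringsAsFactors = FALSE
  )
  if (!is.null(genes_gr$locus_class)) genes$class <- as.character(genes_gr$locus_class)
  if (!is.null(genes_gr$orthogroup)) genes$orthogroup <- as.character(genes_gr$orthogroup)
  rownames(genes) <- NULL
  gene_annotation(genes, features, seqlengths)
}
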