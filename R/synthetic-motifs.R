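#' Default synthetic motif library
#'
#' Eight plant light-signalling motifs (8-9 bp consensus sites with 85%
#' dominant-base probability) covering the classic light-responsive
#' element families:
#' G-box (bZIP/HY5-type), GT element (GT-trihelix), I-box (MYB-related),
#' E-box (bHLH), plus TCP, WRKY, AP2/ERF and CCA1-like evening-element
#' motifs.  The accompanying group map assigns each motif to its
#' transcription-factor family group.
#'
#' @param background Background base frequencies used for the score
#'   matrices.
#' @return List with `pwms` (named list of `PWM`) and `group_map`
#'   (`data.frame` with `motif_id`, `group`).
#' @export
default_motif_library <- function(background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  defs <- list(
    Gbox_bZIP   = list(cons = "CCACGTGG",  group = "G-box/bZIP"),
    GT1_element = list(cons = "GTGGTTAA",  group = "GT-trihelix"),
    Ibox_MYBR   = list(cons = "GGATAAGG",  group = "I-box/MYB-related"),
    Ebox_bHLH   = list(cons = "ACAGCTGT",  group = "E-box/bHLH"),
    TCP_site    = list(cons = "GTGGACCC",  group = "TCP"),
    WRKY_Wbox   = list(cons = "TTTGACCA",  group = "WRKY"),
    AP2_ERF     = list(cons = "AGCCGCCA",  group = "AP2/ERF"),
    CCA1_EE     = list(cons = "AAAATATCT", group = "CCA1-like")
  )
  pwms <- lapply(names(defs), function(id) {
    cons <- defs[[id]]$cons
    codes <- .base_codes(cons)
    counts <- matrix(5, nrow = 4, ncol = nchar(cons))
    counts[cbind(codes + 1L, seq_len(nchar(cons)))] <- 85
    pwm_from_counts(counts, pseudocount = 0, background = background,
                    id = id, group = defs[[id]]$group)
  })
  names(pwms) <- names(defs)
  group_map <- data.frame(motif_id = names(defs),
                          group = vapply(defs, `[[`, character(1), "group"),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(pwms = pwms, group_map = group_map)
}

# Cyclic hexamer whose tiled repetition has the lowest mean two-strand
# cutting rate under `bias` -- used to write sequence-intrinsic decoy dips.
.lowest_bias_seed <- function(bias) {
  k <- 6L
  codes <- 0:4095
  digs <- matrix(0L, 4096, k)
  rem <- codes
  for (j in k:1) { digs[, j] <- rem %% 4L; rem <- rem %/% 4L }
  rot_mean <- numeric(4096)
  for (r in 0:(k - 1)) {
    rot <- cbind(digs[, (r + 1):k, drop = FALSE], digs[, seq_len(r), drop = FALSE])
    code_r <- as.integer(rot %*% 4^((k - 1):0))
    rot_mean <- rot_mean + bias[code_r + 1L] + bias[.rc_codes(code_r) + 1L]
  }
  best <- which.min(rot_mean) - 1L
  paste(.CODE_TO_BASE[digs[best + 1L, ] + 1L], collapse = "")
}

.write_into <- function(seq_chr, pos, what) {
  substr(seq_chr, pos, pos + nchar(what) - 1L) <- what
  seq_chr
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Plant motifs, footprints and decoys into a synthetic genome
#'
#' Writes motif consensus sequences into the genome at three kinds of
#' site, recording every planted instance as ground truth:
#'
#' * Footprint sites: `n_footprints` motif instances inside planted DHSs
#'   (up to four slots per DHS), each protected by a bound factor whose
#'   occupancy over the time course follows the scenario's occupancy
#'   design (constitutive / dark-bound / light-bound).
#' * Decoy dips: `n_decoys` stretches of sequence tiled with the hexamer
#'   of lowest intrinsic cutting rate; they deplete cuts without any
#'   bound protein and exist to challenge the bias-aware footprint
#'   filter.  Decoys are only planted for species A (the DNase species).
#' * LRE census sites: C4-class genes receive planted light-responsive
#'   elements in the window 1.5 kb upstream of the TSS; species A
#'   receives `lre_ratio` times more instances than species B, mirroring
#'   a C4 promoter enriched for LREs relative to its C3 ortholog.
#'
#' @param scenario A [synthetic_scenario()].
#' @param genome Named `DNAStringSet` from
#'   [generate_genome_and_annotation()].
#' @param annotation The matching `GeneAnnotation`.
#' @param truth Truth list from [generate_genome_and_annotation()]
#'   (provides the planted DHSs and gene classes).
#' @param forbid_cds Error if an LRE planting window would overwrite
#'   coding sequence (default `TRUE`; the default layout never does).
#'   Footprint and decoy slots inside DHSs are exempt: transcription
#'   factor sites within coding sequence (duons) are a real feature of
#'   plant genomes and the simulation allows them.
#' @return List with the modified `genome`, `pwms`, `group_map`, and
#'   `truth` extended with `instances` (every planted motif), `footprints`
#'   (`GRanges`), `occupancy` (footprints x time points logical matrix)
#'   and `decoys` (`GRanges`).
#' @export
generate_motif_landscape <- function(scenario, genome, annotation, truth,
                                     forbid_cds = TRUE) {
  species <- truth$species
  lib <- default_motif_library()
  pwms <- lib$pwms
  group_map <- lib$group_map
  consensus <- vapply(pwms, pwm_consensus, character(1))
  seq_chr <- as.character(genome[[1]])
  L <- nchar(seq_chr)
  tp <- scenario$time_points
  genes <- truth$genes
  dhs <- truth$dhs

  set.seed(component_seed(scenario$seed, paste0("motifs_", species)))
  cds <- .features_of_type(annotation, "CDS")
  check_cds <- function(s, e) {
    if (!forbid_cds) return(invisible())
    hit <- IRanges::overlapsAny(GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e)), cds)
    if (any(hit)) stop("motif planting window collides with CDS", call. = FALSE)
  }

  instances <- list()
  fp_rows <- list()
  decoy_rows <- list()

  if (species == "A") {
    n_slots_needed <- scenario$n_footprints + scenario$n_decoys
    slots_per_dhs <- 4L
    n_dhs_used <- ceiling(n_slots_needed / slots_per_dhs)
    dhs_order <- sample.int(length(dhs))
    slot_offsets <- c(70L, 210L, 350L, 490L)
    slot_tab <- do.call(rbind, lapply(dhs_order[seq_len(n_dhs_used)], function(di) {
      data.frame(dhs_idx = di, pos = IRanges::start(dhs)[di] + slot_offsets)
    }))
    slot_tab <- slot_tab[seq_len(n_slots_needed), , drop = FALSE]
    roles <- sample(c(rep("footprint", scenario$n_footprints),
                      rep("decoy", scenario$n_decoys)))

    # occupancy classes for footprints
    of <- scenario$occupancy_fractions
    n_fp <- scenario$n_footprints
    n_occ <- round(of * n_fp)
    n_occ["constitutive"] <- n_fp - sum(n_occ[setdiff(names(n_occ), "constitutive")])
    occ_class <- sample(rep(names(n_occ), times = pmax(n_occ, 0)))

    light_motifs <- c("Gbox_bZIP", "GT1_element", "Ibox_MYBR", "Ebox_bHLH")
    dark_motifs <- c("AP2_ERF", "CCA1_EE")
    neutral_motifs <- c("TCP_site", "WRKY_Wbox")

    decoy_seed <- .lowest_bias_seed(scenario$bias_profile)
    decoy_seq <- paste(rep(decoy_seed, 4), collapse = "")  # 24 bp

    fp_i <- 0L
    for (i in seq_len(nrow(slot_tab))) {
      pos <- slot_tab$pos[i]
      if (roles[i] == "footprint") {
        fp_i <- fp_i + 1L
        cls <- occ_class[fp_i]
        pool <- switch(cls, dark = dark_motifs, light = light_motifs,
                       c(light_motifs, dark_motifs, neutral_motifs))
        mid <- sample(pool, 1L)
        cons <- consensus[[mid]]
        strand <- sample(c("+", "-"), 1L)
        wrt <- if (strand == "+") cons else .revcomp_chr(cons)
        # footprint sites may fall inside gene features (duon-like sites);
        # the CDS guard applies to promoter LRE planting only
        seq_chr <- .write_into(seq_chr, pos, wrt)
        m_end <- pos + nchar(cons) - 1L
        occ <- switch(cls,
                      constitutive = rep(TRUE, length(tp)),
                      dark = tp %in% c(min(tp), max(tp)),
                      light = !(tp %in% c(min(tp), max(tp))))
        instances[[length(instances) + 1L]] <- data.frame(
          species = species, motif_id = mid, chrom = "chr1", start = pos,
          end = m_end, strand = strand, role = "footprint",
          gene_id = dhs$gene_id[slot_tab$dhs_idx[i]], stringsAsFactors = FALSE)
        fp_rows[[fp_i]] <- data.frame(start = pos - 7L, end = m_end + 7L,
                                      motif_id = mid, occ_class = cls,
                                      occ = I(list(occ)))
      } else {
        seq_chr <- .write_into(seq_chr, pos, decoy_seq)
        decoy_rows[[length(decoy_rows) + 1L]] <-
          data.frame(start = pos, end = pos + nchar(decoy_seq) - 1L)
      }
    }
  }

  # LRE census planting for C4-class genes, both species.
  spd <- scenario$species_pair_design
  n_lre_a <- 6L
  n_lre <- if (species == "A") n_lre_a else as.integer(n_lre_a / spd$lre_ratio)
  lre_motifs <- c("Gbox_bZIP", "Ibox_MYBR", "GT1_element", "Ebox_bHLH")
  c4_idx <- which(genes$class == "c4")
  for (gi in c4_idx) {
    g <- genes[gi, ]
    for (k in seq_len(n_lre)) {
      off <- 500L + (k - 1L) * 150L   # upstream offsets 500, 650, ... from TSS
      pos <- if (g$strand == "+") g$tss - off else g$tss + off - 5L
      mid <- lre_motifs[(k - 1L) %% length(lre_motifs) + 1L]
      cons <- consensus[[mid]]
      strand <- if (g$strand == "+") "+" else "-"
      wrt <- if (strand == "+") cons else .revcomp_chr(cons)
      if (pos < 1 || pos + nchar(cons) - 1L > L) next
      check_cds(pos, pos + nchar(cons) - 1L)
      seq_chr <- .write_into(seq_chr, pos, wrt)
      instances[[length(instances) + 1L]] <- data.frame(
        species = species, motif_id = mid, chrom = "chr1", start = pos,
        end = pos + nchar(cons) - 1L, strand = strand, role = "lre",
        gene_id = g$gene_id, stringsAsFactors = FALSE)
    }
  }

  inst_df <- if (length(instances)) do.call(rbind, instances) else
    data.frame(species = character(0), motif_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               role = character(0), gene_id = character(0))

  footprints <- GenomicRanges::GRanges(character(0), IRanges::IRanges())
  occupancy <- matrix(logical(0), nrow = 0, ncol = length(tp),
                      dimnames = list(NULL, as.character(tp)))
  if (length(fp_rows)) {
    fpdf <- do.call(rbind, fp_rows)
    footprints <- GenomicRanges::GRanges("chr1", IRanges::IRanges(fpdf$start, fpdf$end),
                                         motif_id = fpdf$motif_id,
                                         occ_class = fpdf$occ_class,
                                         seqlengths = c(chr1 = L))
    occupancy <- do.call(rbind, fpdf$occ)
    colnames(occupancy) <- as.character(tp)
  }
  decoys <- if (length(decoy_rows)) {
    dd <- do.call(rbind, decoy_rows)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(dd$start, dd$end),
                           seqlengths = c(chr1 = L))
  } else GenomicRanges::GRanges(character(0), IRanges::IRanges())

  truth$instances <- inst_df
  truth$footprints <- footprints
  truth$occupancy <- occupancy
  truth$decoys <- decoys
  list(genome = Biostrings::DNAStringSet(setNames(seq_chr, names(genome)[1])),
       pwms = pwms, group_map = group_map, truth = truth)
}
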