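## Synthetic gene annotations and regulatory peak sets with known overlap
## structure, used as fixtures for the enrichment analyses.

#' Generate a synthetic gene/TSS annotation
#'
#' Places `n_genes` transcription start sites at strictly increasing
#' positions on one chromosome with random strands.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return BED6-style data.frame: `chrom`, `start` (TSS), `end` (TSS + 1),
#'   `name` (gene id), `score`, `strand`.
#' @export
generate_gene_annotation <- function(n_genes, chrom_length, seed,
                                     chrom = "chrSim") {
  n_genes <- check_count(n_genes, "n_genes")
  chrom_length <- check_count(chrom_length, "chrom_length")
  if (chrom_length < 10L * n_genes)
    abort_param("chromosome too short to place genes without collision")
  set.seed(check_count(seed, "seed", 0L))
  tss <- sort(sample.int(chrom_length, n_genes))
  data.frame(chrom = chrom, start = tss, end = tss + 1L,
             name = sprintf("gene%04d", seq_len(n_genes)),
             score = 0L,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic peak set with controlled CNE overlap
#'
#' Creates `floor(overlap_fraction * nrow(cnes))` peaks, each intersecting
#' a distinct randomly chosen CNE by at least 1 bp, plus `n_decoys` decoy
#' peaks that intersect no CNE.
#'
#' @param cnes BED data.frame of CNE intervals.
#' @param overlap_fraction proportion of CNEs to cover.
#' @param n_decoys number of CNE-free decoy peaks.
#' @param seed integer seed.
#' @param peak_width peak width in bp (default 300).
#' @param chrom_length chromosome length; default just beyond the last CNE.
#' @return sorted BED data.frame of peaks.
#' @export
generate_peaks <- function(cnes, overlap_fraction, n_decoys, seed,
                           peak_width = 300,
                           chrom_length = max(cnes$end) + 100000) {
  overlap_fraction <- check_fraction(overlap_fraction, "overlap_fraction")
  n_decoys <- check_count(n_decoys, "n_decoys", 0L)
  set.seed(check_count(seed, "seed", 0L))
  n_cov <- floor(overlap_fraction * nrow(cnes))
  chosen <- if (n_cov > 0) sort(sample.int(nrow(cnes), n_cov)) else integer(0)

  peaks <- lapply(chosen, function(i) {
    ## anchor so the peak intersects the CNE by >= 1 bp
    lo <- max(0, cnes$start[i] - peak_width + 1)
    hi <- cnes$end[i] - 1
    s <- floor(stats::runif(1, lo, hi + 1))
    data.frame(chrom = cnes$chrom[i], start = s, end = s + peak_width,
               stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, c(peaks,
                            list(data.frame(chrom = character(0),
                                            start = numeric(0),
                                            end = numeric(0)))))

  if (n_decoys > 0) {
    ## free space: complement of CNEs, on the CNE chromosome
    ch <- if (nrow(cnes)) cnes$chrom[1] else "chrSim"
    occupied <- cnes[cnes$chrom == ch, , drop = FALSE]
    decoys <- list(); tries <- 0L
    while (length(decoys) < n_decoys) {
      tries <- tries + 1L
      if (tries > 200L * n_decoys)
        abort_param("not enough CNE-free space to place decoy peaks")
      s <- floor(stats::runif(1, 0, chrom_length - peak_width))
      if (!any(occupied$start < s + peak_width & occupied$end > s))
        decoys[[length(decoys) + 1L]] <-
          data.frame(chrom = ch, start = s, end = s + peak_width,
                     stringsAsFactors = FALSE)
    }
    peaks <- rbind(peaks, do.call(rbind, decoys))
  }
  peaks <- sort_bed(peaks)
  if (nrow(peaks)) peaks$name <- sprintf("peak%d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks
}
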