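## Interval arithmetic turning conserved-element calls into CNEs.
## BED data frames (0-based half-open) in and out; IRanges does the set
## operations internally (1-based closed).

bed_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

iranges_to_bed <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}

validate_bed_df <- function(df, what) {
  bad <- which(!(df$start >= 0 & df$end > df$start))
  if (length(bad))
    abort_param(sprintf("malformed %s interval at row %d", what, bad[1]))
  invisible(df)
}

#' Derive CNEs by subtracting flank-expanded coding intervals
#'
#' Expands every coding interval by `flank` bp on both sides (to exclude
#' conserved splice sites), subtracts the expanded set from the conserved
#' elements, and keeps remainders of at least `min_length` bp.
#'
#' @param conserved BED data.frame of conserved elements.
#' @param coding BED data.frame of coding intervals.
#' @param flank bp added to both sides of each coding interval (default 50).
#' @param min_length minimum CNE length in bp (default 30).
#' @return sorted, non-overlapping BED data.frame of CNEs with `name`
#'   column `cne1..n`.
#' @export
derive_cnes <- function(conserved, coding, flank = 50, min_length = 30) {
  validate_bed_df(conserved, "conserved")
  if (nrow(coding)) validate_bed_df(coding, "coding")
  if (flank < 0 || min_length < 0)
    abort_param("`flank` and `min_length` must be >= 0")
  out <- lapply(sort(unique(conserved$chrom)), function(ch) {
    cons <- bed_to_iranges(conserved[conserved$chrom == ch, ])
    cod <- coding[coding$chrom == ch, , drop = FALSE]
    if (nrow(cod)) {
      cod$start <- pmax(0, cod$start - flank)
      cod$end <- cod$end + flank
      keep <- IRanges::setdiff(cons, bed_to_iranges(cod))
    } else {
      keep <- IRanges::reduce(cons)
    }
    keep <- keep[IRanges::width(keep) >= min_length]
    iranges_to_bed(keep, ch)
  })
  out <- do.call(rbind, out)
  out <- sort_bed(out)
  if (nrow(out)) out$name <- sprintf("cne%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Merge CNEs separated by small gaps
#'
#' Chains of intervals on the same chromosome whose inter-interval gap is
#' strictly smaller than `max_gap` bp are merged into one interval, so that
#' clusters of nearby CNEs are not counted as independent observations in
#' enrichment tests.
#'
#' @param cnes BED data.frame.
#' @param max_gap merge gap threshold in bp (default 50; gap < 50 merges).
#' @return sorted BED data.frame of merged intervals, named `mcne1..n`.
#' @export
merge_close <- function(cnes, max_gap = 50) {
  validate_bed_df(cnes, "cne")
  out <- lapply(sort(unique(cnes$chrom)), function(ch) {
    ir <- bed_to_iranges(cnes[cnes$chrom == ch, ])
    merged <- IRanges::reduce(ir, min.gapwidth = max_gap)
    iranges_to_bed(merged, ch)
  })
  out <- sort_bed(do.call(rbind, out))
  if (nrow(out)) out$name <- sprintf("mcne%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

## ids (name column) of intervals in `a` overlapping any interval in `b`
overlapping_names <- function(a, b) {
  hits <- lapply(unique(a$chrom), function(ch) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(ai) || !nrow(bi)) return(character(0))
    ov <- IRanges::findOverlaps(bed_to_iranges(ai), bed_to_iranges(bi))
    ai$name[unique(S4Vectors::queryHits(ov))]
  })
  unlist(hits)
}
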