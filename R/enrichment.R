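## Enrichment of diverged CNEs in gene sets and regulatory peak sets:
## one-sided Fisher's exact test plus a subsampling Z-score.

resolve_predicate <- function(in_set) {
  if (is.function(in_set)) return(in_set)
  if (is.character(in_set)) return(function(ids) ids %in% in_set)
  abort_param("`in_set` must be a function or a character vector of ids")
}

#' One-sided Fisher enrichment of a foreground CNE set
#'
#' Builds the 2x2 table (foreground in-set, foreground out, background
#' in-set, background out) and computes the one-sided (greater)
#' hypergeometric tail p-value and odds ratio `ad/bc`. Foreground and
#' background must be disjoint; the background is the non-diverged
#' remainder of the CNE universe.
#'
#' @param foreground character vector of diverged CNE ids.
#' @param background character vector of remaining CNE ids.
#' @param in_set predicate: a character vector of in-set CNE ids, or a
#'   function mapping an id vector to logical.
#' @param set_name label for the tested set.
#' @return one-row data.frame: `set_name`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value` (`adjusted_p` is added across a batch by
#'   [adjust_enrichment()]).
#' @export
fisher_enrichment <- function(foreground, background, in_set, set_name) {
  if (length(foreground) == 0L || length(background) == 0L)
    abort_param("foreground and background must be non-empty")
  if (length(intersect(foreground, background)))
    abort_param("foreground and background must be disjoint")
  pred <- resolve_predicate(in_set)
  a <- sum(pred(foreground)); b <- length(foreground) - a
  c <- sum(pred(background)); d <- length(background) - c
  p <- if (a + c == 0L) 1
       else stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  odds <- if (b * c == 0L) NA_real_ else (a * d) / (b * c)
  data.frame(set_name = set_name, a = a, b = b, c = c, d = d,
             odds_ratio = odds, p_value = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjust a batch of enrichment results
#'
#' @param results data.frame of rows from [fisher_enrichment()] or
#'   [overlap_enrichment()].
#' @return the same data.frame with `adjusted_p`, sorted by adjusted p.
#' @export
adjust_enrichment <- function(results) {
  results$adjusted_p <- bh_adjust(results$p_value)
  results[order(results$adjusted_p, results$p_value), , drop = FALSE]
}

#' Subsampling Z-score for an observed overlap count
#'
#' Draws `n_subsamples` same-sized subsets of the CNE universe without
#' replacement, counts in-set members of each, and returns
#' `(observed - mean) / sd` of the subsample counts (sample sd).
#'
#' @param observed observed in-set count of the foreground.
#' @param universe character vector of all CNE ids (foreground included).
#' @param sample_size foreground size.
#' @param in_set predicate as in [fisher_enrichment()].
#' @param n_subsamples number of draws (default 10000, minimum 100).
#' @param seed integer seed.
#' @return the Z-score, with subsample mean and sd as attributes
#'   `"mean"` and `"sd"`.
#' @export
subsample_z <- function(observed, universe, sample_size, in_set,
                        n_subsamples = 10000, seed = 1) {
  n_subsamples <- check_count(n_subsamples, "n_subsamples", 100L)
  sample_size <- check_count(sample_size, "sample_size")
  if (sample_size > length(universe))
    abort_param("`sample_size` exceeds the universe size")
  pred <- resolve_predicate(in_set)
  flags <- pred(universe)
  set.seed(check_count(seed, "seed", 0L))
  counts <- vapply(seq_len(n_subsamples), function(i)
    sum(flags[sample.int(length(universe), sample_size)]), numeric(1))
  s <- stats::sd(counts)
  if (s == 0)
    abort_param("degenerate subsampling: predicate constant over universe")
  structure((observed - mean(counts)) / s, mean = mean(counts), sd = s)
}

#' Peak-overlap enrichment of diverged CNEs
#'
#' Tests whether foreground CNEs overlap a peak set (by >= `min_overlap`
#' bp) more often than background CNEs: one-sided Fisher's exact test plus
#' the subsampling Z-score over the combined universe.
#'
#' @param foreground,background disjoint BED data.frames with `name`
#'   columns.
#' @param peaks BED data.frame of peaks.
#' @param set_name label.
#' @param n_subsamples,seed passed to [subsample_z()].
#' @param min_overlap minimum overlap in bp (default 1).
#' @return one-row data.frame as [fisher_enrichment()] plus `subsample_z`
#'   and `n_subsamples`.
#' @export
overlap_enrichment <- function(foreground, background, peaks, set_name,
                               n_subsamples = 10000, seed = 1,
                               min_overlap = 1) {
  if (min_overlap != 1) {
    peaks_pred <- function(ids) {
      all_bed <- rbind(foreground, background)
      hits <- overlapping_names_minov(all_bed, peaks, min_overlap)
      ids %in% hits
    }
  } else {
    hit_ids <- overlapping_names(rbind(foreground, background), peaks)
    peaks_pred <- function(ids) ids %in% hit_ids
  }
  res <- fisher_enrichment(foreground$name, background$name, peaks_pred,
                           set_name)
  z <- tryCatch(
    subsample_z(res$a, c(foreground$name, background$name),
                nrow(foreground), peaks_pred,
                n_subsamples = n_subsamples, seed = seed),
    error = function(e) NA_real_)
  res$subsample_z <- as.numeric(z)
  res$n_subsamples <- n_subsamples
  res
}

## overlap with a minimum width requirement
overlapping_names_minov <- function(a, b, min_overlap) {
  hits <- lapply(unique(a$chrom), function(ch) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(ai) || !nrow(bi)) return(character(0))
    ov <- IRanges::findOverlaps(bed_to_iranges(ai), bed_to_iranges(bi),
                                minoverlap = min_overlap)
    ai$name[unique(S4Vectors::queryHits(ov))]
  })
  unlist(hits)
}

#' Gene-set enrichment of diverged CNEs via regulatory domains
#'
#' For each gene set, tests with a one-sided Fisher's exact test whether
#' foreground CNEs are associated (via [associate_cnes()]) with at least
#' one gene of the set more often than background CNEs, and reports the
#' subsampling Z-score. Results are BH-adjusted across sets.
#'
#' @param foreground,background disjoint BED data.frames of (merged) CNEs.
#' @param cne_gene_map named list from [associate_cnes()] over the
#'   combined universe.
#' @param gene_sets named list: set name -> character vector of gene ids.
#' @param n_subsamples,seed passed to [subsample_z()].
#' @return data.frame, one row per gene set, sorted by adjusted p.
#' @export
gene_set_enrichment <- function(foreground, background, cne_gene_map,
                                gene_sets, n_subsamples = 10000, seed = 1) {
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- gene_sets[[nm]]
    hit_ids <- names(cne_gene_map)[vapply(cne_gene_map, function(g)
      any(g %in% genes), logical(1))]
    res <- fisher_enrichment(foreground$name, background$name, hit_ids, nm)
    z <- tryCatch(
      subsample_z(res$a, c(foreground$name, background$name),
                  nrow(foreground), hit_ids,
                  n_subsamples = n_subsamples, seed = seed),
      error = function(e) NA_real_)
    res$subsample_z <- as.numeric(z)
    res$n_subsamples <- n_subsamples
    res
  })
  adjust_enrichment(do.call(rbind, rows))
}
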