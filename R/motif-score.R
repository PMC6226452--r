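## Occupancy-style motif scoring with GC-matched score cutoffs.
##
## The score of a sequence for a motif sums, over every possible site
## position on both strands, a soft-thresholded log-odds contribution
## softplus2(llr) = log2(1 + 2^llr). Weak and strong sites both
## contribute, no assumption is made about site position, and the score is
## robust to site turnover within the element. Scoring is windowed (200 bp,
## step 100 bp) and the sequence score is the maximum window sum.

softplus2 <- function(x) {
  ## log2(1 + 2^x), overflow-safe
  out <- ifelse(x > 0, x + log2(1 + 2^(-x)), log2(1 + 2^x))
  out[x == -Inf] <- 0
  out
}

## per-position site log-likelihood ratios on one strand; NA-containing
## sites get -Inf (they contribute 0 after softplus)
site_llrs <- function(code, lo) {
  L <- ncol(lo)
  n <- length(code)
  if (n < L) return(numeric(0))
  s <- numeric(n - L + 1)
  bad <- logical(n - L + 1)
  for (j in seq_len(L)) {
    v <- lo[cbind(code[j:(j + n - L)], j)]
    nas <- is.na(v)
    bad <- bad | nas
    v[nas] <- 0
    s <- s + v
  }
  s[bad] <- -Inf
  s
}

#' Occupancy score of a sequence for a PWM
#'
#' Computes, for each 200-bp window (step 100 bp; one window if the
#' sequence is shorter), the sum over all site positions and both strands
#' of `log2(1 + 2^llr)`, where `llr` is the site log-odds of the PWM
#' (pseudocount-added probabilities over a GC-matched background), and
#' returns the maximum window sum. Window anchors are taken symmetrically
#' from both sequence ends, which makes the score exactly invariant to
#' reverse complementation. Site positions containing N contribute 0.
#'
#' @param seq DNA string (ACGTN; gaps are ignored after removal by the
#'   caller).
#' @param pwm a `pwm` object.
#' @param gc_background background GC fraction in (0, 1).
#' @param pseudocount probability mass added to each PWM cell (default
#'   0.01).
#' @param window,step window length and step in bp (defaults 200 / 100).
#' @return non-negative score; 0 (with a warning) when the sequence is
#'   shorter than the motif.
#' @export
score_sequence <- function(seq, pwm, gc_background = 0.5,
                           pseudocount = 0.01, window = 200, step = 100) {
  gc_background <- check_fraction(gc_background, "gc_background", 1e-6,
                                  1 - 1e-6)
  code <- encode_dna(seq)
  code[!is.na(code) & code == 5L] <- NA_integer_   # gaps behave like N
  L <- ncol(pwm$mat)
  n <- length(code)
  if (n < L) {
    warning("sequence shorter than motif; score 0", call. = FALSE)
    return(0)
  }
  bg <- c((1 - gc_background) / 2, gc_background / 2,
          gc_background / 2, (1 - gc_background) / 2)
  lo <- log2((pwm$mat + pseudocount) / bg)
  lo_rc <- lo[4:1, L:1, drop = FALSE]   # reverse strand on forward coding

  v <- softplus2(site_llrs(code, lo)) + softplus2(site_llrs(code, lo_rc))
  n_sites <- length(v)

  if (n <= window) return(sum(v))
  ## window start positions from the left, plus their mirror images
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  starts <- sort(unique(c(starts, (n - window + 2L) - starts)))
  starts <- starts[starts >= 1L & starts <= n - window + 1L]
  cs <- cumsum(c(0, v))
  wsum <- vapply(starts, function(s) {
    last <- min(s + window - L, n_sites)
    cs[last + 1] - cs[s]
  }, numeric(1))
  max(wsum)
}

## draw one site from the PWM column probabilities (consumes RNG stream)
sample_site <- function(pwm) {
  paste(apply(pwm$mat, 2, function(col) sample(BASES, 1, prob = col)),
        collapse = "")
}

## insert `site` at a uniform random position of `seq`, replacing bases
insert_site <- function(seq, site) {
  n <- nchar(seq); L <- nchar(site)
  pos <- sample.int(n - L + 1L, 1)
  paste0(substr(seq, 1, pos - 1), site, substr(seq, pos + L, n))
}

#' GC-binned motif score cutoffs
#'
#' For each GC bin g in 0, 0.05, ..., 1 (clamped to `[0.01, 0.99]` for
#' sequence generation and background), generates `n_seqs` random
#' sequences of `seq_len` bp at GC composition g, inserts one binding site
#' sampled column-wise from the PWM into each at a uniform position,
#' scores them with a GC-matched background, and records the empirical
#' upper `1 - quantile` cutoff: the smallest score such that a fraction
#' `1 - quantile` of the calibration batch scores at least as high (the
#' `n - ceiling((1-q) n) + 1`-th order statistic; for the defaults, 10 of
#' 100 with-site sequences score at or above the cutoff).
#'
#' @param pwm a `pwm` object.
#' @param n_bins number of GC bins spanning 0..1 (default 21).
#' @param n_seqs calibration sequences per bin (default 100).
#' @param seq_len sequence length in bp (default 200).
#' @param quantile cutoff quantile (default 0.9).
#' @param seed integer seed.
#' @param pseudocount passed to [score_sequence()].
#' @return data.frame: `motif_id`, `gc_bin`, `cutoff` (one row per bin).
#' @export
gc_cutoffs <- function(pwm, n_bins = 21, n_seqs = 100, seq_len = 200,
                       quantile = 0.9, seed = 1, pseudocount = 0.01) {
  n_bins <- check_count(n_bins, "n_bins", 2L)
  n_seqs <- check_count(n_seqs, "n_seqs", 10L)
  quantile <- check_fraction(quantile, "quantile", 0.5, 0.999)
  set.seed(check_count(seed, "seed", 0L))
  bins <- seq(0, 1, length.out = n_bins)
  k <- n_seqs - ceiling((1 - quantile) * n_seqs) + 1L
  cutoffs <- vapply(bins, function(g) {
    gg <- min(max(g, 0.01), 0.99)
    scores <- vapply(seq_len(n_seqs), function(i) {
      s <- insert_site(random_dna(seq_len, gg), sample_site(pwm))
      score_sequence(s, pwm, gc_background = gg, pseudocount = pseudocount)
    }, numeric(1))
    sort(scores)[k]
  }, numeric(1))
  data.frame(motif_id = pwm$id, gc_bin = bins, cutoff = cutoffs,
             stringsAsFactors = FALSE)
}

#' Calibration rate of a GC-binned cutoff
#'
#' Generates `n` fresh GC-matched random sequences with one inserted
#' sampled site each and returns the fraction scoring at or above
#' `cutoff`. Used to verify that the cutoff retains the intended tail
#' fraction (10% for the default 90% quantile).
#'
#' @param pwm a `pwm` object.
#' @param gc GC bin (clamped as in [gc_cutoffs()]).
#' @param cutoff score cutoff for this bin.
#' @param n number of fresh sequences.
#' @param seed integer seed.
#' @param seq_len,pseudocount as in [gc_cutoffs()].
#' @return fraction in `[0, 1]`.
#' @export
cutoff_calibration_rate <- function(pwm, gc, cutoff, n = 1000, seed = 1,
                                    seq_len = 200, pseudocount = 0.01) {
  n <- check_count(n, "n", 10L)
  set.seed(check_count(seed, "seed", 0L))
  gg <- min(max(gc, 0.01), 0.99)
  hits <- vapply(seq_len(n), function(i) {
    s <- insert_site(random_dna(seq_len, gg), sample_site(pwm))
    score_sequence(s, pwm, gc_background = gg,
                   pseudocount = pseudocount) >= cutoff
  }, logical(1))
  mean(hits)
}

#' Select CNE-motif pairs with ancestral motif presence
#'
#' Keeps the pairs whose reconstructed ancestral sequence scores strictly
#' above the cutoff of the CNE's nearest GC bin (ties between bins go to
#' the lower bin).
#'
#' @param scores data.frame with columns `cne_id`, `motif_id`,
#'   `ancestral_score`.
#' @param cutoffs data.frame from [gc_cutoffs()] (possibly row-bound over
#'   motifs).
#' @param cne_gc named numeric vector: CNE id -> GC fraction.
#' @return the retained rows of `scores`.
#' @export
select_ancestral_pairs <- function(scores, cutoffs, cne_gc) {
  if (any(!scores$cne_id %in% names(cne_gc)))
    abort_param("missing GC value for some CNEs")
  keep <- vapply(seq_len(nrow(scores)), function(i) {
    ct <- cutoffs[cutoffs$motif_id == scores$motif_id[i], ]
    if (!nrow(ct)) abort_param("no cutoffs for motif ", scores$motif_id[i])
    g <- cne_gc[[scores$cne_id[i]]]
    bin <- which.min(abs(ct$gc_bin - g))   # first (lower) bin wins ties
    scores$ancestral_score[i] > ct$cutoff[bin]
  }, logical(1))
  scores[keep, , drop = FALSE]
}

#' Score CNE sequences of every species for a motif library
#'
#' @param alignments list of `cne_alignment` objects (gaps are stripped per
#'   species before scoring); the ancestral sequence is scored when
#'   present.
#' @param pwms list of `pwm` objects.
#' @param pseudocount passed to [score_sequence()].
#' @return data.frame: `cne_id`, `motif_id`, `gc` (of the ungapped
#'   ancestral or first species sequence), `ancestral_score`, one
#'   `score_<species>` column per species.
#' @export
score_cne_motifs <- function(alignments, pwms, pseudocount = 0.01) {
  rows <- lapply(alignments, function(a) {
    seqs <- vapply(a$seqs, function(s) gsub("-", "", s, fixed = TRUE),
                   character(1))
    anc <- if (!is.null(a$ancestral))
      gsub("-", "", a$ancestral, fixed = TRUE) else NULL
    g <- gc_content(anc %||% seqs[[1]])
    gg <- min(max(g, 0.01), 0.99)
    do.call(rbind, lapply(pwms, function(p) {
      row <- data.frame(cne_id = a$cne_id, motif_id = p$id, gc = g,
                        ancestral_score = if (is.null(anc)) NA_real_
                        else score_sequence(anc, p, gg, pseudocount),
                        stringsAsFactors = FALSE)
      for (sp in names(seqs))
        row[[paste0("score_", sp)]] <-
          score_sequence(seqs[[sp]], p, gg, pseudocount)
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Excess motif score of diverged versus background CNEs per species
#'
#' For each species, compares the motif scores of foreground (diverged)
#' CNE-motif pairs against background pairs: the excess score is the
#' difference of medians, and a one-sided Wilcoxon rank-sum test (normal
#' approximation with continuity and tie correction) gives the p-value in
#' the configured direction. P-values are BH-adjusted across species.
#'
#' @param foreground_scores named list: species -> numeric scores of
#'   foreground pairs.
#' @param background_scores named list: species -> numeric scores of
#'   background pairs (same species).
#' @param direction `"greater"` (foreground scores higher; default) or
#'   `"less"`.
#' @return data.frame: `species`, `median_foreground`,
#'   `median_background`, `excess`, `p_value`, `adjusted_p`.
#' @export
excess_score <- function(foreground_scores, background_scores,
                         direction = c("greater", "less")) {
  direction <- match.arg(direction)
  spp <- names(foreground_scores)
  if (is.null(spp) || !setequal(spp, names(background_scores)))
    abort_param("foreground and background must cover the same species")
  rows <- lapply(spp, function(sp) {
    fg <- foreground_scores[[sp]]; bg <- background_scores[[sp]]
    if (length(fg) == 0L || length(bg) == 0L)
      abort_param("empty score list for species ", sp)
    p <- stats::wilcox.test(fg, bg, alternative = direction,
                            exact = FALSE, correct = TRUE)$p.value
    data.frame(species = sp,
               median_foreground = stats::median(fg),
               median_background = stats::median(bg),
               excess = stats::median(fg) - stats::median(bg),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
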