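uniform_pwm <- function(L = 8) pwm("unif", matrix(0.25, 4, L))

consensus_pwm <- function(site = "ACGTACGT") {
  m <- vapply(strsplit(site, "")[[1]], function(b) {
    col <- rep(0.01, 4)
    col[match(b, c("A", "C", "G", "T"))] <- 0.97
    col / sum(col)
  }, numeric(4))
  pwm("cons", unname(m))
}

test_that("column information content is 2 + sum(p log2 p)", {
  expect_equal(column_ic(rep(0.25, 4)), 0)
  expect_equal(column_ic(c(1, 0, 0, 0)), 2)
  expect_equal(column_ic(c(0.5, 0.5, 0, 0)), 1)
  expect_error(column_ic(c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
})

test_that("occupancy score grows with planted consensus sites", {
  p <- consensus_pwm()
  set.seed(2)
  base <- random_dna_for_test(200, 0.5)
  scores <- vapply(0:3, function(k) {
    s <- base
    for (j in seq_len(k))
      substr(s, 30 * j, 30 * j + 7) <- "ACGTACGT"
    score_sequence(s, p, 0.5)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_gt(scores[4], scores[1])

  ## appending a consensus site strictly increases a short sequence's score
  s0 <- substr(base, 1, 120)
  expect_gt(score_sequence(paste0(s0, "ACGTACGT"), p, 0.5),
            score_sequence(s0, p, 0.5))
})

test_that("scoring is a pure function and reverse-complement invariant", {
  lib <- generate_motif_library(4, seed = 6)
  set.seed(9)
  for (i in 1:6) {
    n <- sample(c(40, 150, 200, 257, 431), 1)
    s <- random_dna_for_test(n, runif(1, 0.25, 0.75))
    p <- lib[[sample(length(lib), 1)]]
    gc <- runif(1, 0.2, 0.8)
    expect_identical(score_sequence(s, p, gc), score_sequence(s, p, gc))
    expect_equal(score_sequence(revcomp(s), p, gc),
                 score_sequence(s, p, gc), tolerance = 1e-9)
  }
  expect_warning(score_sequence("ACG", lib[[1]], 0.5), "shorter")
})

test_that("N positions contribute nothing to the score", {
  p <- consensus_pwm()
  set.seed(3)
  s <- random_dna_for_test(100, 0.5)
  sN <- paste0(substr(s, 1, 40), "N", substr(s, 42, 100))
  expect_lte(score_sequence(sN, p, 0.5), score_sequence(s, p, 0.5) + 1e-9)
  expect_gt(score_sequence(sN, p, 0.5), 0)
})

test_that("GC cutoffs: degenerate PWM gives constant cutoff; seeded", {
  up <- uniform_pwm()
  ct <- gc_cutoffs(up, n_bins = 3, n_seqs = 20, seed = 4)
  ## uniform columns at gc = 0.5: every site has the same log-odds, so all
  ## sequences of equal length score identically
  mid <- ct$cutoff[ct$gc_bin == 0.5]
  s <- random_dna_for_test(200, 0.5)
  expect_equal(score_sequence(s, up, 0.5), mid, tolerance = 1e-9)

  lib <- generate_motif_library(2, seed = 5)
  c1 <- gc_cutoffs(lib[[1]], seed = 11)
  c2 <- gc_cutoffs(lib[[1]], seed = 11)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 21)
  expect_true(all(is.finite(c1$cutoff)))
})

test_that("fresh with-site sequences exceed the cutoff at the target rate", {
  lib <- generate_motif_library(1, seed = 23)
  ct <- gc_cutoffs(lib[[1]], seed = 14)
  r <- cutoff_calibration_rate(lib[[1]], 0.5,
                               ct$cutoff[ct$gc_bin == 0.5],
                               n = 500, seed = 15)
  ## combined order-statistic (cutoff from n = 100) and binomial noise
  expect_lt(abs(r - 0.10), 0.075)
})

test_that("ancestral-presence filter is strict and uses the nearest bin", {
  ct <- data.frame(motif_id = "m1", gc_bin = seq(0, 1, by = 0.05),
                   cutoff = seq(0, 1, by = 0.05) * 100)
  sc <- data.frame(cne_id = c("c1", "c2", "c3"), motif_id = "m1",
                   ancestral_score = c(50, 50 + 1e-9, 50))
  gcs <- c(c1 = 0.52, c2 = 0.52, c3 = 0.52)  # nearest bin 0.50, cutoff 50
  kept <- select_ancestral_pairs(sc, ct, gcs)
  expect_identical(kept$cne_id, "c2")   # exactly-at-cutoff excluded
  ## tie between bins resolves to the lower bin
  gcs2 <- c(c1 = 0.525, c2 = 0.525, c3 = 0.525)
  kept2 <- select_ancestral_pairs(sc, ct, gcs2)
  expect_identical(kept2$cne_id, "c2")
  expect_error(select_ancestral_pairs(sc, ct, c(c1 = 0.5)), "missing GC")
})

test_that("excess scores and Wilcoxon directionality behave correctly", {
  set.seed(21)
  bg <- rnorm(100, 10, 1)
  same <- excess_score(list(sp1 = bg), list(sp1 = bg))
  expect_equal(same$excess, 0)
  expect_gt(same$p_value, 0.4)

  shifted <- excess_score(list(sp1 = bg + 1), list(sp1 = bg))
  expect_equal(shifted$excess, 1)
  expect_lt(shifted$p_value, 1e-4)
  less <- excess_score(list(sp1 = bg + 1), list(sp1 = bg),
                       direction = "less")
  expect_gt(less$p_value, 0.999)
  expect_error(excess_score(list(sp1 = numeric(0)), list(sp1 = bg)),
               "empty")
})

test_that("Wilcoxon p agrees with a permutation oracle within 2-fold", {
  set.seed(31)
  x <- rnorm(30, 0.5, 1); y <- rnorm(30, 0, 1)
  res <- excess_score(list(s = x), list(s = y))
  ## permutation oracle on the rank-sum statistic
  pooled <- c(x, y)
  obs <- sum(rank(pooled)[1:30])
  perm <- replicate(10000, {
    idx <- sample(60, 30)
    sum(rank(pooled)[idx])
  })
  p_perm <- (sum(perm >= obs) + 1) / (10000 + 1)
  expect_lt(res$p_value, 2 * p_perm)
  expect_gt(res$p_value, p_perm / 2)
})

test_that("IC-binned randomization preserves lengths and IC bins", {
  lib <- generate_motif_library(10, seed = 41)
  rnd <- randomize_motifs(lib, n_ic_bins = 5, seed = 42)
  expect_identical(vapply(rnd, function(p) ncol(p$mat), integer(1)),
                   vapply(lib, function(p) ncol(p$mat), integer(1)))
  ## bin ranges from the pooled library
  pool <- do.call(cbind, lapply(lib, function(p) p$mat))
  ic <- apply(pool, 2, column_ic)
  rnk <- rank(ic, ties.method = "first")
  bin <- ceiling(rnk / (length(ic) / 5))
  rng <- vapply(split(ic, bin), range, numeric(2))
  col_idx <- 0
  for (m in seq_along(lib)) {
    for (j in seq_len(ncol(lib[[m]]$mat))) {
      col_idx <- col_idx + 1
      ic_new <- column_ic(rnd[[m]]$mat[, j])
      b <- bin[col_idx]
      expect_gte(ic_new, rng[1, b] - 1e-9)
      expect_lte(ic_new, rng[2, b] + 1e-9)
    }
  }
  ## singleton bins: randomization is the identity on column content
  n_cols <- length(ic)
  same <- randomize_motifs(lib, n_ic_bins = n_cols, seed = 1)
  for (m in seq_along(lib))
    expect_equal(same[[m]]$mat, lib[[m]]$mat)
  expect_error(randomize_motifs(lib, n_ic_bins = 10000, seed = 1),
               "fewer columns")
})
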