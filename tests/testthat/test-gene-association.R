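test_that("regulatory domains follow the basal-plus-extension rules", {
  g1 <- data.frame(chrom = "chr1", start = 1000000, end = 1000001,
                   name = "g1", score = 0, strand = "+")
  d <- build_regulatory_domains(g1, chrom_sizes = c(chr1 = 1e7))
  expect_equal(c(d$basal_start, d$basal_end), c(995000, 1001000))
  expect_equal(c(d$domain_start, d$domain_end), c(695000, 1301000))

  ## basal clipped at the chromosome start
  g2 <- data.frame(chrom = "chr1", start = 2000, end = 2001,
                   name = "g2", score = 0, strand = "+")
  d2 <- build_regulatory_domains(g2, chrom_sizes = c(chr1 = 1e7))
  expect_equal(c(d2$basal_start, d2$basal_end), c(0, 3000))
  expect_equal(d2$domain_start, 0)

  ## minus strand mirrors the basal window
  g3 <- data.frame(chrom = "chr1", start = 1000000, end = 1000001,
                   name = "g3", score = 0, strand = "-")
  d3 <- build_regulatory_domains(g3, chrom_sizes = c(chr1 = 1e7))
  expect_equal(c(d3$basal_start, d3$basal_end), c(999000, 1005000))

  ## extension stops at the neighbor's basal domain
  gg <- data.frame(chrom = "chr1", start = c(1000000, 1010000),
                   end = c(1000001, 1010001), name = c("a", "b"),
                   score = 0, strand = "+")
  dd <- build_regulatory_domains(gg, chrom_sizes = c(chr1 = 1e7))
  expect_equal(dd$domain_end[dd$gene_id == "a"],
               dd$basal_start[dd$gene_id == "b"])
  expect_equal(dd$domain_start[dd$gene_id == "b"],
               dd$basal_end[dd$gene_id == "a"])
  ## no extension invades a foreign basal domain
  expect_lte(dd$domain_end[1], dd$basal_start[2])
  expect_error(build_regulatory_domains(rbind(g1, g1)), "duplicate")
})

test_that("CNE-gene association is overlap-driven", {
  genes <- data.frame(chrom = "chr1", start = c(1000000, 1100000),
                      end = c(1000001, 1100001), name = c("gA", "gB"),
                      score = 0, strand = "+")
  dom <- build_regulatory_domains(genes, chrom_sizes = c(chr1 = 1e7))
  cnes <- data.frame(chrom = "chr1",
                     start = c(996000, 1050000, 1500000),
                     end = c(996100, 1050100, 1500100),
                     name = c("inBasal", "between", "farAway"))
  assoc <- associate_cnes(cnes, dom)
  expect_true("gA" %in% assoc$inBasal)
  expect_setequal(assoc$between, c("gA", "gB"))  # overlapping extensions
  expect_length(assoc$farAway, 0)                # > 300 kb from any TSS
})

test_that("Fisher enrichment reproduces the promoter worked example", {
  fg <- paste0("f", 1:52)
  bg <- paste0("b", 1:18033)
  in_set <- c(paste0("f", 1:12), paste0("b", 1:357))
  res <- fisher_enrichment(fg, bg, in_set, "eye promoters")
  expect_equal(unlist(res[, c("a", "b", "c", "d")]),
               c(a = 12, b = 40, c = 357, d = 17676))
  expect_equal(signif(res$p_value, 2), 4.3e-10)

  res0 <- fisher_enrichment(fg, bg, character(0), "empty")
  expect_equal(res0$p_value, 1)
  expect_true(is.na(res0$odds_ratio))

  res2 <- fisher_enrichment(paste0("f", 1:3), paste0("b", 1:3),
                            c("f1", "f2", "b1"), "tiny")
  expect_equal(res2$p_value, 0.5)

  expect_error(fisher_enrichment(fg, fg, in_set, "x"), "disjoint")
  expect_error(fisher_enrichment(character(0), bg, in_set, "x"),
               "non-empty")
})

test_that("Fisher p matches enumeration on all tables with margins <= 12", {
  for (n1 in 1:12) for (n2 in 1:12) {
    for (a in 0:n1) for (cc in 0:n2) {
      fg <- paste0("f", seq_len(n1))
      bg <- paste0("b", seq_len(n2))
      in_set <- c(fg[seq_len(a)], bg[seq_len(cc)])
      got <- fisher_enrichment(fg, bg, in_set, "t")$p_value
      expect_equal(got, hyper_tail_oracle(a, n1 - a, cc, n2 - cc),
                   tolerance = 1e-12)
    }
  }
})

test_that("subsampling Z matches hypergeometric moments and the null", {
  universe <- paste0("c", 1:400)
  in_set <- paste0("c", 1:80)       # K = 80 of N = 400
  n <- 50
  z <- subsample_z(n * 80 / 400, universe, n, in_set,
                   n_subsamples = 10000, seed = 3)
  expect_lt(abs(as.numeric(z)), 0.1)
  mu <- n * 80 / 400
  sig <- sqrt(n * 0.2 * 0.8 * (400 - n) / (400 - 1))
  mc_se_mean <- sig / sqrt(10000)
  expect_lt(abs(attr(z, "mean") - mu), 3 * mc_se_mean)
  expect_lt(abs(attr(z, "sd") - sig), 3 * sig / sqrt(2 * 10000))

  z2 <- subsample_z(mu, universe, n, in_set, n_subsamples = 10000, seed = 3)
  expect_identical(as.numeric(z), as.numeric(z2))
  expect_error(subsample_z(5, universe, n, universe, 1000, 1),
               "degenerate")
})

test_that("peak-overlap enrichment behaves at the extremes", {
  mk_bed <- function(prefix, n, offset) {
    data.frame(chrom = "chr1", start = offset + (0:(n - 1)) * 1000,
               end = offset + (0:(n - 1)) * 1000 + 100,
               name = paste0(prefix, 1:n))
  }
  fg <- mk_bed("f", 25, 0)
  bg <- mk_bed("b", 250, 100000)
  peaks_all_fg <- data.frame(chrom = "chr1", start = fg$start,
                             end = fg$end, name = paste0("p", 1:25))
  res <- overlap_enrichment(fg, bg, peaks_all_fg, "limb peaks",
                            n_subsamples = 2000, seed = 2)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$subsample_z, 5)

  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0))
  res0 <- overlap_enrichment(fg, bg, empty, "none",
                             n_subsamples = 200, seed = 2)
  expect_equal(res0$a + res0$c, 0)
  expect_equal(res0$p_value, 1)
})

test_that("random foregrounds give calibrated enrichment p-values", {
  set.seed(17)
  universe <- data.frame(chrom = "chr1", start = (0:399) * 1000,
                         end = (0:399) * 1000 + 100,
                         name = paste0("c", 1:400))
  ps <- vapply(1:50, function(i) {
    fg_idx <- sample(400, 40)
    peak_idx <- sample(400, 60)
    peaks <- universe[peak_idx, ]
    fisher_enrichment(universe$name[fg_idx], universe$name[-fg_idx],
                      universe$name[peak_idx], "sim")$p_value
  }, numeric(1))
  ## no inflation: small p-values are not over-represented
  expect_gt(mean(ps > 0.05), 0.8)
  adj <- bh_adjust(ps)
  expect_gt(min(adj), 0.05)
})
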