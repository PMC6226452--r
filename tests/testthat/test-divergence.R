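test_that("percent identity applies the gap-as-mismatch rule", {
  expect_equal(percent_identity("ACGT", "ACGT"), 1.0)
  expect_equal(percent_identity("ACGA", "ACGT"), 0.75)
  expect_equal(percent_identity("AC-T", "ACGT"), 0.75)
  ## ancestral gap columns are excluded from the denominator
  expect_equal(percent_identity("ACGT", "AC-T"), 1.0)
  ## mostly-missing species sequence gives a missing value
  expect_true(is.na(percent_identity("A---------", "ACGTACGTAC")))
  expect_error(percent_identity("ACG", "ACGT"), "length")
})

test_that("seqId normalization follows (pid - 1) / distance", {
  expect_equal(normalized_identity(1.0, 0.2), 0)
  expect_equal(normalized_identity(0.0, 0.5), -2)
  expect_equal(normalized_identity(0.9, 0.25), -0.4)
  expect_true(all(normalized_identity(runif(20), 0.3) <= 0))
  expect_error(normalized_identity(0.5, 0), "distance")
  expect_error(normalized_identity(1.5, 0.2), "pid")
})

test_that("Z-score uses the least diverged loss species and sample sd", {
  expect_equal(z_score(-0.4, c(-0.5, -0.4, -0.3)), 0)
  expect_equal(z_score(c(-0.8, -0.7), c(-0.1, -0.2, -0.3)), -5)
  expect_error(z_score(c(-0.5), c(-0.2, -0.2, -0.2)), "zero sd")
  expect_error(z_score(NA_real_, c(-0.1, -0.2)), "loss-species")
  expect_error(z_score(-0.5, -0.2), ">= 2")
})

test_that("Z is invariant to shifting and positive scaling of seqIds", {
  set.seed(1)
  for (i in 1:20) {
    loss <- -runif(2); others <- -runif(6)
    z0 <- z_score(loss, others)
    shift <- rnorm(1); scale <- runif(1, 0.1, 10)
    expect_equal(z_score(loss + shift, others + shift), z0)
    expect_equal(z_score(loss * scale, others * scale), z0)
  }
})

test_that("screen applies strict cutoffs and missing-data rules", {
  tr <- fixture_tree_12()
  cfg <- screen_config(tr$loss_species, tr$local_species)
  species <- tr$species
  base <- as.data.frame(as.list(stats::setNames(
    rep(-0.2, length(species)), paste0("seqid_", species))))
  mk <- function(zg, zl, drop_sp = NULL) {
    row <- cbind(data.frame(cne_id = "c1", chrom = "chr", start = 0,
                            end = 100), base,
                 data.frame(z_global = zg, z_local = zl))
    for (sp in drop_sp) row[[paste0("seqid_", sp)]] <- NA_real_
    attr(row, "species") <- species
    row
  }
  expect_length(screen_cnes(mk(-3, -4), cfg), 0)     # boundary: strict <
  expect_length(screen_cnes(mk(-3.01, -4), cfg), 1)
  expect_length(screen_cnes(mk(-4, -3), cfg), 0)
  ## missing required species excludes the CNE even with passing Z
  expect_length(screen_cnes(mk(-9, -9, drop_sp = tr$loss_species[1]), cfg), 0)
  ## too few additional species excludes as well
  extra <- setdiff(species, cfg$required_species)
  expect_length(
    screen_cnes(mk(-9, -9, drop_sp = extra[seq_len(length(extra) - 2)]),
                cfg), 0)
  expect_length(screen_cnes(mk(-9, -9)[0, ], cfg), 0)  # empty records
})

test_that("a strongly relaxed planted CNE ranks first by global Z", {
  tr <- fixture_tree_12()
  sim <- evolve_cnes(tr, 100, constrained_rate = 0.2,
                     relaxed_fraction = 0.01, relaxation_factor = 20,
                     seed = 77)
  planted <- sim$truth$cne_id[sim$truth$class == "relaxed_in_loss"]
  expect_length(planted, 1)
  cfg <- screen_config(tr$loss_species, tr$local_species)
  rec <- compute_divergence(sim$alignments, tr, cfg)
  expect_identical(rec$cne_id[which.min(rec$z_global)], planted)
  div <- screen_cnes(rec, cfg)
  expect_identical(as.character(div)[1], planted)
})

test_that("lowering the cutoff never grows the diverged set", {
  tr <- fixture_tree_12()
  sim <- evolve_cnes(tr, 60, constrained_rate = 0.3,
                     relaxed_fraction = 0.2, relaxation_factor = 5,
                     seed = 13)
  cfg3 <- screen_config(tr$loss_species, tr$local_species, z_cutoff = -3)
  rec <- compute_divergence(sim$alignments, tr, cfg3)
  prev <- screen_cnes(rec, cfg3)
  for (cut in c(-4, -5, -8)) {
    cfg <- screen_config(tr$loss_species, tr$local_species, z_cutoff = cut)
    cur <- screen_cnes(rec, cfg)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("decreasing a loss species' pid can only lower the global Z", {
  set.seed(5)
  dist <- runif(8, 0.3, 0.6)
  for (i in 1:10) {
    pid <- runif(8, 0.7, 1)
    sq <- normalized_identity(pid, dist)
    z0 <- z_score(sq[1:2], sq[3:8])
    pid2 <- pid; pid2[1] <- pid[1] * runif(1)
    sq2 <- normalized_identity(pid2, dist)
    expect_lte(z_score(sq2[1:2], sq2[3:8]), z0)
  }
})
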