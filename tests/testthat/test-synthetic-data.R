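test_that("fixture trees have the requested structure and are seed-stable", {
  tr <- generate_fixture_tree(3, 1, 0.5, seed = 7)
  expect_s3_class(tr, "cne_tree")
  expect_length(tr$species, 4)
  expect_identical(tr$loss_species, "loss01")
  expect_silent(ape::read.tree(text = tr$newick))
  expect_true(all(tr$tree$edge.length >= 0))

  tr2 <- generate_fixture_tree(3, 1, 0.5, seed = 7)
  expect_identical(tr$newick, tr2$newick)
  tr3 <- generate_fixture_tree(3, 1, 0.5, seed = 8)
  expect_false(identical(tr$newick, tr3$newick))

  expect_error(generate_fixture_tree(2, 1, 0.5, 1), "n_other_species")
  expect_error(generate_fixture_tree(3, 1, -1, 1), "depth")
})

test_that("clade-mode loss species form a clade, scattered ones do not", {
  tr <- generate_fixture_tree(10, 3, 0.5, seed = 3)
  mrca <- ape::getMRCA(tr$tree, tr$loss_species)
  desc <- ape::extract.clade(tr$tree, mrca)$tip.label
  expect_setequal(desc, tr$loss_species)

  trs <- generate_fixture_tree(10, 2, 0.5, seed = 1, scattered = TRUE)
  mrca <- ape::getMRCA(trs$tree, trs$loss_species)
  desc <- ape::extract.clade(trs$tree, mrca)$tip.label
  expect_gt(length(setdiff(desc, trs$loss_species)), 0)
})

test_that("zero branch lengths leave every sequence identical to the root", {
  tr <- fixture_tree_12()
  tr$tree$edge.length[] <- 0
  sim <- evolve_cnes(tr, 5, seed = 2)
  for (a in sim$alignments)
    expect_true(all(a$seqs == a$ancestral))
})

test_that("relaxation lowers identity to the ancestor in loss species", {
  tr <- fixture_tree_12()
  sim <- evolve_cnes(tr, 250, constrained_rate = 0.1,
                     relaxed_fraction = 1, relaxation_factor = 10,
                     seed = 11)
  pid_loss <- pid_other <- numeric(0)
  for (a in sim$alignments) {
    for (sp in tr$loss_species)
      pid_loss <- c(pid_loss, percent_identity(a$seqs[[sp]], a$ancestral))
    for (sp in setdiff(tr$species, tr$loss_species))
      pid_other <- c(pid_other, percent_identity(a$seqs[[sp]], a$ancestral))
  }
  expect_lt(mean(pid_loss), mean(pid_other) - 0.05)
})

test_that("evolve_cnes validates parameters and is deterministic", {
  tr <- fixture_tree_12()
  tr_no_loss <- tr; tr_no_loss$loss_species <- character(0)
  expect_error(evolve_cnes(tr_no_loss, 5, relaxed_fraction = 0.5, seed = 1),
               "loss_species")
  s1 <- evolve_cnes(tr, 5, seed = 4)
  s2 <- evolve_cnes(tr, 5, seed = 4)
  expect_identical(s1$alignments, s2$alignments)
  lens <- vapply(s1$alignments, function(a) nchar(a$seqs[[1]]), numeric(1))
  expect_true(all(lens >= 30 & lens <= 1000))
})

test_that("gene annotations are valid, ordered, reproducible", {
  g1 <- generate_gene_annotation(1, 1e7, 3)
  expect_equal(nrow(g1), 1)
  expect_true(g1$end == g1$start + 1 && g1$strand %in% c("+", "-"))

  g <- generate_gene_annotation(50, 1e7, 3)
  expect_equal(nrow(g), 50)
  expect_false(is.unsorted(g$start, strictly = TRUE))
  expect_true(all(g$start >= 0 & g$start < 1e7))
  expect_identical(g, generate_gene_annotation(50, 1e7, 3))
  expect_error(generate_gene_annotation(100, 500, 3), "too short")
})

test_that("generated peaks respect the overlap contract", {
  cnes <- data.frame(chrom = "chrSim",
                     start = seq(1000, 40000, by = 2000),
                     end = seq(1000, 40000, by = 2000) + 100,
                     name = paste0("cne", 1:20))
  p0 <- generate_peaks(cnes, 0, 10, seed = 5, chrom_length = 1e6)
  expect_length(overlapping_names_in_test(cnes, p0), 0)

  p1 <- generate_peaks(cnes, 1, 0, seed = 5, chrom_length = 1e6)
  expect_setequal(overlapping_names_in_test(cnes, p1), cnes$name)

  expect_true(all(p1$start >= 0 & p1$end > p1$start))
  expect_false(is.unsorted(p1$start))
  dense <- data.frame(chrom = "chrSim", start = seq(0, 41700, by = 300),
                      end = seq(0, 41700, by = 300) + 299,
                      name = paste0("d", seq(0, 41700, by = 300)))
  expect_error(generate_peaks(dense, 0, 5, seed = 1,
                              chrom_length = 42000),
               "CNE-free")
})

test_that("synthetic motif libraries are normalized and IC-diverse", {
  lib <- generate_motif_library(20, seed = 9)
  for (p in lib)
    expect_true(all(abs(colSums(p$mat) - 1) < 1e-9))
  ics <- unlist(lapply(lib, function(p) apply(p$mat, 2, column_ic)))
  expect_gt(max(ics) - min(ics), 1)
  expect_identical(write_read_meme_roundtrip_ids(lib),
                   vapply(lib, `[[`, character(1), "id"))
  lib2 <- generate_motif_library(20, seed = 9)
  expect_identical(lib, lib2)
  expect_error(generate_motif_library(5, c(3, 2), seed = 1), "length_range")
})
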