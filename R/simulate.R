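## Simulation of CNE evolution along a phylogeny under purifying selection,
## with optional relaxation of constraint on trait-loss branches.

## K80 substitution probabilities for expected t substitutions/site;
## kappa = 1 reduces to Jukes-Cantor. Returns list(same, ts, tv).
k80_probs <- function(t, kappa = 1) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  list(same = 0.25 + 0.25 * e1 + 0.5 * e2,
       ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
       tv   = 0.25 - 0.25 * e1)
}

## transition partner of each base under A=1 C=2 G=3 T=4 (A<->G, C<->T)
TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV_PARTNERS <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

## evolve an integer-coded sequence along one branch
mutate_seq <- function(seq, t, kappa = 1) {
  if (t <= 0) return(seq)
  pr <- k80_probs(t, kappa)
  u <- stats::runif(length(seq))
  out <- seq
  is_ts <- u >= pr$same & u < pr$same + pr$ts
  is_tv1 <- u >= pr$same + pr$ts & u < pr$same + pr$ts + pr$tv
  is_tv2 <- u >= pr$same + pr$ts + pr$tv
  out[is_ts] <- TS_PARTNER[seq[is_ts]]
  tv1 <- vapply(seq[is_tv1], function(b) TV_PARTNERS[[b]][1], integer(1))
  tv2 <- vapply(seq[is_tv2], function(b) TV_PARTNERS[[b]][2], integer(1))
  if (length(tv1)) out[is_tv1] <- tv1
  if (length(tv2)) out[is_tv2] <- tv2
  out
}

#' Simulate CNE alignments with planted lineage-specific relaxation
#'
#' Evolves `n_cnes` conserved non-coding elements along `tree` under a
#' single-nucleotide continuous-time model (Jukes-Cantor by default, K80
#' via `kappa`). Under purifying selection the per-branch expected number
#' of substitutions is `branch_length * constrained_rate`. A fraction
#' `relaxed_fraction` of CNEs is planted as relaxed on the trait-loss
#' lineages: on branches whose descendant leaves are all loss species the
#' rate is multiplied by `relaxation_factor`. Alignments are gap-free, so
#' percent identity reduces to mismatch counting.
#'
#' @param tree a `cne_tree` from [generate_fixture_tree()], or a list with
#'   elements `tree` (phylo) and `loss_species`.
#' @param n_cnes number of CNEs to simulate.
#' @param length_mean mean CNE length in bp; lengths are drawn from a
#'   geometric distribution truncated to `[30, 1000]` bp.
#' @param constrained_rate rate multiplier in (0, 1] relative to the neutral
#'   branch lengths of the tree (selection slows substitution).
#' @param relaxed_fraction proportion of CNEs planted as relaxed in the
#'   loss lineages.
#' @param relaxation_factor rate multiplier (>= 1) applied on loss-exclusive
#'   branches of relaxed CNEs.
#' @param seed integer seed.
#' @param base_freqs root base composition (A, C, G, T).
#' @param kappa transition/transversion rate ratio (1 = Jukes-Cantor).
#' @param cne_spacing mean gap between consecutive CNEs on the simulated
#'   chromosome, bp.
#' @return A list with elements `alignments` (list of `cne_alignment`
#'   objects: `cne_id`, `chrom`, `start`, `end`, `seqs` - a named character
#'   vector per species - and `ancestral`, the true root sequence) and
#'   `truth` (data.frame: `cne_id`, `class` in {constrained,
#'   relaxed_in_loss}, `relaxation_factor`).
#' @export
evolve_cnes <- function(tree, n_cnes, length_mean = 150,
                        constrained_rate = 0.2, relaxed_fraction = 0,
                        relaxation_factor = 1, seed = 1,
                        base_freqs = rep(0.25, 4), kappa = 1,
                        cne_spacing = 2000) {
  phy <- if (inherits(tree, "cne_tree")) tree$tree else tree$tree
  loss_species <- tree$loss_species %||% character(0)
  n_cnes <- check_count(n_cnes, "n_cnes")
  relaxed_fraction <- check_fraction(relaxed_fraction, "relaxed_fraction")
  if (relaxation_factor < 1)
    abort_param("`relaxation_factor` must be >= 1")
  if (constrained_rate <= 0 || constrained_rate > 1)
    abort_param("`constrained_rate` must be in (0, 1]")
  if (relaxed_fraction > 0 && length(loss_species) == 0L)
    abort_param("relaxed_fraction > 0 requires non-empty loss_species")
  set.seed(check_count(seed, "seed", 0L))

  n_tip <- length(phy$tip.label)
  porder <- rev(ape::postorder(phy))  # parents before children
  root <- phy$edge[porder[1], 1]
  loss_edge <- loss_exclusive_edges(phy, loss_species)

  n_relaxed <- floor(relaxed_fraction * n_cnes)
  classes <- rep("constrained", n_cnes)
  if (n_relaxed > 0)
    classes[sample.int(n_cnes, n_relaxed)] <- "relaxed_in_loss"

  ## truncated geometric CNE lengths
  lens <- integer(n_cnes)
  p_geom <- 1 / max(length_mean - 29, 2)
  for (i in seq_len(n_cnes)) {
    repeat {
      l <- 30L + stats::rgeom(1, p_geom)
      if (l <= 1000L) break
    }
    lens[i] <- l
  }
  gaps <- 1L + stats::rgeom(n_cnes, 1 / cne_spacing)

  alignments <- vector("list", n_cnes)
  pos <- 0L
  for (i in seq_len(n_cnes)) {
    L <- lens[i]
    factor_i <- if (classes[i] == "relaxed_in_loss") relaxation_factor else 1
    seqs_int <- vector("list", n_tip + phy$Nnode)
    root_seq <- sample.int(4L, L, replace = TRUE, prob = base_freqs)
    seqs_int[[root]] <- root_seq
    for (e in porder) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      rate <- constrained_rate * (if (loss_edge[e]) factor_i else 1)
      seqs_int[[ch]] <- mutate_seq(seqs_int[[p]],
                                   phy$edge.length[e] * rate, kappa)
    }
    seqs <- vapply(seq_len(n_tip), function(k) decode_dna(seqs_int[[k]]),
                   character(1))
    names(seqs) <- phy$tip.label
    start <- pos + gaps[i]
    pos <- start + L
    alignments[[i]] <- structure(
      list(cne_id = sprintf("cne%05d", i), chrom = "chrSim",
           start = start, end = pos, seqs = seqs,
           ancestral = decode_dna(root_seq)),
      class = "cne_alignment")
  }

  truth <- data.frame(
    cne_id = vapply(alignments, `[[`, character(1), "cne_id"),
    class = classes,
    relaxation_factor = ifelse(classes == "relaxed_in_loss",
                               relaxation_factor, 1),
    stringsAsFactors = FALSE)
  list(alignments = alignments, truth = truth)
}

#' @export
print.cne_alignment <- function(x, ...) {
  cat(sprintf("<cne_alignment> %s %s:%d-%d, %d species x %d columns\n",
              x$cne_id, x$chrom, x$start, x$end, length(x$seqs),
              nchar(x$seqs[[1]])))
  invisible(x)
}

## BED data frame of CNE coordinates for a list of alignments
alignments_bed <- function(alignments) {
  data.frame(chrom = vapply(alignments, `[[`, character(1), "chrom"),
             start = vapply(alignments, function(a) a$start, numeric(1)),
             end = vapply(alignments, function(a) a$end, numeric(1)),
             name = vapply(alignments, `[[`, character(1), "cne_id"),
             stringsAsFactors = FALSE)
}

#' Write per-CNE alignments as multi-FASTA files
#'
#' One gapped FASTA per CNE, record ids are species names; the true
#' ancestral sequence is written with id `_ancestral` when present.
#'
#' @param alignments list of `cne_alignment` objects.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_alignments <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in alignments) {
    lines <- character(0)
    for (sp in names(a$seqs))
      lines <- c(lines, paste0(">", sp), a$seqs[[sp]])
    if (!is.null(a$ancestral))
      lines <- c(lines, ">_ancestral", a$ancestral)
    writeLines(lines, file.path(dir, paste0(a$cne_id, ".fa")))
  }
  invisible(dir)
}

#' Read per-CNE multi-FASTA alignments from a directory
#'
#' @param dir directory of `<cne_id>.fa` files written by
#'   [write_alignments()] or equivalent.
#' @param bed optional BED data frame of CNE coordinates keyed by `name`.
#' @return list of `cne_alignment` objects.
#' @export
read_alignments <- function(dir, bed = NULL) {
  files <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  lapply(files, function(f) {
    recs <- ape::read.FASTA(f)
    seqs <- vapply(as.character(recs), function(v)
      toupper(paste(v, collapse = "")), character(1))
    anc <- NULL
    if ("_ancestral" %in% names(seqs)) {
      anc <- unname(seqs[["_ancestral"]])
      seqs <- seqs[names(seqs) != "_ancestral"]
    }
    id <- sub("\\.fa$", "", basename(f))
    coords <- list(chrom = "chrUnknown", start = 0, end = nchar(seqs[[1]]))
    if (!is.null(bed)) {
      j <- match(id, bed$name)
      if (!is.na(j))
        coords <- list(chrom = bed$chrom[j], start = bed$start[j],
                       end = bed$end[j])
    }
    structure(list(cne_id = id, chrom = coords$chrom, start = coords$start,
                   end = coords$end, seqs = seqs, ancestral = anc),
              class = "cne_alignment")
  })
}
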