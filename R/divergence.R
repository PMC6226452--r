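## Per-species divergence measures and the lineage-specific Z-score screen.

#' Percent identity between a species sequence and the ancestral sequence
#'
#' Identity is counted over the columns in which the ancestor has a base:
#' matches are identical bases; a species gap (or N) opposite an ancestral
#' base counts as a mismatch. A value of 0 corresponds to complete loss of
#' the element. When the species has fewer than `min_nongap_frac` non-gap,
#' non-N characters over the ancestral-base columns, the value is missing
#' (`NA`): too little sequence to measure divergence.
#'
#' @param species_seq gapped sequence of one species.
#' @param ancestral_seq gapped ancestral sequence of equal length.
#' @param min_nongap_frac missing-data threshold (default 0.3).
#' @return fraction in `[0, 1]`, or `NA_real_` when the species sequence is
#'   mostly missing.
#' @export
percent_identity <- function(species_seq, ancestral_seq,
                             min_nongap_frac = 0.3) {
  if (nchar(species_seq) != nchar(ancestral_seq))
    abort_param("species and ancestral sequences differ in length")
  sp <- encode_dna(species_seq)
  an <- encode_dna(ancestral_seq)
  cols <- which(!is.na(an) & an <= 4L)   # ancestral-base columns only
  if (length(cols) == 0L) return(NA_real_)
  sp <- sp[cols]; an <- an[cols]
  present <- !is.na(sp) & sp <= 4L
  if (mean(present) < min_nongap_frac) return(NA_real_)
  sum(present & sp == an) / length(cols)
}

#' Branch-length-normalized sequence identity (seqId)
#'
#' `seqId = (percent identity - 1) / evolutionary distance to the
#' ancestor`, so values are <= 0: 0 means perfect identity and more
#' negative values mean more divergence than expected for the lineage.
#'
#' @param pid fractional percent identity in `[0, 1]` (may be `NA`).
#' @param distance sum of branch lengths from the species to the ancestor,
#'   substitutions/site; must be > 0.
#' @return seqId (<= 0), or `NA` if `pid` is `NA`.
#' @export
normalized_identity <- function(pid, distance) {
  if (any(distance <= 0)) abort_param("`distance` must be > 0")
  if (any(!is.na(pid) & (pid < 0 | pid > 1)))
    abort_param("`pid` must be in [0, 1]")
  (pid - 1) / distance
}

#' Lineage-specific divergence Z-score
#'
#' Compares the least diverged trait-loss species (maximum seqId) with the
#' mean and sample standard deviation of the comparison species:
#' `Z = (max(seqId_loss) - mean(seqId_others)) / sd(seqId_others)`.
#' The same statistic serves the global comparison (all intact species)
#' and the local comparison (a designated close-relative subset).
#'
#' @param loss_values seqIds of the trait-loss species (NAs dropped; at
#'   least one finite value required).
#' @param other_values seqIds of the comparison species (NAs dropped; at
#'   least two finite values required).
#' @return the Z-score.
#' @export
z_score <- function(loss_values, other_values) {
  loss_values <- loss_values[is.finite(loss_values)]
  other_values <- other_values[is.finite(other_values)]
  if (length(loss_values) == 0L)
    abort_param("no finite loss-species seqId")
  if (length(other_values) < 2L)
    abort_param("need >= 2 finite comparison seqIds")
  s <- stats::sd(other_values)
  if (s == 0)
    abort_param("degenerate input: comparison seqIds have zero sd")
  (max(loss_values) - mean(other_values)) / s
}

safe_z <- function(loss_values, other_values) {
  tryCatch(z_score(loss_values, other_values), error = function(e) NA_real_)
}

#' Screen configuration for the lineage-specific divergence screen
#'
#' @param loss_species trait-loss species (non-empty).
#' @param local_species comparison species for the local Z-score.
#' @param required_species species that must all have non-missing seqId for
#'   a CNE to be screened (default: loss and local species).
#' @param min_additional_species minimum number of further species with
#'   non-missing seqId (default 3).
#' @param z_cutoff Z-score cutoff, strictly below which a CNE is called
#'   diverged (default -3).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(loss_species, local_species,
                          required_species = NULL,
                          min_additional_species = 3, z_cutoff = -3) {
  if (length(loss_species) == 0L)
    abort_param("`loss_species` must be non-empty")
  if (!is.numeric(z_cutoff) || z_cutoff >= 0)
    abort_param("`z_cutoff` must be negative")
  structure(list(
    loss_species = loss_species,
    local_species = setdiff(local_species, loss_species),
    required_species = required_species %||%
      union(loss_species, setdiff(local_species, loss_species)),
    min_additional_species = check_count(min_additional_species,
                                         "min_additional_species", 0L),
    z_cutoff = as.numeric(z_cutoff)), class = "screen_config")
}

#' Compute per-CNE divergence records against a phylogeny
#'
#' For each CNE alignment: reconstructs the ancestral sequence at the root
#' (unless the simulator's true ancestral sequence is to be used), computes
#' per-species percent identity and seqId (identity normalized by the
#' species' root-to-tip distance), and the global and local Z-scores.
#'
#' @param alignments list of `cne_alignment` objects.
#' @param tree a `cne_tree` or `phylo`.
#' @param config a [screen_config()].
#' @param min_nongap_frac missing-data threshold for [percent_identity()].
#' @param use_true_ancestor logical; use the simulator's stored root
#'   sequence instead of reconstructing (default `FALSE`).
#' @return data.frame with one row per CNE: `cne_id`, coordinates,
#'   `pid_<species>` and `seqid_<species>` columns, `z_global`, `z_local`.
#'   The species set is stored in the `"species"` attribute.
#' @export
compute_divergence <- function(alignments, tree, config,
                               min_nongap_frac = 0.3,
                               use_true_ancestor = FALSE) {
  phy <- if (inherits(tree, "cne_tree")) tree$tree else tree
  species <- phy$tip.label
  dist <- tip_root_distance(phy)
  loss <- config$loss_species
  global_others <- setdiff(species, loss)
  local_others <- config$local_species

  n <- length(alignments)
  pid <- matrix(NA_real_, n, length(species),
                dimnames = list(NULL, species))
  for (i in seq_len(n)) {
    a <- alignments[[i]]
    anc <- if (use_true_ancestor && !is.null(a$ancestral)) a$ancestral
           else reconstruct_ancestral(a, phy)
    for (sp in intersect(names(a$seqs), species))
      pid[i, sp] <- percent_identity(a$seqs[[sp]], anc, min_nongap_frac)
  }
  seqid <- sweep(pid - 1, 2, dist[species], "/")

  z_global <- vapply(seq_len(n), function(i)
    safe_z(seqid[i, loss], seqid[i, global_others]), numeric(1))
  z_local <- vapply(seq_len(n), function(i)
    safe_z(seqid[i, loss], seqid[i, local_others]), numeric(1))

  out <- data.frame(
    cne_id = vapply(alignments, `[[`, character(1), "cne_id"),
    chrom = vapply(alignments, `[[`, character(1), "chrom"),
    start = vapply(alignments, function(a) a$start, numeric(1)),
    end = vapply(alignments, function(a) a$end, numeric(1)),
    stringsAsFactors = FALSE)
  colnames(pid) <- paste0("pid_", species)
  colnames(seqid) <- paste0("seqid_", species)
  out <- cbind(out, pid, seqid)
  out$z_global <- z_global
  out$z_local <- z_local
  attr(out, "species") <- species
  out
}

#' Screen divergence records for lineage-specific divergence
#'
#' Keeps CNEs that (i) have non-missing seqId for every required species
#' plus at least `min_additional_species` further species, (ii) have a
#' global Z-score strictly below the cutoff, and (iii) a local Z-score
#' strictly below the cutoff. The result is sorted by global Z-score,
#' most diverged first.
#'
#' @param records data.frame from [compute_divergence()].
#' @param config a [screen_config()].
#' @return character vector of diverged CNE ids, sorted by global Z-score
#'   ascending, with the filtered records as attribute `"records"`.
#' @export
screen_cnes <- function(records, config) {
  if (nrow(records) == 0L) return(character(0))
  species <- attr(records, "species") %||%
    sub("^seqid_", "", grep("^seqid_", names(records), value = TRUE))
  seqid <- as.matrix(records[, paste0("seqid_", species), drop = FALSE])
  colnames(seqid) <- species

  req <- config$required_species
  have <- is.finite(seqid)
  req_ok <- rowSums(have[, req, drop = FALSE]) == length(req)
  extra <- setdiff(species, req)
  extra_ok <- rowSums(have[, extra, drop = FALSE]) >=
    config$min_additional_species
  pass <- req_ok & extra_ok &
    is.finite(records$z_global) & records$z_global < config$z_cutoff &
    is.finite(records$z_local) & records$z_local < config$z_cutoff
  kept <- records[pass, , drop = FALSE]
  kept <- kept[order(kept$z_global), , drop = FALSE]
  structure(kept$cne_id, records = kept)
}
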