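## Staged pipeline: simulate -> screen -> associate -> enrich -> motifs ->
## report, driven by a YAML config with seeded, manifest-logged stages.

config_spec <- function() list(
  outdir = list(default = NULL, type = "character", required = TRUE),
  seed = list(default = 1L, type = "integer"),
  n_other_species = list(default = 10L, type = "integer"),
  n_loss_species = list(default = 2L, type = "integer"),
  scattered = list(default = FALSE, type = "logical"),
  tree_depth = list(default = 0.5, type = "numeric"),
  n_cnes = list(default = 300L, type = "integer"),
  length_mean = list(default = 150, type = "numeric"),
  constrained_rate = list(default = 0.2, type = "numeric"),
  relaxed_fraction = list(default = 0.05, type = "numeric"),
  relaxation_factor = list(default = 20, type = "numeric"),
  n_genes = list(default = 30L, type = "integer"),
  chrom_length = list(default = 1000000L, type = "integer"),
  peak_overlap_fraction = list(default = 0.6, type = "numeric"),
  n_decoy_peaks = list(default = 50L, type = "integer"),
  n_motifs = list(default = 8L, type = "integer"),
  z_cutoff = list(default = -3, type = "numeric"),
  min_additional_species = list(default = 3L, type = "integer"),
  merge_gap = list(default = 50L, type = "integer"),
  basal_up = list(default = 5000L, type = "integer"),
  basal_down = list(default = 1000L, type = "integer"),
  max_extension = list(default = 300000L, type = "integer"),
  n_subsamples = list(default = 10000L, type = "integer"),
  gc_bins = list(default = 21L, type = "integer"),
  cutoff_quantile = list(default = 0.9, type = "numeric"),
  pseudocount = list(default = 0.01, type = "numeric"),
  direction = list(default = "greater", type = "character"),
  ic_bins = list(default = 20L, type = "integer"),
  gene_sets_file = list(default = NA_character_, type = "character")
)

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML config, rejects unknown keys and type mismatches, fills in
#' defaults (Z cutoff -3, basal domain 5000/1000 bp, 300 kb extension,
#' 50 bp merge gap, 10,000 subsamples, 21 GC bins, 90% score quantile, 20
#' IC bins), and reports every applied default via `message()`. All errors
#' are aggregated into a single failure.
#'
#' @param path YAML file path.
#' @param quiet suppress default-logging messages.
#' @return object of class `pipeline_config` (a named list).
#' @export
validate_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort_param("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  spec <- config_spec()
  errors <- character(0)
  for (k in setdiff(names(raw), names(spec)))
    errors <- c(errors, sprintf("unknown key: %s", k))
  cfg <- list()
  for (k in names(spec)) {
    s <- spec[[k]]
    if (k %in% names(raw)) {
      v <- raw[[k]]
      ok <- switch(s$type,
                   integer = is.numeric(v) && length(v) == 1 &&
                     (is.na(v) || v == floor(v)),
                   numeric = is.numeric(v) && length(v) == 1,
                   logical = is.logical(v) && length(v) == 1,
                   character = is.character(v) && length(v) == 1)
      if (!ok) {
        errors <- c(errors, sprintf("key %s: expected %s", k, s$type))
        next
      }
      cfg[[k]] <- switch(s$type, integer = as.integer(v),
                         numeric = as.numeric(v), v)
    } else if (isTRUE(s$required)) {
      errors <- c(errors, sprintf("missing required key: %s", k))
    } else {
      cfg[[k]] <- s$default
      if (!quiet)
        message(sprintf("config: %s defaults to %s", k,
                        format(s$default)))
    }
  }
  if (!is.null(cfg$gene_sets_file) && !is.na(cfg$gene_sets_file) &&
      !file.exists(cfg$gene_sets_file))
    errors <- c(errors, sprintf("gene_sets_file not found: %s",
                                cfg$gene_sets_file))
  if (length(errors))
    abort_param("invalid config:\n  ", paste(errors, collapse = "\n  "))
  structure(cfg, class = "pipeline_config")
}

stage_paths <- function(cfg) {
  o <- cfg$outdir
  list(tree = file.path(o, "tree.nwk"),
       roles = file.path(o, "species_roles.yaml"),
       aln_dir = file.path(o, "alignments"),
       cnes = file.path(o, "cnes.bed"),
       truth = file.path(o, "truth.tsv"),
       genes = file.path(o, "genes.bed"),
       peaks = file.path(o, "peaks.bed"),
       motifs = file.path(o, "motifs.meme"),
       divergence = file.path(o, "divergence.tsv"),
       diverged = file.path(o, "diverged_ids.txt"),
       merged = file.path(o, "cnes_merged.bed"),
       domains = file.path(o, "domains.tsv"),
       cne_gene = file.path(o, "cne_gene_map.tsv"),
       enrichment = file.path(o, "enrichment.tsv"),
       cutoffs = file.path(o, "motif_cutoffs.tsv"),
       scores = file.path(o, "motif_scores.tsv"),
       excess = file.path(o, "excess_scores.tsv"),
       report = file.path(o, "report.tsv"))
}

require_artifacts <- function(paths, files, produced_by) {
  missing <- files[!file.exists(files)]
  if (length(missing))
    abort_param(sprintf(
      "missing artifact %s; run stage '%s' first", missing[1], produced_by))
}

write_manifest <- function(cfg, stage, seed, inputs, outputs) {
  man <- list(stage = stage,
              seed = seed,
              parameters = unclass(cfg),
              input_checksums = as.list(tools::md5sum(
                inputs[file.exists(inputs)])),
              outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, file.path(cfg$outdir,
                                      sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

read_screen_inputs <- function(cfg) {
  p <- stage_paths(cfg)
  roles <- yaml::read_yaml(p$roles)
  tree <- structure(list(tree = ape::read.tree(p$tree),
                         loss_species = roles$loss_species,
                         local_species = roles$local_species),
                    class = "cne_tree")
  tree$species <- tree$tree$tip.label
  tree$newick <- ape::write.tree(tree$tree)
  bed <- read_bed(p$cnes)
  list(tree = tree, alignments = read_alignments(p$aln_dir, bed))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic tree, alignments, annotations, peaks,
#' motif library), `screen` (ancestral reconstruction, seqId, Z-scores,
#' diverged calls), `associate` (CNE merging, regulatory domains, CNE-gene
#' map), `enrich` (peak-overlap and optional gene-set enrichment),
#' `motifs` (GC cutoffs, CNE-motif scores, ancestral-presence filter,
#' per-species excess scores), `report` (summary table). Each stage writes
#' its outputs plus a JSON run manifest into `config$outdir` and fails
#' with an actionable error naming the stage to run first when an upstream
#' artifact is missing.
#'
#' @param stage one of `"simulate"`, `"screen"`, `"associate"`,
#'   `"enrich"`, `"motifs"`, `"report"`, or `"all"`.
#' @param config a `pipeline_config` from [validate_config()].
#' @return invisibly, a character vector of the files written.
#' @export
run_stage <- function(stage = c("simulate", "screen", "associate",
                                "enrich", "motifs", "report", "all"),
                      config) {
  stage <- match.arg(stage)
  if (!inherits(config, "pipeline_config"))
    abort_param("`config` must come from validate_config()")
  if (stage == "all") {
    out <- unlist(lapply(c("simulate", "screen", "associate", "enrich",
                           "motifs", "report"), run_stage, config = config))
    return(invisible(out))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- stage_paths(config)
  seed <- derive_seed(config$seed, stage)
  out <- switch(stage,
                simulate = stage_simulate(config, p, seed),
                screen = stage_screen(config, p, seed),
                associate = stage_associate(config, p, seed),
                enrich = stage_enrich(config, p, seed),
                motifs = stage_motifs(config, p, seed),
                report = stage_report(config, p, seed))
  invisible(out)
}

stage_simulate <- function(cfg, p, seed) {
  tree <- generate_fixture_tree(cfg$n_other_species, cfg$n_loss_species,
                                cfg$tree_depth, seed,
                                scattered = cfg$scattered)
  sim <- evolve_cnes(tree, cfg$n_cnes, cfg$length_mean,
                     cfg$constrained_rate, cfg$relaxed_fraction,
                     cfg$relaxation_factor, seed = seed + 1L)
  writeLines(tree$newick, p$tree)
  yaml::write_yaml(list(loss_species = tree$loss_species,
                        local_species = tree$local_species), p$roles)
  write_alignments(sim$alignments, p$aln_dir)
  bed <- alignments_bed(sim$alignments)
  write_bed(bed, p$cnes)
  write_tsv(sim$truth, p$truth)
  genes <- generate_gene_annotation(cfg$n_genes, cfg$chrom_length,
                                    seed + 2L)
  write_bed(genes, p$genes)
  relaxed <- bed[bed$name %in%
                   sim$truth$cne_id[sim$truth$class == "relaxed_in_loss"],
                 , drop = FALSE]
  target <- if (nrow(relaxed)) relaxed else bed
  peaks <- generate_peaks(target, cfg$peak_overlap_fraction,
                          cfg$n_decoy_peaks, seed + 3L,
                          chrom_length = cfg$chrom_length)
  write_bed(peaks, p$peaks)
  write_meme(generate_motif_library(cfg$n_motifs, seed = seed + 4L),
             p$motifs)
  outs <- c(p$tree, p$roles, p$cnes, p$truth, p$genes, p$peaks, p$motifs)
  write_manifest(cfg, "simulate", seed, character(0), outs)
  outs
}

stage_screen <- function(cfg, p, seed) {
  require_artifacts(p, c(p$tree, p$roles, p$cnes), "simulate")
  inp <- read_screen_inputs(cfg)
  config <- screen_config(inp$tree$loss_species, inp$tree$local_species,
                          min_additional_species =
                            cfg$min_additional_species,
                          z_cutoff = cfg$z_cutoff)
  rec <- compute_divergence(inp$alignments, inp$tree, config)
  diverged <- screen_cnes(rec, config)
  rec$pass <- rec$cne_id %in% diverged
  write_tsv(rec, p$divergence)
  writeLines(as.character(diverged), p$diverged)
  write_manifest(cfg, "screen", seed, c(p$tree, p$cnes),
                 c(p$divergence, p$diverged))
  c(p$divergence, p$diverged)
}

stage_associate <- function(cfg, p, seed) {
  require_artifacts(p, c(p$cnes), "simulate")
  require_artifacts(p, c(p$diverged), "screen")
  cnes <- read_bed(p$cnes)
  genes <- read_bed(p$genes)
  merged <- merge_close(cnes, cfg$merge_gap)
  write_bed(merged, p$merged)
  domains <- build_regulatory_domains(
    genes, cfg$basal_up, cfg$basal_down, cfg$max_extension,
    chrom_sizes = stats::setNames(cfg$chrom_length, genes$chrom[1]))
  write_tsv(domains, p$domains)
  cmap <- associate_cnes(merged, domains)
  long <- data.frame(
    cne_id = rep(names(cmap), lengths(cmap)),
    gene_id = unlist(cmap, use.names = FALSE), stringsAsFactors = FALSE)
  write_tsv(long, p$cne_gene)
  write_manifest(cfg, "associate", seed, c(p$cnes, p$genes, p$diverged),
                 c(p$merged, p$domains, p$cne_gene))
  c(p$merged, p$domains, p$cne_gene)
}

## merged CNEs split into foreground (containing >= 1 diverged CNE) and
## background; returns list(fg, bg) of BED data frames
merged_fg_bg <- function(cnes, merged, diverged_ids) {
  div_bed <- cnes[cnes$name %in% diverged_ids, , drop = FALSE]
  fg_names <- if (nrow(div_bed)) overlapping_names(merged, div_bed)
              else character(0)
  list(fg = merged[merged$name %in% fg_names, , drop = FALSE],
       bg = merged[!merged$name %in% fg_names, , drop = FALSE])
}

stage_enrich <- function(cfg, p, seed) {
  require_artifacts(p, c(p$diverged), "screen")
  require_artifacts(p, c(p$merged, p$cne_gene), "associate")
  cnes <- read_bed(p$cnes)
  merged <- read_bed(p$merged)
  diverged <- readLines(p$diverged)
  parts <- merged_fg_bg(cnes, merged, diverged)
  if (nrow(parts$fg) == 0L || nrow(parts$bg) == 0L)
    abort_param("enrichment needs non-empty diverged and background sets")
  peaks <- read_bed(p$peaks)
  res <- overlap_enrichment(parts$fg, parts$bg, peaks, "peaks",
                            n_subsamples = cfg$n_subsamples, seed = seed)
  if (!is.na(cfg$gene_sets_file)) {
    gs <- read_tsv(cfg$gene_sets_file)
    gene_sets <- split(gs$gene_id, gs$set_name)
    long <- read_tsv(p$cne_gene)
    cmap <- stats::setNames(vector("list", nrow(merged)), merged$name)
    for (nm in merged$name) cmap[[nm]] <- character(0)
    if (nrow(long))
      for (i in seq_len(nrow(long)))
        cmap[[long$cne_id[i]]] <- c(cmap[[long$cne_id[i]]], long$gene_id[i])
    res <- rbind(res, cbind(
      gene_set_enrichment(parts$fg, parts$bg, cmap, gene_sets,
                          n_subsamples = cfg$n_subsamples, seed = seed)
      [, names(res)[names(res) != "adjusted_p"], drop = FALSE],
      row.names = NULL))
  }
  res <- adjust_enrichment(res)
  write_tsv(res, p$enrichment)
  write_manifest(cfg, "enrich", seed, c(p$merged, p$peaks, p$diverged),
                 p$enrichment)
  p$enrichment
}

stage_motifs <- function(cfg, p, seed) {
  require_artifacts(p, c(p$tree, p$cnes, p$motifs), "simulate")
  require_artifacts(p, c(p$diverged), "screen")
  inp <- read_screen_inputs(cfg)
  pwms <- read_meme(p$motifs)
  cut_tab <- do.call(rbind, lapply(seq_along(pwms), function(i)
    gc_cutoffs(pwms[[i]], cfg$gc_bins, quantile = cfg$cutoff_quantile,
               seed = seed + i, pseudocount = cfg$pseudocount)))
  write_tsv(cut_tab, p$cutoffs)

  ## score against the reconstructed ancestor
  alns <- lapply(inp$alignments, function(a) {
    a$ancestral <- reconstruct_ancestral(a, inp$tree)
    a
  })
  scores <- score_cne_motifs(alns, pwms, cfg$pseudocount)
  write_tsv(scores, p$scores)

  cne_gc <- stats::setNames(scores$gc[!duplicated(scores$cne_id)],
                            scores$cne_id[!duplicated(scores$cne_id)])
  kept <- select_ancestral_pairs(scores, cut_tab, cne_gc)
  diverged <- readLines(p$diverged)
  species <- inp$tree$species
  fg <- kept[kept$cne_id %in% diverged, , drop = FALSE]
  bg <- kept[!kept$cne_id %in% diverged, , drop = FALSE]
  if (nrow(fg) >= 5 && nrow(bg) >= 5) {
    fg_scores <- lapply(species, function(sp) fg[[paste0("score_", sp)]])
    bg_scores <- lapply(species, function(sp) bg[[paste0("score_", sp)]])
    names(fg_scores) <- names(bg_scores) <- species
    exc <- excess_score(fg_scores, bg_scores, cfg$direction)
  } else {
    exc <- data.frame(species = character(0), median_foreground = numeric(0),
                      median_background = numeric(0), excess = numeric(0),
                      p_value = numeric(0), adjusted_p = numeric(0))
  }
  write_tsv(exc, p$excess)
  write_manifest(cfg, "motifs", seed, c(p$motifs, p$diverged),
                 c(p$cutoffs, p$scores, p$excess))
  c(p$cutoffs, p$scores, p$excess)
}

stage_report <- function(cfg, p, seed) {
  require_artifacts(p, c(p$truth), "simulate")
  require_artifacts(p, c(p$divergence, p$diverged), "screen")
  truth <- read_tsv(p$truth)
  diverged <- readLines(p$diverged)
  relaxed <- truth$cne_id[truth$class == "relaxed_in_loss"]
  constrained <- truth$cne_id[truth$class == "constrained"]
  rows <- list(
    c("n_cnes", nrow(truth)),
    c("n_diverged", length(diverged)),
    c("n_relaxed_planted", length(relaxed)),
    c("sensitivity", if (length(relaxed))
      round(mean(relaxed %in% diverged), 4) else NA),
    c("empirical_fpr", if (length(constrained))
      round(mean(constrained %in% diverged), 5) else NA))
  if (file.exists(p$enrichment)) {
    enr <- read_tsv(p$enrichment)
    if (nrow(enr))
      rows <- c(rows, list(
        c("top_enrichment_set", enr$set_name[1]),
        c("top_enrichment_p", signif(enr$p_value[1], 3)),
        c("top_enrichment_z", signif(enr$subsample_z[1], 3))))
  }
  if (file.exists(p$excess)) {
    exc <- read_tsv(p$excess)
    if (nrow(exc)) {
      best <- exc[which.min(exc$adjusted_p), ]
      rows <- c(rows, list(
        c("max_excess_species", best$species),
        c("max_excess", signif(best$excess, 4)),
        c("max_excess_adjusted_p", signif(best$adjusted_p, 3))))
    }
  }
  rep_df <- data.frame(metric = vapply(rows, `[`, character(1), 1),
                       value = vapply(rows, function(r)
                         as.character(r[2]), character(1)),
                       stringsAsFactors = FALSE)
  write_tsv(rep_df, p$report)
  write_manifest(cfg, "report", seed, c(p$truth, p$diverged), p$report)
  p$report
}
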