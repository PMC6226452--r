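## GREAT-style regulatory domains: basal promoter window plus extension.

#' Build GREAT-style regulatory domains
#'
#' Each gene gets a strand-aware basal domain of `basal_up` bp upstream and
#' `basal_down` bp downstream of the TSS, and a distal domain extending the
#' basal domain in both directions up to the nearest other gene's basal
#' domain or at most `max_extension` bp, clipped to the chromosome.
#' Extensions may overlap other genes' extensions but never invade a
#' foreign basal domain.
#'
#' @param genes BED6-style data.frame from [generate_gene_annotation()] or
#'   a TSS table with `chrom`, `start` (TSS), `name`, `strand`.
#' @param basal_up,basal_down basal domain extent upstream/downstream of
#'   the TSS in bp (defaults 5000 and 1000).
#' @param max_extension maximum distal extension in bp (default 300000).
#' @param chrom_sizes named vector of chromosome lengths; defaults to
#'   unbounded on the right.
#' @return data.frame: `gene_id`, `chrom`, `tss`, `strand`,
#'   `basal_start`, `basal_end`, `domain_start`, `domain_end` (BED
#'   half-open).
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000,
                                     basal_down = 1000,
                                     max_extension = 300000,
                                     chrom_sizes = NULL) {
  if (anyDuplicated(genes$name))
    abort_param("duplicate gene ids")
  tss <- genes$start
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, tss - basal_up, tss - basal_down)
  basal_end <- ifelse(plus, tss + basal_down, tss + basal_up)
  basal_start <- pmax(0, basal_start)
  lim <- if (is.null(chrom_sizes)) rep(Inf, nrow(genes))
         else unname(chrom_sizes[genes$chrom])
  basal_end <- pmin(basal_end, lim)

  dom_start <- numeric(nrow(genes))
  dom_end <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    for (i in idx) {
      others <- setdiff(idx, i)
      ## left: stop at the nearest foreign basal end at or left of our start
      left_bnds <- basal_end[others][basal_end[others] <= basal_start[i]]
      left_stop <- if (length(left_bnds)) max(left_bnds) else 0
      dom_start[i] <- max(basal_start[i] - max_extension, left_stop, 0)
      ## right: stop at the nearest foreign basal start at or right of our end
      right_bnds <- basal_start[others][basal_start[others] >= basal_end[i]]
      right_stop <- if (length(right_bnds)) min(right_bnds) else Inf
      dom_end[i] <- min(basal_end[i] + max_extension, right_stop, lim[i])
      ## overlapping foreign basal domains leave no room to extend
      dom_start[i] <- min(dom_start[i], basal_start[i])
      dom_end[i] <- max(dom_end[i], basal_end[i])
    }
  }
  data.frame(gene_id = genes$name, chrom = genes$chrom, tss = tss,
             strand = genes$strand,
             basal_start = basal_start, basal_end = basal_end,
             domain_start = dom_start, domain_end = dom_end,
             stringsAsFactors = FALSE)
}

#' Associate CNEs with genes via regulatory-domain overlap
#'
#' A CNE is associated with every gene whose regulatory domain it
#' intersects by at least 1 bp.
#'
#' @param cnes BED data.frame with a `name` column.
#' @param domains data.frame from [build_regulatory_domains()].
#' @return named list: CNE id -> character vector of gene ids (possibly
#'   empty), covering every input CNE.
#' @export
associate_cnes <- function(cnes, domains) {
  res <- stats::setNames(vector("list", nrow(cnes)), cnes$name)
  for (i in seq_along(res)) res[[i]] <- character(0)
  for (ch in unique(cnes$chrom)) {
    ci <- cnes[cnes$chrom == ch, , drop = FALSE]
    di <- domains[domains$chrom == ch, , drop = FALSE]
    if (!nrow(ci) || !nrow(di)) next
    ov <- IRanges::findOverlaps(
      bed_to_iranges(ci),
      IRanges::IRanges(start = di$domain_start + 1L, end = di$domain_end))
    for (k in seq_along(ov)) {
      q <- ci$name[S4Vectors::queryHits(ov)[k]]
      res[[q]] <- c(res[[q]], di$gene_id[S4Vectors::subjectHits(ov)[k]])
    }
  }
  res
}
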