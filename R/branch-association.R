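## Phylogeny-aware association between sequence divergence and a binary
## phenotype across independent loss lineages: a generalized least squares
## regression of per-species seqId on the loss indicator with
## Brownian-motion covariance derived from the tree. This approximates the
## branch-based forward-genomics association on species-level values.

#' Phylogeny-aware branch association for independent trait losses
#'
#' For each CNE, regresses the per-species normalized identity (seqId) on a
#' trait-loss indicator by generalized least squares with a
#' Brownian-motion covariance matrix from the tree, and reports the
#' one-sided p-value for the loss coefficient being negative (loss species
#' more diverged). CNEs with any loss species missing are excluded;
#' p-values are Benjamini-Hochberg adjusted across all tested CNEs.
#'
#' @param seq_ids numeric matrix, CNEs x species, of seqId values (NAs
#'   allowed for intact species); rownames are CNE ids.
#' @param tree a `cne_tree` or `phylo`.
#' @param phenotype named character vector over species with values
#'   `"loss"` or `"intact"`.
#' @param min_intact minimum intact species with data per CNE (default 4).
#' @return data.frame: `cne_id`, `statistic` (GLS t statistic),
#'   `p_value` (one-sided), `adjusted_p`. Excluded CNEs are absent.
#' @export
branch_association <- function(seq_ids, tree, phenotype, min_intact = 4) {
  phy <- if (inherits(tree, "cne_tree")) tree$tree else tree
  species <- colnames(seq_ids)
  if (is.null(species) || !all(species %in% phy$tip.label))
    abort_param("seq_ids columns must be named by tree leaves")
  if (!all(species %in% names(phenotype)))
    abort_param("phenotype missing for some species")
  loss_sp <- names(phenotype)[phenotype == "loss"]
  loss_sp <- intersect(loss_sp, species)
  if (length(loss_sp) < 2L)
    abort_param("need >= 2 trait-loss species")

  V_full <- ape::vcv(phy)[species, species]

  ids <- rownames(seq_ids) %||% as.character(seq_len(nrow(seq_ids)))
  res <- lapply(seq_len(nrow(seq_ids)), function(i) {
    y <- seq_ids[i, ]
    ok <- is.finite(y)
    if (!all(loss_sp %in% species[ok])) return(NULL)
    sp <- species[ok]
    if (sum(phenotype[sp] == "intact") < min_intact) return(NULL)
    x <- as.numeric(phenotype[sp] == "loss")
    X <- cbind(1, x)
    V <- V_full[sp, sp]
    fit <- tryCatch({
      Vi <- solve(V)
      XtVi <- crossprod(X, Vi)
      beta <- solve(XtVi %*% X, XtVi %*% y[sp])
      r <- y[sp] - X %*% beta
      df <- length(sp) - 2L
      sigma2 <- as.numeric(crossprod(r, Vi %*% r)) / df
      se <- sqrt(sigma2 * solve(XtVi %*% X)[2, 2])
      tstat <- beta[2] / se
      c(tstat, stats::pt(tstat, df))  # one-sided: loss coefficient < 0
    }, error = function(e) {
      warning(sprintf("CNE %s: singular covariance, skipped", ids[i]),
              call. = FALSE)
      NULL
    })
    if (is.null(fit)) return(NULL)
    data.frame(cne_id = ids[i], statistic = fit[1], p_value = fit[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(cne_id = character(0), statistic = numeric(0),
                      p_value = numeric(0), adjusted_p = numeric(0)))
  out$adjusted_p <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
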