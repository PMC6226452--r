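## Marginal maximum-likelihood ancestral sequence reconstruction under
## Jukes-Cantor, column-vectorized over alignment positions.

## 4x4 JC transition probability matrix for branch length t
jc_pmat <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- (1 - same) / 3
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

#' Reconstruct the ancestral sequence of a CNE alignment
#'
#' Per-column marginal maximum-likelihood reconstruction under the
#' Jukes-Cantor model with the tree's branch lengths (Felsenstein pruning,
#' uniform root prior). Gaps are treated as a fifth, presence/absence
#' character: Fitch parsimony on gap vs base decides whether the ancestral
#' column is a gap (ties resolved towards a base), and leaves that carry a
#' gap or N in a column are treated as missing data in the nucleotide
#' likelihood. Ties between nucleotide states are broken by the fixed base
#' order A < C < G < T.
#'
#' @param alignment a `cne_alignment` (all gapped sequences equal length;
#'   species must be tree leaves).
#' @param tree a `cne_tree` or `phylo` object with branch lengths.
#' @param ancestor_node internal node number (phylo numbering) at which the
#'   marginal reconstruction is taken; defaults to the root. Because the
#'   model is reversible, a non-root ancestor is handled by re-rooting.
#' @return the ancestral gapped sequence as a single character string.
#' @export
reconstruct_ancestral <- function(alignment, tree, ancestor_node = NULL) {
  phy <- if (inherits(tree, "cne_tree")) tree$tree else tree
  species <- names(alignment$seqs)
  if (!all(species %in% phy$tip.label))
    abort_param("alignment species are not all leaves of the tree")
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  if (!is.null(ancestor_node) && ancestor_node != root) {
    phy <- ape::read.tree(text = ape::write.tree(
      ape::root(phy, node = ancestor_node, resolve.root = FALSE)))
    root <- length(phy$tip.label) + 1L
  }
  ## drop tips absent from the alignment (missing genomic sequence)
  absent <- setdiff(phy$tip.label, species)
  if (length(absent)) {
    if (length(species) < 3L)
      abort_param("need >= 3 species present to reconstruct")
    phy <- ape::drop.tip(phy, absent)
    n_tip <- length(phy$tip.label)
    root <- n_tip + 1L
  }

  mat <- do.call(rbind, lapply(phy$tip.label,
                               function(sp) encode_dna(alignment$seqs[[sp]])))
  ncol_aln <- ncol(mat)
  lens <- nchar(alignment$seqs)
  if (length(unique(lens)) != 1L)
    abort_param("gapped sequences differ in length")

  porder <- ape::postorder(phy)
  n_node <- n_tip + phy$Nnode

  ## --- nucleotide likelihoods, gap/N as missing data ------------------
  lik <- vector("list", n_node)      # each: 4 x ncol matrix of partials
  for (k in seq_len(n_tip)) {
    m <- matrix(1, 4, ncol_aln)
    v <- mat[k, ]
    base_col <- which(!is.na(v) & v <= 4L)
    if (length(base_col)) {
      m[, base_col] <- 0
      m[cbind(v[base_col], base_col)] <- 1
    }
    lik[[k]] <- m
  }
  for (e in porder) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    pm <- jc_pmat(phy$edge.length[e])
    contrib <- pm %*% lik[[ch]]
    lik[[p]] <- if (is.null(lik[[p]])) contrib else lik[[p]] * contrib
  }
  root_post <- lik[[root]]           # uniform prior cancels in argmax
  anc_base <- apply(root_post, 2, which.max)  # first max: A<C<G<T tie-break

  ## --- gap state by Fitch parsimony on presence/absence ---------------
  ## state sets coded as bitmask: 1 = base present, 2 = gap
  fitch <- matrix(0L, n_node, ncol_aln)
  fitch[seq_len(n_tip), ] <- ifelse(is.na(mat) | mat <= 4L, 1L, 2L)
  for (e in porder) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    if (all(fitch[p, ] == 0L)) {
      fitch[p, ] <- fitch[ch, ]
    } else {
      inter <- bitwAnd(fitch[p, ], fitch[ch, ])
      uni <- bitwOr(fitch[p, ], fitch[ch, ])
      fitch[p, ] <- ifelse(inter > 0L, inter, uni)
    }
  }
  ## ambiguous root (3) resolved towards presence of a base
  anc_gap <- fitch[root, ] == 2L

  out <- BASES[anc_base]
  out[anc_gap] <- "-"
  paste(out, collapse = "")
}
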