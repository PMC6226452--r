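## Fixture phylogenies with designated trait-loss lineages.

## Recursively build a random binary subtree over `labels` whose total height
## (stem edge included) is `height`. Returns a newick fragment ending in
## ':stem_length', suitable for composition.
build_subtree <- function(labels, height) {
  if (length(labels) == 1L)
    return(sprintf("%s:%.6f", labels, height))
  labels <- sample(labels)
  split_at <- sample(seq_len(length(labels) - 1L), 1L)
  left <- labels[seq_len(split_at)]
  right <- labels[-seq_len(split_at)]
  h <- height * stats::runif(1, 0.2, 0.8)
  sprintf("(%s,%s):%.6f", build_subtree(left, h), build_subtree(right, h),
          height - h)
}

#' Generate a fixture phylogeny with trait-loss lineages
#'
#' Builds a random binary tree over `n_other_species` intact species plus
#' `n_loss_species` trait-loss species, with root-to-tip heights on the
#' order of `depth` substitutions per neutral site. By default the loss
#' species form a single clade (one evolutionary loss, as for limbless
#' snakes), nested inside the tree with a small group of close relatives
#' that serve as the local Z-score comparison set. With `scattered = TRUE`
#' each loss species is instead grafted as the sister of a different intact
#' species, emulating independent trait losses (as for subterranean
#' mammals).
#'
#' @param n_other_species number of intact species (>= 3).
#' @param n_loss_species number of trait-loss species (>= 1).
#' @param depth approximate root-to-tip height in substitutions per site.
#' @param seed integer seed; identical seeds give byte-identical newick.
#' @param scattered logical; scatter loss species instead of one clade.
#' @return An object of class `cne_tree`: a list with elements `tree` (an
#'   `ape` `phylo`), `newick`, `species`, `loss_species` and
#'   `local_species` (close relatives of the loss lineages, used for the
#'   local Z-score).
#' @examples
#' tr <- generate_fixture_tree(6, 2, 0.5, seed = 1)
#' tr$loss_species
#' @export
generate_fixture_tree <- function(n_other_species, n_loss_species, depth,
                                  seed, scattered = FALSE) {
  n_other_species <- check_count(n_other_species, "n_other_species", 3L)
  n_loss_species <- check_count(n_loss_species, "n_loss_species", 1L)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    abort_param("`depth` must be a single positive number")
  set.seed(check_count(seed, "seed", 0L))

  others <- sprintf("sp%02d", seq_len(n_other_species))
  losses <- sprintf("loss%02d", seq_len(n_loss_species))

  if (!scattered) {
    n_near <- max(1L, min(3L, n_other_species - 2L))
    near <- others[seq_len(n_near)]
    far <- others[-seq_len(n_near)]
    h1 <- depth * stats::runif(1, 0.4, 0.7)
    inner <- sprintf("(%s,%s):%.6f",
                     build_subtree(losses, h1 * stats::runif(1, 0.4, 0.8)),
                     build_subtree(near, h1 * stats::runif(1, 0.4, 0.8)),
                     depth - h1)
    nwk <- sprintf("(%s,%s);", inner,
                   build_subtree(far, depth * stats::runif(1, 0.6, 0.95)))
    local_species <- near
  } else {
    if (n_loss_species > n_other_species)
      abort_param("scattered placement needs n_other_species >= n_loss_species")
    nwk <- sprintf("(%s);", build_subtree(others, depth))
    hosts <- sample(others, n_loss_species)
    ## split each host's terminal edge and attach the loss species as sister
    for (i in seq_along(losses)) {
      pat <- sprintf("%s:([0-9.]+)", hosts[i])
      m <- regmatches(nwk, regexec(pat, nwk))[[1]]
      len <- as.numeric(m[2])
      h <- len * stats::runif(1, 0.3, 0.7)
      rep <- sprintf("(%s:%.6f,%s:%.6f):%.6f", hosts[i], h, losses[i], h,
                     len - h)
      nwk <- sub(pat, rep, nwk)
    }
    local_species <- hosts
  }

  tree <- ape::read.tree(text = nwk)
  structure(list(tree = tree,
                 newick = ape::write.tree(tree),
                 species = tree$tip.label,
                 loss_species = losses,
                 local_species = local_species),
            class = "cne_tree")
}

#' @export
print.cne_tree <- function(x, ...) {
  cat(sprintf("<cne_tree> %d species (%d trait-loss: %s)\n",
              length(x$species), length(x$loss_species),
              paste(x$loss_species, collapse = ", ")))
  invisible(x)
}

## list: node id -> integer vector of descendant tip indices
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (i in ape::postorder(tree)) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

## logical over edges: entire descendant leaf set within loss_species
loss_exclusive_edges <- function(tree, loss_species) {
  desc <- descendant_tips(tree)
  vapply(seq_len(nrow(tree$edge)), function(i) {
    tips <- desc[[tree$edge[i, 2]]]
    all(tree$tip.label[tips] %in% loss_species)
  }, logical(1))
}

## distance from each tip to the root, named by tip label
tip_root_distance <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}
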