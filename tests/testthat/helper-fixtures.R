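## Shared fixtures and independent oracles.

make_alignment <- function(seqs, id = "cne1", chrom = "chr1",
                           start = 0, ancestral = NULL) {
  structure(list(cne_id = id, chrom = chrom, start = start,
                 end = start + nchar(seqs[[1]]), seqs = seqs,
                 ancestral = ancestral),
            class = "cne_alignment")
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## Exhaustive-enumeration oracle for marginal ancestral reconstruction at
## the root under Jukes-Cantor: sums the likelihood over all assignments
## of states to the internal nodes. Gap-free alignments only.
jc_p <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  m <- matrix((1 - same) / 3, 4, 4); diag(m) <- same
  m
}

enumerate_ancestral <- function(aln_mat, tree) {
  ## aln_mat: integer matrix (tips x columns), rownames = tip labels
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  pmats <- lapply(seq_len(nrow(tree$edge)),
                  function(e) jc_p(tree$edge.length[e]))
  n_int <- length(internal)
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  apply(aln_mat, 2, function(col) {
    marg <- numeric(4)
    for (g in seq_len(nrow(grid))) {
      states <- integer(n_tip + tree$Nnode)
      states[match(tree$tip.label, tree$tip.label)] <- col
      states[internal] <- grid[g, ]
      lk <- 0.25   # uniform root prior
      for (e in seq_len(nrow(tree$edge))) {
        p <- states[tree$edge[e, 1]]; ch <- states[tree$edge[e, 2]]
        lk <- lk * pmats[[e]][p, ch]
      }
      root_state <- grid[g, 1]   # first internal node is the root
      marg[root_state] <- marg[root_state] + lk
    }
    which.max(marg)
  })
}

## Direct-enumeration hypergeometric tail: P(X >= a) for a 2x2 table with
## foreground size n1 = a + b, background size n2 = c + d, in-set K = a + c.
hyper_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n1 <- a + b
  ks <- max(0, n1 - (N - K)):min(K, n1)
  probs <- choose(K, ks) * choose(N - K, n1 - ks) / choose(N, n1)
  sum(probs[ks >= a])
}

## names of intervals in `a` overlapping any interval in `b` (independent
## of package internals)
overlapping_names_in_test <- function(a, b) {
  hits <- character(0)
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i]
    if (any(same)) hits <- c(hits, a$name[i])
  }
  hits
}

random_dna_for_test <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

write_read_meme_roundtrip_ids <- function(lib) {
  f <- tempfile(fileext = ".meme")
  write_meme(lib, f)
  vapply(read_meme(f), `[[`, character(1), "id")
}

## Small fixture tree reused across screen tests
fixture_tree_12 <- function(seed = 21) {
  generate_fixture_tree(10, 2, 0.5, seed = seed)
}
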