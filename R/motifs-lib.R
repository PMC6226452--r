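## Position probability matrices: synthesis, MEME-like text IO, information
## content, and the IC-binned column randomization control.

#' Construct a PWM object
#'
#' @param id motif id.
#' @param mat 4 x L matrix of column base probabilities (rows A, C, G, T);
#'   every column must sum to 1 within 1e-9.
#' @return object of class `pwm`.
#' @export
pwm <- function(id, mat) {
  if (nrow(mat) != 4L || ncol(mat) < 4L)
    abort_param("PWM must be 4 rows (A,C,G,T) x >= 4 columns")
  if (any(mat < 0) || any(abs(colSums(mat) - 1) > 1e-9))
    abort_param("PWM columns must be probabilities summing to 1")
  rownames(mat) <- BASES
  structure(list(id = id, mat = mat), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, %d columns, total IC %.2f bits\n", x$id,
              ncol(x$mat), sum(apply(x$mat, 2, column_ic))))
  invisible(x)
}

#' Information content of a PWM column
#'
#' `IC = 2 + sum(p * log2 p)` bits with `0 * log 0 = 0`; ranges from 0
#' (uniform column) to 2 (deterministic column).
#'
#' @param column numeric vector of 4 base probabilities summing to 1.
#' @return bits in `[0, 2]`.
#' @export
column_ic <- function(column) {
  if (length(column) != 4L || any(column < 0) ||
      abs(sum(column) - 1) > 1e-6)
    abort_param("column must be 4 probabilities summing to 1")
  lg <- ifelse(column > 0, log2(column), 0)
  2 + sum(column * lg)
}

#' Generate a synthetic motif library
#'
#' Draws each PWM column from a Dirichlet distribution whose concentration
#' varies log-uniformly per column, so that information content varies
#' across columns (flat and sharp columns both occur).
#'
#' @param n_motifs number of motifs.
#' @param length_range integer range of motif lengths (min >= 4).
#' @param seed integer seed.
#' @return list of `pwm` objects.
#' @export
generate_motif_library <- function(n_motifs, length_range = c(6, 15), seed) {
  n_motifs <- check_count(n_motifs, "n_motifs")
  if (length(length_range) != 2L || length_range[1] < 4L ||
      length_range[2] < length_range[1])
    abort_param("`length_range` must be an increasing pair with min >= 4")
  set.seed(check_count(seed, "seed", 0L))
  lapply(seq_len(n_motifs), function(i) {
    L <- sample(seq(length_range[1], length_range[2]), 1)
    cols <- vapply(seq_len(L), function(j) {
      conc <- 10^stats::runif(1, -1, 0.7)   # sharp .. flat columns
      g <- stats::rgamma(4, shape = conc)
      if (sum(g) == 0) g <- rep(1, 4)
      g / sum(g)
    }, numeric(4))
    pwm(sprintf("motif%03d", i), cols)
  })
}

#' Write motifs as MEME-like text
#'
#' Minimal MEME motif format: version header, alphabet, background, and
#' one letter-probability matrix per motif.
#'
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (p in pwms) {
    lines <- c(lines, sprintf("MOTIF %s", p$id),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p$mat)),
               apply(p$mat, 2, function(col)
                 paste(sprintf("%.6f", col), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read MEME-like motif text
#'
#' @param path file path.
#' @return list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(s) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + 1L
    while (h <= length(lines) && !grepl("^letter-probability", lines[h]))
      h <- h + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    mat <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4))
    ## renormalize against rounding in the text representation
    mat <- sweep(unname(mat), 2, colSums(mat), "/")
    pwm(id, mat)
  })
}

#' IC-binned column randomization of motifs
#'
#' Pools all columns of the library, ranks them by information content
#' into `n_ic_bins` equal-frequency bins, and rebuilds every motif by
#' replacing each of its columns with a uniformly drawn column from the
#' same IC bin. Motif lengths are preserved; this destroys base
#' preferences while conserving the IC profile.
#'
#' @param library list of `pwm` objects.
#' @param n_ic_bins number of IC bins (default 20).
#' @param seed integer seed.
#' @return list of randomized `pwm` objects (ids suffixed `_rand`).
#' @export
randomize_motifs <- function(library, n_ic_bins = 20, seed = 1) {
  n_ic_bins <- check_count(n_ic_bins, "n_ic_bins")
  pool <- do.call(cbind, lapply(library, function(p) p$mat))
  if (ncol(pool) < n_ic_bins)
    abort_param("library has fewer columns than IC bins")
  ic <- apply(pool, 2, column_ic)
  ## equal-frequency bins by IC rank (ties broken by column order)
  rnk <- rank(ic, ties.method = "first")
  bin <- ceiling(rnk / (length(ic) / n_ic_bins))
  by_bin <- split(seq_along(ic), bin)
  set.seed(check_count(seed, "seed", 0L))
  col_idx <- 0L
  lapply(library, function(p) {
    L <- ncol(p$mat)
    new_cols <- vapply(seq_len(L), function(j) {
      col_idx <<- col_idx + 1L
      cand <- by_bin[[as.character(bin[col_idx])]]
      pool[, cand[sample.int(length(cand), 1)]]
    }, numeric(4))
    pwm(paste0(p$id, "_rand"), new_cols)
  })
}
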