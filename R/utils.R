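#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_param <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    abort_param(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi)
    abort_param(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  as.numeric(x)
}

#' Derive a reproducible stage seed from a master seed
#'
#' Mixes a master seed with a text label so that pipeline stages draw from
#' independent but fully reproducible random streams.
#'
#' @param master single integer master seed.
#' @param label character scalar (for example a stage name).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  master <- check_count(master, "master", min = 0L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100003L
  as.integer((as.double(master) * 7919 + h * 104729) %% (2^31 - 1000))
}

## uppercase DNA string -> integer vector: A=1 C=2 G=3 T=4, '-'=5, N/other=NA
encode_dna <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c(BASES, "-"))
  v
}

decode_dna <- function(v) {
  out <- c(BASES, "-")[v]
  out[is.na(v)] <- "N"
  paste(out, collapse = "")
}

## random DNA of given GC content; consumes the current RNG stream
random_dna <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

gc_content <- function(seq) {
  v <- encode_dna(seq)
  v <- v[!is.na(v) & v <= 4L]
  if (length(v) == 0L) return(NA_real_)
  mean(v == 2L | v == 3L)
}

#' Read a BED file into a data frame
#'
#' Columns beyond the first three are mapped to `name`, `score`, `strand`
#' when present. Coordinates stay 0-based half-open.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- nm[seq_len(ncol(df))]
  bad <- which(!(df$start >= 0 & df$end > df$start))
  if (length(bad))
    abort_param(sprintf("malformed interval at line %d of %s", bad[1], path))
  df
}

#' Write a data frame of intervals as BED
#'
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

sort_bed <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
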