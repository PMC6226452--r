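## False discovery rate estimates for the divergence screen.

#' Simulation-based FDR estimate
#'
#' Scales the pass rate of a constrained (null) simulation to the screened
#' set: `fpr = n_null_pass / n_null_total`, `expected_fp = fpr *
#' n_screened`, `fdr = expected_fp / n_called`.
#'
#' @param n_null_pass simulated null CNEs passing the full screen.
#' @param n_null_total simulated null CNEs screened.
#' @param n_screened real CNEs screened.
#' @param n_called real CNEs called diverged.
#' @return object of class `fdr_estimate`: list with
#'   `false_positive_rate`, `expected_false_positives`, `fdr` (all
#'   fractions/counts, not percentages).
#' @examples
#' simulation_fdr(40, 38090, 164422, 5439)
#' @export
simulation_fdr <- function(n_null_pass, n_null_total, n_screened, n_called) {
  n_null_pass <- check_count(n_null_pass, "n_null_pass", 0L)
  n_null_total <- check_count(n_null_total, "n_null_total", 1L)
  n_screened <- check_count(n_screened, "n_screened", 1L)
  n_called <- check_count(n_called, "n_called", 1L)
  fpr <- n_null_pass / n_null_total
  efp <- fpr * n_screened
  structure(list(false_positive_rate = fpr,
                 expected_false_positives = efp,
                 fdr = efp / n_called),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(paste0("FDR estimate: false-positive rate %.3f%%, ",
                     "%.1f expected false positives, FDR %.2f%%\n"),
              100 * x$false_positive_rate, x$expected_false_positives,
              100 * x$fdr))
  invisible(x)
}

#' Sister-lineage upper bound on the FDR
#'
#' Assumes every CNE called diverged in a matched sister-lineage control
#' screen is a false positive, giving the conservative bound
#' `n_control_called / n_called`.
#'
#' @param n_control_called CNEs called diverged in the sister-lineage
#'   control screen.
#' @param n_called CNEs called diverged in the trait-loss screen.
#' @return upper-bound FDR as a fraction.
#' @examples
#' sister_bound_fdr(616, 5439)  # 0.1133
#' @export
sister_bound_fdr <- function(n_control_called, n_called) {
  n_control_called <- check_count(n_control_called, "n_control_called", 0L)
  n_called <- check_count(n_called, "n_called", 1L)
  n_control_called / n_called
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, preserving input
#' order; a validating wrapper around [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    abort_param("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
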