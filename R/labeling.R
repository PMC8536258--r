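# Independent-recombination binomial labeling model.

#' Per-cell labeling probability from the unlabeled-ovariole fraction
#'
#' Under independent recombination events, each of `n_targets` dividing
#' precursor cells in an ovariole is labeled with the same probability `p`, so
#' the chance that an ovariole carries no clone is `(1 - p)^n_targets`.
#' Inverting the observed unlabeled fraction gives `p`.
#'
#' @param unlabeled_fraction observed fraction of ovarioles with no marked
#'   cells, in (0, 1].
#' @param n_targets assumed number of dividing precursor cells per ovariole.
#' @return the per-cell labeling probability.
#' @examples
#' infer_per_cell_probability(0.4, 6)    # ~0.14
#' infer_per_cell_probability(0.53, 20)  # ~0.031
#' @export
infer_per_cell_probability <- function(unlabeled_fraction, n_targets) {
  if (n_targets < 1 || n_targets != round(n_targets)) {
    stop("'n_targets' must be a positive integer")
  }
  if (unlabeled_fraction <= 0) {
    stop("degenerate input: unlabeled_fraction must be > 0 ",
         "(p is defined at 1 only in the limit)")
  }
  if (unlabeled_fraction > 1) stop("'unlabeled_fraction' must be <= 1")
  1 - unlabeled_fraction^(1 / n_targets)
}

#' Expected fraction of single-cell lineages among marked ovarioles
#'
#' With `n` target cells each labeled independently with probability `p`, the
#' chance that exactly one cell in an ovariole is labeled is
#' `n * p * (1 - p)^(n - 1)`. Dividing by the labeled-ovariole fraction gives
#' the expected proportion of marked ovarioles whose marks derive from a single
#' cell.
#'
#' The supplied `labeled_fraction` is used in the denominator as given, which
#' mirrors the desk arithmetic this model supports; if it is inconsistent with
#' `(p, n)` by more than 0.02 a warning is issued. With `strict = TRUE` the
#' labeled fraction is instead recomputed as `1 - (1 - p)^n`.
#'
#' @param p_cell per-cell labeling probability.
#' @param n_targets number of target cells.
#' @param labeled_fraction observed fraction of ovarioles with any marked cell.
#' @param strict recompute the labeled fraction from `(p_cell, n_targets)`
#'   instead of trusting the supplied value.
#' @return expected single-lineage fraction. Values above 1 (possible only for
#'   inconsistent inputs) are returned as-is with a warning, never clamped.
#' @examples
#' single_lineage_fraction(0.14, 6, 0.6)     # ~0.66
#' single_lineage_fraction(0.031, 20, 0.47)  # ~0.72
#' @export
single_lineage_fraction <- function(p_cell, n_targets, labeled_fraction,
                                    strict = FALSE) {
  stopifnot(p_cell >= 0, p_cell <= 1, n_targets >= 1)
  if (!strict && labeled_fraction <= 0) {
    stop("division undefined: labeled_fraction must be > 0")
  }
  implied <- 1 - (1 - p_cell)^n_targets
  if (strict) {
    labeled_fraction <- implied
    if (labeled_fraction <= 0) stop("p_cell = 0 labels nothing")
  } else if (abs(implied - labeled_fraction) > 0.02) {
    warning(sprintf(
      "labeled_fraction %.3f is inconsistent with (p, n) which imply %.3f; %s",
      labeled_fraction, implied, "proceeding with the supplied value"))
  }
  out <- n_targets * p_cell * (1 - p_cell)^(n_targets - 1) / labeled_fraction
  if (out > 1) {
    warning(sprintf("single-lineage fraction %.3f exceeds 1 (inconsistent inputs)",
                    out))
  }
  out
}

#' Binomial labeling estimate for one experiment
#'
#' Convenience wrapper chaining [infer_per_cell_probability()] and
#' [single_lineage_fraction()] from the observed unlabeled fraction.
#'
#' @inheritParams infer_per_cell_probability
#' @return a `labeling_estimate` object with components `n_targets`, `p_cell`,
#'   `labeled_fraction` and `single_fraction`.
#' @examples
#' labeling_estimate(0.4, 6)
#' @export
labeling_estimate <- function(unlabeled_fraction, n_targets) {
  p <- infer_per_cell_probability(unlabeled_fraction, n_targets)
  labeled <- 1 - unlabeled_fraction
  single <- if (labeled > 0) {
    single_lineage_fraction(p, n_targets, labeled)
  } else {
    NA_real_
  }
  structure(list(n_targets = n_targets, p_cell = p,
                 labeled_fraction = labeled, single_fraction = single),
            class = "labeling_estimate")
}

#' @export
print.labeling_estimate <- function(x, ...) {
  cat(sprintf(
    "Binomial labeling model (%d target cells):\n  p(cell labeled) = %.4f\n  labeled ovarioles = %.3f\n  single-lineage fraction among marked = %.3f\n",
    x$n_targets, x$p_cell, x$labeled_fraction, x$single_fraction))
  invisible(x)
}
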