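# Per-lineage yield disaggregation and the 16-FSC-normalized precursor census.

#' Per-single-lineage mean cell yields
#'
#' @param ec_per_ec_lineage mean marked ECs produced by an EC-only lineage.
#' @param fsc_per_fsc_lineage mean marked FSCs produced by an FSC-only lineage.
#' @param ec_per_ecfsc_lineage mean marked ECs produced by an EC/FSC lineage.
#' @param fsc_per_ecfsc_lineage mean marked FSCs produced by an EC/FSC lineage.
#' @return a `per_lineage_yields` object. FC-only lineages carry no cell-yield
#'   accounting: marked FCs are scored by location, not count, and never enter
#'   the census arithmetic.
#' @export
per_lineage_yields <- function(ec_per_ec_lineage, fsc_per_fsc_lineage,
                               ec_per_ecfsc_lineage = NA_real_,
                               fsc_per_ecfsc_lineage = NA_real_) {
  v <- c(ec_per_ec_lineage, fsc_per_fsc_lineage,
         ec_per_ecfsc_lineage, fsc_per_ecfsc_lineage)
  if (any(v < 0, na.rm = TRUE)) stop("yields must be non-negative")
  structure(list(ec_per_ec_lineage = ec_per_ec_lineage,
                 fsc_per_fsc_lineage = fsc_per_fsc_lineage,
                 ec_per_ecfsc_lineage = ec_per_ecfsc_lineage,
                 fsc_per_ecfsc_lineage = fsc_per_ecfsc_lineage),
            class = "per_lineage_yields")
}

#' @export
print.per_lineage_yields <- function(x, ...) {
  cat(sprintf(
    "Per-lineage yields:\n  ECs/EC-only %.2f   FSCs/FSC-only %.2f   ECs/EC-FSC %.2f   FSCs/EC-FSC %.2f\n",
    x$ec_per_ec_lineage, x$fsc_per_fsc_lineage,
    x$ec_per_ecfsc_lineage, x$fsc_per_ecfsc_lineage))
  invisible(x)
}

#' Composition of double-lineage ovarioles within a pure category
#'
#' An ovariole observed as EC-only can hide either two EC-only lineages or an
#' (EC-only, FC-only) pair, because FC-only lineages leave no trace in that
#' category's defining counts (and likewise for FSC-only ovarioles). Among
#' double-lineage ovarioles in the category, the same-type and cross-type
#' proportions are `p^2 : 2 p p_fc` renormalized, where `p` is the focal
#' lineage frequency. The mean number of focal lineages per category ovariole
#' is then `sigma + (1 - sigma) * (2 w_same + w_cross)`.
#'
#' @param freqs a [lineage_frequencies()] object.
#' @param sigma single-lineage fraction.
#' @param category `"EC_only"` or `"FSC_only"`.
#' @return list with `w_same`, `w_cross` and `lineages_per_ovariole`.
#' @examples
#' f <- lineage_frequencies(0.63, 0.13, 0.05, 0.19)
#' category_pair_composition(f, 0.3, "EC_only")  # ~ (0.624, 0.376), 1.44
#' @export
category_pair_composition <- function(freqs, sigma,
                                      category = c("EC_only", "FSC_only")) {
  stopifnot(inherits(freqs, "lineage_frequencies"), sigma >= 0, sigma <= 1)
  category <- match.arg(category)
  p <- if (category == "EC_only") freqs$p_ec else freqs$p_fsc
  same <- p^2
  cross <- 2 * p * freqs$p_fc
  if (same + cross == 0) {
    stop("undefined composition: no double-lineage ovarioles can appear in ",
         category, " with these frequencies")
  }
  w_same <- same / (same + cross)
  w_cross <- cross / (same + cross)
  list(w_same = w_same, w_cross = w_cross,
       lineages_per_ovariole = sigma + (1 - sigma) * (2 * w_same + w_cross))
}

#' Mean yield per single lineage from a per-ovariole mean
#'
#' @param observed_mean_per_ovariole mean marked cells per category ovariole.
#' @param lineages_per_ovariole mean focal lineages per category ovariole, from
#'   [category_pair_composition()].
#' @return the per-lineage mean yield (the quotient).
#' @examples
#' per_lineage_yield(2.53, 1.44)  # ~1.76 ECs per EC-only lineage
#' @export
per_lineage_yield <- function(observed_mean_per_ovariole,
                              lineages_per_ovariole) {
  if (lineages_per_ovariole <= 0) stop("lineages_per_ovariole must be > 0")
  observed_mean_per_ovariole / lineages_per_ovariole
}

#' EC/FSC lineage yields by subtraction from experiment totals
#'
#' EC/FSC lineages are never observed pure, so their yields are obtained by
#' accounting: the total number of marked lineages is
#' `n_marked * (2 - sigma)`, the EC output of EC-only lineages and the FSC
#' output of FSC-only lineages are subtracted from the experiment totals, and
#' the remainders are divided by the number of EC/FSC lineages.
#'
#' @param table a [clone_category_table()] with `total_ec` and `total_fsc`.
#' @param freqs a [lineage_frequencies()] object.
#' @param sigma single-lineage fraction.
#' @param yields_so_far a [per_lineage_yields()] carrying the EC-only and
#'   FSC-only per-lineage yields.
#' @return the completed [per_lineage_yields()], with the total lineage count
#'   in attribute `total_lineages`.
#' @export
ecfsc_yields_by_subtraction <- function(table, freqs, sigma, yields_so_far) {
  stopifnot(inherits(table, "clone_category_table"),
            inherits(freqs, "lineage_frequencies"),
            inherits(yields_so_far, "per_lineage_yields"))
  if (freqs$p_ecfsc <= 0) stop("p_ecfsc must be > 0 to attribute any yield")
  total_lineages <- table$n_marked * (2 - sigma)
  n_ecfsc <- total_lineages * freqs$p_ecfsc
  ec_rest <- table$total_ec -
    total_lineages * freqs$p_ec * yields_so_far$ec_per_ec_lineage
  fsc_rest <- table$total_fsc -
    total_lineages * freqs$p_fsc * yields_so_far$fsc_per_fsc_lineage
  if (ec_rest < 0 || fsc_rest < 0) {
    stop(sprintf(paste0(
      "inconsistent inputs: subtraction residuals are negative ",
      "(EC remainder %.2f of %.0f total; FSC remainder %.2f of %.0f total; ",
      "%.1f lineages assumed)"),
      ec_rest, table$total_ec, fsc_rest, table$total_fsc, total_lineages))
  }
  out <- per_lineage_yields(
    ec_per_ec_lineage = yields_so_far$ec_per_ec_lineage,
    fsc_per_fsc_lineage = yields_so_far$fsc_per_fsc_lineage,
    ec_per_ecfsc_lineage = ec_rest / n_ecfsc,
    fsc_per_ecfsc_lineage = fsc_rest / n_ecfsc
  )
  attr(out, "total_lineages") <- total_lineages
  out
}

#' Precursor census normalized to 16 adult FSCs per germarium
#'
#' Only EC/FSC and FSC-only lineages produce FSCs, at mean rates `x` and `y`
#' per lineage. Requiring the average FSC output per precursor times the total
#' precursor count to equal the adult complement of 16 FSCs gives
#' `n_total = 16 / (p_ecfsc * x + p_fsc * y)`; per-type counts are the lineage
#' frequencies times `n_total`.
#'
#' @param freqs a [lineage_frequencies()] object.
#' @param yields a completed [per_lineage_yields()] (FSC yields present).
#' @param fsc_per_germarium normalization constant; 16 adult FSCs.
#' @return a `precursor_census` object with `n_total` and per-type counts
#'   `n_ec`, `n_ecfsc`, `n_fsc`, `n_fc`.
#' @export
precursor_census <- function(freqs, yields, fsc_per_germarium = 16) {
  stopifnot(inherits(freqs, "lineage_frequencies"),
            inherits(yields, "per_lineage_yields"))
  denom <- freqs$p_ecfsc * yields$fsc_per_ecfsc_lineage +
    freqs$p_fsc * yields$fsc_per_fsc_lineage
  if (is.na(denom) || denom <= 0) {
    stop("no FSC production: p_ecfsc*x + p_fsc*y must be > 0")
  }
  n_total <- fsc_per_germarium / denom
  structure(list(n_total = n_total,
                 n_ec = freqs$p_ec * n_total,
                 n_ecfsc = freqs$p_ecfsc * n_total,
                 n_fsc = freqs$p_fsc * n_total,
                 n_fc = freqs$p_fc * n_total,
                 fsc_normalization = fsc_per_germarium),
            class = "precursor_census")
}

#' @export
print.precursor_census <- function(x, ...) {
  cat(sprintf(
    "Precursor census (normalized to %g FSCs per germarium):\n  total dividing precursors n = %.1f\n  EC-only %.1f   EC/FSC %.1f   FSC-only %.1f   FC-only %.1f\n",
    x$fsc_normalization, x$n_total, x$n_ec, x$n_ecfsc, x$n_fsc, x$n_fc))
  invisible(x)
}

#' Per-germarium production of ECs from total marked-cell yields
#'
#' Scales the summed marked r1 EC, r2a EC and FSC counts of one clone-marking
#' time point to a per-germarium basis using 16 FSCs per germarium: cells of a
#' type made from dividing precursors = 16 * (marked cells of that type) /
#' (marked FSCs). Valid whether ovarioles carry one or several marked lineages,
#' because it only uses totals.
#'
#' @param x_r1 total marked region-1 ECs over all clones.
#' @param y_r2a total marked region-2a ECs.
#' @param z_fsc total marked FSCs; must be positive.
#' @return a `germarium_production` object with `r1_made`, `r2a_made` and
#'   `ec_made` (their sum).
#' @examples
#' germarium_production(20, 37, 69)  # ~ (4.6, 8.6, 13.2)
#' @export
germarium_production <- function(x_r1, y_r2a, z_fsc) {
  stopifnot(x_r1 >= 0, y_r2a >= 0)
  if (z_fsc <= 0) stop("z_fsc must be > 0")
  structure(list(x_r1 = x_r1, y_r2a = y_r2a, z_fsc = z_fsc,
                 r1_made = 16 * x_r1 / z_fsc,
                 r2a_made = 16 * y_r2a / z_fsc,
                 ec_made = 16 * (x_r1 + y_r2a) / z_fsc),
            class = "germarium_production")
}

#' @export
print.germarium_production <- function(x, ...) {
  cat(sprintf(
    "ECs made per germarium from dividing precursors (16 FSCs/germarium):\n  r1 %.1f   r2a %.1f   total %.1f  (from %g r1, %g r2a, %g FSC marked cells)\n",
    x$r1_made, x$r2a_made, x$ec_made, x$x_r1, x$y_r2a, x$z_fsc))
  invisible(x)
}

#' ECs whose precursors stopped dividing between two labeling times
#'
#' Only dividing precursors can found clones, so the drop in per-germarium EC
#' production between an early and a later clone-induction time estimates the
#' number of adult ECs whose precursors ceased dividing in the interval.
#'
#' @param production_early,production_late [germarium_production()] objects
#'   for the earlier and later induction times.
#' @return the difference in `ec_made` (early minus late). A negative value is
#'   returned as-is with a warning.
#' @export
nondividing_ec_estimate <- function(production_early, production_late) {
  stopifnot(inherits(production_early, "germarium_production"),
            inherits(production_late, "germarium_production"))
  out <- production_early$ec_made - production_late$ec_made
  if (out < 0) {
    warning("later time point shows higher EC production; estimate is negative")
  }
  out
}
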