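# Full pipeline: category table -> sigma decision -> deconvolution ->
# per-lineage yields -> precursor census, with report output.

#' Run the full precursor-census pipeline on a clone-category table
#'
#' Chains the stages: observed category frequencies, single-lineage fraction
#' decision, mixture deconvolution, yield disaggregation and the 16-FSC
#' precursor census.
#'
#' The `sigma` policy:
#' * a number in \[0, 1\]: fixed single-lineage fraction;
#' * `"auto"`: estimated on a grid from the EC+FC class
#'   ([estimate_single_fraction()]);
#' * `"all_double"`: sigma = 0, shared-category equations;
#' * `"all_double_ecfc"`: sigma = 0 with the EC+FC-anchored, category-exclusive
#'   variant ([solve_all_double_ecfc_anchored()]) used when FC-only ovarioles
#'   are essentially absent.
#'
#' The census total always satisfies the identity
#' `n_total = 16 * n_lineages / total_fsc`, because the EC/FSC FSC yield is
#' constructed by subtraction; the report records this.
#'
#' @param table a [clone_category_table()].
#' @param sigma sigma policy (see above).
#' @param grid_step grid spacing for `sigma = "auto"`.
#' @param fsc_per_germarium normalization constant (16 adult FSCs).
#' @return a `census_report` list with components `observed`, `sigma`,
#'   `freqs`, `composition`, `yields`, `total_lineages`, `census`,
#'   `table_row` (a one-row data frame shaped like a published summary row)
#'   and `notes`.
#' @examples
#' run_full_census(load_experiment("marcm_0h"), sigma = 0.3)
#' @export
run_full_census <- function(table, sigma = "auto", grid_step = 0.05,
                            fsc_per_germarium = 16) {
  stopifnot(inherits(table, "clone_category_table"))
  if (table$n_marked < 1) stop("empty input: no marked ovarioles")
  obs <- aggregate_frequencies(table)
  notes <- character(0)

  if (is.numeric(sigma)) {
    assumption <- mixture_assumption(sigma, mode = "fixed")
  } else {
    assumption <- switch(match.arg(sigma, c("auto", "all_double",
                                            "all_double_ecfc")),
      auto = estimate_single_fraction(obs, grid_step = grid_step),
      all_double = mixture_assumption(0, mode = "all_double"),
      all_double_ecfc = mixture_assumption(0, mode = "all_double")
    )
  }
  anchored <- identical(sigma, "all_double_ecfc")
  s <- assumption$sigma

  n <- stats::setNames(table$categories$n, table$categories$category)
  freqs <- if (anchored) {
    solve_all_double_ecfc_anchored(
      f_ec_only = n[["EC_only"]] / table$n_marked,
      f_ecfc = n[["EC_plus_FC"]] / table$n_marked,
      f_fsc_only = n[["FSC_only"]] / table$n_marked
    )
  } else {
    solve_lineage_frequencies(obs, s)
  }

  means <- stats::setNames(table$categories$mean_ec, table$categories$category)
  n_ec_cat <- n[["EC_only"]] + n[["EC_plus_FC"]]
  if (n_ec_cat == 0) stop("no EC-bearing, FSC-free ovarioles: EC yield undefined")
  ec_mean_obs <- (zero_na(means[["EC_only"]]) * n[["EC_only"]] +
                  zero_na(means[["EC_plus_FC"]]) * n[["EC_plus_FC"]]) / n_ec_cat
  fsc_means <- stats::setNames(table$categories$mean_fsc,
                               table$categories$category)
  fsc_mean_obs <- fsc_means[["FSC_only"]]
  if (freqs$p_fsc > 0 && (is.na(fsc_mean_obs) || n[["FSC_only"]] == 0)) {
    stop("FSC-only yield needed (p_fsc > 0) but no FSC-only ovarioles scored")
  }
  if (is.na(fsc_mean_obs)) fsc_mean_obs <- 0

  comp_ec <- category_pair_composition(freqs, s, "EC_only")
  comp_fsc <- if (freqs$p_fsc > 0) {
    category_pair_composition(freqs, s, "FSC_only")
  } else {
    list(w_same = NA_real_, w_cross = NA_real_, lineages_per_ovariole = 1)
  }
  base_yields <- per_lineage_yields(
    ec_per_ec_lineage = per_lineage_yield(ec_mean_obs,
                                          comp_ec$lineages_per_ovariole),
    fsc_per_fsc_lineage = per_lineage_yield(fsc_mean_obs,
                                            comp_fsc$lineages_per_ovariole)
  )
  yields <- ecfsc_yields_by_subtraction(table, freqs, s, base_yields)
  census <- precursor_census(freqs, yields, fsc_per_germarium)

  total_lineages <- attr(yields, "total_lineages")
  identity_n <- fsc_per_germarium * total_lineages / table$total_fsc
  if (abs(identity_n - census$n_total) > 1e-6) {
    notes <- c(notes, sprintf(
      "census total %.2f differs from the accounting identity 16*L/Z = %.2f",
      census$n_total, identity_n))
  }

  table_row <- data.frame(
    n_marked = table$n_marked, sigma = s,
    p_ec = freqs$p_ec, ec_yield = yields$ec_per_ec_lineage,
    p_ecfsc = freqs$p_ecfsc, ecfsc_ec_yield = yields$ec_per_ecfsc_lineage,
    ecfsc_fsc_yield = yields$fsc_per_ecfsc_lineage,
    p_fsc = freqs$p_fsc, fsc_yield = yields$fsc_per_fsc_lineage,
    p_fc = freqs$p_fc,
    n_total = census$n_total, n_ec = census$n_ec, n_ecfsc = census$n_ecfsc,
    n_fsc = census$n_fsc, n_fc = census$n_fc
  )

  structure(list(observed = obs, sigma = assumption, freqs = freqs,
                 composition = list(EC_only = comp_ec, FSC_only = comp_fsc),
                 yields = yields, total_lineages = total_lineages,
                 census = census, table_row = table_row, notes = notes),
            class = "census_report")
}

zero_na <- function(x) ifelse(is.na(x), 0, x)

#' @export
print.census_report <- function(x, ...) {
  print(x$observed)
  print(x$sigma)
  print(x$freqs)
  print(x$yields)
  cat(sprintf("Total marked lineages: %.1f\n", x$total_lineages))
  print(x$census)
  for (note in x$notes) cat("note:", note, "\n")
  invisible(x)
}

#' Serialize a census report (or any pipeline object) to JSON
#'
#' @param report a `census_report` (or other pipeline result built from lists).
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  x <- unclass_deep(report)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}

#' Per-germarium production estimates for a table of marked-cell totals
#'
#' Applies [germarium_production()] row-wise to a table of summed marked r1
#' EC, r2a EC and FSC counts (one row per clone-induction time).
#'
#' @param totals data frame with columns `x_r1`, `y_r2a`, `z_fsc` and any
#'   identifying columns (kept).
#' @return the input with `r1_made`, `r2a_made` and `ec_made` columns added.
#' @examples
#' table2_production(load_production_totals())
#' @export
table2_production <- function(totals) {
  stopifnot(all(c("x_r1", "y_r2a", "z_fsc") %in% names(totals)))
  prod <- mapply(function(x, y, z) {
    g <- germarium_production(x, y, z)
    c(g$r1_made, g$r2a_made, g$ec_made)
  }, totals$x_r1, totals$y_r2a, totals$z_fsc)
  totals$r1_made <- prod[1, ]
  totals$r2a_made <- prod[2, ]
  totals$ec_made <- prod[3, ]
  totals
}
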