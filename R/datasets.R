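# Bundled example datasets: aggregated clone-scoring summaries from published
# ovarian lineage-tracing experiments, used by the worked examples and tests.

#' Load a bundled clone-scoring experiment summary
#'
#' Four aggregated clone-category tables from ovarian clone-marking
#' experiments examined in newly eclosed adults:
#'
#' * `"marcm_0h"`: MARCM clones induced at pupariation (0 hr APF, 5 days
#'   before eclosion); 207 ovarioles scored, 98 marked.
#' * `"marcm_36h"`: MARCM clones induced at 36 hr APF; 121 marked ovarioles.
#' * `"multicolor"`: GFP-only clones from multicolor labeling at 0 hr APF;
#'   26 marked of 115 ovarioles.
#' * `"bond_gal4"`: bond-GAL4/G-TRACE lineages; 73 marked ovarioles (the
#'   unlabeled count was not reported and is stored as 0; it plays no role in
#'   the census).
#'
#' The FSC-only mean yields are stored at full precision where the summary
#' rounds them (e.g. 14 FSCs over 3 ovarioles for `"marcm_0h"`).
#'
#' @param name experiment name.
#' @return a [clone_category_table()].
#' @examples
#' load_experiment("marcm_0h")
#' @export
load_experiment <- function(name = c("marcm_0h", "marcm_36h", "multicolor",
                                     "bond_gal4")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "clonecensus",
                      mustWork = TRUE)
  read_category_table(path)
}

#' Load the bundled marked-cell totals time course
#'
#' Summed marked r1 EC, r2a EC and FSC counts over all clones for MARCM
#' inductions 2-6 days before eclosion, the input to [table2_production()].
#'
#' @return data frame with columns `days_before_eclosion`, `x_r1`, `y_r2a`,
#'   `z_fsc`.
#' @export
load_production_totals <- function() {
  path <- system.file("extdata", "production_totals.csv",
                      package = "clonecensus", mustWork = TRUE)
  utils::read.csv(path)
}
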