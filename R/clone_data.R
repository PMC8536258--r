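# Clone-scoring data model: per-ovariole records, category tables, observed
# category frequencies.

CLONE_CATEGORIES <- c("EC_only", "EC_FSC", "FSC_only", "FC_only", "EC_plus_FC")
FC_LOCATION_CODES <- c("I", "G", "E1", "E2", "E3", "E4")
BASAL_STALK_LEVELS <- c("yes", "no", "not_imaged")
SCORING_AGES <- c("eclosion_day0", "adult_day2")

#' Validate and normalize a table of per-ovariole clone-scoring records
#'
#' A records table has one row per scored ovariole with the marked-cell counts
#' by adult cell type and the locations of marked follicle cells (FCs). Marked
#' FCs are recorded by location code, not by count: `fc_locations` is a
#' semicolon-joined subset of `I` (immediately posterior to the Fas3 border,
#' region 2b), `G` (germarial, region 3) and `E1`--`E4` (egg chambers numbered
#' anterior to posterior, `E4` the most mature). An ovariole with no marked
#' cell of any type is retained and counted as unlabeled.
#'
#' @param records data frame with columns `ovariole_id`, `n_r1_ec`, `n_r2a_ec`,
#'   `n_fsc`, `fc_locations` (semicolon-joined codes, empty string or `NA` for
#'   none), and optionally `basal_stalk` (`"yes"`, `"no"`, `"not_imaged"`;
#'   default `"not_imaged"`), `scoring_age` (`"eclosion_day0"` or
#'   `"adult_day2"`; default `"eclosion_day0"`) and `fsc_inferred` (logical,
#'   set by [reclassify_day2_adult()]).
#' @return the records as a validated data frame with all optional columns
#'   filled in.
#' @seealso [read_ovariole_records()], [ingest_records()]
#' @export
ovariole_records <- function(records) {
  records <- as.data.frame(records)
  required <- c("ovariole_id", "n_r1_ec", "n_r2a_ec", "n_fsc", "fc_locations")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("missing record columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("n_r1_ec", "n_r2a_ec", "n_fsc")) {
    x <- records[[col]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != round(x))) {
      stop("malformed records: '", col, "' must hold non-negative integer counts")
    }
  }
  records$fc_locations <- ifelse(is.na(records$fc_locations), "",
                                 as.character(records$fc_locations))
  codes <- fc_location_list(records$fc_locations)
  bad <- !vapply(codes, function(x) all(x %in% FC_LOCATION_CODES), logical(1))
  if (any(bad)) {
    stop("malformed records: unknown FC location code(s) in row(s) ",
         paste(which(bad), collapse = ", "),
         " (allowed: ", paste(FC_LOCATION_CODES, collapse = ", "), ")")
  }
  if (is.null(records$basal_stalk)) records$basal_stalk <- "not_imaged"
  if (!all(records$basal_stalk %in% BASAL_STALK_LEVELS)) {
    stop("'basal_stalk' must be one of: ", paste(BASAL_STALK_LEVELS, collapse = ", "))
  }
  if (is.null(records$scoring_age)) records$scoring_age <- "eclosion_day0"
  if (!all(records$scoring_age %in% SCORING_AGES)) {
    stop("'scoring_age' must be one of: ", paste(SCORING_AGES, collapse = ", "))
  }
  if (is.null(records$fsc_inferred)) records$fsc_inferred <- FALSE
  records
}

fc_location_list <- function(fc_locations) {
  strsplit(ifelse(is.na(fc_locations), "", fc_locations), ";", fixed = TRUE)
}

#' Read per-ovariole clone-scoring records from a delimited text file
#'
#' @param file path to a delimited text file with a header row and one row per
#'   ovariole (see [ovariole_records()] for the columns).
#' @param sep field separator, comma by default.
#' @return validated records data frame.
#' @export
read_ovariole_records <- function(file, sep = ",") {
  ovariole_records(utils::read.table(file, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
}

# Category of each record. FSC presence takes priority; an EC+FC pattern
# without FSCs is the discontinuous two-lineage signature and is kept as its
# own category. Unlabeled rows get NA.
classify_records <- function(records) {
  ec <- records$n_r1_ec + records$n_r2a_ec > 0
  fsc <- records$n_fsc > 0 | records$fsc_inferred
  fc <- nchar(records$fc_locations) > 0
  category <- rep(NA_character_, nrow(records))
  category[fsc & ec] <- "EC_FSC"
  category[fsc & !ec] <- "FSC_only"
  category[!fsc & ec & fc] <- "EC_plus_FC"
  category[!fsc & ec & !fc] <- "EC_only"
  category[!fsc & !ec & fc] <- "FC_only"
  factor(category, levels = CLONE_CATEGORIES)
}

#' Build a clone-category table from per-ovariole records
#'
#' Assigns every record to exactly one clone category and computes per-category
#' ovariole counts and mean marked-cell yields, together with experiment-wide
#' totals of marked ECs and FSCs. The category scheme: any marked FSC makes the
#' ovariole `EC_FSC` (if any EC is marked) or `FSC_only`; otherwise marked ECs
#' and FCs together give `EC_plus_FC`, ECs alone `EC_only`, and FCs alone
#' `FC_only`. Ovarioles with no marked cells are counted as unlabeled.
#'
#' @param records records data frame, validated by [ovariole_records()].
#' @return a `clone_category_table` object.
#' @examples
#' recs <- data.frame(
#'   ovariole_id = 1:3, n_r1_ec = c(2, 0, 0), n_r2a_ec = c(1, 1, 0),
#'   n_fsc = c(0, 2, 0), fc_locations = c("", "I", "E3;E4"))
#' ingest_records(ovariole_records(recs))
#' @export
ingest_records <- function(records) {
  records <- ovariole_records(records)
  category <- classify_records(records)
  n_ec <- records$n_r1_ec + records$n_r2a_ec
  n_by_cat <- as.integer(table(category))
  mean_of <- function(x) {
    vapply(CLONE_CATEGORIES, function(cat) {
      sel <- !is.na(category) & category == cat
      if (!any(sel)) NA_real_ else mean(x[sel])
    }, numeric(1))
  }
  categories <- data.frame(
    category = CLONE_CATEGORIES,
    n = n_by_cat,
    mean_ec = mean_of(n_ec),
    mean_r1_ec = mean_of(records$n_r1_ec),
    mean_r2a_ec = mean_of(records$n_r2a_ec),
    mean_fsc = mean_of(records$n_fsc),
    row.names = NULL
  )
  clone_category_table(
    categories = categories,
    n_scored = nrow(records),
    n_unlabeled = sum(is.na(category)),
    total_ec = sum(n_ec[!is.na(category)]),
    total_fsc = sum(records$n_fsc[!is.na(category)])
  )
}

#' Clone-category table constructor
#'
#' Container for a clone-scoring experiment in aggregated form: per-category
#' ovariole counts and mean yields plus experiment totals. Usually produced by
#' [ingest_records()] or [read_category_table()]; the constructor is exported
#' so tables published in aggregated form can be entered directly.
#'
#' @param categories data frame with columns `category` (the five category
#'   names), `n` (ovariole counts) and `mean_ec`, `mean_fsc` (mean marked cells
#'   per ovariole in the category; `NA` where not applicable). Optional
#'   `mean_r1_ec`/`mean_r2a_ec` columns carry the region split.
#' @param n_scored total ovarioles scored, including unlabeled ones.
#' @param n_unlabeled ovarioles with no marked cells.
#' @param total_ec,total_fsc total marked ECs and FSCs summed over all marked
#'   ovarioles. If `NULL`, reconstructed from the category means.
#' @return a `clone_category_table` object.
#' @export
clone_category_table <- function(categories, n_scored, n_unlabeled,
                                 total_ec = NULL, total_fsc = NULL) {
  categories <- as.data.frame(categories)
  if (!setequal(categories$category, CLONE_CATEGORIES)) {
    stop("'categories' must have exactly one row per clone category")
  }
  categories <- categories[match(CLONE_CATEGORIES, categories$category), ,
                           drop = FALSE]
  rownames(categories) <- NULL
  if (any(categories$n < 0) || n_scored < 0 || n_unlabeled < 0) {
    stop("ovariole counts must be non-negative")
  }
  n_marked <- sum(categories$n)
  if (n_marked != n_scored - n_unlabeled) {
    stop("category counts (", n_marked, ") must sum to scored minus unlabeled (",
         n_scored - n_unlabeled, ")")
  }
  wsum <- function(means, ns) sum(ifelse(is.na(means), 0, means) * ns)
  implied_ec <- wsum(categories$mean_ec, categories$n)
  implied_fsc <- wsum(categories$mean_fsc, categories$n)
  if (is.null(total_ec)) total_ec <- implied_ec
  if (is.null(total_fsc)) total_fsc <- implied_fsc
  # published means are rounded, so totals are only checked loosely
  for (pair in list(c(total_ec, implied_ec, "EC"), c(total_fsc, implied_fsc, "FSC"))) {
    tot <- as.numeric(pair[1]); imp <- as.numeric(pair[2])
    if (abs(tot - imp) > 0.05 * max(tot, 1) + 2) {
      warning("total ", pair[3], " marked (", tot,
              ") is far from the category-weighted sum of means (",
              round(imp, 1), ")")
    }
  }
  structure(
    list(categories = categories, n_scored = n_scored,
         n_unlabeled = n_unlabeled, n_marked = n_marked,
         total_ec = total_ec, total_fsc = total_fsc),
    class = "clone_category_table"
  )
}

#' @export
print.clone_category_table <- function(x, ...) {
  cat("Clone-category table: ", x$n_scored, " ovarioles scored, ",
      x$n_marked, " marked (", x$n_unlabeled, " unlabeled)\n", sep = "")
  df <- x$categories
  df$freq <- round(100 * df$n / max(x$n_marked, 1), 1)
  print(df[, c("category", "n", "freq", "mean_ec", "mean_fsc")], digits = 3,
        row.names = FALSE)
  cat("Total marked ECs:", x$total_ec, " Total marked FSCs:", x$total_fsc, "\n")
  invisible(x)
}

#' Read an aggregated clone-category table from a delimited text file
#'
#' The file mirrors a published summary row: one line per clone category with
#' the ovariole count and mean yields, one `unlabeled` line, and experiment
#' totals in `#key: value` header comments (`n_scored`, `total_ec`,
#' `total_fsc`; the totals are optional and otherwise reconstructed from the
#' means).
#'
#' @param file path to the delimited file. Columns: `category`, `n`,
#'   `mean_ec`, `mean_fsc` (empty where not applicable).
#' @param sep field separator, comma by default.
#' @return a `clone_category_table` object.
#' @export
read_category_table <- function(file, sep = ",") {
  lines <- readLines(file)
  header <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*([-0-9.eE]+)", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = sep, stringsAsFactors = FALSE)
  unlabeled <- df$n[df$category == "unlabeled"]
  if (length(unlabeled) != 1) stop("file must contain one 'unlabeled' row")
  cats <- df[df$category %in% CLONE_CATEGORIES, , drop = FALSE]
  n_scored <- if (!is.null(meta$n_scored)) meta$n_scored else sum(df$n)
  clone_category_table(
    categories = data.frame(category = cats$category, n = cats$n,
                            mean_ec = cats$mean_ec, mean_fsc = cats$mean_fsc),
    n_scored = n_scored,
    n_unlabeled = unlabeled,
    total_ec = meta$total_ec,
    total_fsc = meta$total_fsc
  )
}

#' Reclassify records scored in 2-day-old adults
#'
#' Marked FSCs present at eclosion can be lost (by becoming FCs) during the
#' first two days of adulthood. Because egg chambers bud roughly every 12
#' hours, any FC made from such an FSC after eclosion must lie in the germarium
#' or the two youngest egg chambers. A record scored at day 2 with no marked
#' FSC but marked FCs at `I`, `G`, `E1` or `E2` is therefore treated as
#' FSC-containing with an FSC count of zero (category `EC_FSC` or `FSC_only`
#' according to its EC content). Marked FCs confined to older egg chambers
#' (`E3`, `E4`) do not trigger the rule, and marked ECs are never reattributed.
#' The operation is idempotent.
#'
#' @param records records data frame; all rows must have
#'   `scoring_age == "adult_day2"`.
#' @return the records with the `fsc_inferred` flag set where the rule fires.
#' @export
reclassify_day2_adult <- function(records) {
  records <- ovariole_records(records)
  if (!all(records$scoring_age == "adult_day2")) {
    stop("reclassify_day2_adult() applies only to records scored at adult day 2")
  }
  young <- c("I", "G", "E1", "E2")
  hit <- vapply(fc_location_list(records$fc_locations),
                function(x) any(x %in% young), logical(1))
  records$fsc_inferred <- records$fsc_inferred | (records$n_fsc == 0 & hit)
  records
}

#' Observed category frequencies with the shared EC+FC convention
#'
#' Reduces a clone-category table to the four observed frequencies used by the
#' mixture deconvolution. The `EC_plus_FC` category (marked ECs and FCs but no
#' FSC, a discontinuous pattern taken as the signature of two independent
#' lineages) is counted inside **both** the EC-without-FSC and FC-without-FSC
#' frequencies; this shared-counting convention is what the deconvolution
#' equations expect.
#'
#' @param table a `clone_category_table`.
#' @return an `aggregated_frequencies` object with components `f_ec`
#'   (marked ECs, no FSC), `f_fc` (marked FCs, no FSC), `f_fsc` (marked FSCs,
#'   no EC), `f_ecfc` (the EC+FC class itself) and `n_marked`.
#' @examples
#' aggregate_frequencies(load_experiment("marcm_0h"))
#' @export
aggregate_frequencies <- function(table) {
  stopifnot(inherits(table, "clone_category_table"))
  if (table$n_marked < 1) stop("no marked ovarioles: frequencies undefined")
  n <- stats::setNames(table$categories$n, table$categories$category)
  aggregated_frequencies(
    f_ec = (n[["EC_only"]] + n[["EC_plus_FC"]]) / table$n_marked,
    f_fc = (n[["FC_only"]] + n[["EC_plus_FC"]]) / table$n_marked,
    f_fsc = n[["FSC_only"]] / table$n_marked,
    f_ecfc = n[["EC_plus_FC"]] / table$n_marked,
    n_marked = table$n_marked
  )
}

#' Construct observed category frequencies directly
#'
#' @param f_ec fraction of marked ovarioles with marked ECs but no FSC
#'   (EC-only plus EC+FC).
#' @param f_fc fraction with marked FCs but no FSC (FC-only plus EC+FC).
#' @param f_fsc fraction with marked FSCs but no ECs (FSC-only).
#' @param f_ecfc fraction in the EC+FC class itself; `NA` when unknown.
#' @param n_marked number of marked ovarioles behind the frequencies (optional).
#' @return an `aggregated_frequencies` object.
#' @export
aggregated_frequencies <- function(f_ec, f_fc, f_fsc, f_ecfc = NA_real_,
                                   n_marked = NA_integer_) {
  vals <- c(f_ec, f_fc, f_fsc, f_ecfc)
  if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  if (!is.na(f_ecfc) && f_ecfc > min(f_ec, f_fc) + 1e-9) {
    stop("f_ecfc cannot exceed f_ec or f_fc (EC+FC is counted inside both)")
  }
  structure(list(f_ec = as.numeric(f_ec), f_fc = as.numeric(f_fc),
                 f_fsc = as.numeric(f_fsc), f_ecfc = as.numeric(f_ecfc),
                 n_marked = n_marked),
            class = "aggregated_frequencies")
}

#' @export
print.aggregated_frequencies <- function(x, ...) {
  cat("Observed clone-category frequencies",
      if (!is.na(x$n_marked)) paste0(" (", x$n_marked, " marked ovarioles)"),
      ":\n", sep = "")
  cat(sprintf("  EC no FSC: %.3f   FC no FSC: %.3f   FSC no EC: %.3f   EC+FC: %s\n",
              x$f_ec, x$f_fc, x$f_fsc,
              if (is.na(x$f_ecfc)) "NA" else sprintf("%.3f", x$f_ecfc)))
  invisible(x)
}
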