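# Shared helpers: independent oracles and record builders.

# Absolute-tolerance comparison (expect_equal's tolerance is relative, which
# is the wrong scale for printed values near zero).
expect_near <- function(object, expected, tol) {
  lab <- paste(deparse(substitute(object)), collapse = "")
  testthat::expect(
    all(abs(object - expected) <= tol),
    sprintf("%s (= %s) is not within %g of %s", lab,
            paste(signif(object, 6), collapse = ", "), tol,
            paste(expected, collapse = ", "))
  )
  invisible(object)
}

# Brute-force forward model: enumerate the 4 single-lineage outcomes and all
# 16 ordered lineage pairs, classify each outcome into the observable clone
# categories, and marginalize. Independent of the closed forms in the package.
enum_category_frequencies <- function(freqs, sigma) {
  types <- c("EC_only", "EC_FSC", "FSC_only", "FC_only")
  p <- c(freqs$p_ec, freqs$p_ecfsc, freqs$p_fsc, freqs$p_fc)
  has_ec <- c(TRUE, TRUE, FALSE, FALSE)
  has_fsc <- c(FALSE, TRUE, TRUE, FALSE)
  has_fc <- c(FALSE, NA, NA, TRUE)  # FCs optional for FSC-containing types
  classify <- function(ec, fsc, fc) {
    if (fsc && ec) "EC_FSC"
    else if (fsc) "FSC_only"
    else if (ec && fc) "EC_plus_FC"
    else if (ec) "EC_only"
    else "FC_only"
  }
  acc <- c(EC_only = 0, EC_FSC = 0, FSC_only = 0, FC_only = 0, EC_plus_FC = 0)
  for (i in 1:4) {
    cat_i <- classify(has_ec[i], has_fsc[i], isTRUE(has_fc[i]))
    acc[cat_i] <- acc[cat_i] + sigma * p[i]
    for (j in 1:4) {
      cat_ij <- classify(has_ec[i] || has_ec[j], has_fsc[i] || has_fsc[j],
                         isTRUE(has_fc[i]) || isTRUE(has_fc[j]))
      acc[cat_ij] <- acc[cat_ij] + (1 - sigma) * p[i] * p[j]
    }
  }
  list(f_ec = acc[["EC_only"]] + acc[["EC_plus_FC"]],
       f_fc = acc[["FC_only"]] + acc[["EC_plus_FC"]],
       f_fsc = acc[["FSC_only"]],
       f_ecfc = acc[["EC_plus_FC"]])
}

# Random point on the 4-simplex.
random_freqs <- function() {
  x <- stats::rexp(4)
  x <- x / sum(x)
  lineage_frequencies(x[1], x[2], x[3], x[4])
}

# One-line record builder.
rec <- function(id, r1 = 0, r2a = 0, fsc = 0, fc = "", stalk = "not_imaged",
                age = "eclosion_day0") {
  data.frame(ovariole_id = id, n_r1_ec = r1, n_r2a_ec = r2a, n_fsc = fsc,
             fc_locations = fc, basal_stalk = stalk, scoring_age = age,
             stringsAsFactors = FALSE)
}

# Per-ovariole records that aggregate exactly to the 0 hr APF MARCM category
# counts (46/24/3/9/16 marked of 207 scored). Cell counts per row are chosen
# so the category means are not needed downstream of count checks.
marcm_0h_like_records <- function() {
  rows <- list()
  add <- function(n, ...) {
    for (i in seq_len(n)) rows[[length(rows) + 1]] <<- rec(length(rows) + 1, ...)
  }
  add(46, r1 = 2, r2a = 1)                      # EC_only
  add(24, r1 = 2, r2a = 2, fsc = 4, fc = "I")   # EC_FSC
  add(3, fsc = 4, fc = "I;G")                   # FSC_only
  add(9, fc = "E3;E4")                          # FC_only
  add(16, r1 = 3, fc = "E4")                    # EC_plus_FC
  add(109)                                      # unlabeled
  do.call(rbind, rows)
}
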