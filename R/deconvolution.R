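# One-vs-two-lineage mixture deconvolution of clone-category frequencies.
#
# Model: a fraction sigma of marked ovarioles carries exactly one marked
# lineage, the rest exactly two, with lineage types drawn independently from
# the single-lineage type frequencies (p_ec, p_ecfsc, p_fsc, p_fc). Any pair
# involving an FSC-producing lineage lands in an FSC-containing category, so
# the EC-without-FSC, FC-without-FSC and FSC-without-EC observables depend
# only on the type frequencies via:
#   f_ec   = s*p_ec  + (1-s)(p_ec^2  + 2 p_ec p_fc)
#   f_fc   = s*p_fc  + (1-s)(p_fc^2  + 2 p_ec p_fc)
#   f_fsc  = s*p_fsc + (1-s)(p_fsc^2 + 2 p_fsc p_fc)
#   f_ecfc = (1-s) * 2 p_ec p_fc

#' Single-lineage type frequencies
#'
#' The proportions of the four single-cell lineage types among all marked
#' lineages: `p_ec` (lineages producing only ECs), `p_ecfsc` (ECs and FSCs,
#' with or without FCs), `p_fsc` (FSCs but no ECs, with or without FCs) and
#' `p_fc` (only FCs). Must sum to 1.
#'
#' @param p_ec,p_ecfsc,p_fsc,p_fc the four proportions.
#' @return a `lineage_frequencies` object.
#' @export
lineage_frequencies <- function(p_ec, p_ecfsc, p_fsc, p_fc) {
  v <- c(p_ec = p_ec, p_ecfsc = p_ecfsc, p_fsc = p_fsc, p_fc = p_fc)
  if (any(v < -1e-12 | v > 1 + 1e-12)) {
    stop("lineage-type frequencies must lie in [0, 1]")
  }
  if (abs(sum(v) - 1) > 1e-9) {
    stop("lineage-type frequencies must sum to 1 (got ", sum(v), ")")
  }
  structure(as.list(pmin(pmax(v, 0), 1)), class = "lineage_frequencies")
}

#' @export
print.lineage_frequencies <- function(x, ...) {
  cat(sprintf(
    "Single-lineage type frequencies:\n  EC-only %.3f   EC/FSC %.3f   FSC-only %.3f   FC-only %.3f\n",
    x$p_ec, x$p_ecfsc, x$p_fsc, x$p_fc))
  invisible(x)
}

#' Mixture assumption on the number of lineages per marked ovariole
#'
#' @param sigma fraction of marked ovarioles carrying exactly one lineage; the
#'   remainder are assumed to carry exactly two.
#' @param mode how sigma was chosen: fixed by the user, estimated on a grid
#'   ([estimate_single_fraction()]), or one of the limiting assumptions
#'   `all_double` (sigma = 0) and `all_single` (sigma = 1).
#' @param residual for grid estimates, the absolute gap between predicted and
#'   observed EC+FC frequency at the chosen sigma.
#' @param grid for grid estimates, the per-sigma search table.
#' @return a `mixture_assumption` object.
#' @export
mixture_assumption <- function(sigma,
                               mode = c("fixed", "grid_estimated",
                                        "all_double", "all_single"),
                               residual = NA_real_, grid = NULL) {
  mode <- match.arg(mode)
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]")
  if (mode == "all_double" && sigma != 0) stop("all_double means sigma = 0")
  if (mode == "all_single" && sigma != 1) stop("all_single means sigma = 1")
  structure(list(sigma = sigma, mode = mode, residual = residual, grid = grid),
            class = "mixture_assumption")
}

#' @export
print.mixture_assumption <- function(x, ...) {
  cat(sprintf("Mixture assumption: sigma = %.2f (%s)", x$sigma, x$mode))
  if (!is.na(x$residual)) cat(sprintf(", EC+FC residual %.4f", x$residual))
  cat("\n")
  invisible(x)
}

#' Forward model: category frequencies expected from lineage-type frequencies
#'
#' Predicts the observable category frequencies for given single-lineage type
#' frequencies and single-lineage fraction `sigma`. Two-lineage pairs that
#' involve an FSC-producing lineage together with an EC- or FC-producing one
#' fall into FSC-containing categories and therefore never contribute to
#' `f_ec`, `f_fc` or `f_ecfc`; `f_fsc` counts only the pairs with no EC
#' lineage. The EC+FC class arises purely from (EC-only, FC-only) pairs.
#'
#' @param freqs a [lineage_frequencies()] object.
#' @param sigma single-lineage fraction in \[0, 1\].
#' @return an [aggregated_frequencies()] object.
#' @examples
#' f <- lineage_frequencies(0.63, 0.13, 0.05, 0.19)
#' forward_category_frequencies(f, 0.3)
#' @export
forward_category_frequencies <- function(freqs, sigma) {
  stopifnot(inherits(freqs, "lineage_frequencies"), sigma >= 0, sigma <= 1)
  a <- freqs$p_ec; b <- freqs$p_fc; r <- freqs$p_fsc
  aggregated_frequencies(
    f_ec = sigma * a + (1 - sigma) * (a^2 + 2 * a * b),
    f_fc = sigma * b + (1 - sigma) * (b^2 + 2 * a * b),
    f_fsc = sigma * r + (1 - sigma) * (r^2 + 2 * r * b),
    f_ecfc = (1 - sigma) * 2 * a * b
  )
}

# Solve the coupled (p_ec, p_fc) system by damped Newton iteration with the
# analytic Jacobian, started from the sigma = 1 identity solution. Returns
# c(a, b) or NULL if no root with finite residual < tol is found.
solve_ec_fc_pair <- function(f_ec, f_fc, sigma, tol = 1e-12) {
  fun <- function(v) {
    a <- v[1]; b <- v[2]
    c(sigma * a + (1 - sigma) * (a^2 + 2 * a * b) - f_ec,
      sigma * b + (1 - sigma) * (b^2 + 2 * a * b) - f_fc)
  }
  newton <- function(v) {
    for (i in seq_len(100)) {
      Fv <- fun(v)
      if (max(abs(Fv)) < tol) return(v)
      a <- v[1]; b <- v[2]
      J <- matrix(c(sigma + (1 - sigma) * (2 * a + 2 * b), (1 - sigma) * 2 * a,
                    (1 - sigma) * 2 * b, sigma + (1 - sigma) * (2 * a + 2 * b)),
                  2, 2, byrow = TRUE)
      step <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      # damp: halve the step until the residual shrinks and stays in [0,1]^2
      lambda <- 1
      repeat {
        cand <- v - lambda * step
        if (all(cand >= 0) && all(cand <= 1) &&
            sum(fun(cand)^2) < sum(Fv^2)) break
        lambda <- lambda / 2
        if (lambda < 1e-8) return(NULL)
      }
      v <- cand
    }
    if (max(abs(fun(v))) < 1e-9) v else NULL
  }
  sol <- newton(c(f_ec, f_fc))
  if (!is.null(sol)) return(sol)
  # fallback: coarse grid on [0,1]^2, refined by Newton from the best cell
  grid <- seq(0, 1, by = 0.02)
  cells <- expand.grid(a = grid, b = grid)
  ss <- mapply(function(a, b) sum(fun(c(a, b))^2), cells$a, cells$b)
  newton(as.numeric(cells[which.min(ss), ]))
}

# Positive root of (1-s) p^2 + (s + 2 (1-s) b) p = f_fsc. Unique non-negative
# root; the paired root is always <= 0, so no ambiguity arises except at
# f_fsc = 0 where both roots coincide with 0 or are negative.
solve_fsc_quadratic <- function(f_fsc, p_fc, sigma) {
  A <- 1 - sigma
  B <- sigma + 2 * (1 - sigma) * p_fc
  if (A == 0) {
    if (B == 0) stop("infeasible: sigma = 1 with p_fc undefined denominator")
    return(f_fsc / B)
  }
  (-B + sqrt(B^2 + 4 * A * f_fsc)) / (2 * A)
}

#' Deconvolve observed category frequencies into lineage-type frequencies
#'
#' Inverts the forward mixture model at a given single-lineage fraction
#' `sigma`: the coupled pair of equations for (`p_ec`, `p_fc`) is solved from
#' `f_ec` and `f_fc` by damped Newton iteration (grid-search fallback), then
#' `p_fsc` is the root in \[0, 1\] of its quadratic given `f_fsc`, and
#' `p_ecfsc` follows by complement. The forward model at the solution
#' reproduces the three input frequencies to 1e-9.
#'
#' @param obs an [aggregated_frequencies()] object (the `f_ecfc` component is
#'   not used here; see [estimate_single_fraction()]).
#' @param sigma single-lineage fraction, or a [mixture_assumption()].
#' @return a [lineage_frequencies()] object.
#' @examples
#' obs <- aggregated_frequencies(0.63, 0.25, 0.03, 0.163)
#' solve_lineage_frequencies(obs, 0.3)
#' @export
solve_lineage_frequencies <- function(obs, sigma) {
  stopifnot(inherits(obs, "aggregated_frequencies"))
  if (inherits(sigma, "mixture_assumption")) sigma <- sigma$sigma
  stopifnot(sigma >= 0, sigma <= 1)
  ab <- solve_ec_fc_pair(obs$f_ec, obs$f_fc, sigma)
  if (is.null(ab) || any(ab < -1e-9) || any(ab > 1 + 1e-9)) {
    stop("infeasible frequencies: no (p_ec, p_fc) in [0,1] satisfies the ",
         "EC/FC pair of equations for f_ec = ", signif(obs$f_ec, 4),
         ", f_fc = ", signif(obs$f_fc, 4), " at sigma = ", sigma)
  }
  a <- min(max(ab[1], 0), 1); b <- min(max(ab[2], 0), 1)
  r <- solve_fsc_quadratic(obs$f_fsc, b, sigma)
  if (r < -1e-9 || r > 1 + 1e-9) {
    stop("infeasible frequencies: FSC-only quadratic has no root in [0,1] for ",
         "f_fsc = ", signif(obs$f_fsc, 4))
  }
  q <- 1 - a - b - r
  if (q < -1e-9) {
    stop("infeasible frequencies: complement p_ecfsc = ", signif(q, 4),
         " is negative (p_ec + p_fc + p_fsc exceeds 1)")
  }
  out <- lineage_frequencies(a, max(q, 0), r, b)
  check <- forward_category_frequencies(out, sigma)
  gap <- max(abs(c(check$f_ec - obs$f_ec, check$f_fc - obs$f_fc,
                   check$f_fsc - obs$f_fsc)))
  if (gap > 1e-9) {
    stop("solver failed to reproduce the observed frequencies (gap ",
         signif(gap, 3), ")")
  }
  out
}

#' All-double deconvolution anchored on the EC+FC class
#'
#' Variant used when FC-only ovarioles are essentially absent, so the
#' FC-lineage frequency must be anchored on the EC+FC class instead. Every
#' marked ovariole is assumed to carry exactly two lineages (`sigma = 0`), and
#' the observables are taken category-exclusive: `p_ec = sqrt(f_ec_only)` from
#' the pure (EC, EC) class, `p_fc = f_ecfc / (2 p_ec)` from the mixed class,
#' `p_fsc` from its quadratic `p_fsc^2 + 2 p_fsc p_fc = f_fsc_only`, and
#' `p_ecfsc` by complement.
#'
#' @param f_ec_only fraction of marked ovarioles with only marked ECs
#'   (excluding the EC+FC class, unlike [aggregate_frequencies()]).
#' @param f_ecfc fraction in the EC+FC class.
#' @param f_fsc_only fraction with marked FSCs but no ECs.
#' @return a [lineage_frequencies()] object.
#' @examples
#' solve_all_double_ecfc_anchored(0.3836, 0.0959, 0.0137)
#' @export
solve_all_double_ecfc_anchored <- function(f_ec_only, f_ecfc, f_fsc_only) {
  stopifnot(f_ec_only >= 0, f_ec_only <= 1, f_ecfc >= 0, f_ecfc <= 1,
            f_fsc_only >= 0, f_fsc_only <= 1)
  if (f_ec_only == 0 && f_ecfc > 0) {
    stop("infeasible: f_ecfc > 0 requires EC-only lineages (f_ec_only > 0)")
  }
  a <- sqrt(f_ec_only)
  b <- if (f_ecfc == 0) 0 else f_ecfc / (2 * a)
  r <- if (f_fsc_only == 0) 0 else (-2 * b + sqrt(4 * b^2 + 4 * f_fsc_only)) / 2
  q <- 1 - a - b - r
  if (q < -1e-9) {
    stop("infeasible: components sum to ", signif(a + b + r, 4), " > 1")
  }
  lineage_frequencies(a, max(q, 0), r, b)
}

#' Estimate the single-lineage fraction from the EC+FC class
#'
#' Searches a grid of candidate single-lineage fractions. For each grid value
#' the EC/FC pair of equations is solved from the observed `f_ec` and `f_fc`,
#' and the EC+FC frequency predicted by the forward model is compared with the
#' observed one; the grid value minimizing the absolute gap is returned. Ties
#' break toward the larger sigma, i.e. the weaker clustering assumption.
#'
#' @param obs an [aggregated_frequencies()] object with `f_ecfc` defined.
#' @param grid_step grid spacing; must divide 1 evenly (default 0.05).
#' @return a [mixture_assumption()] with `mode = "grid_estimated"`, the
#'   winning residual, and the full search table in `$grid`.
#' @examples
#' obs <- aggregated_frequencies(0.63, 0.25, 0.03, 0.163)
#' estimate_single_fraction(obs)  # sigma = 0.30
#' @export
estimate_single_fraction <- function(obs, grid_step = 0.05) {
  stopifnot(inherits(obs, "aggregated_frequencies"))
  if (is.na(obs$f_ecfc)) stop("f_ecfc must be observed to estimate sigma")
  k <- 1 / grid_step
  if (abs(k - round(k)) > 1e-9) stop("grid_step must divide 1 evenly")
  sigmas <- seq(0, 1, by = grid_step)
  predicted <- rep(NA_real_, length(sigmas))
  for (i in seq_along(sigmas)) {
    ab <- tryCatch(solve_ec_fc_pair(obs$f_ec, obs$f_fc, sigmas[i]),
                   error = function(e) NULL)
    if (is.null(ab) || any(ab < -1e-9) || sum(ab) > 1 + 1e-9) next
    predicted[i] <- (1 - sigmas[i]) * 2 * ab[1] * ab[2]
  }
  grid <- data.frame(sigma = sigmas, predicted_f_ecfc = predicted,
                     residual = abs(predicted - obs$f_ecfc),
                     feasible = !is.na(predicted))
  if (!any(grid$feasible)) {
    stop("sigma estimation failed: no feasible sigma on the grid")
  }
  ok <- which(grid$feasible)
  best <- ok[grid$residual[ok] <= min(grid$residual[ok]) + 1e-12]
  pick <- max(best)  # ties -> larger sigma (fewer assumed doubles)
  mixture_assumption(sigma = grid$sigma[pick], mode = "grid_estimated",
                     residual = grid$residual[pick], grid = grid)
}
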