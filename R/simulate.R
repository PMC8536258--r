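# Synthetic clone-scoring datasets with known ground truth, the generative
# mirror of the one-vs-two-lineage mixture model. Used to validate the whole
# inference pipeline by parameter recovery.

#' Configuration for a synthetic clone-scoring experiment
#'
#' The generator emulates the study conditions of a clone-marking experiment:
#' each ovariole is unlabeled with probability `1 - labeled_fraction`;
#' a labeled ovariole carries one marked lineage with probability `sigma_true`
#' and otherwise exactly two, each drawn independently from `true_freqs`.
#' Marked-cell counts per lineage follow zero-truncated negative binomial
#' distributions whose truncated means equal `yield_means` (truncation
#' guarantees a lineage shows its defining cell type); EC counts are split
#' into r1/r2a binomially. FC locations use a two-zone scheme along the AP
#' axis: FC-only lineages draw either a terminal-chamber run (`E4` backwards)
#' or an anterior run (`I` forwards), FSC-containing lineages an anterior run.
#' Locations are plumbing for the record format; the census math never uses
#' them.
#'
#' @param n_ovarioles number of ovarioles to score.
#' @param true_freqs a [lineage_frequencies()] object: ground-truth type
#'   proportions.
#' @param sigma_true fraction of labeled ovarioles with exactly one lineage.
#' @param labeled_fraction probability an ovariole carries any marked cell;
#'   default 0.473, the labeled fraction of the 0 hr APF MARCM experiment.
#' @param yield_means named list of per-lineage mean yields (of the truncated
#'   count distributions): `ec_only` (ECs per EC-only lineage), `fsc_only`
#'   (FSCs per FSC-only lineage), `ecfsc_ec` and `ecfsc_fsc` (ECs and FSCs per
#'   EC/FSC lineage). All must exceed 1. Defaults echo the 0 hr APF MARCM
#'   inference (1.76, 4.32, 3.15, 3.47).
#' @param yield_dispersion negative binomial size parameter; smaller means
#'   more overdispersed counts.
#' @param r1_share probability a marked EC lies in region 1 (anterior);
#'   default 0.6, matching the roughly 19:14 r1:r2a ratio of adult EC output.
#' @param fc_prob probability an FSC-containing lineage also shows marked FCs.
#' @param terminal_share probability an FC-only lineage draws from the
#'   terminal-chamber pool rather than the anterior pool.
#' @param seed integer random seed; required, so datasets are reproducible.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_ovarioles,
                              true_freqs,
                              sigma_true,
                              labeled_fraction = 0.473,
                              yield_means = list(ec_only = 1.76,
                                                 fsc_only = 4.32,
                                                 ecfsc_ec = 3.15,
                                                 ecfsc_fsc = 3.47),
                              yield_dispersion = 2,
                              r1_share = 0.6,
                              fc_prob = 0.9,
                              terminal_share = 0.7,
                              seed = 1L) {
  stopifnot(inherits(true_freqs, "lineage_frequencies"),
            n_ovarioles >= 1,
            sigma_true >= 0, sigma_true <= 1,
            labeled_fraction > 0, labeled_fraction <= 1,
            yield_dispersion > 0,
            r1_share >= 0, r1_share <= 1,
            fc_prob >= 0, fc_prob <= 1,
            terminal_share >= 0, terminal_share <= 1)
  needed <- c("ec_only", "fsc_only", "ecfsc_ec", "ecfsc_fsc")
  if (!all(needed %in% names(yield_means))) {
    stop("yield_means needs components: ", paste(needed, collapse = ", "))
  }
  if (any(unlist(yield_means[needed]) <= 1)) {
    stop("yield means must exceed 1 (zero-truncated counts average above 1)")
  }
  structure(list(n_ovarioles = as.integer(n_ovarioles),
                 true_freqs = true_freqs, sigma_true = sigma_true,
                 labeled_fraction = labeled_fraction,
                 yield_means = yield_means,
                 yield_dispersion = yield_dispersion,
                 r1_share = r1_share, fc_prob = fc_prob,
                 terminal_share = terminal_share, seed = as.integer(seed)),
            class = "simulation_config")
}

# Untruncated NB mean mu such that the zero-truncated mean equals 'target':
# E[X | X > 0] = mu / (1 - (k / (k + mu))^k).
ztnb_mu <- function(target, size) {
  f <- function(mu) mu / (1 - (size / (size + mu))^size) - target
  stats::uniroot(f, lower = 1e-9, upper = target, tol = 1e-12)$root
}

# Zero-truncated NB sampler by inverse CDF restricted to X >= 1.
rztnb <- function(n, target_mean, size) {
  if (n == 0) return(integer(0))
  mu <- ztnb_mu(target_mean, size)
  p0 <- stats::pnbinom(0, size = size, mu = mu)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, size = size, mu = mu)
}

# Contiguous anterior runs ("I", "I;G", ...) and terminal runs ("E4", "E3;E4").
ANTERIOR_RUNS <- c("I", "I;G", "I;G;E1", "I;G;E1;E2")
TERMINAL_RUNS <- c("E4", "E3;E4")

#' Simulate a clone-scoring dataset with known ground truth
#'
#' Draws per-ovariole records under the generative mixture model described in
#' [simulation_config()]. Identical configurations (including the seed)
#' produce identical datasets.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_clone_dataset`: list with `records` (a data frame
#'   accepted by [ingest_records()]) and `truth` (the config plus realized
#'   per-ovariole lineage counts and types).
#' @examples
#' cfg <- simulation_config(500, lineage_frequencies(0.63, 0.13, 0.05, 0.19),
#'                          sigma_true = 0.3, seed = 7)
#' sim <- simulate_dataset(cfg)
#' ingest_records(sim$records)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_ovarioles
  marked <- stats::runif(n) < config$labeled_fraction
  n_lineages <- integer(n)
  n_lineages[marked] <- 1L +
    (stats::runif(sum(marked)) >= config$sigma_true)

  ov_of_lineage <- rep(seq_len(n), n_lineages)
  k <- length(ov_of_lineage)
  types <- c("EC_only", "EC_FSC", "FSC_only", "FC_only")
  probs <- c(config$true_freqs$p_ec, config$true_freqs$p_ecfsc,
             config$true_freqs$p_fsc, config$true_freqs$p_fc)
  type <- sample(types, k, replace = TRUE, prob = probs)

  ec <- integer(k); fsc <- integer(k); fc_run <- character(k)
  disp <- config$yield_dispersion
  i <- type == "EC_only"
  ec[i] <- rztnb(sum(i), config$yield_means$ec_only, disp)
  i <- type == "EC_FSC"
  ec[i] <- rztnb(sum(i), config$yield_means$ecfsc_ec, disp)
  fsc[i] <- rztnb(sum(i), config$yield_means$ecfsc_fsc, disp)
  i <- type == "FSC_only"
  fsc[i] <- rztnb(sum(i), config$yield_means$fsc_only, disp)

  # FC locations: contiguous runs along the AP axis, never used by the census
  has_fsc <- type %in% c("EC_FSC", "FSC_only")
  with_fc <- has_fsc & stats::runif(k) < config$fc_prob
  fc_run[with_fc] <- ANTERIOR_RUNS[sample.int(4, sum(with_fc), replace = TRUE,
                                              prob = c(0.4, 0.3, 0.2, 0.1))]
  i <- type == "FC_only"
  terminal <- stats::runif(k) < config$terminal_share
  pick_t <- i & terminal
  fc_run[pick_t] <- TERMINAL_RUNS[sample.int(2, sum(pick_t), replace = TRUE)]
  pick_a <- i & !terminal
  fc_run[pick_a] <- ANTERIOR_RUNS[sample.int(4, sum(pick_a), replace = TRUE)]

  r1 <- stats::rbinom(k, ec, config$r1_share)

  agg <- function(x) {
    out <- numeric(n)
    s <- rowsum(x, ov_of_lineage)
    out[as.integer(rownames(s))] <- s
    out
  }
  union_runs <- function(runs) {
    runs <- runs[nzchar(runs)]
    if (length(runs) == 0) return("")
    codes <- unique(unlist(strsplit(runs, ";", fixed = TRUE)))
    paste(FC_LOCATION_CODES[FC_LOCATION_CODES %in% codes], collapse = ";")
  }
  fc_locations <- rep("", n)
  if (k > 0) {
    by_ov <- split(fc_run, ov_of_lineage)
    fc_locations[as.integer(names(by_ov))] <-
      vapply(by_ov, union_runs, character(1))
  }

  basal <- rep("not_imaged", n)
  term_ov <- unique(ov_of_lineage[i & terminal])
  basal[term_ov] <- ifelse(stats::runif(length(term_ov)) < 0.5, "yes", "no")

  records <- data.frame(
    ovariole_id = seq_len(n),
    n_r1_ec = agg(r1),
    n_r2a_ec = agg(ec - r1),
    n_fsc = agg(fsc),
    fc_locations = fc_locations,
    basal_stalk = basal,
    scoring_age = "eclosion_day0",
    stringsAsFactors = FALSE
  )
  truth_types <- rep("", n)
  if (k > 0) {
    by_ov <- split(type, ov_of_lineage)
    truth_types[as.integer(names(by_ov))] <-
      vapply(by_ov, paste, character(1), collapse = "+")
  }
  structure(list(records = ovariole_records(records),
                 truth = list(config = config,
                              n_lineages = n_lineages,
                              lineage_types = truth_types)),
            class = "simulated_clone_dataset")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Parameter-recovery experiment on synthetic data
#'
#' Repeats simulate, deconvolve, census over replicates and summarizes how
#' well the pipeline recovers the generating parameters: per-parameter bias
#' and root-mean-square error for the four lineage-type frequencies and the
#' census total, plus the hit rate of the grid sigma estimate (at the grid
#' resolution of `grid_step`). Pipeline errors in individual replicates are
#' collected, not raised.
#'
#' @param config a [simulation_config()]; replicate `i` uses seed
#'   `config$seed + i - 1`.
#' @param n_replicates number of replicates (>= 1).
#' @param sigma policy passed to [run_full_census()]; the default `"auto"`
#'   exercises the sigma grid estimate.
#' @param grid_step sigma grid spacing.
#' @return a `recovery_report`: list with `estimates` (one row per successful
#'   replicate), `truth`, `bias`, `rmse`, `sigma_hit_rate` and `failures`.
#' @export
recovery_experiment <- function(config, n_replicates, sigma = "auto",
                                grid_step = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  true_n_total <- 16 / (config$true_freqs$p_ecfsc * config$yield_means$ecfsc_fsc +
                        config$true_freqs$p_fsc * config$yield_means$fsc_only)
  rows <- vector("list", n_replicates)
  failures <- list()
  for (i in seq_len(n_replicates)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    res <- tryCatch({
      sim <- simulate_dataset(cfg_i)
      table <- ingest_records(sim$records)
      rep <- run_full_census(table, sigma = sigma, grid_step = grid_step)
      data.frame(replicate = i, sigma_hat = rep$sigma$sigma,
                 p_ec = rep$freqs$p_ec, p_ecfsc = rep$freqs$p_ecfsc,
                 p_fsc = rep$freqs$p_fsc, p_fc = rep$freqs$p_fc,
                 n_total = rep$census$n_total)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(replicate = i,
                                               message = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  estimates <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(estimates) || nrow(estimates) == 0) {
    stop("all replicates failed; first error: ", failures[[1]]$message)
  }
  truth <- c(sigma = config$sigma_true,
             p_ec = config$true_freqs$p_ec, p_ecfsc = config$true_freqs$p_ecfsc,
             p_fsc = config$true_freqs$p_fsc, p_fc = config$true_freqs$p_fc,
             n_total = true_n_total)
  pars <- c("p_ec", "p_ecfsc", "p_fsc", "p_fc", "n_total")
  bias <- vapply(pars, function(p) mean(estimates[[p]]) - truth[[p]], numeric(1))
  rmse <- vapply(pars, function(p) sqrt(mean((estimates[[p]] - truth[[p]])^2)),
                 numeric(1))
  structure(list(estimates = estimates, truth = truth, bias = bias,
                 rmse = rmse,
                 sigma_hit_rate = mean(abs(estimates$sigma_hat -
                                           config$sigma_true) < 1e-9),
                 failures = failures),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", nrow(x$estimates), "replicate(s):\n")
  print(round(rbind(truth = x$truth[names(x$bias)], bias = x$bias,
                    rmse = x$rmse), 4))
  cat(sprintf("sigma grid hit rate: %.2f (%d failures)\n",
              x$sigma_hit_rate, length(x$failures)))
  invisible(x)
}
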