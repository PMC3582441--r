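#' Pairwise-accuracy experiment on simulated fragments
#'
#' The standard simulation protocol for the pairwise-consistency
#' evaluation: simulate `n_reps` datasets, fit the mixture model on each,
#' and record the precision-recall curve over MC thresholds together with
#' the majority-vote no-assembly baseline.  Averaging the per-repeat
#' curves reproduces the model's operating characteristics (e.g. recall
#' around 0.07 at MC threshold 4 with precision near 1 under the default
#' conditions with 2000 sites).
#'
#' @param n_reps number of simulated repeats.
#' @param n_sites,coverage,len_range,error_rate simulator conditions (see
#'   [simulate_fragments()]).
#' @param thresholds MC thresholds for the curve (ascending).
#' @param seeds integer seeds, one per repeat.
#' @param alpha allele error rate used by the fit.
#' @param control a [haplomix_control()].
#' @return list with `curves` (per-repeat data frames), `baselines`
#'   (per-repeat `hap_eval` records), `full` (per-repeat evaluation with
#'   no MC filtering, i.e. one block per component) and the conditions.
#' @export
pairwise_accuracy_experiment <- function(n_reps = 10, n_sites = 2000,
                                         coverage = 5, len_range = c(3, 7),
                                         error_rate = 0.1,
                                         thresholds = seq(-2, 12, by = 0.25),
                                         seeds = seq_len(n_reps),
                                         alpha = 0.1,
                                         control = haplomix_control()) {
  stopifnot(length(seeds) == n_reps)
  curves <- vector("list", n_reps)
  baselines <- vector("list", n_reps)
  full <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_fragments(n_sites, coverage, len_range, error_rate,
                              seed = seeds[r])
    fit <- with_seed(seeds[r] + 10000L,
                     haplomix(sim$fragments, alpha = alpha, control = control))
    curves[[r]] <- precision_recall_curve(sim$fragments, fit, sim$truth,
                                          thresholds)
    baselines[[r]] <- no_assembly_baseline(sim$fragments, sim$truth)
    full[[r]] <- evaluate_blocks(extract_blocks(sim$fragments, fit, -Inf),
                                 sim$fragments, sim$truth)
  }
  list(curves = curves, baselines = baselines, full = full,
       thresholds = thresholds,
       conditions = list(n_reps = n_reps, n_sites = n_sites,
                         coverage = coverage, len_range = len_range,
                         error_rate = error_rate, seeds = seeds))
}

#' Summarise a pairwise-accuracy experiment
#'
#' @param exp result of [pairwise_accuracy_experiment()].
#' @param mc_threshold threshold at which model recall/precision are read.
#' @return list of averaged quantities: `recall_at_threshold` and
#'   `precision_at_threshold` (model, at `mc_threshold`),
#'   `baseline_recall`, `baseline_precision`, `recall_at_baseline_precision`
#'   (model recall at the smallest threshold whose precision reaches that
#'   repeat's baseline precision) and `full_precision` (no MC filter).
#' @export
summarise_pairwise_experiment <- function(exp, mc_threshold = 4) {
  n <- length(exp$curves)
  at_thr <- function(cv) cv[which.min(abs(cv$threshold - mc_threshold)), ]
  rec_thr <- vapply(exp$curves, function(cv) at_thr(cv)$recall, numeric(1))
  prec_thr <- vapply(exp$curves, function(cv) at_thr(cv)$precision, numeric(1))
  base_rec <- vapply(exp$baselines, `[[`, numeric(1), "recall")
  base_prec <- vapply(exp$baselines, `[[`, numeric(1), "precision")
  rec_match <- vapply(seq_len(n), function(r) {
    cv <- exp$curves[[r]]
    ok <- which(!is.nan(cv$precision) & cv$precision >= base_prec[r])
    if (!length(ok)) return(0)
    cv$recall[ok[1L]]   # thresholds ascend, so ok[1] is the smallest
  }, numeric(1))
  list(recall_at_threshold = mean(rec_thr),
       precision_at_threshold = mean(prec_thr),
       baseline_recall = mean(base_rec),
       baseline_precision = mean(base_prec),
       recall_at_baseline_precision = mean(rec_match),
       full_precision = mean(vapply(exp$full, `[[`, numeric(1), "precision")))
}

#' MC-threshold dependency over fragment-quality conditions
#'
#' For each combination of coverage, fragment-length range and error rate,
#' simulates `n_reps` datasets, fits the model, and finds the lowest MC
#' threshold whose average precision reaches `target_precision`.  Under a
#' wide range of conditions this minimal threshold stays bounded (by about
#' 6 nats), which motivates the package's default MC threshold.
#'
#' @param coverages,error_rates numeric grids.
#' @param len_ranges list of `c(l1, l2)` ranges.
#' @param n_sites sites per simulated dataset.
#' @param n_reps repeats per grid cell.
#' @param target_precision precision to reach (default 0.95).
#' @param thresholds candidate MC thresholds (ascending).
#' @param base_seed integer from which per-cell, per-repeat seeds are
#'   derived deterministically.
#' @param alpha allele error rate used by the fit.
#' @param control a [haplomix_control()].
#' @param verbose print one line per cell.
#' @return data frame with one row per cell: conditions plus
#'   `min_threshold` (NA when the target precision is never reached).
#' @export
mc_dependency_experiment <- function(coverages = c(3, 5, 10),
                                     error_rates = c(0.05, 0.1, 0.15, 0.2),
                                     len_ranges = list(c(3, 7), c(5, 10), c(8, 15)),
                                     n_sites = 1000, n_reps = 10,
                                     target_precision = 0.95,
                                     thresholds = seq(0, 10, by = 0.1),
                                     base_seed = 1L, alpha = 0.1,
                                     control = haplomix_control(),
                                     verbose = FALSE) {
  grid <- expand.grid(cell_len = seq_along(len_ranges),
                      coverage = coverages, error_rate = error_rates)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    lr <- len_ranges[[grid$cell_len[g]]]
    prec <- matrix(NA_real_, n_reps, length(thresholds))
    for (r in seq_len(n_reps)) {
      seed <- base_seed + 1000L * g + r
      sim <- simulate_fragments(n_sites, grid$coverage[g], lr,
                                grid$error_rate[g], seed = seed)
      fit <- with_seed(seed + 500L,
                       haplomix(sim$fragments, alpha = alpha, control = control))
      cv <- precision_recall_curve(sim$fragments, fit, sim$truth, thresholds)
      prec[r, ] <- cv$precision
    }
    avg <- colMeans(prec, na.rm = TRUE)
    ok <- which(!is.nan(avg) & avg >= target_precision)
    min_thr <- if (length(ok)) thresholds[ok[1L]] else NA_real_
    rows[[g]] <- data.frame(coverage = grid$coverage[g],
                            l1 = lr[1L], l2 = lr[2L],
                            error_rate = grid$error_rate[g],
                            min_threshold = min_thr)
    if (verbose)
      message(sprintf("c=%d l=[%d,%d] e=%.2f -> min MC %.2f",
                      grid$coverage[g], lr[1L], lr[2L], grid$error_rate[g],
                      min_thr))
  }
  do.call(rbind, rows)
}
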