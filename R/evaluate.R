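#' Pairwise-consistency counts against a known phasing
#'
#' A pair of sites `(j, j')` inside one predicted block is *consistent*
#' when the predicted joint phase equals the true joint phase or its global
#' switch — equivalently, when the predicted relative phase (equal or
#' opposite alleles on haplotype 0) matches the true relative phase.  The
#' counts of consistent (CP) and inconsistent (IP) pairs are summed over
#' all within-block pairs of all blocks.  Unlike the switch-error rate,
#' CP/(CP+IP) reflects the global damage of a switch: one switch in the
#' middle of a block makes about half of its pairs inconsistent, while one
#' near an end affects few.
#'
#' @param blocks list of blocks from [extract_blocks()].
#' @param truth phase vector of haplotype-0 alleles covering all block
#'   sites.
#' @return named numeric vector `c(CP = ..., IP = ...)`.
#' @export
pair_consistency <- function(blocks, truth) {
  cp <- 0
  ip <- 0
  for (b in blocks) {
    tv <- truth[b$sites]
    if (anyNA(tv)) stop("truth phasing is missing at a block site")
    x <- xor(b$phase, tv)            # per-site agreement with haplotype 0
    n1 <- sum(x)
    n0 <- length(x) - n1
    cp <- cp + choose(n0, 2) + choose(n1, 2)
    ip <- ip + n0 * n1
  }
  c(CP = cp, IP = ip)
}

#' Total number of phaseable site pairs
#'
#' The prediction space of the pairwise measures: the sum of
#' `choose(k, 2)` over the connected components (with at least two sites)
#' of the co-spanning site graph.  Pairs in different components can never
#' be phased relative to each other from the fragments, so they are not
#' counted against recall.
#'
#' @param fs a [fragment_set()].
#' @return pair count (scalar).
#' @export
total_pairs <- function(fs) {
  sum(vapply(connected_components(fs),
             function(comp) choose(length(comp), 2), numeric(1)))
}

#' Switch-error rate of predicted blocks
#'
#' A switch error is a neighbouring pair of sites (consecutive within a
#' block) whose predicted relative phase disagrees with the truth.  The
#' rate divides the number of switch errors by the number of neighbouring
#' pairs over all blocks.  Note the known pathology motivating the
#' pairwise measures: an isolated miscalled site produces two adjacent
#' switch errors although the block's front and back remain mutually
#' consistent.
#'
#' @inheritParams pair_consistency
#' @return list with `switch_errors`, `neighbor_pairs` and `rate`.
#' @export
switch_error_rate <- function(blocks, truth) {
  errs <- 0L
  pairs <- 0L
  for (b in blocks) {
    tv <- truth[b$sites]
    if (anyNA(tv)) stop("truth phasing is missing at a block site")
    x <- xor(b$phase, tv)
    errs <- errs + sum(x[-1L] != x[-length(x)])
    pairs <- pairs + length(x) - 1L
  }
  list(switch_errors = errs, neighbor_pairs = pairs,
       rate = if (pairs > 0L) errs / pairs else NaN)
}

# assemble the standard evaluation record
eval_result <- function(cp, ip, total, switch_errors = NA_integer_,
                        neighbor_pairs = NA_integer_) {
  predicted <- cp + ip
  structure(list(
    CP = cp, IP = ip,
    precision = if (predicted > 0) cp / predicted else NaN,
    predicted_pairs = predicted,
    total_pairs = total,
    recall = if (total > 0) predicted / total else NaN,
    switch_errors = switch_errors,
    neighbor_pairs = neighbor_pairs,
    switch_error_rate = if (!is.na(neighbor_pairs) && neighbor_pairs > 0)
      switch_errors / neighbor_pairs else NaN
  ), class = "hap_eval")
}

#' @export
print.hap_eval <- function(x, ...) {
  cat("<hap_eval> CP=", x$CP, " IP=", x$IP,
      " precision=", format(x$precision, digits = 4),
      " recall=", format(x$recall, digits = 4),
      if (!is.na(x$switch_errors))
        paste0(" switch_error_rate=", format(x$switch_error_rate, digits = 4)),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate predicted blocks against a known phasing
#'
#' Combines [pair_consistency()], [switch_error_rate()] and the
#' [total_pairs()] prediction space into one record.
#'
#' @param blocks list of blocks from [extract_blocks()].
#' @param fs the [fragment_set()] defining the prediction space.
#' @param truth phase vector of haplotype-0 alleles.
#' @return A `hap_eval` object with fields `CP`, `IP`, `precision`,
#'   `predicted_pairs`, `total_pairs`, `recall`, `switch_errors`,
#'   `neighbor_pairs`, `switch_error_rate`.
#' @export
evaluate_blocks <- function(blocks, fs, truth) {
  ci <- pair_consistency(blocks, truth)
  se <- switch_error_rate(blocks, truth)
  eval_result(ci[["CP"]], ci[["IP"]], total_pairs(fs),
              se$switch_errors, se$neighbor_pairs)
}

#' Majority-vote baseline without assembly
#'
#' The no-assembly reference point: for every pair of sites co-spanned by
#' at least one fragment, each spanning fragment votes for the relative
#' phase given by its two alleles (equal or opposite); the pair is
#' predicted only when one phase has a strict majority, and scored
#' consistent or inconsistent against the truth.  Tied votes leave the
#' pair unpredicted.  Recall uses the same [total_pairs()] space as the
#' model-based prediction.
#'
#' @param fs a [fragment_set()].
#' @param truth phase vector of haplotype-0 alleles.
#' @return A `hap_eval` object (switch-error fields are `NA`: the baseline
#'   predicts unordered pairs, not contiguous segments).
#' @export
no_assembly_baseline <- function(fs, truth) {
  total <- total_pairs(fs)
  if (fs$n_frag == 0L) return(eval_result(0, 0, total))
  # enumerate all within-fragment site pairs with their vote
  lens <- tabulate(fs$frag, fs$n_frag)
  pair_i <- integer(0)
  pair_j <- integer(0)
  vote <- integer(0)
  off <- c(0L, cumsum(lens))
  for (i in seq_len(fs$n_frag)) {
    idx <- (off[i] + 1L):off[i + 1L]
    s <- fs$site[idx]
    a <- fs$allele[idx]
    pr <- utils::combn(seq_along(s), 2L)
    pair_i <- c(pair_i, s[pr[1L, ]])
    pair_j <- c(pair_j, s[pr[2L, ]])
    vote <- c(vote, as.integer(a[pr[1L, ]] == a[pr[2L, ]]))  # 1 = same allele
  }
  key <- paste(pair_i, pair_j)
  same <- rowsum(vote, key)
  n <- rowsum(rep(1L, length(vote)), key)
  maj <- sign(2 * same - n)                     # +1 same, -1 opposite, 0 tie
  predicted <- maj != 0
  ij <- do.call(rbind, strsplit(rownames(same)[predicted], " "))
  ti <- truth[as.integer(ij[, 1L])]
  tj <- truth[as.integer(ij[, 2L])]
  if (anyNA(ti) || anyNA(tj)) stop("truth phasing is missing at a spanned site")
  true_same <- ifelse(ti == tj, 1, -1)
  cp <- sum(maj[predicted] == true_same)
  eval_result(cp, sum(predicted) - cp, total)
}

#' Precision-recall curve over MC thresholds
#'
#' Extracts blocks at each threshold and evaluates them, giving the
#' operating curve of the MC filter.  Recall is anti-monotone in the
#' threshold.
#'
#' @param fs a [fragment_set()].
#' @param fit a [haplomix()] fit.
#' @param truth phase vector of haplotype-0 alleles.
#' @param thresholds numeric vector of MC thresholds (sorted ascending).
#' @return data frame with one row per threshold: `threshold`, `CP`, `IP`,
#'   `precision`, `predicted_pairs`, `recall`, `switch_error_rate`.
#' @export
precision_recall_curve <- function(fs, fit, truth,
                                   thresholds = seq(-2, 12, by = 0.5)) {
  rows <- lapply(thresholds, function(th) {
    ev <- evaluate_blocks(extract_blocks(fs, fit, th), fs, truth)
    data.frame(threshold = th, CP = ev$CP, IP = ev$IP,
               precision = ev$precision, predicted_pairs = ev$predicted_pairs,
               recall = ev$recall, switch_error_rate = ev$switch_error_rate)
  })
  do.call(rbind, rows)
}
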