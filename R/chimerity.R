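#' Log-likelihood of a fragment against a known haplotype
#'
#' Under a simple per-site error model with rate `alpha0`, the probability
#' of fragment `f` given that it originates from haplotype `h` of the known
#' phasing is `(1 - alpha0)^n * alpha0^(L - n)`, where `n` is the number of
#' spanned sites at which the fragment matches haplotype `h` and `L` the
#' number of spanned sites.  The default `alpha0 = 0.028` is an empirical
#' sequence error rate for pooled fosmid data.
#'
#' @param f a [snp_fragment()].
#' @param truth phase vector of haplotype-0 alleles covering all sites of
#'   `f` (no `NA` among them).
#' @param h haplotype, 0 or 1.
#' @param alpha0 error rate in (0, 1).
#' @return log-probability in nats.
#' @export
truth_loglik <- function(f, truth, h, alpha0 = 0.028) {
  tv <- truth[f$sites]
  if (anyNA(tv)) stop("truth phasing is missing at a site spanned by the fragment")
  hap <- if (h == 0L) tv else 1L - tv
  n <- sum(f$alleles == hap)
  n * log(1 - alpha0) + (length(f$sites) - n) * log(alpha0)
}

#' Chimerity of a fragment
#'
#' Chimeric fragments arise in pooled long-fragment sequencing when read
#' clusters from the two homologous chromosomes are merged into one
#' fragment.  Against a known phasing, chimerity measures the gain in log
#' likelihood from breaking the fragment into a prefix assigned to one
#' haplotype and a suffix assigned to the other:
#' \deqn{-\log\frac{\max_h P_0(f\mid h)}{\max_{j,h} P_0(f_{\le j}\mid h)\,
#'   P_0(f_{> j}\mid \bar h)}}{ -log[max_h P0(f|h) / max_{j,h} P0(f<=j|h) P0(f>j|hbar)] }
#' The split index `j` runs over the spanned sites excluding the last, so
#' both parts are non-empty (allowing the empty suffix would make the score
#' trivially zero for every fragment).  A fragment perfectly matching one
#' haplotype scores `log(alpha0 / (1 - alpha0))` (about -3.55 nats at the
#' default rate); a perfect half-and-half chimera with `k` sites per half
#' scores `k * log((1 - alpha0) / alpha0)`.
#'
#' @inheritParams truth_loglik
#' @return chimerity in nats, with the best split site as attribute
#'   `"split"` (the last site of the prefix).
#' @export
chimerity <- function(f, truth, alpha0 = 0.028) {
  L <- length(f$sites)
  if (L < 2L) stop("chimerity is undefined for fragments spanning < 2 sites")
  tv <- truth[f$sites]
  if (anyNA(tv)) stop("truth phasing is missing at a site spanned by the fragment")
  l1 <- log(1 - alpha0)
  l0 <- log(alpha0)
  match0 <- as.integer(f$alleles == tv)        # matches against haplotype 0
  ll0 <- ifelse(match0 == 1L, l1, l0)          # per-site loglik given h = 0
  ll1 <- ifelse(match0 == 1L, l0, l1)
  whole <- max(sum(ll0), sum(ll1))
  p0 <- cumsum(ll0)[-L]                        # prefix given h = 0
  p1 <- cumsum(ll1)[-L]
  s0 <- sum(ll0) - p0                          # suffix given h = 0
  s1 <- sum(ll1) - p1
  split_ll <- pmax(p0 + s1, p1 + s0)           # prefix h, suffix h-bar
  best <- which.max(split_ll)
  score <- -(whole - split_ll[best])
  attr(score, "split") <- f$sites[best]
  score
}

#' Chimerity report for a fragment set
#'
#' @param fs a [fragment_set()].
#' @inheritParams truth_loglik
#' @return data frame with one row per fragment: `id`, `n_sites`,
#'   `chimerity`, `split_site`.
#' @export
chimerity_report <- function(fs, truth, alpha0 = 0.028) {
  scores <- lapply(fs$fragments, chimerity, truth = truth, alpha0 = alpha0)
  data.frame(
    id = vapply(fs$fragments, `[[`, character(1), "id"),
    n_sites = vapply(fs$fragments, function(f) length(f$sites), integer(1)),
    chimerity = vapply(scores, as.numeric, numeric(1)),
    split_site = vapply(scores, attr, numeric(1), "split")
  )
}

#' Remove potential chimeric fragments
#'
#' Drops every fragment whose chimerity against the known phasing exceeds
#' `threshold` (default 10 nats, at which, for the default error rate, a
#' clean fragment is never removed while a balanced chimera with three or
#' more sites per half always is).
#'
#' @inheritParams chimerity_report
#' @param threshold removal threshold in nats.
#' @return The filtered [fragment_set()]; the number of fragments removed
#'   is attached as attribute `"n_removed"`.
#' @export
filter_chimeric <- function(fs, truth, threshold = 10, alpha0 = 0.028) {
  rep <- chimerity_report(fs, truth, alpha0)
  keep <- rep$chimerity <= threshold
  out <- fs_subset(fs, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}
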