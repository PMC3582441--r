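#' Simulate a SNP fragment dataset
#'
#' Emulates pooled long-fragment sequencing over `n_sites` heterozygous
#' sites: a true phasing is drawn uniformly per site; each of the two
#' haplotypes is replicated `coverage` times; every replicate is cut into
#' consecutive pieces whose lengths are drawn uniformly from
#' `len_range[1]..len_range[2]` (the trailing remainder may be shorter and
#' is kept only if it still spans two sites); finally every emitted allele
#' is flipped independently with probability `error_rate`.  The defaults
#' (`n_sites = 1000`, `coverage = 5`, lengths 3-7, `error_rate = 0.1`)
#' are the standard simulation conditions used throughout the package's
#' evaluation.  Optionally a fraction of fragments is turned into chimeras
#' via [inject_chimeras()].
#'
#' @param n_sites number of heterozygous sites `M`.
#' @param coverage haplotype replications `c` (per haplotype).
#' @param len_range integer bounds `c(l1, l2)` on piece lengths in sites;
#'   `l1 >= 2`.
#' @param error_rate allele flip probability `e` in `[0, 0.5)`.
#' @param chimera_rate fraction of fragments converted to chimeras.
#' @param seed optional integer seed; when given, the result is a
#'   deterministic function of the arguments and the caller's RNG state is
#'   left untouched.
#' @return list with `fragments` (a [fragment_set()]), `truth` (phase
#'   vector of haplotype-0 alleles) and `chimeric` (logical per fragment;
#'   all `FALSE` unless `chimera_rate > 0`).
#' @export
simulate_fragments <- function(n_sites = 1000, coverage = 5,
                               len_range = c(3, 7), error_rate = 0.1,
                               chimera_rate = 0, seed = NULL) {
  l1 <- as.integer(len_range[1L])
  l2 <- as.integer(len_range[2L])
  if (l1 < 2L) stop("minimum fragment length must be at least 2 sites")
  if (l2 < l1) stop("'len_range' must be non-decreasing")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("'error_rate' must be in [0, 0.5)")
  with_seed(seed, {
    truth <- sample(0:1, n_sites, replace = TRUE)
    frags <- list()
    for (h in 0:1) {
      hap <- if (h == 0L) truth else 1L - truth
      for (cc in seq_len(coverage)) {
        pos <- 1L
        piece <- 1L
        while (pos <= n_sites) {
          len <- if (l1 == l2) l1 else sample(l1:l2, 1L)
          sites <- pos:min(pos + len - 1L, n_sites)
          pos <- pos + len
          if (length(sites) < 2L) next
          alleles <- hap[sites]
          if (error_rate > 0) {
            flip <- runif(length(alleles)) < error_rate
            alleles[flip] <- 1L - alleles[flip]
          }
          frags[[length(frags) + 1L]] <-
            snp_fragment(sprintf("sim_h%d_c%d_p%d", h, cc, piece),
                         sites, alleles)
          piece <- piece + 1L
        }
      }
    }
    fs <- fragment_set(frags, n_sites = n_sites)
    chim <- rep(FALSE, fs$n_frag)
    if (chimera_rate > 0) {
      fs <- inject_chimeras(fs, truth, rate = chimera_rate,
                            error_rate = error_rate)
      chim <- attr(fs, "chimeric")
    }
    list(fragments = fs, truth = truth, chimeric = chim)
  })
}

#' Inject chimeric fragments
#'
#' Mimics the erroneous merging of read clusters with different
#' chromosomal origins: for a Bernoulli(`rate`) subset of fragments, the
#' suffix after a uniformly chosen interior spanned site is replaced by
#' the *opposite* haplotype's true alleles, re-flipped at `error_rate`.
#' The fragment count is unchanged.
#'
#' @param fs a [fragment_set()].
#' @param truth phase vector of haplotype-0 alleles.
#' @param rate probability that a fragment is made chimeric.
#' @param error_rate flip probability applied to the resampled suffix.
#' @param seed optional integer seed (see [simulate_fragments()]).
#' @return A [fragment_set()] with a logical attribute `"chimeric"`
#'   marking the altered fragments.
#' @export
inject_chimeras <- function(fs, truth, rate, error_rate = 0, seed = NULL) {
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]")
  with_seed(seed, {
    chim <- runif(fs$n_frag) < rate
    frags <- fs$fragments
    for (i in which(chim)) {
      f <- frags[[i]]
      L <- length(f$sites)
      # fragments carry >= 2 sites, so an interior split always exists
      cut <- if (L == 2L) 1L else sample(L - 1L, 1L)
      suf <- (cut + 1L):L
      # decide which haplotype the prefix matches best, resample the
      # suffix from the other one
      tv <- truth[f$sites]
      pre_match0 <- sum(f$alleles[1:cut] == tv[1:cut])
      from_h0 <- pre_match0 >= cut / 2
      new <- if (from_h0) 1L - tv[suf] else tv[suf]
      if (error_rate > 0) {
        flip <- runif(length(new)) < error_rate
        new[flip] <- 1L - new[flip]
      }
      f$alleles[suf] <- new
      frags[[i]] <- f
    }
    out <- fragment_set(frags, n_sites = fs$n_sites)
    attr(out, "chimeric") <- chim
    out
  })
}
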