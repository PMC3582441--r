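#' Phase-probability parameters of the mixture model
#'
#' The mixture model emits each fragment independently from one of two
#' haplotypes (mixture weights fixed at 1/2 each).  Its free parameters are
#' the per-site phase probabilities `theta[j, ]` over the two possible
#' phases `(0,1)` and `(1,0)` — i.e. the probability that haplotype 0
#' carries allele 0 (column `"p01"`) or allele 1 (column `"p10"`) at site
#' `j` — plus a fixed allele error rate `alpha`.  `alpha` is deliberately
#' not estimated from the SNP-site data: it is better pinned down from
#' external information about sequencing/mapping error, and defaults to 0.1.
#'
#' @param theta numeric matrix with `n_sites` rows and 2 columns; rows must
#'   sum to 1.  Use [phase_to_params()] to build parameters from a known
#'   phase vector.
#' @param alpha allele error rate in `(0, 0.5)`.
#' @return An object of class `phase_params`.
#' @export
phase_params <- function(theta, alpha = 0.1) {
  theta <- as.matrix(theta)
  if (ncol(theta) != 2L) stop("'theta' must have two columns")
  if (any(theta < 0) || any(abs(rowSums(theta) - 1) > 1e-12))
    stop("'theta' rows must be nonnegative and sum to 1")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must be a single value in (0, 0.5)")
  colnames(theta) <- c("p01", "p10")
  structure(list(theta = theta, alpha = alpha), class = "phase_params")
}

#' @export
print.phase_params <- function(x, ...) {
  cat("<phase_params> ", nrow(x$theta), " sites, alpha = ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' Build deterministic parameters from a phase vector
#'
#' Places probability `1 - eps` on the phase given by `phase` (the
#' haplotype-0 allele per site) and splits the rest; unphased (`NA`) sites
#' get the symmetric 1/2-1/2 distribution.  Handy for oracles and for
#' likelihood evaluation at a known truth.
#'
#' @param phase integer vector of haplotype-0 alleles (0/1, `NA` allowed).
#' @param alpha allele error rate.
#' @param eps probability mass left on the opposite phase (0 gives a
#'   degenerate distribution; the likelihood stays finite since the
#'   emission model keeps probability `alpha` on mismatches).
#' @return A [phase_params()] object.
#' @export
phase_to_params <- function(phase, alpha = 0.1, eps = 0) {
  th <- matrix(0.5, length(phase), 2L)
  ok <- !is.na(phase)
  th[ok, ] <- cbind(ifelse(phase[ok] == 0L, 1 - eps, eps),
                    ifelse(phase[ok] == 0L, eps, 1 - eps))
  phase_params(th, alpha)
}

#' Allele emission probability
#'
#' Probability of observing allele `sigma` when the true allele on the
#' emitting haplotype is `sigma_true`: `1 - alpha` on a match and `alpha`
#' on a mismatch, independent of fragment and position.
#'
#' @param sigma,sigma_true observed and true alleles in `{0, 1}`
#'   (vectorised).
#' @param alpha allele error rate.
#' @return numeric vector of probabilities.
#' @export
emission_prob <- function(sigma, sigma_true, alpha = 0.1) {
  if (!all(c(sigma, sigma_true) %in% c(0, 1)))
    stop("alleles must be 0 or 1")
  ifelse(sigma == sigma_true, 1 - alpha, alpha)
}

# per-entry per-haplotype site factors: s_h = sum_nu theta[j, nu] *
# pe(allele | nu_h).  Returns a list with log factors for h = 0 and h = 1.
site_log_factors <- function(site, allele, params) {
  th <- params$theta
  alpha <- params$alpha
  pa0 <- ifelse(allele == 0L, 1 - alpha, alpha)  # pe(allele | true 0)
  pa1 <- 1 - pa0                                 # pe(allele | true 1)
  t1 <- th[site, 1L]
  t2 <- th[site, 2L]
  list(h0 = log(t1 * pa0 + t2 * pa1), h1 = log(t1 * pa1 + t2 * pa0))
}

#' Marginal log-likelihood of fragments
#'
#' `fragment_loglik()` evaluates, for one fragment `f`, the log of
#' `sum_h 0.5 * prod_{j in X(f)} sum_nu theta[j, nu] * pe(f_j | nu_h)`:
#' the fragment's haplotype origin and the phase at each spanned site are
#' marginalised out.  `data_loglik()` sums this over all fragments of a
#' set (fragments are emitted independently).  All arithmetic is in natural
#' log space, so connectivity and chimerity scores downstream are in nats.
#'
#' @param f a [snp_fragment()].
#' @param fs a [fragment_set()].
#' @param params a [phase_params()] with at least `max(sites)` rows.
#' @return log-probability (scalar).
#' @export
fragment_loglik <- function(f, params) {
  if (!length(f$sites)) stop("fragment spans no site")
  if (max(f$sites) > nrow(params$theta))
    stop("fragment spans site beyond the parameter range")
  lf <- site_log_factors(f$sites, f$alleles, params)
  log(0.5) + lse2(sum(lf$h0), sum(lf$h1))
}

#' @rdname fragment_loglik
#' @export
data_loglik <- function(fs, params) {
  if (fs$n_frag == 0L) return(0)
  if (fs$n_sites > nrow(params$theta))
    stop("parameters cover fewer sites than the fragment set")
  lf <- site_log_factors(fs$site, fs$allele, params)
  l0 <- sum_by_index(lf$h0, fs$frag, fs$n_frag)
  l1 <- sum_by_index(lf$h1, fs$frag, fs$n_frag)
  sum(log(0.5) + lse2(l0, l1))
}

#' Twist parameters at a site
#'
#' Swaps the two phase probabilities at every site `j >= j0`, leaving sites
#' before `j0` untouched.  Twisting at `j0 = 1` yields the globally
#' switched parameter set, under which the marginal likelihood is
#' identical; twisting twice at the same site is the identity.
#'
#' @param params a [phase_params()].
#' @param j0 twist site (`1 <= j0 <= n_sites + 1`; `n_sites + 1` is a
#'   no-op).
#' @return A new [phase_params()] object; the input is not modified.
#' @export
twist_params <- function(params, j0) {
  j0 <- as.integer(j0)
  m <- nrow(params$theta)
  if (length(j0) != 1L || is.na(j0) || j0 < 1L || j0 > m + 1L)
    stop("'j0' must be a single site in 1..", m + 1L)
  th <- params$theta
  if (j0 <= m) th[j0:m, ] <- th[j0:m, 2:1]
  phase_params(th, params$alpha)
}
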