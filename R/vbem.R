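#' Dirichlet state of the variational posterior
#'
#' The variational posterior over the phase probabilities factorises over
#' sites into independent two-parameter Dirichlet distributions with
#' hyperparameters `lam[j, ]`; `lam0` holds the prior hyperparameters.  The
#' posterior-mean point estimate of the phase probabilities is
#' `lam / rowSums(lam)`.
#'
#' @param lam strictly positive matrix, `n_sites` rows by 2 columns.
#' @param lam0 prior hyperparameters, same shape (recycled from a scalar).
#' @return An object of class `dirichlet_state`.
#' @export
dirichlet_state <- function(lam, lam0 = 1) {
  lam <- as.matrix(lam)
  if (ncol(lam) != 2L) stop("'lam' must have two columns")
  if (any(lam <= 0)) stop("'lam' must be strictly positive")
  if (length(lam0) == 1L) lam0 <- matrix(lam0, nrow(lam), 2L)
  lam0 <- as.matrix(lam0)
  if (!all(dim(lam0) == dim(lam)) || any(lam0 <= 0))
    stop("'lam0' must be strictly positive and match 'lam'")
  structure(list(lam = unname(lam), lam0 = unname(lam0)),
            class = "dirichlet_state")
}

#' Initialise a Dirichlet state
#'
#' Builds a prior state `lam0 = prior` everywhere, optionally seeded toward
#' a known phase (one extra count on the true phase per phased site, the
#' standard truth-seeded initialisation used to approximate the maximal
#' attainable likelihood) and/or perturbed by uniform jitter to break the
#' switch symmetry of the model, which makes the unjittered symmetric state
#' a saddle point.
#'
#' @param n_sites number of sites.
#' @param prior prior hyperparameter value (scalar or `n_sites` x 2 matrix).
#' @param phase optional phase vector (haplotype-0 alleles; `NA` = skip).
#' @param jitter upper bound of the `U(0, jitter)` perturbation added per
#'   entry (uses the current RNG state).
#' @return A [dirichlet_state()].
#' @export
dirichlet_init <- function(n_sites, prior = 1, phase = NULL, jitter = 0) {
  lam0 <- if (length(prior) == 1L) matrix(prior, n_sites, 2L) else as.matrix(prior)
  lam <- lam0
  if (!is.null(phase)) {
    idx <- which(!is.na(phase))
    lam[cbind(idx, 1L + phase[idx])] <- lam[cbind(idx, 1L + phase[idx])] + 1
  }
  if (jitter > 0) lam <- lam + matrix(runif(2L * n_sites, 0, jitter), n_sites, 2L)
  dirichlet_state(lam, lam0)
}

# twist Dirichlet hyperparameters at j0, like twist_params()
twist_state <- function(state, j0) {
  m <- nrow(state$lam)
  lam <- state$lam
  if (j0 <= m) lam[j0:m, ] <- lam[j0:m, 2:1]
  dirichlet_state(lam, state$lam0)
}

# posterior-mean phase probabilities of a state
posterior_mean_params <- function(state, alpha = 0.1) {
  phase_params(state$lam / rowSums(state$lam), alpha)
}

# Mean-field E-step.  For each fragment entry (i, j) and haplotype origin h,
#   log beta_{ihj nu} = log pe(f_ij | nu_h) + E[log theta_{j nu}]
# with E[log theta] = digamma(lam) - digamma(rowSums(lam)); then
#   q_ih  ∝ 0.5 * prod_j sum_nu beta_{ihj nu}
#   rho_{ihj .} = beta_{ihj .} / sum_nu beta_{ihj nu}.
# Returns responsibilities and the per-fragment normalisers log Z_i.
vb_e_step <- function(fs, state, alpha = 0.1) {
  if (any(state$lam <= 0)) stop("Dirichlet state must be strictly positive")
  el <- digamma(state$lam) - digamma(rowSums(state$lam))
  l_match <- log(1 - alpha)
  l_mis <- log(alpha)
  lpa0 <- ifelse(fs$allele == 0L, l_match, l_mis)   # log pe(a | true 0)
  lpa1 <- ifelse(fs$allele == 1L, l_match, l_mis)
  e1 <- el[fs$site, 1L]
  e2 <- el[fs$site, 2L]
  b01 <- lpa0 + e1   # h = 0, nu = (0,1)
  b02 <- lpa1 + e2   # h = 0, nu = (1,0)
  b11 <- lpa1 + e1   # h = 1, nu = (0,1)
  b12 <- lpa0 + e2   # h = 1, nu = (1,0)
  s0 <- lse2(b01, b02)
  s1 <- lse2(b11, b12)
  lq0 <- log(0.5) + sum_by_index(s0, fs$frag, fs$n_frag)
  lq1 <- log(0.5) + sum_by_index(s1, fs$frag, fs$n_frag)
  log_z <- lse2(lq0, lq1)
  q <- cbind(exp(lq0 - log_z), exp(lq1 - log_z))
  rho0 <- exp(b01 - s0)  # P(nu = (0,1) | h = 0) per entry
  rho1 <- exp(b11 - s1)  # P(nu = (0,1) | h = 1)
  list(q = q, rho0 = rho0, rho1 = rho1, log_z = log_z)
}

# Conjugate M-step: lam = lam0 + expected phase-indicator counts.
vb_m_step <- function(fs, post, lam0) {
  q0 <- post$q[fs$frag, 1L]
  q1 <- post$q[fs$frag, 2L]
  n1 <- q0 * post$rho0 + q1 * post$rho1        # mass on nu = (0,1)
  m <- nrow(lam0)
  lam <- lam0 + cbind(sum_by_index(n1, fs$site, m),
                      sum_by_index(1 - n1, fs$site, m))
  dirichlet_state(lam, lam0)
}

# KL(Dir(lam_j) || Dir(lam0_j)) summed over sites
dirichlet_kl <- function(lam, lam0) {
  s <- rowSums(lam)
  s0 <- rowSums(lam0)
  sum(lgamma(s) - lgamma(s0)) - sum(lgamma(lam) - lgamma(lam0)) +
    sum((lam - lam0) * (digamma(lam) - digamma(s)))
}

#' Run variational Bayes EM to convergence
#'
#' Alternates the mean-field E-step (fragment origin and per-site phase
#' responsibilities) with the conjugate Dirichlet M-step, tracking the
#' evidence lower bound `sum_i log Z_i - sum_j KL(Q_j || prior_j)` after
#' each E-step.  The bound is non-decreasing across cycles; iteration stops
#' when it changes by less than `tol` or after `max_iter` cycles.  The
#' default engine runs the whole loop in compiled code; `engine = "R"` uses
#' the reference implementation and must agree to numerical precision.
#'
#' @param fs a [fragment_set()].
#' @param init a [dirichlet_state()] (see [dirichlet_init()]).
#' @param alpha allele error rate.
#' @param tol convergence tolerance on the ELBO change.
#' @param max_iter maximum number of E/M cycles.
#' @param engine `"cpp"` (default) or `"R"`.
#' @return A list with the converged `state` ([dirichlet_state()]), the
#'   posterior-mean `params` ([phase_params()]), fragment-origin
#'   responsibilities `q`, `elbo`, `elbo_trace` and `n_iter`.
#' @export
run_vbem <- function(fs, init, alpha = 0.1, tol = 1e-6, max_iter = 500L,
                     engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (tol <= 0) stop("'tol' must be positive")
  stopifnot(inherits(init, "dirichlet_state"))
  if (nrow(init$lam) != fs$n_sites)
    stop("state has ", nrow(init$lam), " sites but fragment set has ", fs$n_sites)
  if (fs$n_frag == 0L) {
    return(list(state = init, params = posterior_mean_params(init, alpha),
                q = matrix(numeric(0), 0L, 2L),
                elbo = -dirichlet_kl(init$lam, init$lam0),
                elbo_trace = numeric(0), n_iter = 0L))
  }
  if (engine == "cpp") {
    res <- vbem_run_cpp(fs$frag, fs$site, fs$allele, fs$n_frag, fs$n_sites,
                        init$lam, init$lam0, alpha, tol, as.integer(max_iter))
    state <- dirichlet_state(res$lam, init$lam0)
    return(list(state = state,
                params = posterior_mean_params(state, alpha),
                q = res$q, elbo = res$elbo[length(res$elbo)],
                elbo_trace = as.numeric(res$elbo), n_iter = res$n_iter))
  }
  state <- init
  trace <- numeric(0)
  post <- NULL
  for (it in seq_len(max_iter)) {
    post <- vb_e_step(fs, state, alpha)
    elbo <- sum(post$log_z) - dirichlet_kl(state$lam, state$lam0)
    trace <- c(trace, elbo)
    state <- vb_m_step(fs, post, state$lam0)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) break
  }
  list(state = state, params = posterior_mean_params(state, alpha),
       q = post$q, elbo = trace[length(trace)], elbo_trace = trace,
       n_iter = length(trace))
}
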