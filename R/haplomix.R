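#' Control parameters for [haplomix()]
#'
#' @param tol ELBO convergence tolerance per VBEM run (nats).
#' @param max_iter maximum E/M cycles per VBEM run.
#' @param restarts random restarts of the initial VBEM run; the start with
#'   the best ELBO is kept.
#' @param max_twists cap on twist attempts (each attempt is one VBEM
#'   re-run from a twisted state).
#' @param twist_ceiling only boundaries with connectivity below this value
#'   (nats) are twist candidates; a twist at a strongly supported boundary
#'   cannot raise the likelihood.
#' @param jitter scale of the uniform perturbation added to the prior at
#'   initialisation (breaks the switch symmetry of the model).
#' @param accept_tol minimal data log-likelihood improvement for a twist
#'   to be accepted.
#' @param engine VBEM engine, `"cpp"` (default) or `"R"`.
#' @param verbose print progress of the twist loop.
#' @return list of class `haplomix_control`.
#' @export
haplomix_control <- function(tol = 1e-6, max_iter = 500L, restarts = 3L,
                             max_twists = 100L, twist_ceiling = 2,
                             jitter = 0.1, accept_tol = 1e-6,
                             engine = c("cpp", "R"), verbose = FALSE) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts),
                 max_twists = as.integer(max_twists),
                 twist_ceiling = twist_ceiling, jitter = jitter,
                 accept_tol = accept_tol, engine = match.arg(engine),
                 verbose = isTRUE(verbose)),
            class = "haplomix_control")
}

#' Fit the haplotype mixture model to SNP fragments
#'
#' Fits the two-haplotype mixture model by variational Bayes EM and the
#' twist-restart heuristic.  Each fragment is modelled as emitted from one
#' of two equally probable haplotypes, with per-site phase probabilities
#' carrying a Dirichlet prior and a fixed allele error rate `alpha`.  A
#' converged VBEM run can be trapped in a local optimum containing switch
#' errors; the optimiser therefore repeatedly re-runs VBEM from states
#' whose Dirichlet hyperparameters are twisted (haplotype labels swapped
#' from a low-connectivity boundary onward), accepting a twist only when
#' the marginal data log-likelihood at the posterior-mean parameters
#' improves.  The accepted log-likelihood is non-decreasing across the
#' loop.
#'
#' @param fragments a [fragment_set()] (see [read_fragments()],
#'   [simulate_fragments()]).
#' @param alpha allele error rate of the emission model (fixed, not
#'   estimated; default 0.1).
#' @param prior Dirichlet prior hyperparameter for every (site, phase)
#'   cell (default 1, the flat prior).
#' @param mc_threshold default MC threshold (nats) used by [summary()],
#'   [predict()] and [plot()] methods; 6 retains only strongly supported
#'   boundaries.
#' @param init optional [dirichlet_state()] to start from; overrides the
#'   jittered random restarts (used e.g. for truth-seeded upper-bound
#'   runs).
#' @param control a [haplomix_control()] list.
#' @return An object of class `haplomix`: a list with the converged
#'   `state` ([dirichlet_state()]), posterior-mean `params`
#'   ([phase_params()]), fragment-origin responsibilities `q`, `loglik`
#'   (marginal data log-likelihood at the posterior mean), `elbo` and
#'   `elbo_trace` (of the final accepted run), `connectivity` (per-site
#'   boundary profile), `phase` (called haplotype-0 alleles),
#'   `components`, `twist_trace` (one row per attempt: site, connectivity,
#'   accepted, loglik) and the call.
#' @examples
#' sim <- simulate_fragments(n_sites = 60, coverage = 5, seed = 1)
#' fit <- haplomix(sim$fragments, control = haplomix_control(restarts = 1))
#' fit
#' blocks <- predict(fit, type = "blocks", mc_threshold = 2)
#' evaluate_blocks(blocks, sim$fragments, sim$truth)
#' @export
haplomix <- function(fragments, alpha = 0.1, prior = 1, mc_threshold = 6,
                     init = NULL, control = haplomix_control()) {
  stopifnot(inherits(fragments, "fragment_set"))
  fs <- fragments
  m <- fs$n_sites
  # initial VBEM, best of several jittered restarts
  if (!is.null(init)) {
    best <- run_vbem(fs, init, alpha, control$tol, control$max_iter,
                     control$engine)
  } else {
    best <- NULL
    for (r in seq_len(max(1L, control$restarts))) {
      st <- dirichlet_init(m, prior = prior, jitter = control$jitter)
      fit <- run_vbem(fs, st, alpha, control$tol, control$max_iter,
                      control$engine)
      if (is.null(best) || fit$elbo > best$elbo) best <- fit
    }
  }
  cur <- best
  ll <- data_loglik(fs, cur$params)
  trace <- list()
  attempts <- 0L
  tried <- integer(0)
  # boundaries covered by at least one fragment (a twist elsewhere is a no-op)
  delta <- tabulate(pmin(fs$first + 1L, m + 1L), m + 1L) -
    tabulate(pmin(fs$last + 1L, m + 1L), m + 1L)
  covered <- which(cumsum(delta)[seq_len(m)] > 0L)
  prof <- connectivity_profile(fs, cur$params)
  repeat {
    if (attempts >= control$max_twists) break
    cand <- covered[prof[covered] < control$twist_ceiling]
    cand <- setdiff(cand, tried)
    if (!length(cand)) break
    j0 <- cand[which.min(prof[cand])]
    attempts <- attempts + 1L
    tried <- c(tried, j0)
    alt <- run_vbem(fs, twist_state(cur$state, j0), alpha, control$tol,
                    control$max_iter, control$engine)
    ll_alt <- data_loglik(fs, alt$params)
    accepted <- ll_alt > ll + control$accept_tol
    trace[[attempts]] <- data.frame(site = j0, connectivity = prof[j0],
                                    accepted = accepted, loglik = max(ll, ll_alt))
    if (control$verbose)
      message(sprintf("twist %d at site %d (conn %.3f): %s (loglik %.4f)",
                      attempts, j0, prof[j0],
                      if (accepted) "accepted" else "rejected",
                      max(ll, ll_alt)))
    if (accepted) {
      cur <- alt
      ll <- ll_alt
      tried <- integer(0)
      prof <- connectivity_profile(fs, cur$params)
    }
  }
  structure(list(
    state = cur$state, params = cur$params, q = cur$q,
    loglik = ll, elbo = cur$elbo, elbo_trace = cur$elbo_trace,
    connectivity = prof,
    phase = call_phases(cur$params),
    components = connected_components(fs),
    twist_trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(site = integer(0), connectivity = numeric(0),
                 accepted = logical(0), loglik = numeric(0)),
    n_sites = m, n_frag = fs$n_frag,
    alpha = alpha, prior = prior, mc_threshold = mc_threshold,
    control = control, call = match.call()
  ), class = "haplomix")
}

#' @export
print.haplomix <- function(x, ...) {
  acc <- sum(x$twist_trace$accepted)
  cat("Haplotype mixture model fit (VBEM + twist restarts)\n",
      "  sites: ", x$n_sites, ", fragments: ", x$n_frag,
      ", components: ", length(x$components), "\n",
      "  log-likelihood: ", format(x$loglik, digits = 8),
      "  (", nrow(x$twist_trace), " twist attempts, ", acc, " accepted)\n",
      "  alpha = ", x$alpha, ", MC threshold = ", x$mc_threshold, "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.haplomix <- function(object, mc_threshold = object$mc_threshold, ...) {
  fs_sites <- sort(unique(unlist(object$components)))
  blocks <- extract_blocks_fit(object, mc_threshold)
  tab <- if (length(blocks)) {
    data.frame(
      start = vapply(blocks, function(b) b$sites[1L], integer(1)),
      end = vapply(blocks, function(b) b$sites[length(b$sites)], integer(1)),
      n_sites = vapply(blocks, function(b) length(b$sites), integer(1)),
      MC = vapply(blocks, `[[`, numeric(1), "mc")
    )
  } else {
    data.frame(start = integer(0), end = integer(0), n_sites = integer(0),
               MC = numeric(0))
  }
  structure(list(fit = object, mc_threshold = mc_threshold, blocks = tab,
                 phased_sites = sum(tab$n_sites),
                 component_sites = length(fs_sites)),
            class = "summary.haplomix")
}

#' @export
print.summary.haplomix <- function(x, ...) {
  print(x$fit)
  cat("  blocks at MC >= ", x$mc_threshold, ": ", nrow(x$blocks),
      " covering ", x$phased_sites, "/", x$component_sites,
      " phaseable sites\n", sep = "")
  if (nrow(x$blocks)) {
    print(utils::head(x$blocks, 10L), row.names = FALSE)
    if (nrow(x$blocks) > 10L) cat("  ... ", nrow(x$blocks) - 10L,
                                  " more blocks\n", sep = "")
  }
  invisible(x)
}

# blocks from a fit without re-deriving profile/components; the fragment
# set argument is unused when a full fit is supplied
extract_blocks_fit <- function(fit, mc_threshold) {
  extract_blocks(NULL, fit, mc_threshold)
}

#' @export
coef.haplomix <- function(object, ...) object$params$theta

#' @export
logLik.haplomix <- function(object, ...) {
  structure(object$loglik, df = object$n_sites, nobs = object$n_frag,
            class = "logLik")
}

#' Predict phases or blocks from a fit
#'
#' @param object a [haplomix()] fit.
#' @param type `"blocks"` for confidently phased blocks at the MC
#'   threshold, `"phase"` for the raw per-site phase calls (haplotype-0
#'   alleles over all sites, regardless of confidence).
#' @param mc_threshold MC threshold in nats (defaults to the fit's).
#' @param ... unused.
#' @return list of blocks, or an integer phase vector.
#' @export
predict.haplomix <- function(object, type = c("blocks", "phase"),
                             mc_threshold = object$mc_threshold, ...) {
  type <- match.arg(type)
  if (type == "phase") return(object$phase)
  extract_blocks_fit(object, mc_threshold)
}

#' Plot the connectivity profile of a fit
#'
#' Draws the per-boundary connectivity along the sites with the MC
#' threshold as a horizontal reference; boundaries below the line cut the
#' assembly into blocks.
#'
#' @param x a [haplomix()] fit.
#' @param mc_threshold threshold line to draw (defaults to the fit's).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.haplomix <- function(x, mc_threshold = x$mc_threshold, ...) {
  j <- seq_len(x$n_sites)
  plot(j, x$connectivity, type = "h", col = "grey40",
       xlab = "site", ylab = "connectivity (nats)",
       main = "Boundary connectivity", ...)
  abline(h = mc_threshold, col = "firebrick", lty = 2)
  invisible(x)
}

#' @export
residuals.haplomix <- function(object, ...) {
  stop("residuals are not defined for a haplotype mixture fit; ",
       "use evaluate_blocks() against a known phasing instead")
}
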