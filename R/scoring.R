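#' Connectivity of a site boundary
#'
#' The connectivity at site `j0` is the drop in marginal log-likelihood
#' incurred by twisting the parameters at `j0` (swapping the haplotype
#' labels for all sites `>= j0`):
#' `log P(F | theta) - log P(F | twist(theta, j0))`, in nats.  By the
#' switch symmetry of the model, only the fragments covering `j0`
#' contribute, and the score is computed as that restricted sum.  It
#' measures how strongly the data tie the phasing across the boundary: 0
#' when no fragment covers it, large when a switch there would be clearly
#' inconsistent with the covering fragments.
#'
#' @param fs a [fragment_set()].
#' @param params a [phase_params()] (typically the posterior mean of a fit).
#' @param j0 boundary site, `1 <= j0 <= n_sites`.
#' @return connectivity in nats (scalar).
#' @seealso [connectivity_profile()] for all boundaries at once,
#'   [mc_score()], [extract_blocks()]
#' @export
connectivity <- function(fs, params, j0) {
  j0 <- as.integer(j0)
  if (length(j0) != 1L || is.na(j0) || j0 < 1L || j0 > fs$n_sites)
    stop("'j0' must be a single site in 1..", fs$n_sites)
  idx <- covering_index(fs, j0)
  if (!length(idx)) return(0)
  sub <- fs_subset(fs, idx)
  data_loglik(sub, params) - data_loglik(sub, twist_params(params, j0))
}

#' Connectivity at every boundary
#'
#' Computes `connectivity(fs, params, j)` for all `j = 1..n_sites` in a
#' single pass using per-fragment prefix products: a fragment spanning
#' sites `s_1 < ... < s_L` contributes the same likelihood difference to
#' every boundary in `(s_k, s_{k+1}]`.
#'
#' @inheritParams connectivity
#' @return numeric vector of length `n_sites` (entry 1 is always 0).
#' @export
connectivity_profile <- function(fs, params) {
  m <- fs$n_sites
  if (fs$n_frag == 0L) return(numeric(m))
  lf <- site_log_factors(fs$site, fs$allele, params)
  c0 <- grouped_cumsum(lf$h0, fs$frag)
  c1 <- grouped_cumsum(lf$h1, fs$frag)
  tot0 <- sum_by_index(lf$h0, fs$frag, fs$n_frag)
  tot1 <- sum_by_index(lf$h1, fs$frag, fs$n_frag)
  ll <- log(0.5) + lse2(tot0, tot1)          # per-fragment log-likelihood
  # entries that are not the last of their fragment define a split
  n <- length(fs$frag)
  not_last <- fs$frag == c(fs$frag[-1L], 0L)
  f <- fs$frag[not_last]
  # twisted log-likelihood when the suffix after this entry is flipped
  lt <- log(0.5) + lse2(c0[not_last] + tot1[f] - c1[not_last],
                        c1[not_last] + tot0[f] - c0[not_last])
  d <- ll[f] - lt
  lo <- fs$site[not_last] + 1L                         # first boundary affected
  hi <- fs$site[c(FALSE, not_last[-n])]                # last boundary affected
  add <- numeric(m + 1L)
  tmp <- rowsum(c(d, -d), c(lo, hi + 1L))
  idx <- as.integer(rownames(tmp))
  ok <- idx <= m + 1L
  add[idx[ok]] <- tmp[ok]
  cumsum(add)[seq_len(m)]
}

#' Minimum connectivity (MC) over a site range
#'
#' The MC score of a pair `(j1, j2)` is the minimum connectivity over the
#' boundaries `j1 < j <= j2`; a range phased with high MC contains no
#' weakly supported cut and is therefore protected against switch errors.
#' If MC exceeds a threshold for `(j1, j2)` it exceeds it for every pair
#' inside the range, so MC can be viewed as defined on ranges.
#'
#' @param connectivities numeric vector of per-boundary connectivities
#'   indexed by site (as returned by [connectivity_profile()]).
#' @param j1,j2 range endpoints, `j1 < j2`.
#' @return MC score in nats.
#' @export
mc_score <- function(connectivities, j1, j2) {
  if (j1 >= j2) stop("'j1' must be smaller than 'j2'")
  min(connectivities[(j1 + 1L):j2])
}

#' Call phases from a fitted model
#'
#' Selects, at each site, the phase with the larger posterior-mean
#' probability; an exact tie is broken deterministically to phase `(0,1)`
#' (haplotype-0 allele 0).  The globally switched call is an equivalent
#' prediction.
#'
#' @param fit a [haplomix()] fit, or a [phase_params()] object.
#' @return integer phase vector of haplotype-0 alleles (length `n_sites`).
#' @export
call_phases <- function(fit) {
  theta <- if (inherits(fit, "phase_params")) fit$theta
           else if (inherits(fit, "haplomix")) fit$params$theta
           else stop("'fit' must be a haplomix fit or phase_params")
  as.integer(theta[, 2L] > theta[, 1L])
}

#' Extract confidently phased blocks
#'
#' Within each connected component of the co-spanning site graph, reports
#' the maximal runs of consecutive member sites whose internal boundaries
#' all have connectivity at or above `mc_threshold`; runs of fewer than two
#' sites are discarded.  Every site pair inside a reported block then has
#' an MC score of at least the threshold.  Boundaries are taken between
#' consecutive sites *of the component*, so components that are
#' non-contiguous in coordinates are handled.
#'
#' @param fs a [fragment_set()].
#' @param fit a [haplomix()] fit (or [phase_params()], from which the
#'   connectivity profile and phase calls are computed).
#' @param mc_threshold minimum boundary connectivity, in nats; the package
#'   default of 6 retains only strongly supported cuts, `-Inf` yields one
#'   block per component.
#' @return list of `hap_block` objects with fields `sites`, `phase`
#'   (haplotype-0 alleles), `boundary_connectivity` (named by the right
#'   site of each internal boundary) and `mc`.
#' @export
extract_blocks <- function(fs, fit, mc_threshold = 6) {
  if (inherits(fit, "haplomix")) {
    conn <- fit$connectivity
    phase <- fit$phase
    comps <- fit$components
  } else {
    conn <- connectivity_profile(fs, fit)
    phase <- call_phases(fit)
    comps <- connected_components(fs)
  }
  blocks <- list()
  for (comp in comps) {
    k <- length(comp)
    keep <- conn[comp[-1L]] >= mc_threshold   # boundary before comp[i+1]
    runs <- split(seq_len(k), cumsum(c(TRUE, !keep)))
    for (r in runs) {
      if (length(r) < 2L) next
      sites <- comp[r]
      bc <- conn[sites[-1L]]
      names(bc) <- sites[-1L]
      blocks[[length(blocks) + 1L]] <- structure(
        list(sites = sites, phase = phase[sites],
             boundary_connectivity = bc, mc = min(bc)),
        class = "hap_block")
    }
  }
  blocks
}

#' @export
print.hap_block <- function(x, ...) {
  cat("<hap_block> sites ", x$sites[1L], "-", x$sites[length(x$sites)],
      " (n=", length(x$sites), "), MC = ", format(x$mc, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Write or read phased blocks
#'
#' Plain-text block format: a header line
#' `BLOCK start=<j1> end=<j2> n=<k> MC=<score>` followed by one line per
#' site, `<site> <hap0_allele> <hap1_allele> <connectivity|.>`, where the
#' connectivity column gives the boundary score at the site's left boundary
#' (`.` for the first site of a block).  Scores are in nats.
#'
#' @param blocks list of blocks from [extract_blocks()].
#' @param path file to write or read.
#' @return `write_blocks()` returns `path` invisibly; `read_blocks()`
#'   returns a list of `hap_block` objects.
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# haplomix blocks; connectivity/MC in nats", con)
  for (b in blocks) {
    writeLines(sprintf("BLOCK start=%d end=%d n=%d MC=%.6g",
                       b$sites[1L], b$sites[length(b$sites)],
                       length(b$sites), b$mc), con)
    conn <- c(".", sprintf("%.6g", b$boundary_connectivity))
    writeLines(paste(b$sites, b$phase, 1L - b$phase, conn), con)
  }
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  starts <- which(startsWith(lines, "BLOCK"))
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    body <- lines[(starts[k] + 1L):ends[k]]
    tok <- do.call(rbind, strsplit(body, "[[:space:]]+"))
    sites <- as.integer(tok[, 1L])
    bc <- as.numeric(tok[-1L, 4L])
    names(bc) <- sites[-1L]
    structure(list(sites = sites, phase = as.integer(tok[, 2L]),
                   boundary_connectivity = bc, mc = min(bc)),
              class = "hap_block")
  })
}
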