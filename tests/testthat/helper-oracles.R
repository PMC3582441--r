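# Shared fixtures and independent brute-force oracles.

# build a fragment_set from matrix-dialect strings ("0", "1", "-")
fs_from_rows <- function(rows, n_sites = NULL) {
  frags <- lapply(seq_along(rows), function(i) {
    chars <- strsplit(rows[i], "")[[1]]
    sites <- which(chars != "-")
    snp_fragment(paste0("f", i), sites, as.integer(chars[sites]))
  })
  fragment_set(frags, n_sites = n_sites %||% max(nchar(rows)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small fragment set for property checks
random_fs <- function(n_frag, n_sites, span_max = n_sites) {
  frags <- lapply(seq_len(n_frag), function(i) {
    k <- sample(2:min(span_max, n_sites), 1)
    sites <- sort(sample(n_sites, k))
    snp_fragment(paste0("r", i), sites, sample(0:1, k, replace = TRUE))
  })
  fragment_set(frags, n_sites = n_sites)
}

random_params <- function(n_sites, alpha = 0.1) {
  t1 <- runif(n_sites, 0.01, 0.99)
  phase_params(cbind(t1, 1 - t1), alpha)
}

# Oracle: fragment marginal likelihood by exhaustive enumeration over the
# haplotype origin h and all 2^L phase assignments over the spanned sites.
brute_fragment_loglik <- function(f, params) {
  th <- params$theta
  alpha <- params$alpha
  L <- length(f$sites)
  total <- 0
  for (h in 0:1) {
    for (mask in 0:(2^L - 1)) {
      nu <- as.integer(intToBits(mask))[1:L]   # 0 = phase (0,1), 1 = (1,0)
      p <- 0.5
      for (k in 1:L) {
        j <- f$sites[k]
        hap_allele <- if (nu[k] == 0) h else 1 - h  # allele of haplotype h
        pe <- if (f$alleles[k] == hap_allele) 1 - alpha else alpha
        p <- p * th[j, nu[k] + 1] * pe
      }
      total <- total + as.numeric(p)
    }
  }
  log(total)
}

brute_data_loglik <- function(fs, params) {
  sum(vapply(fs$fragments, brute_fragment_loglik, numeric(1), params = params))
}

# Oracle: covering fragments straight from the definition j1 < j <= j2
brute_covering <- function(fs, j) {
  keep <- vapply(fs$fragments, function(f) {
    any(outer(f$sites, f$sites, function(a, b) a < j & j <= b))
  }, logical(1))
  fs$fragments[keep]
}

# Oracle: chimerity by exhaustive enumeration over split sites and origins
brute_chimerity <- function(f, truth, alpha0 = 0.028) {
  L <- length(f$sites)
  whole <- max(truth_loglik(f, truth, 0L, alpha0),
               truth_loglik(f, truth, 1L, alpha0))
  best <- -Inf
  for (k in 1:(L - 1)) {
    pre <- snp_fragment("pre", f$sites[1:k], f$alleles[1:k])
    suf <- snp_fragment("suf", f$sites[(k + 1):L], f$alleles[(k + 1):L])
    for (h in 0:1) {
      val <- truth_loglik(pre, truth, h, alpha0) +
        truth_loglik(suf, truth, 1L - h, alpha0)
      best <- max(best, val)
    }
  }
  -(whole - best)
}

# Oracle: CP/IP by direct enumeration of all in-block site pairs
brute_pair_consistency <- function(blocks, truth) {
  cp <- 0; ip <- 0
  for (b in blocks) {
    n <- length(b$sites)
    for (a in 1:(n - 1)) for (d in (a + 1):n) {
      ja <- b$sites[a]; jd <- b$sites[d]
      pred_same <- b$phase[a] == b$phase[d]
      true_same <- truth[ja] == truth[jd]
      if (pred_same == true_same) cp <- cp + 1 else ip <- ip + 1
    }
  }
  c(CP = cp, IP = ip)
}

# truth-seeded fit: VBEM started from the known phase (one extra Dirichlet
# count on the true phase per site)
truth_seeded_loglik <- function(fs, truth, alpha = 0.1, prior = 1) {
  st <- dirichlet_init(fs$n_sites, prior = prior, phase = truth)
  fit <- run_vbem(fs, st, alpha = alpha)
  data_loglik(fs, fit$params)
}
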