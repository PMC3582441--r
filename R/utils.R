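# internal numerical helpers

# elementwise log(exp(a) + exp(b)), stable for large negative inputs
lse2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> -Inf without NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# cumulative sum of x restarting at each new group; groups must be contiguous
grouped_cumsum <- function(x, group) {
  cs <- cumsum(x)
  first <- which(!duplicated(group))
  offset <- rep(c(0, cs[first[-1] - 1]), diff(c(first, length(x) + 1L)))
  cs - offset
}

# sum x by integer index into a vector of length n (absent indices get 0)
sum_by_index <- function(x, index, n) {
  tmp <- rowsum(x, index)
  out <- numeric(n)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

# temporarily set the RNG seed, restoring prior state on exit
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
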