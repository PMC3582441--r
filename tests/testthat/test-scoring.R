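test_that("connectivity matches the likelihood-drop definition", {
  # single fragment {1,2} with alleles (0,0), deterministic phase (0,1):
  # P = 0.41 untwisted, 0.09 twisted at 2
  fs <- fs_from_rows("00")
  det <- phase_to_params(c(0L, 0L), alpha = 0.1)
  expect_equal(connectivity(fs, det, 2), log(0.41 / 0.09))
  expect_equal(connectivity(fs, det, 1), 0)  # nothing covers the cut at 1
  # uncovered site in a larger set
  fs2 <- fs_from_rows(c("11---", "---00"))
  expect_equal(connectivity(fs2, random_params(5), 3), 0)
  # restricted sum equals the full-likelihood difference on random inputs
  set.seed(101)
  for (rep in 1:5) {
    fs <- random_fs(n_frag = 8, n_sites = 10)
    params <- random_params(10)
    for (j0 in 1:10) {
      full <- data_loglik(fs, params) -
        data_loglik(fs, twist_params(params, j0))
      expect_equal(connectivity(fs, params, j0), full, tolerance = 1e-10)
    }
  }
})

test_that("the profile equals per-boundary connectivity everywhere", {
  set.seed(111)
  for (rep in 1:5) {
    fs <- random_fs(n_frag = 10, n_sites = 12)
    params <- random_params(12)
    prof <- connectivity_profile(fs, params)
    expect_equal(prof,
                 vapply(1:12, function(j) connectivity(fs, params, j),
                        numeric(1)),
                 tolerance = 1e-10)
  }
})

test_that("MC score is the minimum over interior boundaries", {
  conn <- c(NA, 1.5, 0.2, 3.0)
  expect_equal(mc_score(conn, 1, 4), 0.2)
  expect_equal(mc_score(conn, 3, 4), 3.0)
  expect_error(mc_score(conn, 3, 3), "smaller")
  # nested monotonicity: MC(j1,j3) <= min(MC(j1,j2), MC(j2,j3))
  set.seed(121)
  conn <- c(NA, runif(9))
  for (rep in 1:20) {
    js <- sort(sample(1:10, 3))
    expect_lte(mc_score(conn, js[1], js[3]),
               min(mc_score(conn, js[1], js[2]), mc_score(conn, js[2], js[3])))
  }
})

test_that("phase calls take the posterior-mean argmax with a fixed tie rule", {
  params <- phase_params(rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8)))
  expect_equal(call_phases(params), c(0L, 0L, 1L))  # tie -> phase (0,1)
  expect_equal(call_phases(twist_params(params, 1))[c(1, 3)], c(1L, 0L))
})

test_that("blocks are maximal runs above the MC threshold", {
  stub <- structure(list(connectivity = c(0, 7, 2, 8), phase = c(0L, 0L, 1L, 1L),
                         components = list(1:4)), class = "haplomix")
  blocks <- extract_blocks(NULL, stub, 6)
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$sites, 1:2)
  expect_equal(blocks[[2]]$sites, 3:4)
  expect_equal(blocks[[1]]$mc, 7)
  # -Inf: one block per component; +Inf: none
  expect_length(extract_blocks(NULL, stub, -Inf), 1L)
  expect_length(extract_blocks(NULL, stub, Inf), 0L)
  # every in-block pair clears the threshold via mc_score
  set.seed(131)
  sim <- simulate_fragments(n_sites = 60, coverage = 3, seed = 17)
  fit <- haplomix(sim$fragments, control = haplomix_control(restarts = 1))
  for (th in c(0, 2, 6)) {
    for (b in extract_blocks(sim$fragments, fit, th)) {
      expect_gte(b$mc, th)
      n <- length(b$sites)
      expect_gte(mc_score(fit$connectivity, b$sites[1], b$sites[n]), th)
    }
  }
})

test_that("raising the threshold never adds predicted pairs", {
  sim <- simulate_fragments(n_sites = 80, coverage = 3, seed = 23)
  fit <- haplomix:::with_seed(1L, haplomix(sim$fragments,
                                           control = haplomix_control(restarts = 1)))
  pairs_at <- function(th) sum(vapply(extract_blocks(sim$fragments, fit, th),
                                      function(b) choose(length(b$sites), 2),
                                      numeric(1)))
  counts <- vapply(seq(-1, 10, by = 0.5), pairs_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("block membership is invariant under the global parameter switch", {
  sim <- simulate_fragments(n_sites = 50, coverage = 4, seed = 29)
  fit <- haplomix:::with_seed(2L, haplomix(sim$fragments,
                                           control = haplomix_control(restarts = 1)))
  sw <- twist_params(fit$params, 1)
  b1 <- extract_blocks(sim$fragments, fit$params, 4)
  b2 <- extract_blocks(sim$fragments, sw, 4)
  expect_equal(lapply(b1, `[[`, "sites"), lapply(b2, `[[`, "sites"))
  # phases are globally switched, an equivalent prediction
  expect_equal(lapply(b1, function(b) 1L - b$phase), lapply(b2, `[[`, "phase"))
})

test_that("block files round-trip", {
  stub <- structure(list(connectivity = c(0, 7.25, 2, 8.5),
                         phase = c(0L, 1L, 1L, 0L),
                         components = list(1:4)), class = "haplomix")
  blocks <- extract_blocks(NULL, stub, 6)
  p <- withr::local_tempfile()
  write_blocks(blocks, p)
  back <- read_blocks(p)
  expect_equal(lapply(back, `[[`, "sites"), lapply(blocks, `[[`, "sites"))
  expect_equal(lapply(back, `[[`, "phase"), lapply(blocks, `[[`, "phase"))
  expect_equal(vapply(back, `[[`, numeric(1), "mc"),
               vapply(blocks, `[[`, numeric(1), "mc"), tolerance = 1e-5)
})
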