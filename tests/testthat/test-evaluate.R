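make_block <- function(sites, phase) {
  structure(list(sites = as.integer(sites), phase = as.integer(phase),
                 boundary_connectivity = setNames(rep(NA_real_,
                                                      length(sites) - 1L),
                                                  sites[-1L]),
                 mc = NA_real_), class = "hap_block")
}

test_that("pair consistency counts switch damage globally", {
  truth <- rep(0L, 5)
  # one switch after site 2: pairs within {1,2} and {3,4,5} stay consistent
  pred <- make_block(1:5, c(0, 0, 1, 1, 1))
  ci <- pair_consistency(list(pred), truth)
  expect_equal(ci, c(CP = 4, IP = 6))
  expect_equal(ci[["CP"]] / sum(ci), 0.4)
  # the global switch of the truth is an equivalent phasing
  expect_equal(pair_consistency(list(pred), 1L - truth), ci)
  perfect <- make_block(1:5, 1L - truth)
  expect_equal(pair_consistency(list(perfect), truth)[["IP"]], 0)
  # two switches bracketing a middle run: front and back stay consistent
  bracket <- make_block(1:5, c(0, 1, 1, 0, 0))
  expect_equal(pair_consistency(list(bracket), truth),
               brute_pair_consistency(list(bracket), truth))
  expect_equal(pair_consistency(list(bracket), truth)[["CP"]], 4)  # {1,4},{1,5},{4,5},{2,3}
  # enumeration oracle on random blocks; CP + IP covers every pair
  set.seed(161)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    truth_r <- sample(0:1, 10, replace = TRUE)
    b <- make_block(sort(sample(10, n)), sample(0:1, n, replace = TRUE))
    ci <- pair_consistency(list(b), truth_r)
    expect_equal(ci, brute_pair_consistency(list(b), truth_r))
    expect_equal(sum(ci), choose(n, 2))
  }
})

test_that("the prediction space sums pairs over components", {
  set.seed(171)
  fs10 <- random_fs(n_frag = 12, n_sites = 10, span_max = 4)
  comps <- connected_components(fs10)
  expect_equal(total_pairs(fs10),
               sum(vapply(comps, function(x) choose(length(x), 2), numeric(1))))
  one <- fragment_set(list(snp_fragment("a", 1:10, rep(0L, 10))))
  expect_equal(total_pairs(one), 45)
  two <- fragment_set(list(snp_fragment("a", c(1, 4, 5), c(0, 0, 0)),
                           snp_fragment("b", 2:3, c(0, 0))))
  expect_equal(total_pairs(two), 4)
  expect_equal(total_pairs(fragment_set(list())), 0)
})

test_that("switch errors count neighbouring inconsistencies", {
  truth <- rep(0L, 5)
  one_switch <- make_block(1:5, c(0, 0, 1, 1, 1))
  expect_equal(switch_error_rate(list(one_switch), truth)$rate, 0.25)
  # an isolated miscalled site counts twice although only one site is wrong
  lone <- make_block(1:5, c(0, 0, 1, 0, 0))
  se <- switch_error_rate(list(lone), truth)
  expect_equal(se$switch_errors, 2L)
  expect_equal(se$rate, 0.5)
  expect_equal(switch_error_rate(list(make_block(1:5, truth)), truth)$rate, 0)
})

test_that("majority voting predicts strict-majority pairs only", {
  # sites {1,2}: two fragments vote equal-alleles, one votes opposite
  fs <- fs_from_rows(c("00", "00", "01"))
  ev <- no_assembly_baseline(fs, c(0L, 0L))
  expect_equal(ev$predicted_pairs, 1)
  expect_equal(ev$CP, 1)
  expect_equal(ev$recall, 1)
  # against a truth with opposite relative phase the vote is inconsistent
  expect_equal(no_assembly_baseline(fs, c(0L, 1L))$IP, 1)
  # a tied vote leaves the pair unpredicted
  tie <- fs_from_rows(c("00", "01"))
  expect_equal(no_assembly_baseline(tie, c(0L, 0L))$predicted_pairs, 0)
  # noise-free simulation: every predicted pair is consistent
  sim <- simulate_fragments(n_sites = 100, coverage = 3, error_rate = 0,
                            seed = 19)
  ev <- no_assembly_baseline(sim$fragments, sim$truth)
  expect_equal(ev$precision, 1)
  expect_lt(ev$recall, 1)   # only co-spanned pairs can be voted on
})

test_that("precision-recall curves are anti-monotone in the threshold", {
  sim <- simulate_fragments(n_sites = 80, coverage = 4, seed = 37)
  fit <- haplomix:::with_seed(3L, haplomix(sim$fragments,
                                           control = haplomix_control(restarts = 1)))
  cv <- precision_recall_curve(sim$fragments, fit, sim$truth,
                               thresholds = c(-Inf, 0, 2, 4, 8))
  expect_equal(cv$recall[1], 1)   # no filtering keeps whole components
  expect_true(all(diff(cv$predicted_pairs) <= 0))
  # noise-free data is phased perfectly at every threshold
  sim0 <- simulate_fragments(n_sites = 80, coverage = 4, error_rate = 0,
                             seed = 41)
  fit0 <- haplomix:::with_seed(4L, haplomix(sim0$fragments,
                                            control = haplomix_control(restarts = 1)))
  cv0 <- precision_recall_curve(sim0$fragments, fit0, sim0$truth,
                                thresholds = c(-Inf, 0, 2))
  expect_true(all(cv0$precision == 1))
})
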