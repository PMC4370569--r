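test_that("mean_diff_statistic is the member vs non-member mean difference", {
  expect_equal(mean_diff_statistic(c(2, 2, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 2)
  expect_equal(mean_diff_statistic(c(3, 1, 1, 1), c(TRUE, FALSE, FALSE, FALSE)), 2)
  expect_equal(mean_diff_statistic(rep(5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0)
  expect_error(mean_diff_statistic(1:4, rep(TRUE, 4)), "degenerate")
  expect_error(mean_diff_statistic(1:4, rep(FALSE, 4)), "degenerate")
})

test_that("circular_shift rotates labels per chromosome and conserves counts", {
  expect_identical(circular_shift(c(TRUE, FALSE, FALSE, FALSE), 1),
                   c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(circular_shift(c(TRUE, FALSE, FALSE, FALSE), 0),
                   c(TRUE, FALSE, FALSE, FALSE))
  # full cycle is the identity
  expect_identical(circular_shift(c(TRUE, FALSE, TRUE, FALSE), 4),
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_error(circular_shift(c(TRUE, FALSE), 5), "out of range")
  # per-chromosome rotation, conservation of per-chromosome counts
  set.seed(3)
  chrom <- rep(c("a", "b"), c(7, 5))
  for (i in 1:20) {
    mask <- runif(12) < 0.4
    offs <- c(sample(0:6, 1), sample(0:4, 1))
    sh <- circular_shift(mask, offs, chrom)
    expect_equal(sum(sh[chrom == "a"]), sum(mask[chrom == "a"]))
    expect_equal(sum(sh[chrom == "b"]), sum(mask[chrom == "b"]))
  }
})

test_that("exhaustive enumeration matches hand-derived small cases", {
  vals <- c(3, 1, 1, 1)
  mask <- c(TRUE, FALSE, FALSE, FALSE)
  et <- exhaustive_test(vals, mask, alternative = "greater")
  # null stats over the 4 offsets are {2, -2/3, -2/3, -2/3}
  expect_equal(sort(et$null_stats), sort(c(2, rep(-2/3, 3))))
  expect_equal(et$n_permutations, 4L)
  # only the identity attains >= 2
  expect_equal(et$p_value, 1 / 4)
  # all values equal: p = 1
  expect_equal(exhaustive_test(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE),
                               alternative = "greater")$p_value, 1)
  # two chromosomes of 3 probes each enumerate 9 offset pairs
  et2 <- exhaustive_test(rnorm(6), c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                         chrom = rep(c("a", "b"), each = 3))
  expect_equal(et2$n_permutations, 9L)
  expect_error(
    exhaustive_test(rnorm(4000), c(TRUE, rep(FALSE, 3999)),
                    chrom = rep(c("a", "b"), each = 2000),
                    max_combinations = 1e6),
    "permutation_test"
  )
})

test_that("sampled p-values are smoothed, bounded and seed-reproducible", {
  vals <- c(3, 1, 1, 1)
  mask <- c(TRUE, FALSE, FALSE, FALSE)
  pt <- permutation_test(vals, mask, n_permutations = 100, seed = 7,
                         alternative = "greater")
  expect_gte(pt$p_value, 1 / 101)
  expect_lte(pt$p_value, 1)
  expect_length(pt$null_stats, 100)
  pt2 <- permutation_test(vals, mask, n_permutations = 100, seed = 7,
                          alternative = "greater")
  expect_identical(pt$null_stats, pt2$null_stats)
  expect_identical(pt$p_value, pt2$p_value)
  pt3 <- permutation_test(vals, mask, n_permutations = 100, seed = 8,
                          alternative = "greater")
  expect_false(identical(pt$null_stats, pt3$null_stats))
  # constant values: every rotation gives the observed 0, p = 1
  ptc <- permutation_test(rep(4, 6), c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                          n_permutations = 50, seed = 1)
  expect_equal(ptc$p_value, 1)
})

test_that("sampled test converges to the exhaustive oracle", {
  set.seed(21)
  worst <- 0
  for (i in 1:15) {
    n1 <- sample(15:40, 1); n2 <- sample(15:40, 1)
    chrom <- rep(c("a", "b"), c(n1, n2))
    vals <- c(as.numeric(stats::arima.sim(list(ar = 0.6), n1)),
              as.numeric(stats::arima.sim(list(ar = 0.6), n2)))
    mask <- rep(FALSE, n1 + n2)
    mask[sample(n1, 4)] <- TRUE
    mask[n1 + sample(n2, 4)] <- TRUE
    pe <- exhaustive_test(vals, mask, chrom)$p_value
    ps <- permutation_test(vals, mask, chrom, n_permutations = 4000,
                           seed = 100 + i)$p_value
    se <- sqrt(pe * (1 - pe) / 4000)
    worst <- max(worst, abs(ps - pe) / max(se, 1e-6))
  }
  expect_lt(worst, 4)
})

test_that("the statistic is invariant under joint rotation of mask and values", {
  set.seed(5)
  chrom <- rep(c("a", "b"), c(20, 30))
  vals <- rnorm(50)
  mask <- runif(50) < 0.3
  mask[1] <- TRUE; mask[21] <- TRUE  # ensure members on both chromosomes
  obs <- mean_diff_statistic(vals, mask)
  for (i in 1:10) {
    offs <- c(sample(0:19, 1), sample(0:29, 1))
    vshift <- vals
    vshift[1:20] <- vals[1:20][((seq_len(20) - 1 - offs[1]) %% 20) + 1]
    vshift[21:50] <- vals[21:50][((seq_len(30) - 1 - offs[2]) %% 30) + 1]
    mshift <- circular_shift(mask, offs, chrom)
    expect_equal(mean_diff_statistic(vshift, mshift), obs)
  }
})

test_that("p-value decreases stochastically with injected effect size", {
  pvals <- sapply(c(0, 0.5, 1, 2), function(eff) {
    ps <- sapply(1:12, function(r) {
      g <- make_genome_and_features(
        c(chrA = 30000),
        feature_plan = data.frame(class = "tRNA", n = 10L, length = 300L,
                                  placement = "uniform"),
        subtelomere_length = 0, seed = 300 + r)
      sim <- simulate_probe_signal(g$layout, g$features, "tRNA",
                                   effect = eff, seed = 400 + r)
      permutation_test_track(sim$ratio, sim$mask, n_permutations = 99,
                             seed = 500 + r, alternative = "greater")$p_value
    })
    mean(ps)
  })
  expect_true(all(diff(pvals) <= 0.05))  # monotone up to noise
  expect_lt(pvals[4], 0.1)
})

test_that("joint mode applies one offset across the concatenated genome", {
  set.seed(9)
  chrom <- rep(c("a", "b"), each = 10)
  vals <- rnorm(20)
  mask <- rep(FALSE, 20); mask[c(2, 15)] <- TRUE
  et <- exhaustive_test(vals, mask, chrom, mode = "joint")
  expect_equal(et$n_permutations, 20L)
  etp <- exhaustive_test(vals, mask, chrom, mode = "per_chromosome")
  expect_equal(etp$n_permutations, 100L)
})
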