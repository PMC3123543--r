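test_that("sample_derangement produces fixed-point-free permutations", {
  expect_identical(sample_derangement(2, rng_seed = 1), c(2L, 1L))
  expect_error(sample_derangement(1), "n < 2")
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:9, 1)
    perm <- sample_derangement(n)
    expect_identical(sort(perm), seq_len(n))
    expect_true(all(perm != seq_len(n)))
  }
})

test_that("permute_dataset preserves marginals and breaks the pairing", {
  synth <- toy_paired(p = 4, m = 5, seed = 9)
  pd <- synth$paired
  perm_data <- permute_dataset(pd, rng_seed = 3)
  perm <- attr(perm_data, "derangement")
  expect_true(all(perm != seq_len(pd$n)))
  # per-gene sorted value multisets unchanged
  expect_equal(t(apply(perm_data$mrna$values, 1, sort)),
               t(apply(pd$mrna$values, 1, sort)))
  # miRNA block untouched; labels preserved
  expect_identical(perm_data$mirna$values, pd$mirna$values)
  expect_identical(colnames(perm_data$mrna$values), colnames(pd$mrna$values))
  # determinism
  expect_identical(permute_dataset(pd, rng_seed = 3)$mrna$values,
                   perm_data$mrna$values)
})

test_that("correlation_significant_pairs matches a brute-force oracle", {
  synth <- toy_paired(p = 5, m = 5, seed = 12)
  pd <- synth$paired
  thr <- -0.6
  called <- correlation_significant_pairs(pd, thr)
  # brute force over all pairs
  expected <- list()
  for (i in rownames(pd$mrna$values)) for (j in rownames(pd$mirna$values)) {
    r <- stats::cor(pd$mrna$values[i, ], pd$mirna$values[j, ])
    if (r <= thr) expected[[length(expected) + 1L]] <- c(j, i, r)
  }
  expect_identical(nrow(called), length(expected))
  if (nrow(called)) {
    got <- paste(called$mirna_id, called$mrna_id)
    want <- vapply(expected, function(e) paste(e[1], e[2]), character(1))
    expect_setequal(got, want)
  }

  # exact inverse and exact positive pairs
  vals <- pd$mrna$values
  vals[1, ] <- 20 - pd$mirna$values[1, ]
  vals[2, ] <- 2 + pd$mirna$values[1, ]
  pd2 <- pd; pd2$mrna <- expression_matrix(vals, is_log2 = TRUE)
  called2 <- correlation_significant_pairs(pd2, -0.999)
  got2 <- paste(called2$mirna_id, called2$mrna_id)
  expect_true(paste(rownames(pd$mirna$values)[1],
                    rownames(pd$mrna$values)[1]) %in% got2)
  expect_false(paste(rownames(pd$mirna$values)[1],
                     rownames(pd$mrna$values)[2]) %in% got2)
})

test_that("estimate_false_detection_rate counts calls over deranged data", {
  synth <- toy_paired(p = 4, m = 5, seed = 21)
  pd <- synth$paired
  # a threshold below -1 can never call: rate 0
  est0 <- estimate_false_detection_rate(pd, "correlation", threshold = -1.1,
                                        n_simulations = 5, rng_seed = 2,
                                        threshold_grid = c(-1.1))
  expect_equal(est0$rate, 0)
  # a threshold of +1 calls every pair: rate 1
  est1 <- estimate_false_detection_rate(pd, "correlation", threshold = 1,
                                        n_simulations = 5, rng_seed = 2,
                                        threshold_grid = c(1))
  expect_equal(est1$rate, 1)

  # independent recount oracle over the same permuted datasets
  thr <- -0.7; sims <- 20
  est <- estimate_false_detection_rate(pd, "correlation", threshold = thr,
                                       n_simulations = sims, rng_seed = 5)
  count <- 0L
  for (s in seq_len(sims)) {
    perm_data <- permute_dataset(pd, rng_seed = plstarget:::pair_seed(5, s, 0L))
    for (i in rownames(pd$mrna$values)) for (j in rownames(pd$mirna$values)) {
      r <- stats::cor(perm_data$mrna$values[i, ], perm_data$mirna$values[j, ])
      if (r <= thr) count <- count + 1L
    }
  }
  expect_equal(est$false_positives, count)
  expect_equal(est$rate, count / (sims * 5 * 4))

  # sweep monotone in the threshold (exact, from the same table)
  expect_true(all(diff(est$sweep$false_positives) >= 0))

  # rate estimates from disjoint seed batches agree within Monte-Carlo error
  estA <- estimate_false_detection_rate(pd, "correlation", threshold = thr,
                                        n_simulations = 40, rng_seed = 101)
  estB <- estimate_false_detection_rate(pd, "correlation", threshold = thr,
                                        n_simulations = 40, rng_seed = 202)
  pooled <- (estA$rate + estB$rate) / 2
  mc_sd <- sqrt(pooled * (1 - pooled) / (40 * 20))
  expect_lt(abs(estA$rate - estB$rate), 6 * mc_sd + 1e-9)

  expect_error(estimate_false_detection_rate(pd, "correlation",
                                             n_simulations = 0), "at least 1")
})

test_that("the PLS caller's chance rate integrates with the sweep machinery", {
  synth <- toy_paired(p = 4, m = 4, seed = 30)
  est <- estimate_false_detection_rate(synth$paired, "pls", threshold = 0.3,
                                       n_simulations = 3, rng_seed = 9,
                                       B = 40)
  expect_true(est$rate >= 0 && est$rate <= 1)
  expect_true(all(diff(est$sweep$false_positives) >= 0))
  expect_equal(est$total_pairs, 3 * 4 * 4)
})

test_that("calibrate_correlation_threshold picks closest-without-exceeding", {
  synth <- toy_paired(p = 4, m = 5, seed = 40)
  pd <- synth$paired
  grid <- seq(-1, -0.5, by = 0.05)
  thr <- calibrate_correlation_threshold(pd, target_rate = 0.05,
                                         n_simulations = 30, rng_seed = 6,
                                         threshold_grid = grid)
  sweep_tab <- attr(thr, "sweep")
  # oracle: the largest grid threshold whose rate does not exceed the target
  ok <- sweep_tab$rate_percent <= 5
  expect_equal(as.numeric(thr), max(sweep_tab$threshold[ok]))
  # selected rate <= target; next grid point (if any) exceeds it
  sel <- which(sweep_tab$threshold == as.numeric(thr))
  if (sel < nrow(sweep_tab)) {
    expect_gt(sweep_tab$rate_percent[sel + 1], 5)
  }

  # unattainable target: a grid whose only point calls every pair (r <= 1
  # always holds) exceeds any target rate below 100%
  expect_error(
    calibrate_correlation_threshold(pd, target_rate = 0.5,
                                    n_simulations = 5, rng_seed = 1,
                                    threshold_grid = c(1)),
    "no grid threshold")
  expect_error(calibrate_correlation_threshold(pd, 0), "target_rate")
})
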