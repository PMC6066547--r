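test_that("noisy_softmax reduces to the closed-form softmax at sigma 0", {
  expect_equal(noisy_softmax(c(0, 0))$probabilities, c(0.5, 0.5))
  expect_equal(noisy_softmax(c(1, 0))$probabilities,
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    z <- rnorm(10, sd = 5)
    p <- noisy_softmax(z)$probabilities
    expect_equal(p, softmax_closed(z), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # stabilized: huge logits do not overflow
  expect_equal(sum(noisy_softmax(c(1e4, 1e4 - 1, 0))$probabilities), 1)
  expect_error(noisy_softmax(c(Inf, 0)), "finite")
  expect_error(noisy_softmax(c(1, 0), sigma = -1), "sigma")
})

test_that("noise injection preserves normalization and exchangeability", {
  set.seed(42)
  p <- noisy_softmax(c(1, 2, 3), sigma = 2)$probabilities
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # equal logits: each of K = 3 categories ranks first ~ 1/3 of draws
  set.seed(43)
  n <- 20000
  wins <- tabulate(vapply(seq_len(n), function(i) {
    which.max(noisy_softmax(c(0, 0, 0), sigma = 1)$probabilities)
  }, 0L), 3)
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(wins / n - 1 / 3) < 3 * se))
})

test_that("top_n orders by probability with index tie-breaking", {
  expect_equal(top_n(c(0.5, 0.3, 0.2), 2), c(1L, 2L))
  expect_equal(top_n(c(0.2, 0.3, 0.5), 2), c(3L, 2L))
  expect_equal(top_n(rep(0.25, 4), 2), c(1L, 2L))
  expect_equal(top_n(c(0.1, 0.2, 0.7), 3), c(3L, 2L, 1L))
  expect_error(top_n(c(0.5, 0.5), 3), "n must be")
})

test_that("scenario classification equals exhaustive set enumeration", {
  # all top-2 configurations over 6 categories: iterate every pair of
  # top-2 sets for the originals and the mixture
  pairs <- combn(6, 2, simplify = FALSE)
  probs_for <- function(top) {
    p <- rep(0.01, 6); p[top] <- c(0.4, 0.3); p / sum(p)
  }
  for (tm in pairs) for (t1 in pairs) for (t2 in pairs) {
    got <- classify_scenario(probs_for(tm), probs_for(t1), probs_for(t2), 2)
    expect_identical(got$value, scenario_brute(tm, t1, t2))
    if (got$value %in% c("none", "both")) {
      expect_true(is.na(got$winner))
    } else {
      expect_identical(got$winner,
                       if (got$value == "first") "source1" else "source2")
    }
  }
})

test_that("scenario classification is symmetric in the two originals", {
  set.seed(7)
  for (i in 1:50) {
    m <- softmax_closed(rnorm(10)); a <- softmax_closed(rnorm(10))
    b <- softmax_closed(rnorm(10))
    s1 <- classify_scenario(m, a, b, 3)$value
    s2 <- classify_scenario(m, b, a, 3)$value
    expect_identical(s2, switch(s1, first = "second", second = "first", s1))
  }
})

test_that("scenario can only move none -> one -> both as N grows", {
  rank_of <- function(v) c(none = 0, first = 1, second = 1, both = 2)[[v]]
  set.seed(8)
  for (i in 1:500) {
    m <- rnorm(8); a <- rnorm(8); b <- rnorm(8)
    vals <- vapply(1:8, function(n) {
      classify_scenario(softmax_closed(m), softmax_closed(a),
                        softmax_closed(b), n)$value
    }, "")
    ranks <- vapply(vals, rank_of, 0)
    expect_true(all(diff(ranks) >= 0))
  }
  # identical distributions: always both
  p <- softmax_closed(rnorm(6))
  expect_identical(classify_scenario(p, p, p, 1)$value, "both")
})

test_that("scenario probabilities recover known proportions", {
  all_first <- rep("first", 200)
  sp <- scenario_probabilities(all_first, 90, 10, seed = 1)
  expect_equal(sp$p_one, 1)
  expect_equal(sp$p_none + sp$p_one + sp$p_both, 1, tolerance = 1e-9)
  expect_equal(sp$se_one, 0)

  set.seed(9)
  pool <- sample(c("none", "first", "both"), 500, replace = TRUE,
                 prob = c(0.2, 0.7, 0.1))
  truth <- c(mean(pool == "none"), mean(pool == "first"),
             mean(pool == "both"))
  sp2 <- scenario_probabilities(pool, 90, 200, seed = 2)
  est <- c(sp2$p_none, sp2$p_one, sp2$p_both)
  # subsampling is unbiased for the pool proportions; allow 3 estimated SEs
  ses <- c(sp2$se_none, sp2$se_one, sp2$se_both)
  expect_true(all(abs(est - truth) < 3 * pmax(ses, 1e-3)))

  # sampling the whole pool every iteration removes all variability
  sp3 <- scenario_probabilities(pool, length(pool), 5, seed = 3)
  expect_equal(sp3$se_none, 0)
  expect_equal(sp3$p_none, truth[1])
  expect_error(scenario_probabilities(character(0)), "empty")
  expect_error(scenario_probabilities(pool, 1000), "sample_size")
})

test_that("sigma sweep reduces to the deterministic pipeline at sigma 0", {
  set.seed(10)
  trial_logits <- lapply(1:40, function(i) {
    list(mix = rnorm(12, sd = 2), orig1 = rnorm(12, sd = 2),
         orig2 = rnorm(12, sd = 2))
  })
  det_vals <- vapply(trial_logits, function(tr) {
    classify_scenario(softmax_closed(tr$mix), softmax_closed(tr$orig1),
                      softmax_closed(tr$orig2), 5)$value
  }, "")
  det <- scenario_probabilities(det_vals, length(det_vals), 1, seed = 1)

  sw <- sigma_sweep(trial_logits, n = 5, sigma_grid = 0, reference = det,
                    iterations = 3, seed = 4)
  expect_equal(sw$sweep$p_none, det$p_none)
  expect_equal(sw$sweep$p_one, det$p_one)
  expect_equal(sw$sweep$p_both, det$p_both)
  expect_equal(sw$best_sigma, 0)

  # reference equal to the sigma = 0 result -> best sigma is 0
  sw2 <- sigma_sweep(trial_logits, n = 5, sigma_grid = c(0, 1, 3),
                     reference = det, iterations = 20, seed = 5)
  expect_equal(sw2$best_sigma, 0)
  expect_equal(sw2$sweep$tv_distance[1], 0, tolerance = 1e-12)
})

test_that("with large-margin originals, noise pushes mixtures toward none", {
  # originals dominated by one huge logit, mixture nearly flat: raising
  # sigma increasingly knocks the mixture's top-5 off both originals' sets
  set.seed(11)
  trial_logits <- lapply(1:60, function(i) {
    o1 <- rnorm(20, sd = 0.1); o1[1] <- 40
    o2 <- rnorm(20, sd = 0.1); o2[2] <- 40
    mix <- rnorm(20, sd = 0.05)
    list(mix = mix, orig1 = o1, orig2 = o2)
  })
  ref <- list(p_none = 1, p_one = 0, p_both = 0)
  sw <- sigma_sweep(trial_logits, n = 2, sigma_grid = c(0, 2, 5),
                    reference = ref, iterations = 30, noise_all = FALSE,
                    seed = 6)
  expect_true(all(diff(sw$sweep$p_none) > -0.05))
})
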