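test_that("log feature ratios are antisymmetric and correct", {
  f1 <- c(gradient = 2, luminance = 100)
  f2 <- c(gradient = 1, luminance = 100)
  x <- log_ratio_features(f1, f2)
  expect_equal(unname(x["gradient"]), log(2))
  expect_equal(unname(x["luminance"]), 0)
  expect_equal(log_ratio_features(f2, f1), -x)
  expect_equal(log_ratio_features(f1, f1), c(gradient = 0, luminance = 0))
  expect_error(log_ratio_features(f1, f2, subset = "nope"), "absent")
})

test_that("lambda = 0 fit agrees with stats::glm (independent cross-check)", {
  tr <- make_choice_trials(c(a = 1.0, b = -0.5), n_pairs = 400, seed = 21)
  fit <- fit_dominance_glm(tr, c("a", "b"), lambda_grid = 0)
  x <- log(as.matrix(tr[, c("a_1", "b_1")]) / as.matrix(tr[, c("a_2", "b_2")]))
  ref <- stats::glm(tr$y ~ x - 1, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("the fit recovers a known single coefficient", {
  tr <- make_choice_trials(c(gradient = 1.4), n_pairs = 2000, seed = 31)
  fit <- fit_dominance_glm(tr, "gradient", lambda_grid = 0)
  expect_true(abs(fit$coefficients[["gradient"]] - 1.4) <
                3 * fit$se[["gradient"]])
  expect_true(fit$converged)
})

test_that("coin-flip winners give coefficients indistinguishable from 0", {
  tr <- make_choice_trials(c(a = 0, b = 0, c = 0), n_pairs = 2000, seed = 41)
  fit <- fit_dominance_glm(tr, c("a", "b", "c"), lambda_grid = 0)
  expect_true(all(abs(fit$coefficients) < 3 * fit$se))
})

test_that("swap-duplicated trials leave the unpenalized estimate unchanged", {
  tr <- make_choice_trials(c(a = 0.8), n_pairs = 300, seed = 51)
  swapped <- tr
  swapped$a_1 <- tr$a_2
  swapped$a_2 <- tr$a_1
  swapped$y <- 1L - tr$y
  doubled <- rbind(tr, swapped)
  f1 <- fit_dominance_glm(tr, "a", lambda_grid = 0)
  f2 <- fit_dominance_glm(doubled, "a", lambda_grid = 0)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-6)
})

test_that("separation and constant predictors are flagged, not fatal", {
  # perfectly separable: y = 1 iff log-ratio > 0
  set.seed(61)
  x <- rnorm(100)
  tr <- data.frame(pair_id = as.character(1:100), y = as.integer(x > 0),
                   a_1 = exp(x / 2), a_2 = exp(-x / 2))
  fit <- suppressWarnings(fit_dominance_glm(tr, "a",
                                            lambda_grid = c(0, 0.01)))
  expect_true("complete_separation" %in% fit$flags ||
                fit$lambda > 0)
  expect_true(all(is.finite(fit$coefficients)))

  trc <- tr
  trc$b_1 <- 5; trc$b_2 <- 5
  fitc <- suppressWarnings(fit_dominance_glm(trc, c("a", "b"),
                                             lambda_grid = 0.05))
  expect_equal(unname(fitc$coefficients["b"]), 0)
  expect_true(any(grepl("constant_predictor", fitc$flags)))
})

test_that("ridge shrinks toward zero as lambda grows", {
  tr <- make_choice_trials(c(a = 1.2), n_pairs = 500, seed = 71)
  b <- vapply(c(0, 0.1, 1), function(lam) {
    fit_dominance_glm(tr, "a", lambda_grid = lam)$coefficients[["a"]]
  }, 0)
  expect_true(all(diff(abs(b)) < 0))
  expect_true(all(b > 0))
})

test_that("model choices and agreement follow the 0.5 threshold rule", {
  tr <- make_choice_trials(c(a = 1.5), n_pairs = 200, seed = 81)
  fit <- fit_dominance_glm(tr, "a", lambda_grid = 0)
  sc <- predict_and_score(fit, tr)
  expect_true(sc$agreement >= 0 && sc$agreement <= 1)
  expect_equal(sc$agreement, mean(sc$y_model == tr$y))
  expect_equal(sc$y_model, as.integer(sc$probabilities >= 0.5))

  # hand-built toy: agreement = matching fraction
  toy <- data.frame(pair_id = as.character(1:4), y = c(1L, 1L, 1L, 0L),
                    a_1 = exp(c(1, -1, 1, 1) / 2),
                    a_2 = exp(-c(1, -1, 1, 1) / 2))
  toy_fit <- structure(list(coefficients = c(a = 1), se = c(a = NA),
                            lambda = 0, n_trials = 4, features = "a",
                            eps = 1e-8, converged = TRUE,
                            flags = character()),
                       class = "dominance_fit")
  sc2 <- predict_and_score(toy_fit, toy)
  expect_equal(sc2$y_model, c(1L, 0L, 1L, 1L))
  expect_equal(sc2$agreement, 0.5)
})

test_that("best_subsets finds the signal feature and scores sensibly", {
  beta <- c(a = 1.3, b = 0, c = 0)
  tr <- make_choice_trials(beta, n_pairs = 600, seed = 91)
  bs <- best_subsets(tr, c("a", "b", "c"), max_size = 2, folds = 5,
                     lambda_grid = 0, seed = 1)
  expect_equal(nrow(bs), 3 + 3)
  best1 <- bs$subset[bs$size == 1 & bs$best_in_size]
  expect_equal(best1, "a")
  expect_true(all(bs$agreement >= 0 & bs$agreement <= 1))

  one <- best_subsets(tr, "a", max_size = 1, folds = 5, seed = 1)
  expect_equal(nrow(one), 1)
})

test_that("Clopper-Pearson matches closed forms and the bisection oracle", {
  ci <- clopper_pearson(0, 10)
  expect_equal(unname(ci["lower"]), 0)
  expect_equal(unname(ci["upper"]), 1 - 0.025^(1 / 10), tolerance = 1e-12)
  expect_equal(unname(clopper_pearson(10, 10)["upper"]), 1)
  expect_equal(unname(clopper_pearson(10, 10)["lower"]), 0.025^(1 / 10),
               tolerance = 1e-12)

  for (n in c(5, 10, 30)) for (k in unique(c(0, 1, n %/% 2, n))) {
    got <- clopper_pearson(k, n)
    want <- cp_brute(k, n)
    expect_equal(unname(got), unname(want), tolerance = 1e-6)
  }
  expect_error(clopper_pearson(5, 4), "successes")
  expect_error(clopper_pearson(1, 10, level = 1.2), "level")
})

test_that("dominance curves bin correctly and respect symmetry", {
  tr <- make_choice_trials(c(a = 1.4), n_pairs = 1000, seed = 101)
  tr$y <- 1L
  cv <- dominance_curve(tr, "a", n_bins = 5)
  expect_true(all(cv$p == 1))
  expect_true(all(cv$upper == 1))
  expect_true(all(cv$lower <= cv$p & cv$p <= cv$upper))
  expect_equal(sum(cv$n), nrow(tr))

  # symmetric trial set: P(+r bin) = 1 - P(mirror bin)
  tr2 <- make_choice_trials(c(a = 1.0), n_pairs = 400, seed = 111)
  swapped <- tr2
  swapped$a_1 <- tr2$a_2; swapped$a_2 <- tr2$a_1; swapped$y <- 1L - tr2$y
  sym <- rbind(tr2, swapped)
  cv2 <- dominance_curve(sym, "a", n_bins = 6)
  expect_equal(cv2$p, rev(1 - cv2$p), tolerance = 1e-12)
  expect_equal(cv2$n, rev(cv2$n))
})

test_that("binned curves track the generating logistic", {
  ok <- 0; total <- 0
  for (seed in 1:20) {
    tr <- make_choice_trials(c(a = 1.4), n_pairs = 1000, seed = 120 + seed)
    cv <- dominance_curve(tr, "a", n_bins = 7)
    # per-bin truth is the within-bin mean of the generating logistic
    # (bin-center evaluation would carry a curvature bias)
    x <- log(tr$a_1 / tr$a_2)
    edges <- seq(min(x), max(x), length.out = 8)
    bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    truth <- vapply(sort(unique(bin)), function(b) {
      mean(plogis(1.4 * x[bin == b]))
    }, 0)
    total <- total + nrow(cv)
    ok <- ok + sum(cv$lower <= truth & truth <= cv$upper)
  }
  expect_gte(ok / total, 0.95)
})
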