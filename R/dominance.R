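#' Log feature ratios between the two images of a pair
#'
#' Component i is log(f_i(I1) / f_i(I2)) after flooring both values at a
#' small epsilon; antisymmetric under swapping the two images.
#'
#' @param features1,features2 named numeric feature vectors for the two
#'   source images.
#' @param subset feature names to use (default: all shared names).
#' @param eps floor applied to both feature values before the ratio.
#' @return named numeric vector of log ratios.
#' @export
log_ratio_features <- function(features1, features2,
                               subset = intersect(names(features1),
                                                  names(features2)),
                               eps = 1e-8) {
  if (!all(subset %in% names(features1)) ||
      !all(subset %in% names(features2))) {
    stop_invalid("subset contains feature names absent from the vectors")
  }
  x <- log(pmax(features1[subset], eps) / pmax(features2[subset], eps))
  if (!all(is.finite(x))) stop_invalid("non-finite log ratio after flooring")
  x
}

# Design matrix of log ratios from a trials data.frame with <feat>_1/<feat>_2
# columns. Returns list(x, y, usable).
trial_design <- function(trials, subset, eps = 1e-8) {
  c1 <- paste0(subset, "_1")
  c2 <- paste0(subset, "_2")
  missing <- setdiff(c(c1, c2), names(trials))
  if (length(missing)) {
    stop_invalid("trials lack feature columns: %s",
                 paste(missing, collapse = ", "))
  }
  usable <- !is.na(trials$y)
  f1 <- as.matrix(trials[usable, c1, drop = FALSE])
  f2 <- as.matrix(trials[usable, c2, drop = FALSE])
  x <- log(pmax(f1, eps) / pmax(f2, eps))
  colnames(x) <- subset
  if (!all(is.finite(x))) stop_invalid("non-finite log ratio after flooring")
  list(x = x, y = as.numeric(trials$y[usable]), usable = usable)
}

# Zero-intercept ridge logistic regression by Newton/IRLS.
# Objective: -(1/n) sum loglik + (lambda/2) ||beta||^2.
ridge_logistic <- function(x, y, lambda = 0, max_iter = 100L, tol = 1e-10) {
  n <- nrow(x); p <- ncol(x)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g <- -drop(crossprod(x, y - mu)) / n + lambda * beta
    H <- crossprod(x, x * w) / n + diag(lambda, p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta - step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged)
}

ridge_logistic_se <- function(x, y, beta, lambda) {
  n <- nrow(x); p <- ncol(x)
  mu <- stats::plogis(drop(x %*% beta))
  w <- mu * (1 - mu)
  info <- crossprod(x, x * w)             # unpenalized Fisher information
  A <- info + diag(n * lambda, p)
  V <- tryCatch(solve(A, info) %*% solve(A), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, p))
  sqrt(pmax(diag(V), 0))
}

log_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

seeded_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

#' Fit the zero-intercept logistic dominance model
#'
#' Fits P(y = 1 | x) = 1 / (1 + exp(-sum_i beta_i x_i)) on log-feature-ratio
#' predictors, with no intercept (the two classes are balanced by
#' construction: relabeling the pair flips both x and y) and an optional
#' ridge penalty whose strength is chosen by cross-validated log-loss over
#' `lambda_grid` (lambda = 0 allowed, giving the unpenalized fit). Positive
#' beta_i means the image with the larger parameter i tends to win.
#'
#' Only trials where exactly one image was chosen (`y` not NA) enter the fit.
#'
#' @param trials data.frame with column `y` (1 = first image won, 0 = second,
#'   NA = not a single-winner trial) and columns `<feature>_1`, `<feature>_2`
#'   holding the two sources' parameter values.
#' @param subset feature names to include.
#' @param lambda_grid candidate ridge strengths; a single value skips CV.
#' @param folds CV folds for lambda selection (default 10).
#' @param eps epsilon floor for feature values.
#' @param seed seed for the CV fold assignment.
#' @return object of class `dominance_fit`: coefficients, standard errors,
#'   `lambda`, `n_trials`, `features`, `converged`, `flags`.
#' @export
fit_dominance_glm <- function(trials, subset, lambda_grid = 0, folds = 10L,
                              eps = 1e-8, seed = 1L) {
  d <- trial_design(trials, subset, eps)
  n <- nrow(d$x)
  if (n < 20L) stop_invalid("need >= 20 usable single-winner trials, got %d", n)
  if (folds < 2L) stop_invalid("folds must be >= 2")
  flags <- character()

  const <- apply(d$x, 2, function(col) stats::sd(col) == 0)
  x_fit <- d$x[, !const, drop = FALSE]
  if (any(const)) {
    flags <- c(flags, paste0("constant_predictor:",
                             paste(subset[const], collapse = ",")))
  }

  lambda_grid <- sort(unique(lambda_grid))
  lambda <- lambda_grid[1]
  if (length(lambda_grid) > 1L && ncol(x_fit) > 0L) {
    fold_id <- seeded_folds(n, folds, seed)
    cv_loss <- vapply(lambda_grid, function(lam) {
      losses <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fit <- ridge_logistic(x_fit[tr, , drop = FALSE], d$y[tr], lam)
        p <- stats::plogis(drop(x_fit[!tr, , drop = FALSE] %*% fit$beta))
        log_loss(d$y[!tr], p)
      }, 0)
      mean(losses)
    }, 0)
    lambda <- lambda_grid[which.min(cv_loss)]   # first minimum: smallest lambda
  }

  if (ncol(x_fit) == 0L) {
    fit <- list(beta = numeric(0), converged = TRUE)
  } else {
    fit <- ridge_logistic(x_fit, d$y, lambda)
    separated <- !fit$converged || max(abs(fit$beta)) > 25
    if (lambda == 0 && separated) {
      flags <- c(flags, "complete_separation")
      pos <- lambda_grid[lambda_grid > 0]
      lambda <- if (length(pos)) min(pos) else 1e-4
      fit <- ridge_logistic(x_fit, d$y, lambda)
    }
  }

  beta <- stats::setNames(rep(0, length(subset)), subset)
  se <- stats::setNames(rep(NA_real_, length(subset)), subset)
  if (ncol(x_fit) > 0L) {
    beta[!const] <- fit$beta
    se[!const] <- ridge_logistic_se(x_fit, d$y, fit$beta, lambda)
  }
  structure(list(coefficients = beta, se = se, lambda = lambda,
                 n_trials = n, features = subset, eps = eps,
                 converged = fit$converged, flags = flags),
            class = "dominance_fit")
}

#' @export
print.dominance_fit <- function(x, ...) {
  cat(sprintf("Zero-intercept logistic dominance fit (n = %d, lambda = %g)\n",
              x$n_trials, x$lambda))
  print(round(rbind(beta = x$coefficients, se = x$se), 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Model choices and agreement with observed winners
#'
#' The model picks the first image when the fitted probability exceeds 0.5
#' (ties at exactly 0.5 resolve to the first image); agreement is the
#' fraction of trials where the model choice matches the observed winner,
#' i.e. 1 - mean |y_model - y|.
#'
#' @param fit a `dominance_fit`.
#' @param trials trials data.frame (see [fit_dominance_glm()]).
#' @return list with `y_model` (per usable trial), `probabilities`, and
#'   `agreement`.
#' @export
predict_and_score <- function(fit, trials) {
  d <- trial_design(trials, fit$features, fit$eps)
  p <- stats::plogis(drop(d$x %*% fit$coefficients))
  y_model <- as.integer(p >= 0.5)
  list(y_model = y_model, probabilities = p,
       agreement = 1 - mean(abs(y_model - d$y)))
}

#' Best feature subsets by cross-validated agreement
#'
#' Exhaustively enumerates feature subsets up to `max_size`; for each,
#' selects the ridge strength by CV log-loss on the training folds' data and
#' scores held-out agreement per fold. Reports every subset plus, per size,
#' which is best.
#'
#' @param trials trials data.frame.
#' @param features candidate feature names.
#' @param max_size largest subset size to enumerate.
#' @param folds CV folds (default 10).
#' @param lambda_grid ridge strengths offered to each subset.
#' @param seed fold-assignment seed (shared across subsets so scores are
#'   comparable).
#' @return data.frame: subset (comma-joined names), size, agreement (mean
#'   over folds), se (across folds), lambda, best_in_size.
#' @export
best_subsets <- function(trials, features, max_size = length(features),
                         folds = 10L, lambda_grid = 0, seed = 1L) {
  if (max_size > length(features)) {
    stop_invalid("max_size exceeds the number of features")
  }
  d0 <- trial_design(trials, features)
  n <- nrow(d0$x)
  fold_id <- seeded_folds(n, folds, seed)
  rows <- list()
  for (size in seq_len(max_size)) {
    combos <- utils::combn(features, size, simplify = FALSE)
    for (sub in combos) {
      fit_full <- fit_dominance_glm(trials, sub, lambda_grid, folds,
                                    seed = seed)
      lam <- fit_full$lambda
      x <- d0$x[, sub, drop = FALSE]
      agree <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        const <- apply(x[tr, , drop = FALSE], 2,
                       function(col) stats::sd(col) == 0)
        b <- rep(0, length(sub))
        if (any(!const)) {
          b[!const] <- ridge_logistic(x[tr, !const, drop = FALSE],
                                      d0$y[tr], lam)$beta
        }
        p <- stats::plogis(drop(x[!tr, , drop = FALSE] %*% b))
        1 - mean(abs(as.integer(p >= 0.5) - d0$y[!tr]))
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(sub, collapse = ","), size = size,
        agreement = mean(agree), se = stats::sd(agree) / sqrt(folds),
        lambda = lam, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$best_in_size <- FALSE
  for (size in unique(out$size)) {
    i <- which(out$size == size)
    out$best_in_size[i[which.max(out$agreement[i])]] <- TRUE
  }
  out
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Via the beta-quantile characterization: lower = B(alpha/2; k, n-k+1),
#' upper = B(1-alpha/2; k+1, n-k), with lower = 0 at k = 0 and upper = 1 at
#' k = n.
#'
#' @param successes number of successes k, 0 <= k <= n.
#' @param n number of trials, >= 1.
#' @param level confidence level in (0, 1), default 0.95.
#' @return named vector `c(lower =, upper =)`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1L || successes < 0L || successes > n) {
    stop_invalid("require 0 <= successes <= n and n >= 1")
  }
  if (level <= 0 || level >= 1) stop_invalid("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Binned dominance curve for a single image parameter
#'
#' Empirical probability of choosing the first image as a function of the
#' log parameter ratio, in equal-width bins spanning the observed range,
#' with exact Clopper-Pearson intervals per bin. Empty bins are omitted.
#'
#' @param trials trials data.frame.
#' @param feature single feature name.
#' @param n_bins number of equal-width bins on the log-ratio axis (default 9).
#' @param level confidence level for the intervals.
#' @return data.frame: bin_center, p (empirical P(pick I1)), lower, upper,
#'   n (trials in bin).
#' @export
dominance_curve <- function(trials, feature, n_bins = 9L, level = 0.95) {
  stopifnot(length(feature) == 1L)
  d <- trial_design(trials, feature)
  x <- drop(d$x)
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  rows <- lapply(sort(unique(bin)), function(b) {
    inb <- bin == b
    k <- sum(d$y[inb]); m <- sum(inb)
    ci <- clopper_pearson(k, m, level)
    data.frame(bin_center = (edges[b] + edges[b + 1L]) / 2,
               p = k / m, lower = ci["lower"], upper = ci["upper"], n = m,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
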