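# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths.

# Brute-force profile-likelihood grid search for the random-intercept model
# y = X beta + Z u + e fitted by ML, using dense matrix algebra.
lme_grid_oracle <- function(X, y, subject, lambda_grid) {
  subject <- factor(subject)
  Z <- stats::model.matrix(~ subject - 1)
  n <- length(y)
  best <- list(ll = -Inf)
  for (lam in lambda_grid) {
    V <- diag(n) + lam * tcrossprod(Z)
    Vi <- solve(V)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- as.numeric(t(r) %*% Vi %*% r)
    s2 <- rss / n
    ll <- -0.5 * n * log(2 * pi * s2) - 0.5 * determinant(V)$modulus -
      0.5 * n
    if (ll > best$ll) {
      best <- list(ll = as.numeric(ll), lambda = lam, beta = as.numeric(beta),
                   sigma2_e = s2, sigma2_u = lam * s2)
    }
  }
  best
}

# Explicit leave-one-out refit definition of Cook's distance.
cooks_loo_oracle <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  p <- ncol(X)
  s2 <- sum(fit$residuals^2) / (length(y) - p)
  XtX <- crossprod(X)
  vapply(seq_along(y), function(i) {
    bi <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
    d <- beta - bi
    as.numeric(t(d) %*% XtX %*% d) / (p * s2)
  }, numeric(1))
}

# Moment/rank formula correlations.
pearson_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
}
spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

# Match detected saccade onsets to ground-truth onsets within a tolerance;
# greedy one-to-one matching by increasing time difference.
match_events <- function(truth_onsets, detected_onsets, tol_ms = 20) {
  if (length(truth_onsets) == 0 || length(detected_onsets) == 0) {
    return(data.frame(truth = integer(0), detected = integer(0),
                      err = numeric(0)))
  }
  cand <- expand.grid(truth = seq_along(truth_onsets),
                      detected = seq_along(detected_onsets))
  cand$err <- detected_onsets[cand$detected] - truth_onsets[cand$truth]
  cand <- cand[abs(cand$err) <= tol_ms, ]
  cand <- cand[order(abs(cand$err)), ]
  used_t <- used_d <- logical(0)
  keep <- logical(nrow(cand))
  taken_t <- rep(FALSE, length(truth_onsets))
  taken_d <- rep(FALSE, length(detected_onsets))
  for (k in seq_len(nrow(cand))) {
    if (!taken_t[cand$truth[k]] && !taken_d[cand$detected[k]]) {
      keep[k] <- TRUE
      taken_t[cand$truth[k]] <- TRUE
      taken_d[cand$detected[k]] <- TRUE
    }
  }
  cand[keep, ]
}

# Small helper: simulated three-task session for one parameter set.
simulate_session <- function(params, seed, n_cycles = 35, n_jumps = 78,
                             n_cues = 18) {
  list(pursuit = simulate_trace(make_pursuit_schedule(n_cycles = n_cycles),
                                params, seed = seed),
       visually_guided = simulate_trace(
         make_visually_guided_schedule(n_jumps = n_jumps, seed = 11),
         params, seed = seed + 1),
       antisaccade = simulate_trace(
         make_antisaccade_schedule(n_peripheral = n_cues, seed = 13),
         params, seed = seed + 2))
}
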