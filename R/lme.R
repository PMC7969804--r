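#' Maximum-likelihood random-intercept linear mixed model
#'
#' Fits `y = X beta + Z u + e` where `Z` indicates subjects, `u ~ N(0,
#' sigma2_u)` and `e ~ N(0, sigma2_e)`, by maximum likelihood (not REML).
#' The likelihood is profiled analytically over `beta` and `sigma2_e`,
#' leaving a one-dimensional maximisation over the variance ratio
#' `lambda = sigma2_u / sigma2_e`; the fit is exact for this model family
#' and fast enough to sit inside nested cross-validation loops.
#'
#' @param y numeric outcome vector.
#' @param X numeric fixed-effects matrix (one row per observation), or
#'   `NULL` for an intercept-only model.
#' @param subject subject identifier vector (coerced to factor); defines the
#'   random-intercept grouping.
#' @param intercept add an intercept column to `X`? (default `TRUE`).
#' @param random fit the subject random intercept? With `FALSE` the model
#'   degenerates to ordinary least squares (the fixed-effects-only
#'   baseline).
#' @return an object of class `lme_ml` with components `coefficients`,
#'   `ranef` (named per-subject BLUP intercepts), `sigma2_u`, `sigma2_e`,
#'   `lambda`, `logLik`, `fitted.values`, `residuals`.
#' @examples
#' set.seed(1)
#' subj <- rep(1:6, each = 4)
#' u <- rnorm(6, sd = 2)[subj]
#' x <- rnorm(24)
#' y <- 1 + 0.5 * x + u + rnorm(24, sd = 0.3)
#' fit <- fit_lme(y, cbind(x = x), subj)
#' coef(fit)
#' @export
fit_lme <- function(y, X = NULL, subject, intercept = TRUE, random = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (nrow(X) != n) stop("`X` and `y` must have the same number of rows",
                           call. = FALSE)
  }
  if (length(subject) != n) stop("`subject` must match `y` in length",
                                 call. = FALSE)
  if (anyNA(y) || (!is.null(X) && anyNA(X))) {
    stop("missing values in `y` or `X`; impute before fitting",
         call. = FALSE)
  }
  subject <- factor(subject)
  m <- nlevels(subject)
  if (random && m < 2) stop("need >= 2 subjects for a random intercept",
                            call. = FALSE)
  Xd <- if (intercept) cbind(`(Intercept)` = rep(1, n), X) else X
  if (is.null(Xd) || ncol(Xd) == 0) {
    stop("empty fixed-effects design: supply `X` or set `intercept = TRUE`",
         call. = FALSE)
  }
  if (is.null(colnames(Xd))) colnames(Xd) <- paste0("x", seq_len(ncol(Xd)))
  if (n <= ncol(Xd)) stop("need more rows than fixed-effect columns",
                          call. = FALSE)
  res <- cpp_lme_fit(Xd, y, as.integer(subject) - 1L, m, random)
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(Xd)
  u <- as.numeric(res$u)
  names(u) <- levels(subject)
  fitted <- as.numeric(Xd %*% beta) + u[as.integer(subject)]
  structure(list(coefficients = beta, ranef = u,
                 sigma2_u = res$sigma2_u, sigma2_e = res$sigma2_e,
                 lambda = res$lambda, logLik = res$loglik,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, X = Xd, subject = subject,
                 intercept = intercept, random = random,
                 call = match.call()),
            class = "lme_ml")
}

#' @export
print.lme_ml <- function(x, digits = 4, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("sigma2_u = %.*g, sigma2_e = %.*g, logLik = %.*g\n",
              digits, x$sigma2_u, digits, x$sigma2_e, digits, x$logLik))
  invisible(x)
}

#' @export
summary.lme_ml <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              sigma2_u = object$sigma2_u, sigma2_e = object$sigma2_e,
              icc = object$sigma2_u / (object$sigma2_u + object$sigma2_e),
              logLik = object$logLik,
              n = length(object$y), n_subjects = nlevels(object$subject),
              ranef_sd = sd(object$ranef))
  class(out) <- "summary.lme_ml"
  out
}

#' @export
print.summary.lme_ml <- function(x, digits = 4, ...) {
  cat(sprintf("ML random-intercept model: %d obs, %d subjects\n",
              x$n, x$n_subjects))
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Variance components: sigma2_u = %.*g, sigma2_e = %.*g (ICC %.2f)\n",
              digits, x$sigma2_u, digits, x$sigma2_e, x$icc))
  cat(sprintf("logLik = %.*g\n", digits, x$logLik))
  invisible(x)
}

#' @export
coef.lme_ml <- function(object, ...) object$coefficients

#' Random-intercept BLUPs of a fitted model
#' @param object an `lme_ml` fit.
#' @param ... unused.
#' @return named numeric vector, one empirical best linear unbiased
#'   predictor per subject.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.lme_ml <- function(object, ...) object$ranef

#' @export
fitted.lme_ml <- function(object, ...) object$fitted.values

#' @export
residuals.lme_ml <- function(object, ...) object$residuals

#' @export
logLik.lme_ml <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients) + 1 + as.integer(object$random),
            nobs = length(object$y), class = "logLik")
}

#' Predict from a random-intercept mixed model
#'
#' For a subject seen in training the prediction is `x beta + u_subject`
#' (the subject's BLUP intercept); for an unseen subject it is the
#' population-level `x beta`.
#'
#' @param object an `lme_ml` fit.
#' @param newX fixed-effects matrix for the new rows (without the intercept
#'   column if the model has one); `NULL` returns fitted values.
#' @param newsubject subject identifiers for the new rows; `NULL` predicts
#'   at the population level.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lme_ml <- function(object, newX = NULL, newsubject = NULL, ...) {
  if (is.null(newX) && is.null(newsubject)) return(object$fitted.values)
  if (is.null(newX)) {
    Xd <- object$X[0, , drop = FALSE]
    nr <- length(newsubject)
    Xd <- matrix(1, nr, 1)
    if (ncol(object$X) > 1) stop("`newX` required for models with covariates",
                                 call. = FALSE)
  } else {
    newX <- as.matrix(newX)
    Xd <- if (object$intercept) cbind(1, newX) else newX
    if (ncol(Xd) != ncol(object$X)) {
      stop("`newX` has the wrong number of columns", call. = FALSE)
    }
  }
  pred <- as.numeric(Xd %*% object$coefficients)
  if (!is.null(newsubject)) {
    idx <- match(as.character(newsubject), names(object$ranef))
    uadd <- ifelse(is.na(idx), 0, object$ranef[idx])
    pred <- pred + unname(uadd)
  }
  pred
}

#' @export
simulate.lme_ml <- function(object, nsim = 1, seed = NULL, ...) {
  sim1 <- function() {
    u <- rnorm(nlevels(object$subject), sd = sqrt(object$sigma2_u))
    as.numeric(object$X %*% object$coefficients) +
      u[as.integer(object$subject)] +
      rnorm(length(object$y), sd = sqrt(object$sigma2_e))
  }
  out <- with_seed(seed, replicate(nsim, sim1()))
  as.data.frame(out)
}

#' @export
plot.lme_ml <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals,
                 xlab = "fitted", ylab = "residual",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
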