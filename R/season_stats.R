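#' Per-session change tests against baseline
#'
#' One-sample two-sided t-tests of each non-baseline session's
#' subtractive-normalized deltas against zero, per outcome.
#'
#' @param delta_tbl output of [subtractive_normalize()].
#' @param cols outcome columns (default: all normalized numeric columns).
#' @param session_col session key.
#' @return data frame with `session`, `outcome`, `mean`, `t`, `df`, `p`
#'   (`NA` when fewer than 2 deltas are available).
#' @export
session_change_tests <- function(delta_tbl, cols = NULL,
                                 session_col = "session") {
  stopifnot(is.data.frame(delta_tbl), "baseline" %in% names(delta_tbl))
  if (is.null(cols)) {
    cols <- setdiff(names(delta_tbl)[vapply(delta_tbl, is.numeric,
                                            logical(1))],
                    c("subject_id", session_col))
  }
  tb <- delta_tbl[!delta_tbl$baseline, , drop = FALSE]
  sessions <- sort(unique(tb[[session_col]]))
  out <- expand.grid(session = sessions, outcome = cols,
                     stringsAsFactors = FALSE)
  out$mean <- out$t <- out$df <- out$p <- NA_real_
  for (k in seq_len(nrow(out))) {
    v <- tb[[out$outcome[k]]][tb[[session_col]] == out$session[k]]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && sd(v) > 0) {
      tt <- t.test(v, mu = 0)
      out$mean[k] <- mean(v)
      out$t[k] <- unname(tt$statistic)
      out$df[k] <- unname(tt$parameter)
      out$p[k] <- tt$p.value
    } else if (length(v) >= 2 && sd(v) == 0 && all(v == 0)) {
      out$mean[k] <- 0; out$t[k] <- 0; out$df[k] <- length(v) - 1
      out$p[k] <- 1
    }
  }
  out[order(out$outcome, out$session), ]
}

#' Cohen's d between two cohorts
#'
#' Pooled-SD standardized mean difference, `(meanA - meanB) / s_pooled`
#' with `(n - 1)`-weighted pooling, labelled negligible (<0.2), small,
#' medium (0.5--0.8) or large (>=0.8) by magnitude.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return list with `d` and `label`.
#' @examples
#' cohort_effect_sizes(c(0, 2), c(1, 3))  # d = -1/sqrt(2), "medium"
#' @export
cohort_effect_sizes <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  label <- if (abs(d) < 0.2) "negligible" else if (abs(d) < 0.5) "small"
  else if (abs(d) < 0.8) "medium" else "large"
  list(d = d, label = label)
}

#' ONSD-vs-composite correlation panel
#'
#' Pearson (linear) and Spearman (monotone) correlations, with p-values,
#' between subtractive-normalized ONSD deltas and each normalized ImPACT
#' composite; baseline rows must already be excluded by the caller.
#'
#' @param delta_onsd numeric vector of ONSD deltas.
#' @param delta_composites data frame of composite deltas (paired rows).
#' @return data frame with one row per composite: `pearson_r`,
#'   `pearson_p`, `spearman_r`, `spearman_p`, `n`.
#' @export
correlation_panel <- function(delta_onsd, delta_composites) {
  stopifnot(is.data.frame(delta_composites),
            length(delta_onsd) == nrow(delta_composites))
  out <- lapply(names(delta_composites), function(cc) {
    y <- delta_composites[[cc]]
    ok <- !is.na(delta_onsd) & !is.na(y)
    xx <- delta_onsd[ok]; yy <- y[ok]
    if (length(xx) < 3 || sd(xx) == 0 || sd(yy) == 0) {
      stop("constant or too-short vector for composite ", cc, call. = FALSE)
    }
    pe <- cor.test(xx, yy, method = "pearson")
    sp <- cor.test(xx, yy, method = "spearman", exact = FALSE)
    data.frame(composite = cc, pearson_r = unname(pe$estimate),
               pearson_p = pe$p.value, spearman_r = unname(sp$estimate),
               spearman_p = sp$p.value, n = length(xx))
  })
  do.call(rbind, out)
}

#' Linear vs quadratic fit diagnostics with Cook's D screening
#'
#' Least-squares linear and quadratic fits of `y` on `x` with overall
#' F-test p-values and adjusted R-squared; the model with higher adjusted
#' R-squared is declared better. Cook's distance is computed per
#' observation for each fit and values above 1 are flagged as influential
#' outliers.
#'
#' @param x,y numeric vectors, n >= 4.
#' @return object of class `fit_diagnostics`: list with `linear`,
#'   `quadratic` (each `coef`, `r2`, `adj_r2`, `p`, `cooks_d`, `flagged`),
#'   and `better` (`"linear"` or `"quadratic"`).
#' @export
fit_diagnostics <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need n >= 4", call. = FALSE)
  if (sd(x) == 0) stop("collinear design: x is constant", call. = FALSE)
  if (length(unique(x)) < 3) {
    stop("collinear design: quadratic fit needs >= 3 distinct x values",
         call. = FALSE)
  }
  fit_one <- function(fml) {
    f <- lm(fml)
    sm <- summary(f)
    fs <- sm$fstatistic
    cd <- cooks.distance(f)
    list(fit = f, coef = coef(f), r2 = sm$r.squared,
         adj_r2 = sm$adj.r.squared,
         p = if (is.null(fs)) NA_real_ else
           unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
         cooks_d = unname(cd), flagged = which(unname(cd) > 1))
  }
  lin <- fit_one(y ~ x)
  quad <- fit_one(y ~ x + I(x^2))
  structure(list(linear = lin, quadratic = quad,
                 better = if (quad$adj_r2 > lin$adj_r2) "quadratic"
                          else "linear"),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, digits = 3, ...) {
  cat("Linear vs quadratic fit\n")
  cat(sprintf("  linear:    adj R2 = %.*f, p = %.3g, %d point(s) with Cook's D > 1\n",
              digits, x$linear$adj_r2, x$linear$p, length(x$linear$flagged)))
  cat(sprintf("  quadratic: adj R2 = %.*f, p = %.3g, %d point(s) with Cook's D > 1\n",
              digits, x$quadratic$adj_r2, x$quadratic$p,
              length(x$quadratic$flagged)))
  cat(sprintf("  better by adjusted R2: %s\n", x$better))
  invisible(x)
}
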