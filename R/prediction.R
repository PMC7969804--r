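#' Prediction metrics
#'
#' Pearson correlation (with two-sided t-distribution p-value), RMSE, bias
#' (mean predicted minus mean actual) and R-squared (squared correlation)
#' between held-out predictions and actual outcomes.
#'
#' @param predicted,actual equal-length numeric vectors, n >= 3.
#' @return list with `corr`, `p`, `rmse`, `bias`, `r2`, `n`.
#' @examples
#' evaluate_predictions(c(1, 2, 3) + 0.5, c(1, 2, 3))  # corr 1, bias 0.5
#' @export
evaluate_predictions <- function(predicted, actual) {
  ok <- !is.na(predicted) & !is.na(actual)
  predicted <- predicted[ok]
  actual <- actual[ok]
  if (length(actual) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(predicted) == 0 || sd(actual) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- cor.test(predicted, actual)
  r <- unname(ct$estimate)
  list(corr = r, p = ct$p.value,
       rmse = sqrt(mean((predicted - actual)^2)),
       bias = mean(predicted) - mean(actual),
       r2 = r^2, n = length(actual))
}

# standardize by training statistics; zero-variance and all-missing
# columns are dropped; missing entries imputed by training means
.fold_standardize <- function(train, test_row) {
  mu <- colMeans(train, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  for (jj in seq_len(ncol(train))) {
    train[is.na(train[, jj]), jj] <- mu[jj]
  }
  sdv <- apply(train, 2, sd)
  keep <- which(is.finite(sdv) & sdv > 1e-12)
  train <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2,
                 sdv[keep], "/")
  test_row <- test_row[keep]
  nas <- is.na(test_row)
  test_row[nas] <- mu[keep][nas]
  test_row <- (test_row - mu[keep]) / sdv[keep]
  list(train = train, test = test_row, keep = keep)
}

#' Leave-one-session-out prediction of an outcome from oculomotor features
#'
#' The core nested cross-validation: each subject-session is held out once;
#' within each outer training set, features are imputed (training means),
#' standardized, and reduced by PCA fitted on the training rows only; an
#' inner leave-one-session-out loop over the training rows evaluates every
#' candidate number of leading principal components and keeps the count
#' maximizing inner predicted-vs-actual Pearson correlation (ties go to
#' the smallest count); the model is refit on the full training set with
#' the chosen components and the held-out session is predicted using its
#' subject's random-intercept BLUP estimated from that subject's other
#' sessions. The raw variant includes a fixed intercept; the
#' subtractive-normalized variant does not (the data are already without
#' offsets). A fixed-effects-only baseline (no random intercept) is run
#' through the identical procedure for comparison.
#'
#' @param features numeric matrix, one row per subject-session (may
#'   contain `NA`); for `variant = "sn"` supply baseline-subtracted
#'   features with baseline rows already removed.
#' @param y outcome vector (raw ONSD / PC-ImPACT, or their deltas).
#' @param subject subject identifiers, one per row.
#' @param session session identifiers (bookkeeping only).
#' @param variant `"raw"` (intercept included) or `"sn"` (no intercept).
#' @param pc_grid candidate PC counts (default `1:10`, truncated to the
#'   feasible range).
#' @param baseline also run the fixed-effects-only comparison model
#'   (default `TRUE`).
#' @return object of class `loso_result`: `predictions` data frame
#'   (`subject`, `session`, `actual`, `predicted`, `n_pcs`, and with
#'   `baseline` the `predicted_fixed`, `n_pcs_fixed` columns), `metrics`,
#'   `metrics_fixed`, `variant`, and per-fold loadings/coefficients for
#'   [feature_importance()].
#' @export
loso_predict <- function(features, y, subject, session = NULL,
                         variant = c("raw", "sn"), pc_grid = 1:10,
                         baseline = TRUE) {
  variant <- match.arg(variant)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  y <- as.numeric(y)
  n <- nrow(features)
  stopifnot(length(y) == n, length(subject) == n)
  if (is.null(session)) session <- stats::ave(rep(1, n), subject,
                                              FUN = cumsum)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  subject <- factor(subject)
  intercept <- variant == "raw"
  pc_grid <- sort(unique(as.integer(pc_grid)))
  stopifnot(all(pc_grid >= 1))
  pred <- pred_fixed <- rep(NA_real_, n)
  npc <- npc_fixed <- rep(NA_integer_, n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fs <- .fold_standardize(features[tr, , drop = FALSE], features[i, ])
    ytr <- y[tr]
    subj_tr <- factor(subject[tr])  # drop unused levels
    pca <- prcomp(fs$train, center = FALSE, scale. = FALSE)
    kmax <- min(max(pc_grid), ncol(pca$rotation), length(tr) - 2L -
                  as.integer(intercept))
    grid <- pc_grid[pc_grid <= kmax]
    if (length(grid) == 0) grid <- 1L
    P <- pca$x[, seq_len(max(grid)), drop = FALSE]
    if (sd(ytr) == 0) {
      # degenerate training outcome: fold flagged, no prediction
      folds[[i]] <- NULL
      next
    }
    pick <- function(random) {
      ip <- cpp_inner_loso(P, ytr, as.integer(subj_tr) - 1L,
                           nlevels(subj_tr), as.integer(grid), intercept,
                           random)
      cors <- apply(ip, 2, function(pp) {
        ok <- is.finite(pp)
        if (sum(ok) < 3 || sd(pp[ok]) == 0) -Inf else cor(pp[ok], ytr[ok])
      })
      grid[which.max(cors)]  # first max -> smallest count on ties
    }
    x_ho <- as.numeric(fs$test %*% pca$rotation[, seq_len(max(grid)),
                                                drop = FALSE])
    k <- pick(TRUE)
    fit <- fit_lme(ytr, P[, seq_len(k), drop = FALSE], subj_tr,
                   intercept = intercept, random = TRUE)
    pred[i] <- predict(fit, matrix(x_ho[seq_len(k)], 1), subject[i])
    npc[i] <- k
    folds[[i]] <- list(
      loadings = pca$rotation[, seq_len(k), drop = FALSE],
      coef = coef(fit)[if (intercept) -1L else seq_len(k)],
      intercept = if (intercept) coef(fit)[1] else NULL,
      feature_names = colnames(features)[fs$keep])
    if (baseline) {
      kf <- pick(FALSE)
      fitf <- fit_lme(ytr, P[, seq_len(kf), drop = FALSE], subj_tr,
                      intercept = intercept, random = FALSE)
      pred_fixed[i] <- predict(fitf, matrix(x_ho[seq_len(kf)], 1))
      npc_fixed[i] <- kf
    }
  }
  predictions <- data.frame(subject = as.character(subject),
                            session = session, actual = y,
                            predicted = pred, n_pcs = npc)
  metrics_fixed <- NULL
  if (baseline) {
    predictions$predicted_fixed <- pred_fixed
    predictions$n_pcs_fixed <- npc_fixed
    metrics_fixed <- evaluate_predictions(pred_fixed, y)
  }
  structure(list(predictions = predictions,
                 metrics = evaluate_predictions(pred, y),
                 metrics_fixed = metrics_fixed,
                 variant = variant, pc_grid = pc_grid,
                 folds = folds),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, digits = 3, ...) {
  cat(sprintf("Leave-one-session-out predictions (%s variant, %d sessions)\n",
              toupper(x$variant), nrow(x$predictions)))
  fmt <- function(m, label) {
    cat(sprintf("  %-12s corr = %.*f (p = %.3g), RMSE = %.*f, bias = %.*f\n",
                label, digits, m$corr, m$p, digits, m$rmse, digits, m$bias))
  }
  fmt(x$metrics, "mixed:")
  if (!is.null(x$metrics_fixed)) fmt(x$metrics_fixed, "fixed-only:")
  invisible(x)
}

#' @export
summary.loso_result <- function(object, ...) {
  pcs <- table(object$predictions$n_pcs)
  out <- list(metrics = object$metrics,
              metrics_fixed = object$metrics_fixed,
              variant = object$variant, pc_counts = pcs)
  class(out) <- "summary.loso_result"
  out
}

#' @export
print.summary.loso_result <- function(x, ...) {
  print(structure(list(predictions = data.frame(x = numeric(0)),
                       metrics = x$metrics, metrics_fixed = x$metrics_fixed,
                       variant = x$variant), class = "loso_result"))
  cat("  chosen PC counts:\n")
  print(x$pc_counts)
  invisible(x)
}

#' @export
plot.loso_result <- function(x, ...) {
  p <- x$predictions
  graphics::plot(p$actual, p$predicted,
                 xlab = "actual", ylab = "predicted (held out)",
                 main = sprintf("%s-LME held-out predictions",
                                toupper(x$variant)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Feature-importance weighting across cross-validation folds
#'
#' Within each fold, the `top_k` features by absolute loading on each
#' selected principal component are weighted by |loading| x |PC
#' coefficient| and summed per feature; weights are averaged across folds
#' and normalized so the largest feature contribution is exactly 1,
#' reported split by central vs dispersion channel.
#'
#' @param result a `loso_result`.
#' @param top_k features kept per component (default 20).
#' @return data frame (`feature`, `weight`, `channel`, `task`) sorted by
#'   decreasing weight; empty when no folds completed.
#' @export
feature_importance <- function(result, top_k = 20) {
  stopifnot(inherits(result, "loso_result"))
  folds <- Filter(Negate(is.null), result$folds)
  if (length(folds) == 0) {
    return(data.frame(feature = character(0), weight = numeric(0),
                      channel = character(0), task = character(0)))
  }
  all_feats <- unique(unlist(lapply(folds, `[[`, "feature_names")))
  acc <- matrix(0, length(folds), length(all_feats),
                dimnames = list(NULL, all_feats))
  for (fi in seq_along(folds)) {
    fo <- folds[[fi]]
    L <- fo$loadings
    bet <- fo$coef
    for (j in seq_len(ncol(L))) {
      ord <- order(abs(L[, j]), decreasing = TRUE)
      sel <- ord[seq_len(min(top_k, nrow(L)))]
      fn <- fo$feature_names[sel]
      acc[fi, fn] <- acc[fi, fn] + abs(L[sel, j]) * abs(bet[j])
    }
  }
  w <- colMeans(acc)
  if (max(w) > 0) w <- w / max(w)
  reg <- feature_registry()
  mi <- match(all_feats, reg$name)
  out <- data.frame(feature = all_feats, weight = unname(w),
                    channel = ifelse(is.na(mi), NA_character_,
                                     reg$channel[mi]),
                    task = ifelse(is.na(mi), NA_character_, reg$task[mi]))
  out[order(-out$weight), ]
}

#' Season-level prediction pipeline on a cohort
#'
#' Convenience wrapper tying the pipeline together for a simulated (or
#' assembled) cohort: builds the requested outcome (raw ONSD, raw
#' PC-ImPACT, or their subtractive-normalized versions), applies the same
#' normalization to the oculomotor features, and runs [loso_predict()].
#' For the subtractive-normalized PC-ImPACT outcome the composites are
#' reciprocal-transformed first, baseline-subtracted per subject, and the
#' principal component is fitted on the non-baseline deltas.
#'
#' @param cohort a `cohort_sim` with a feature matrix (or a list with
#'   `outcomes` and `features` of the same shape).
#' @param outcome `"onsd"` or `"impact"`.
#' @param variant `"raw"` or `"sn"`.
#' @param pc_grid,baseline passed to [loso_predict()].
#' @return a `loso_result` (see [loso_predict()]).
#' @export
cohort_loso <- function(cohort, outcome = c("onsd", "impact"),
                        variant = c("raw", "sn"), pc_grid = 1:10,
                        baseline = TRUE) {
  outcome <- match.arg(outcome)
  variant <- match.arg(variant)
  ot <- cohort$outcomes
  feats <- cohort$features
  stopifnot(is.data.frame(ot), !is.null(feats), nrow(feats) == nrow(ot))
  if (variant == "raw") {
    y <- if (outcome == "onsd") ot$onsd_mm else impact_pc(ot)$scores
    return(loso_predict(feats, y, ot$subject_id, ot$session,
                        variant = "raw", pc_grid = pc_grid,
                        baseline = baseline))
  }
  # subtractive-normalized variant
  ftbl <- data.frame(subject_id = ot$subject_id, session = ot$session,
                     as.data.frame(feats), check.names = FALSE)
  fsn <- subtractive_normalize(ftbl)
  keep <- !fsn$baseline
  Xsn <- as.matrix(fsn[keep, colnames(feats), drop = FALSE])
  if (outcome == "onsd") {
    osn <- subtractive_normalize(ot[c("subject_id", "session", "onsd_mm")])
    y <- osn$onsd_mm[keep]
  } else {
    tt <- ot[.IMPACT_COLS]
    tt[.IMPACT_RECIPROCAL] <- lapply(ot[.IMPACT_RECIPROCAL],
                                     function(v) {
                                       if (any(v <= 0)) {
                                         stop("reciprocal-bound composite <= 0",
                                              call. = FALSE)
                                       }
                                       1 / v
                                     })
    dt <- subtractive_normalize(cbind(ot[c("subject_id", "session")], tt))
    y <- impact_pc(dt[keep, .IMPACT_COLS], reciprocal = FALSE)$scores
  }
  loso_predict(Xsn, y, ot$subject_id[keep], ot$session[keep],
               variant = "sn", pc_grid = pc_grid, baseline = baseline)
}
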