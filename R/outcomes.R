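.IMPACT_COLS <- c("verbal", "visual", "visual_motor", "reaction_time",
                  "impulse_control", "symptom")
.IMPACT_RECIPROCAL <- c("reaction_time", "impulse_control", "symptom")

#' PC-ImPACT: oriented first principal component of ImPACT composites
#'
#' Reaction time, impulse control and symptom score improve downward, so
#' their reciprocals are taken before analysis; all columns are then
#' standardized (the composites have incommensurate units) and
#' eigen-decomposed. The first component is oriented so the verbal, visual
#' and visual-motor loadings are positive: higher PC-ImPACT means higher
#' functional neurocognitive performance.
#'
#' @param composites data frame with columns `verbal`, `visual`,
#'   `visual_motor`, `reaction_time`, `impulse_control`, `symptom`.
#' @param drop_symptom exclude the subjective symptom score from the PCA
#'   (default `FALSE`: the symptom column is carried through and receives a
#'   small negative loading).
#' @param reciprocal apply the reciprocal transform to the
#'   lower-is-better composites (default `TRUE`). Set `FALSE` when the
#'   input is already on the transformed scale -- e.g. baseline-subtracted
#'   deltas of transformed composites, which may be negative.
#' @return object of class `impact_pc`: list with `scores` (PC-ImPACT per
#'   row), `loadings` (oriented rotation matrix, orthonormal columns),
#'   `var_explained` (fractions, first entry is the headline diagnostic),
#'   `center`, `scale` (training statistics on the reciprocal-transformed
#'   scale), `cols`.
#' @examples
#' set.seed(2)
#' z <- rnorm(20)
#' tbl <- data.frame(verbal = 80 + 5 * z, visual = 70 + 4 * z,
#'                   visual_motor = 40 + 2 * z,
#'                   reaction_time = 0.55 - 0.03 * z + 0.6,
#'                   impulse_control = 6 - z + 8, symptom = 5 - z + 8)
#' pc <- impact_pc(tbl)
#' pc$var_explained[1]
#' @export
impact_pc <- function(composites, drop_symptom = FALSE, reciprocal = TRUE) {
  stopifnot(is.data.frame(composites))
  cols <- if (drop_symptom) setdiff(.IMPACT_COLS, "symptom") else .IMPACT_COLS
  missing_cols <- setdiff(cols, names(composites))
  if (length(missing_cols)) {
    stop("missing composite columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(composites[cols])
  if (nrow(x) < 2) stop("need at least 2 rows for a principal component",
                        call. = FALSE)
  if (anyNA(x)) stop("missing composite values", call. = FALSE)
  recip <- if (reciprocal) intersect(.IMPACT_RECIPROCAL, cols) else character(0)
  if (length(recip)) {
    if (any(x[, recip] <= 0)) {
      stop("reaction_time, impulse_control and symptom must be > 0 ",
           "(reciprocal transform)", call. = FALSE)
    }
    x[, recip] <- 1 / x[, recip]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) stop("constant composite column", call. = FALSE)
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  # orientation: cognitive composites load positively on PC1
  cog <- intersect(c("verbal", "visual", "visual_motor"), cols)
  if (sum(rot[cog, 1]) < 0) {
    rot[, 1] <- -rot[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = unname(pc$x[, 1]), loadings = rot,
                 var_explained = ve, center = ctr, scale = scl,
                 cols = cols, drop_symptom = drop_symptom,
                 reciprocal = reciprocal),
            class = "impact_pc")
}

#' @export
print.impact_pc <- function(x, digits = 3, ...) {
  cat("PC-ImPACT model\n")
  cat(sprintf("  first PC explains %.1f%% of composite variance\n",
              100 * x$var_explained[1]))
  cat("  PC1 loadings:\n")
  print(round(x$loadings[, 1], digits))
  invisible(x)
}

#' @export
predict.impact_pc <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$cols])
  recip <- if (isTRUE(object$reciprocal)) {
    intersect(.IMPACT_RECIPROCAL, object$cols)
  } else {
    character(0)
  }
  if (length(recip)) {
    if (any(x[, recip] <= 0)) stop("reciprocal-bound composite <= 0",
                                   call. = FALSE)
    x[, recip] <- 1 / x[, recip]
  }
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  unname(as.numeric(z %*% object$loadings[, 1]))
}

#' Subtractive normalization against each subject's baseline session
#'
#' Subtracts each subject's first-session (baseline) value from every
#' session's value, for features and outcomes alike. Baseline rows are
#' retained, flagged, and identically zero; they are used only for
#' normalization and are excluded from subtractive-normalized model
#' fitting, so the eligible row count is `nrow - n_subjects`.
#'
#' @param tbl data frame keyed by subject and session.
#' @param cols columns to normalize (default: all numeric columns other
#'   than the keys).
#' @param subject_col,session_col key column names.
#' @return `tbl` with normalized `cols` and a logical `baseline` column.
#' @export
subtractive_normalize <- function(tbl, cols = NULL,
                                  subject_col = "subject_id",
                                  session_col = "session") {
  stopifnot(is.data.frame(tbl),
            all(c(subject_col, session_col) %in% names(tbl)))
  if (is.null(cols)) {
    cols <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                    c(subject_col, session_col, "baseline"))
  }
  base_session <- min(tbl[[session_col]])
  subj <- tbl[[subject_col]]
  has_base <- unique(subj[tbl[[session_col]] == base_session])
  missing_base <- setdiff(unique(subj), has_base)
  if (length(missing_base)) {
    stop("subject(s) missing a baseline (session ", base_session,
         ") record: ", paste(missing_base, collapse = ", "), call. = FALSE)
  }
  base_rows <- tbl[tbl[[session_col]] == base_session, , drop = FALSE]
  idx <- match(subj, base_rows[[subject_col]])
  out <- tbl
  for (cc in cols) out[[cc]] <- tbl[[cc]] - base_rows[[cc]][idx]
  out$baseline <- tbl[[session_col]] == base_session
  out
}

#' Per-session means of subtractive-normalized outcomes
#'
#' @param delta_tbl output of [subtractive_normalize()].
#' @param cols outcome columns to summarise (default: all normalized
#'   numeric columns).
#' @param session_col session key.
#' @return long data frame with `session`, `outcome`, `mean`, `se`, `n`.
#' @export
changes_summary <- function(delta_tbl, cols = NULL,
                            session_col = "session") {
  stopifnot(is.data.frame(delta_tbl), session_col %in% names(delta_tbl))
  if (is.null(cols)) {
    cols <- setdiff(names(delta_tbl)[vapply(delta_tbl, is.numeric,
                                            logical(1))],
                    c("subject_id", session_col))
  }
  sessions <- sort(unique(delta_tbl[[session_col]]))
  out <- expand.grid(session = sessions, outcome = cols,
                     stringsAsFactors = FALSE)
  out$mean <- out$se <- NA_real_
  out$n <- 0L
  for (k in seq_len(nrow(out))) {
    v <- delta_tbl[[out$outcome[k]]][delta_tbl[[session_col]] ==
                                       out$session[k]]
    v <- v[!is.na(v)]
    out$n[k] <- length(v)
    if (length(v) >= 1) out$mean[k] <- mean(v)
    if (length(v) >= 2) out$se[k] <- sd(v) / sqrt(length(v))
  }
  out[order(out$outcome, out$session), c("session", "outcome", "mean",
                                         "se", "n")]
}
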