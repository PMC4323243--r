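# Observer-reliability statistics and the Friedman cross-plane test.
# Pearson r and the Friedman statistic are computed from their defining
# formulas; library routines are used only as cross-checks in the test suite.

#' Pearson correlation with t-based p-value
#'
#' Computed from the sum formula
#' `r = (n*Sxy - Sx*Sy) / sqrt((n*Sxx - Sx^2) * (n*Syy - Sy^2))`
#' with a two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. If either vector has zero variance, r is
#' undefined and returned as `NA` with a warning (never coerced to 1).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_usage("x and y must have equal length")
  if (n < 3L) stop_usage("Pearson correlation needs at least 3 pairs")
  sx <- sum(x); sy <- sum(y)
  vx <- n * sum(x^2) - sx^2
  vy <- n * sum(y^2) - sy^2
  if (vx <= 0 || vy <= 0) {
    warning("zero variance: correlation undefined, returning NA")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- (n * sum(x * y) - sx * sy) / sqrt(vx * vy)
  r <- min(1, max(-1, r))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

.pair_trials <- function(trials, mode) {
  meta <- data.frame(
    idx = seq_along(trials),
    subject = vapply(trials, function(t) t$subject_id, ""),
    observer = vapply(trials, function(t) t$observer, ""),
    trial = vapply(trials, function(t) t$trial, 1L),
    stringsAsFactors = FALSE)
  pairs <- list()
  if (mode == "intraobserver") {
    # same observer, trial 1 vs trial 2, per subject
    for (key in unique(paste(meta$subject, meta$observer, sep = "\r"))) {
      sub <- meta[paste(meta$subject, meta$observer, sep = "\r") == key, ]
      t1 <- sub$idx[sub$trial == 1L]; t2 <- sub$idx[sub$trial == 2L]
      if (length(t1) != 1L || length(t2) != 1L) {
        stop_pairing(sprintf(
          "subject \"%s\" observer \"%s\": need exactly one trial 1 and one trial 2",
          sub$subject[1], sub$observer[1]))
      }
      pairs[[length(pairs) + 1L]] <- c(t1, t2)
    }
  } else {
    # observer 1 vs observer 2, matched by subject and trial
    obs <- sort(unique(meta$observer))
    if (length(obs) != 2L) {
      stop_pairing(sprintf("interobserver mode needs exactly 2 observers, found %d",
                           length(obs)))
    }
    for (key in unique(paste(meta$subject, meta$trial, sep = "\r"))) {
      sub <- meta[paste(meta$subject, meta$trial, sep = "\r") == key, ]
      a <- sub$idx[sub$observer == obs[1]]; b <- sub$idx[sub$observer == obs[2]]
      if (length(a) != 1L || length(b) != 1L) {
        stop_pairing(sprintf(
          "subject \"%s\" trial %d: need one set from each observer",
          sub$subject[1], sub$trial[1]))
      }
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  pairs
}

#' Intra-/interobserver landmark reliability
#'
#' Pairs repeated digitisations of the same subjects and, per landmark and
#' coordinate axis, reports the mean absolute coordinate difference across
#' subjects and the Pearson correlation (with two-sided p) between the two
#' paired coordinate vectors. `"intraobserver"` pairs each observer's trial 1
#' against their trial 2; `"interobserver"` pairs the two observers'
#' trial-matched digitisations.
#'
#' @param trials List of [landmark_set()]s carrying `subject_id`, `observer`
#'   and `trial` metadata.
#' @param mode `"intraobserver"` or `"interobserver"`.
#' @param landmarks Landmarks to analyse (default: those present in every
#'   trial set).
#' @param bonferroni Also report Bonferroni-adjusted p-values (off by
#'   default; one correlation is reported per landmark-axis cell, unadjusted,
#'   as is conventional for reliability tables).
#' @return A `reliability_report` data frame with columns `landmark`, `axis`,
#'   `n`, `mean_abs_diff` (mm), `r`, `p` (and `p_adj` when requested), and a
#'   `mode` attribute.
#' @export
landmark_reliability <- function(trials,
                                 mode = c("intraobserver", "interobserver"),
                                 landmarks = NULL, bonferroni = FALSE) {
  mode <- match.arg(mode)
  if (length(trials) < 2L) stop_usage("need at least two landmark sets")
  if (is.null(landmarks)) {
    landmarks <- Reduce(intersect, lapply(trials, landmark_names))
    landmarks <- setdiff(landmarks, .derived_landmarks)
  }
  for (t in trials) require_landmarks(t, landmarks)
  pairs <- .pair_trials(trials, mode)
  n <- length(pairs)
  if (n < 3L) stop_usage("need at least 3 paired subjects for correlation")
  axes <- c("X", "Y", "Z")
  rows <- list()
  for (lm in landmarks) {
    A <- t(vapply(pairs, function(p) trials[[p[1]]]$points[lm, ], numeric(3)))
    B <- t(vapply(pairs, function(p) trials[[p[2]]]$points[lm, ], numeric(3)))
    for (k in 1:3) {
      ct <- withCallingHandlers(
        pearson_r(A[, k], B[, k]),
        warning = function(w) {
          warning(sprintf("landmark %s axis %s: %s", lm, axes[k],
                          conditionMessage(w)), call. = FALSE)
          invokeRestart("muffleWarning")
        })
      rows[[length(rows) + 1L]] <- data.frame(
        landmark = lm, axis = axes[k], n = n,
        mean_abs_diff = mean(abs(A[, k] - B[, k])),
        r = ct$r, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_adj <- pmin(1, out$p * nrow(out))
  attr(out, "mode") <- mode
  class(out) <- c("reliability_report", class(out))
  out
}

#' Write a reliability report as a wide per-axis CSV
#'
#' One row per landmark with mean absolute difference, r and p for each of
#' the X, Y, Z axes — the layout of published reliability tables.
#'
#' @param report A [landmark_reliability()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reliability_csv <- function(report, path) {
  lms <- unique(report$landmark)
  out <- data.frame(landmark = lms, stringsAsFactors = FALSE)
  for (ax in c("X", "Y", "Z")) {
    sub <- report[report$axis == ax, ]
    i <- match(lms, sub$landmark)
    out[[paste0(ax, "_mean")]] <- sub$mean_abs_diff[i]
    out[[paste0(ax, "_r")]] <- sub$r[i]
    out[[paste0(ax, "_p")]] <- sub$p[i]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Friedman rank test for k related samples
#'
#' Nonparametric test for differences among k treatments (here: reference
#' planes) measured on the same n blocks (subjects or landmarks). Values are
#' ranked within each block with midranks for ties; the statistic
#' `Q = 12n/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2`, divided by the standard
#' tie-correction factor `1 - sum(t^3 - t) / (n k (k^2 - 1))`, is referred to
#' a chi-square distribution with k - 1 degrees of freedom.
#'
#' @param blocks Numeric n x k matrix (or data frame): n blocks in rows,
#'   k treatments in columns; no missing cells.
#' @return Object of class `friedman_result`: list with `statistic`, `dof`,
#'   `p_value`, `n`, `k`.
#' @export
friedman_test <- function(blocks) {
  x <- as.matrix(blocks)
  if (anyNA(x)) stop_usage("missing cells are not allowed")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop_usage("need at least 2 blocks and 2 treatments")
  ranks <- t(apply(x, 1L, rank))          # midranks for ties
  Rj <- colSums(ranks)
  q_num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  tie_sum <- sum(apply(ranks, 1L, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  }))
  q_den <- n * k * (k + 1) - tie_sum / (k - 1)
  stat <- if (q_den <= 0) 0 else q_num / q_den
  p <- if (q_den <= 0) 1 else stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(statistic = stat, dof = k - 1L, p_value = p, n = n, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman rank test: Q = %.4f, df = %d, p = %.4g (n = %d blocks, k = %d treatments)\n",
              x$statistic, x$dof, x$p_value, x$n, x$k))
  invisible(x)
}

#' Write a Friedman result to JSON
#' @param result A [friedman_test()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_friedman_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
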