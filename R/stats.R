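# Validation statistics for composite endoscopic indices: Spearman rank
# correlation, multilevel-lesion ground truth rules, ROC-based cutoff
# selection with diagnostic performance, ICC(2,1) inter-rater reliability,
# Shapiro-Wilk normality.

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties and a two-sided p-value
#' from the standard large-sample approximation (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble with `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed",
                                 call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Multilevel bowel lesion ground truth
#'
#' Per-score definitions of inflammation distributed across multiple
#' small-bowel regions. Lewis Score: more than 2 of the 3 tertiles inflamed.
#' CECDAI: both the proximal and distal segments inflamed. CDACE: at least 2
#' inflamed quartiles, excluding the case of exactly 2 consecutive quartiles
#' (which may correspond to a single region of the coarser systems);
#' adjacency means consecutive indices 1-2, 2-3, 3-4, with no wraparound.
#'
#' @param inflamed A logical matrix or data frame, one row per study and one
#'   column per region (4 quartiles for CDACE, 3 tertiles for LS, 2 segments
#'   proximal/distal for CECDAI), or a single logical vector for one study.
#' @param system `"CDACE"`, `"LS"` or `"CECDAI"`.
#' @return Logical vector, one entry per study.
#' @export
#' @examples
#' multilevel_lesion(c(TRUE, TRUE, FALSE, FALSE), "CDACE")   # adjacent pair
#' multilevel_lesion(c(TRUE, FALSE, TRUE, FALSE), "CDACE")
multilevel_lesion <- function(inflamed, system = c("CDACE", "LS", "CECDAI")) {
  system <- match.arg(system)
  if (is.data.frame(inflamed)) inflamed <- as.matrix(inflamed)
  if (is.null(dim(inflamed))) inflamed <- matrix(inflamed, nrow = 1)
  if (!is.logical(inflamed) || anyNA(inflamed)) {
    stop("inflamed must be logical with no missing values", call. = FALSE)
  }
  need <- c(CDACE = 4L, LS = 3L, CECDAI = 2L)[[system]]
  if (ncol(inflamed) != need) {
    stop(system, " requires ", need, " regions per study, got ",
         ncol(inflamed), call. = FALSE)
  }
  switch(system,
    LS = rowSums(inflamed) > 2,
    CECDAI = rowSums(inflamed) == 2,
    CDACE = apply(inflamed, 1, function(z) {
      idx <- which(z)
      length(idx) >= 2 && !(length(idx) == 2 && diff(idx) == 1)
    })
  )
}

#' ROC-based cutoff selection with diagnostic performance
#'
#' Builds the empirical ROC curve (AUC by the trapezoidal rule), selects the
#' cutoff maximising Youden's J (sensitivity + specificity - 1), and reports
#' sensitivity, specificity, PPV and NPV at that cutoff. A positive test is
#' `score >= cutoff`; the reported cutoff is the midpoint between the
#' adjacent distinct score values, and ties in J are broken toward higher
#' specificity (the larger cutoff).
#'
#' @param scores Numeric vector of index values (higher = more diseased).
#' @param labels Logical vector of reference-standard labels (`TRUE` =
#'   condition present), same length as `scores`.
#' @return An object of class `cdace_roc` with elements `cutoff`, `auc`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden`, `curve` (tibble of
#'   all candidate thresholds), `n_pos`, `n_neg`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' r <- roc_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' glance(r)
roc_cutoff <- function(scores, labels) {
  stopifnot(is.numeric(scores), is.logical(labels))
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate ROC: both classes must be present", call. = FALSE)
  }
  v <- sort(unique(scores))
  # candidate thresholds: below min, midpoints between adjacent distinct
  # values, above max; positive means score >= threshold
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  curve <- tibble::tibble(
    threshold = thr,
    tp = vapply(thr, function(t) sum(scores >= t & labels), numeric(1)),
    fp = vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  ) |>
    dplyr::mutate(
      fn = n_pos - .data$tp, tn = n_neg - .data$fp,
      sensitivity = .data$tp / n_pos,
      specificity = .data$tn / n_neg,
      youden = .data$sensitivity + .data$specificity - 1
    )
  # trapezoidal AUC over the empirical ROC (FPR descending along thresholds)
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
  # Youden maximum; ties toward higher specificity = larger threshold
  best <- curve[curve$youden == max(curve$youden), ]
  best <- best[which.max(best$threshold), ]
  out <- list(
    cutoff = best$threshold,
    auc = auc,
    sensitivity = best$sensitivity,
    specificity = best$specificity,
    ppv = if (best$tp + best$fp > 0) best$tp / (best$tp + best$fp) else NA_real_,
    npv = if (best$tn + best$fn > 0) best$tn / (best$tn + best$fn) else NA_real_,
    youden = best$youden,
    curve = curve,
    n_pos = n_pos, n_neg = n_neg
  )
  class(out) <- "cdace_roc"
  out
}

#' @export
print.cdace_roc <- function(x, ...) {
  cat("ROC cutoff analysis (", x$n_pos, " positive / ", x$n_neg,
      " negative)\n", sep = "")
  cat(sprintf("  AUC %.3f; cutoff %.3g (positive: score >= cutoff)\n",
              x$auc, x$cutoff))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation (Shrout--Fleiss), the standard inter-rater reliability
#' statistic for a subjects-by-readers score matrix:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n}}
#' with \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} the subject, reader and error mean
#' squares of the two-way ANOVA. The 95% confidence interval uses the
#' F-distribution construction for ICC(2,1).
#'
#' @param m A complete numeric matrix or data frame, subjects as rows
#'   (n >= 2) and readers as columns (k >= 2).
#' @param conf_level Confidence level for the interval, default 0.95.
#' @return An object of class `cdace_icc` with elements `icc`, `ci_low`,
#'   `ci_high`, `ms_subject`, `ms_reader`, `ms_error`, `n`, `k`,
#'   `conf_level`. Supports [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' m <- cbind(r1 = c(9, 6, 8, 7, 10), r2 = c(9, 5, 9, 8, 10))
#' icc_2_1(m)
icc_2_1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (!is.numeric(m) || anyNA(m)) {
    stop("m must be a complete numeric matrix", call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 readers",
                           call. = FALSE)
  g <- mean(m)
  ri <- rowMeans(m); cj <- colMeans(m)
  msr <- k * sum((ri - g)^2) / (n - 1)
  msc <- n * sum((cj - g)^2) / (k - 1)
  mse <- sum((m - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + g)^2) /
    ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) stop("undefined ICC: zero total variance", call. = FALSE)
  icc <- (msr - mse) / denom
  # Shrout-Fleiss F-based interval with Satterthwaite df
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  out <- list(icc = icc, ci_low = lower, ci_high = upper,
              ms_subject = msr, ms_reader = msc, ms_error = mse,
              n = n, k = k, conf_level = conf_level)
  class(out) <- "cdace_icc"
  out
}

#' @export
print.cdace_icc <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.3f (%g%% CI %.3f-%.3f), n = %d subjects, k = %d readers\n",
    x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] returning a tidy one-row
#' tibble; used to check the distribution of extracted score data before
#' reliability analysis.
#'
#' @param x Numeric vector, 3 <= n <= 5000, not constant.
#' @return A one-row tibble with `statistic` (W) and `p_value`.
#' @export
normality_check <- function(x) {
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  if (length(x) < 3 || length(x) > 5000) {
    stop("sample size must be in 3..5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("normality undefined for a constant vector",
                              call. = FALSE)
  sw <- stats::shapiro.test(x)
  tibble::tibble(statistic = unname(sw$statistic), p_value = sw$p.value)
}
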