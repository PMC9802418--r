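# Independent oracles used to check package computations by a second route.

# Pearson product-moment formula applied to average ranks, written out
# explicitly (no call to cor()).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exhaustive-threshold ROC oracle: every candidate cutoff is tried by brute
# force; AUC via the Mann-Whitney pair count (ties count 1/2).
oracle_roc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  auc <- mean(cmp)
  v <- sort(unique(scores))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  best <- NULL
  for (t in thr) {
    sens <- mean(pos >= t); spec <- mean(neg < t)
    j <- sens + spec - 1
    # ties in J resolved toward the larger threshold (higher specificity)
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && t > best$cutoff)) {
      best <- list(cutoff = t, j = j, sens = sens, spec = spec)
    }
  }
  tp <- sum(pos >= best$cutoff); fp <- sum(neg >= best$cutoff)
  fn <- length(pos) - tp; tn <- length(neg) - fp
  list(cutoff = best$cutoff, auc = auc,
       sensitivity = best$sens, specificity = best$spec,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

# Enumerates every reachable (li, r, s) triple by looping over all 5^4
# quartile-grade profiles and the four stenosis grades.
oracle_triples <- function() {
  out <- list()
  for (g1 in 0:4) for (g2 in 0:4) for (g3 in 0:4) for (g4 in 0:4) {
    g <- c(g1, g2, g3, g4)
    for (s in 0:3) {
      out[[length(out) + 1]] <- c(li = sum(g), r = sum(g > 0), s = s)
    }
  }
  unique(do.call(rbind, out))
}

# Two-way ANOVA mean squares via stats::aov on the long layout, then the
# Shrout-Fleiss ICC(2,1) formula assembled by hand.
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    reader = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + reader, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# A study whose quartile profile and stenosis pattern are chosen directly.
make_study <- function(id, grades, traversed = logical(0),
                       reached_colon = TRUE, sb_duration = 1000) {
  lesions <- NULL
  idx <- which(grades > 0)
  if (length(idx) > 0) {
    types <- names(lesion_types())
    lesions <- data.frame(
      timestamp_s = (idx - 1) / 4 * sb_duration + sb_duration / 8,
      lesion_type = types[grades[idx] + 1]
    )
  }
  stenoses <- if (length(traversed) > 0) {
    data.frame(timestamp_s = seq_along(traversed) * sb_duration / 10,
               traversed = traversed)
  }
  sbce_study(id, sb_duration, lesions = lesions, stenoses = stenoses,
             reached_colon = reached_colon)
}
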