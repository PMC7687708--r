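# independent brute-force oracles, deliberately written with different
# algorithms than the package implementations they check

# average precision by explicit threshold enumeration: at every distinct
# score value t, classify score >= t and accumulate precision x recall step
oracle_average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    precision <- tp / sum(pred)
    recall <- tp / P
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# best F1 by explicit confusion-matrix evaluation at every distinct score
oracle_best_f1 <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- 0
  for (t in unique(scores)) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    best <- max(best, f1)
  }
  best
}

# dense simplex grid for non-negative least squares: directions u on the
# probability simplex (step 1/steps per coordinate), each scaled by the
# optimal non-negative scalar, so any non-negative w = c*u is covered
make_simplex_grid <- function(d, steps = 100L) {
  stopifnot(d == 4L)  # only the 4-type case is enumerated
  g <- expand.grid(i = 0:steps, j = 0:steps, k = 0:steps)
  g <- g[g$i + g$j + g$k <= steps, ]
  W <- rbind(g$i, g$j, g$k, steps - g$i - g$j - g$k) / steps
  W
}

oracle_nnls_best_residual <- function(R, b, W) {
  D <- R %*% W                       # candidate directions in data space
  num <- colSums(D * b)
  den <- colSums(D * D)
  cs <- pmax(0, num / den)           # optimal non-negative scale per direction
  res2 <- sum(b * b) - 2 * cs * num + cs^2 * den
  sqrt(max(min(res2), 0))
}

# Welch two-sample t-test coded directly from the textbook formulas
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p.value = p)
}
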