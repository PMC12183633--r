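# Independent oracles used across the suite. These deliberately take naive
# code paths (explicit loops, closed forms) so they cannot share a bug with
# the package implementations they check.

# auROC by exhaustive comparison of every positive-negative pair
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# auPRC by explicit threshold sweep: recompute TP/FP by counting at every
# recall-change threshold, trapezoid between vertices, anchored at recall 0
sweep_pr_auc <- function(labels, scores) {
  np <- sum(labels == 1)
  ts <- sort(unique(scores[labels == 1]), decreasing = TRUE)
  area <- 0; pr <- 0; pp <- NA
  for (t in ts) {
    tp <- 0; fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (labels[i] == 1) tp <- tp + 1 else fp <- fp + 1
      }
    }
    r <- tp / np; p <- tp / (tp + fp)
    if (is.na(pp)) pp <- p
    area <- area + (r - pr) * (p + pp) / 2
    pr <- r; pp <- p
  }
  area
}

# confusion counts by a plain loop
loop_confusion <- function(labels, predicted) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && predicted[i] == 1) tp <- tp + 1
    if (labels[i] == 0 && predicted[i] == 0) tn <- tn + 1
    if (labels[i] == 0 && predicted[i] == 1) fp <- fp + 1
    if (labels[i] == 1 && predicted[i] == 0) fn <- fn + 1
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# differential entropy of N(mu, sigma^2 I_d), nats
gaussian_entropy <- function(d, sigma) (d / 2) * log(2 * pi * exp(1) * sigma^2)

# geometric-mean closed form of the first-neighbour estimator
geometric_mean_form <- function(points, epsilon = 1e-12) {
  n <- nrow(points); d <- ncol(points)
  dm <- as.matrix(dist(points)); diag(dm) <- Inf
  rho <- pmax(apply(dm, 1, min), epsilon)
  d * mean(log(rho)) + (d / 2) * log(pi) - lgamma(1 + d / 2) -
    digamma(1) + log(n - 1)
}

# small labelled embedding set with both classes
toy_set <- function(n_pos = 6, n_neg = 8, d = 2, seed = 1, epoch = 0L) {
  set.seed(seed)
  embedding_set(matrix(rnorm((n_pos + n_neg) * d), ncol = d),
                rep(c(1L, 0L), c(n_pos, n_neg)), epoch = epoch)
}
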