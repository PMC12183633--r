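#' Log-volume of the d-dimensional unit ball
#'
#' Returns `log(V_d)` with `V_d = pi^(d/2) / Gamma(1 + d/2)`, computed
#' entirely in log space via `lgamma()`. In linear space `V_d` underflows to
#' zero near d ~ 1500 (and is already ~1e-297 at d = 768), which would poison
#' the entropy estimate; the log form stays finite for any practical d.
#'
#' @param d positive integer dimension (vectorised).
#' @return `log(V_d)` in nats.
#' @examples
#' exp(log_unit_ball_volume(1:3)) # 2, pi, 4*pi/3
#' @export
log_unit_ball_volume <- function(d) {
  if (any(!is.finite(d)) || any(d < 1) || any(d != floor(d)))
    stop_emb("domain", "d must be a positive integer")
  (d / 2) * log(pi) - lgamma(1 + d / 2)
}

# additive constant of the k-NN estimator: gamma + log(N-1) in the classical
# first-neighbour form; psi(N) - psi(k) in the digamma generalisation for k>1
kl_additive_constant <- function(N, k) {
  if (k == 1L) -digamma(1) + log(N - 1) else digamma(N) - digamma(k)
}

#' Kozachenko-Leonenko differential-entropy estimate
#'
#' Nonparametric estimate of the differential entropy of a continuous
#' distribution from a sample, using nearest-neighbour distances instead of
#' an explicit density estimate. For the default `k = 1` each sample
#' contributes
#' \deqn{h_i = d \log \rho_i + \log V_d + \gamma + \log(N - 1),}
#' where \eqn{\rho_i} is the Euclidean distance from point i to its nearest
#' other point, \eqn{V_d} the unit-ball volume and \eqn{\gamma} the
#' Euler-Mascheroni constant; the estimate is the arithmetic mean of the
#' \eqn{h_i}, which is algebraically identical to the geometric-mean form
#' \eqn{H_N = d \log \bar\rho + \log V_d + \gamma + \log(N-1)} with
#' \eqn{\bar\rho = (\prod_i \rho_i)^{1/N}}. All logarithms are natural, so
#' entropies are in nats.
#'
#' For `k > 1` the digamma generalisation is used (\eqn{\gamma + \log(N-1)}
#' replaced by \eqn{\psi(N) - \psi(k)}, with \eqn{\rho_i} the k-th-neighbour
#' distance); this is an extension beyond the classical first-neighbour
#' form.
#'
#' Duplicate points give \eqn{\rho_i = 0}; distances are floored at
#' `epsilon` so the estimator stays finite, the clamp count is reported in
#' the result, and a warning is emitted when more than 10% of distances were
#' clamped.
#'
#' @param points numeric matrix, N rows (samples) by d columns (dimensions),
#'   with `N >= k + 1` and all entries finite.
#' @param k neighbour order (default 1, the classical estimator).
#' @param epsilon positive floor for neighbour distances (default 1e-12).
#' @param metric distance metric; only `"euclidean"` is supported.
#' @return An object of class `kl_entropy`: a list with `H` (the estimate,
#'   nats), `contributions` (per-sample terms, mean equals `H`),
#'   `median_contribution`, `d`, `N`, `k`, and `n_clamped`.
#' @examples
#' kl_entropy(matrix(c(0, 1), ncol = 1))$H # log(2) + gamma
#' @export
kl_entropy <- function(points, k = 1L, epsilon = 1e-12, metric = "euclidean") {
  if (!identical(metric, "euclidean"))
    stop_emb("config", sprintf("unsupported metric '%s'", metric))
  if (!is.matrix(points)) points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop_emb("domain", "points contain non-finite values")
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop_emb("config", "epsilon must be > 0")
  k <- as.integer(k)
  N <- nrow(points)
  d <- ncol(points)
  if (k < 1L) stop_emb("config", "k must be >= 1")
  if (N <= k)
    stop_emb("sample_size", sprintf("need N >= k + 1 samples (N = %d, k = %d)",
                                    N, k))
  rho <- .knn_kth_dist(points, k)
  clamped <- rho < epsilon
  n_clamped <- sum(clamped)
  rho[clamped] <- epsilon
  contributions <- d * log(rho) + log_unit_ball_volume(d) +
    kl_additive_constant(N, k)
  if (n_clamped > 0.1 * N)
    warning(sprintf(
      "%d of %d nearest-neighbour distances (%.0f%%) clamped at epsilon = %g; the estimate is dominated by duplicate or near-duplicate points",
      n_clamped, N, 100 * n_clamped / N, epsilon))
  structure(
    list(H = mean(contributions), contributions = contributions,
         median_contribution = median(contributions),
         d = d, N = N, k = k, epsilon = epsilon, n_clamped = n_clamped),
    class = "kl_entropy"
  )
}

#' @export
print.kl_entropy <- function(x, ...) {
  cat(sprintf("Kozachenko-Leonenko entropy estimate (k = %d)\n", x$k))
  cat(sprintf("  H = %.6f nats  (N = %d, d = %d, median contribution %.6f)\n",
              x$H, x$N, x$d, x$median_contribution))
  if (x$n_clamped > 0)
    cat(sprintf("  %d neighbour distance(s) clamped at epsilon = %g\n",
                x$n_clamped, x$epsilon))
  invisible(x)
}

#' Class-conditional entropy estimates
#'
#' Estimates the differential entropy of the positive (label 1) and negative
#' (label 0) point clouds of one epoch snapshot. By default each class's
#' neighbour search is confined to its own cloud (within-class), so the two
#' estimates are the class-conditional entropies and are independent of the
#' other class's geometry. With `pooled = TRUE` neighbours are instead found
#' in the union of both clouds and per-class summaries are taken over each
#' class's contributions; this couples the estimates and is provided for
#' comparison only.
#'
#' @param set an [embedding_set()]; each class needs at least `k + 1` samples.
#' @inheritParams kl_entropy
#' @param pooled use the pooled neighbour search (default `FALSE`).
#' @return A list with elements `pos` and `neg`, both of class `kl_entropy`.
#' @export
class_entropy <- function(set, k = 1L, epsilon = 1e-12, pooled = FALSE) {
  stopifnot(inherits(set, "embedding_set"))
  k <- as.integer(k)
  pos_idx <- which(set$labels == 1L)
  neg_idx <- which(set$labels == 0L)
  for (cls in list(c("positive", length(pos_idx)), c("negative", length(neg_idx))))
    if (as.integer(cls[2]) <= k)
      stop_emb("sample_size",
               sprintf("%s class has %s samples; need at least k + 1 = %d",
                       cls[1], cls[2], k + 1L))
  if (!pooled) {
    return(list(
      pos = kl_entropy(set$features[pos_idx, , drop = FALSE], k, epsilon),
      neg = kl_entropy(set$features[neg_idx, , drop = FALSE], k, epsilon)
    ))
  }
  whole <- kl_entropy(set$features, k, epsilon)
  slice <- function(idx) {
    h <- whole$contributions[idx]
    structure(list(H = mean(h), contributions = h,
                   median_contribution = median(h), d = whole$d,
                   N = length(idx), k = k, epsilon = epsilon,
                   n_clamped = NA_integer_),
              class = "kl_entropy")
  }
  list(pos = slice(pos_idx), neg = slice(neg_idx))
}

#' Per-epoch class entropy gap trajectory
#'
#' Computes, for each epoch snapshot, the mean and median of the per-sample
#' entropy contributions of the positive and negative classes and the
#' absolute gaps between them (delta_mean, delta_median). The trajectory of
#' delta_mean across epochs is the separability statistic used to choose the
#' optimal fine-tuning epoch: a well-behaved fine-tuning run shows a
#' coincidence-separation-coincidence profile with the gap peaking where the
#' extractor discriminates best.
#'
#' @param sets list of [embedding_set()]s with strictly increasing epochs.
#' @inheritParams class_entropy
#' @return An object of class `entropy_trajectory` wrapping a data frame
#'   `records` with one row per epoch and columns `epoch`, `pos_mean`,
#'   `pos_median`, `neg_mean`, `neg_median`, `delta_mean`, `delta_median`,
#'   `n_pos`, `n_neg`, `n_clamped`.
#' @seealso [select_optimal_epoch()]
#' @export
entropy_trajectory <- function(sets, k = 1L, epsilon = 1e-12, pooled = FALSE) {
  if (inherits(sets, "embedding_set")) sets <- list(sets)
  if (length(sets) == 0L)
    stop_emb("input", "need at least one epoch snapshot")
  epochs <- vapply(sets, function(s) s$epoch, integer(1))
  if (anyDuplicated(epochs))
    stop_emb("input", "duplicate epoch indices in trajectory input")
  if (is.unsorted(epochs, strictly = TRUE))
    stop_emb("input", "epochs must be strictly increasing")
  rows <- lapply(sets, function(s) {
    ce <- class_entropy(s, k = k, epsilon = epsilon, pooled = pooled)
    data.frame(
      epoch = s$epoch,
      pos_mean = ce$pos$H, pos_median = ce$pos$median_contribution,
      neg_mean = ce$neg$H, neg_median = ce$neg$median_contribution,
      delta_mean = abs(ce$pos$H - ce$neg$H),
      delta_median = abs(ce$pos$median_contribution - ce$neg$median_contribution),
      n_pos = ce$pos$N, n_neg = ce$neg$N,
      n_clamped = sum(c(ce$pos$n_clamped, ce$neg$n_clamped), na.rm = TRUE)
    )
  })
  structure(list(records = do.call(rbind, rows), k = as.integer(k),
                 epsilon = epsilon, pooled = pooled),
            class = "entropy_trajectory")
}

#' @export
as.data.frame.entropy_trajectory <- function(x, ...) x$records

#' @export
print.entropy_trajectory <- function(x, digits = 4, ...) {
  cat(sprintf("entropy trajectory over %d epochs (k = %d%s)\n",
              nrow(x$records), x$k,
              if (x$pooled) ", pooled neighbours" else ""))
  print(format(x$records, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.entropy_trajectory <- function(object, ...) {
  sel <- select_optimal_epoch(object)
  cat(sprintf("peak delta_mean %.4f nats at epoch %d (median criterion %s)\n",
              max(object$records$delta_mean), sel$optimal_epoch,
              if (sel$agreement_with_median) "agrees" else "disagrees"))
  invisible(sel)
}

#' @export
plot.entropy_trajectory <- function(x, ...) {
  r <- x$records
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(r$epoch, cbind(r$pos_mean, r$neg_mean), type = "b",
                    pch = c(19, 1), lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "mean entropy contribution (nats)",
                    main = "class entropy", ...)
  graphics::legend("topleft", c("positive", "negative"), pch = c(19, 1),
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::matplot(r$epoch, cbind(r$delta_mean, r$delta_median), type = "b",
                    pch = c(19, 1), lty = 1, col = c("black", "grey50"),
                    xlab = "epoch", ylab = "entropy gap (nats)",
                    main = "class entropy gap", ...)
  graphics::legend("topleft", c(expression(Delta * "mean"),
                                expression(Delta * "median")),
                   pch = c(19, 1), col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Select the optimal epoch from an entropy-gap trajectory
#'
#' The optimal epoch maximises delta_mean; ties are broken by larger
#' delta_median, then by the smaller epoch. `agreement_with_median` records
#' whether the delta_median criterion (with the symmetric tie-breaking)
#' selects the same epoch — agreement between the two is evidence the gap
#' peak is real rather than an artefact of one summary statistic.
#'
#' @param trajectory an [entropy_trajectory()] object, or a data frame with
#'   columns `epoch`, `delta_mean`, `delta_median`.
#' @return An object of class `epoch_selection`: `optimal_epoch`,
#'   `criterion` (`"delta_mean"`), `agreement_with_median`, `trajectory`
#'   (the records data frame).
#' @export
select_optimal_epoch <- function(trajectory) {
  rec <- if (inherits(trajectory, "entropy_trajectory")) trajectory$records
         else as.data.frame(trajectory)
  if (is.null(rec) || nrow(rec) == 0L)
    stop_emb("input", "empty trajectory")
  needed <- c("epoch", "delta_mean", "delta_median")
  if (!all(needed %in% names(rec)))
    stop_emb("input", paste("trajectory must have columns",
                            paste(needed, collapse = ", ")))
  by_mean <- order(-rec$delta_mean, -rec$delta_median, rec$epoch)
  by_median <- order(-rec$delta_median, -rec$delta_mean, rec$epoch)
  opt <- rec$epoch[by_mean[1L]]
  structure(
    list(optimal_epoch = as.integer(opt), criterion = "delta_mean",
         agreement_with_median = rec$epoch[by_median[1L]] == opt,
         trajectory = rec),
    class = "epoch_selection"
  )
}

#' @export
print.epoch_selection <- function(x, ...) {
  i <- match(x$optimal_epoch, x$trajectory$epoch)
  cat(sprintf("optimal epoch: %d (delta_mean = %.4f nats; median criterion %s)\n",
              x$optimal_epoch, x$trajectory$delta_mean[i],
              if (x$agreement_with_median) "agrees" else "disagrees"))
  invisible(x)
}
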