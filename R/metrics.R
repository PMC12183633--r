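#' Confusion counts for binary predictions
#'
#' @param labels binary truth vector (1 = positive).
#' @param predicted binary prediction vector, same length.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(labels, predicted) {
  if (length(labels) != length(predicted))
    stop_emb("input", "labels and predicted must have equal length")
  if (length(labels) < 1L)
    stop_emb("input", "need at least one sample")
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  if (!all(labels %in% 0:1) || !all(predicted %in% 0:1))
    stop_emb("label", "labels and predictions must be 0/1")
  structure(list(TP = sum(labels == 1L & predicted == 1L),
                 TN = sum(labels == 0L & predicted == 0L),
                 FP = sum(labels == 0L & predicted == 1L),
                 FN = sum(labels == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FN %d\nFP %d  TN %d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy, Matthews correlation coefficient, sensitivity/recall
#' (Sn), specificity (Sp), negative predictive value (NPV) and precision (P)
#' from a 2x2 confusion table. A metric whose denominator is zero is
#' reported as 0 and its name recorded in the `degenerate` field rather than
#' raising an error, so fold-level degeneracies cannot abort a
#' cross-validation run.
#'
#' @param counts a [confusion()] result, or a list with fields TP, TN, FP,
#'   FN.
#' @return A list with fields `ACC`, `MCC`, `Sn`, `Sp`, `NPV`, `P` and
#'   `degenerate` (character vector of zero-denominator metrics).
#' @examples
#' m <- scalar_metrics(list(TP = 50, TN = 40, FP = 10, FN = 0))
#' c(m$ACC, m$MCC) # 0.9, 0.8165
#' @export
scalar_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  total <- TP + TN + FP + FN
  if (total <= 0) stop_emb("input", "empty confusion table")
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  ACC <- (TP + TN) / total
  Sn  <- safe(TP, TP + FN, "Sn")
  Sp  <- safe(TN, TN + FP, "Sp")
  NPV <- safe(TN, TN + FN, "NPV")
  P   <- safe(TP, TP + FP, "P")
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  MCC <- safe(TP * TN - FP * FN, mcc_den, "MCC")
  list(ACC = ACC, MCC = MCC, Sn = Sn, Sp = Sp, NPV = NPV, P = P,
       degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, with ties counted half, via
#' midranks. Identical to exhaustive comparison of all positive-negative
#' pairs.
#'
#' @param labels binary truth vector (1 = positive); both classes must be
#'   present.
#' @param scores numeric scores, higher = more positive.
#' @return auROC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_emb("input", "labels and scores must have equal length")
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop_emb("undefined_metric", "auROC needs both classes present")
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' The curve is evaluated at every threshold where recall changes (the
#' distinct scores attained by positive samples, swept in descending
#' order), anchored at recall 0 with the precision of the first vertex, and
#' integrated by the trapezoidal rule. Thresholds that only add false
#' positives (no recall change) do not create vertices.
#'
#' @inheritParams roc_auc
#' @return auPRC in \[0, 1\]; requires at least one positive.
#' @export
pr_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_emb("input", "labels and scores must have equal length")
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  if (np == 0L)
    stop_emb("undefined_metric", "auPRC needs at least one positive")
  thresholds <- sort(unique(scores[labels == 1L]), decreasing = TRUE)
  area <- 0
  prev_r <- 0; prev_p <- NA_real_
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    r <- tp / np
    p <- tp / sum(sel)
    if (is.na(prev_p)) prev_p <- p # anchor (0, P at first vertex)
    area <- area + (r - prev_r) * (p + prev_p) / 2
    prev_r <- r; prev_p <- p
  }
  area
}

#' Full eight-metric evaluation report
#'
#' Bundles the six threshold metrics (from hard predictions) with the two
#' threshold-free ranking metrics (from continuous scores).
#'
#' @param labels binary truth vector.
#' @param predicted binary predictions.
#' @param scores continuous scores for auROC/auPRC; when `NULL`, `predicted`
#'   is used as a (coarse) score.
#' @return An object of class `metrics_report`: fields `ACC`, `MCC`, `Sn`,
#'   `Sp`, `NPV`, `P`, `auROC`, `auPRC`, plus `counts` and `degenerate`.
#' @export
metrics_report <- function(labels, predicted, scores = NULL) {
  if (is.null(scores)) scores <- as.numeric(predicted)
  counts <- confusion(labels, predicted)
  sm <- scalar_metrics(counts)
  degenerate <- sm$degenerate
  auroc <- tryCatch(roc_auc(labels, scores),
                    embentropy_undefined_metric = function(e) {
                      degenerate <<- c(degenerate, "auROC"); 0 })
  auprc <- tryCatch(pr_auc(labels, scores),
                    embentropy_undefined_metric = function(e) {
                      degenerate <<- c(degenerate, "auPRC"); 0 })
  structure(list(ACC = sm$ACC, MCC = sm$MCC, Sn = sm$Sn, Sp = sm$Sp,
                 NPV = sm$NPV, P = sm$P, auROC = auroc, auPRC = auprc,
                 counts = counts, degenerate = degenerate),
            class = "metrics_report")
}

metric_names <- c("ACC", "MCC", "Sn", "Sp", "NPV", "P", "auROC", "auPRC")

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  v <- vapply(metric_names, function(m) x[[m]], numeric(1))
  print(round(v, digits))
  if (length(x$degenerate))
    cat("degenerate (zero-denominator) metrics reported as 0:",
        paste(unique(x$degenerate), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  as.data.frame(setNames(as.list(vapply(metric_names, function(m) x[[m]],
                                        numeric(1))), metric_names))
}
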