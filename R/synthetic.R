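#' Default unimodal entropy-gap profile
#'
#' Zero at both ends, a gentle shoulder rising to 1 nat next to the peak,
#' and a `peak`-nat spike at `planted_epoch`: the
#' coincidence-separation-coincidence shape in which the classes start
#' indistinguishable, separate most at the planted epoch, and re-overlap
#' with over-fine-tuning.
#'
#' @param epochs number of snapshots T + 1 (epoch 0 included).
#' @param planted_epoch epoch index (0-based) of the gap peak.
#' @param peak gap at the planted epoch, nats.
#' @return Numeric vector of length `epochs`.
#' @export
default_gap_profile <- function(epochs = 11L, planted_epoch = 6L, peak = 4) {
  last <- epochs - 1L
  e <- 0:last
  left <- if (planted_epoch > 1L) e / (planted_epoch - 1L) else rep(0, epochs)
  right <- if (planted_epoch < last - 1L) (last - e) / (last - planted_epoch - 1L)
           else rep(0, epochs)
  gap <- pmin(left, right, 1)
  gap[planted_epoch + 1L] <- peak
  gap
}

#' Configure a synthetic epoch trajectory
#'
#' Parameterises a seeded generator of epoch-indexed embedding snapshots
#' that stands in for the outputs of a fine-tuned sequence feature
#' extractor. At epoch e, negatives are drawn from N(0, sigma_neg^2 I_d)
#' and positives from N(mu_e, sigma_pos_e^2 I_d) with
#' `sigma_pos_e = sigma_neg * exp(gap_profile[e] / d)`, so the true
#' class-conditional entropy gap is exactly `gap_profile[e]` nats
#' (Gaussian entropy is (d/2) log(2 pi e sigma^2), hence the gap is
#' d * log(sigma_pos / sigma_neg)). The class-mean distance `|mu_e|` follows
#' `mean_separation_profile`, coupling classifier quality to the entropy
#' gap.
#'
#' Defaults mirror the benchmark setting the package targets: d = 16 for
#' speed, 400 positives vs 972 negatives (the 1:2.43 imbalance), 11
#' snapshots (epoch 0 = not fine-tuned through epoch 10) with the gap
#' peaking at 4 nats at epoch 6 over shoulders of at most 1 nat, and a mean
#' separation of 0.75 x the gap profile.
#'
#' @param d embedding dimension.
#' @param n_pos,n_neg per-class sample counts.
#' @param epochs number of snapshots including epoch 0.
#' @param sigma_neg negative-class scale (the fixed reference cloud).
#' @param gap_profile non-negative vector of target entropy gaps in nats,
#'   length `epochs`, with a unique maximum at `planted_epoch`.
#' @param planted_epoch 0-based epoch at which the gap peaks.
#' @param mean_separation_profile class-mean distances per epoch, length
#'   `epochs`; defaults to `0.75 * gap_profile`.
#' @param seed integer seed.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(d = 16L, n_pos = 400L, n_neg = 972L,
                              epochs = 11L, sigma_neg = 1,
                              gap_profile = NULL, planted_epoch = 6L,
                              mean_separation_profile = NULL, seed = 1L) {
  epochs <- as.integer(epochs)
  planted_epoch <- as.integer(planted_epoch)
  if (epochs < 1L) stop_emb("config", "need at least one epoch")
  if (planted_epoch < 0L || planted_epoch >= epochs)
    stop_emb("config", "planted_epoch must lie in 0..epochs-1")
  if (is.null(gap_profile))
    gap_profile <- default_gap_profile(epochs, planted_epoch)
  if (length(gap_profile) != epochs)
    stop_emb("config", sprintf("gap_profile must have length %d", epochs))
  if (any(gap_profile < 0))
    stop_emb("config", "gap_profile must be non-negative")
  peak <- which(gap_profile == max(gap_profile))
  if (length(peak) != 1L || peak != planted_epoch + 1L)
    stop_emb("config", "planted_epoch must be the unique argmax of gap_profile")
  if (is.null(mean_separation_profile))
    mean_separation_profile <- 0.75 * gap_profile
  if (length(mean_separation_profile) != epochs)
    stop_emb("config", sprintf("mean_separation_profile must have length %d",
                               epochs))
  structure(list(d = as.integer(d), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), epochs = epochs,
                 sigma_neg = sigma_neg, gap_profile = gap_profile,
                 planted_epoch = planted_epoch,
                 mean_separation_profile = mean_separation_profile,
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

#' Simulate an epoch trajectory of embedding snapshots
#'
#' Draws one [embedding_set()] per epoch under a [trajectory_config()].
#' Sample IDs are stable across epochs — the same virtual sequence receives
#' a new representation at each epoch, as snapshots of a fine-tuned
#' extractor would. Deterministic given `config$seed`.
#'
#' @param config a [trajectory_config()].
#' @return List of `embedding_set`s, epochs `0 .. epochs - 1`.
#' @examples
#' sets <- simulate_trajectory(trajectory_config(n_pos = 50, n_neg = 120,
#'                                               seed = 7))
#' select_optimal_epoch(entropy_trajectory(sets))$optimal_epoch
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  ids <- c(sprintf("pos_%05d", seq_len(config$n_pos)),
           sprintf("neg_%05d", seq_len(config$n_neg)))
  labels <- rep(c(1L, 0L), c(config$n_pos, config$n_neg))
  with_seed(config$seed, {
    lapply(seq_len(config$epochs), function(i) {
      gap <- config$gap_profile[i]
      sep <- config$mean_separation_profile[i]
      sigma_pos <- config$sigma_neg * exp(gap / config$d)
      pos <- matrix(rnorm(config$n_pos * config$d, sd = sigma_pos),
                    config$n_pos, config$d)
      pos[, 1L] <- pos[, 1L] + sep
      neg <- matrix(rnorm(config$n_neg * config$d, sd = config$sigma_neg),
                    config$n_neg, config$d)
      embedding_set(rbind(pos, neg), labels, ids, epoch = i - 1L)
    })
  })
}

#' Simulate a single two-Gaussian classification set
#'
#' Two spherical unit-variance Gaussian classes separated by `mean_gap`
#' along the first axis. The raw first coordinate then has a known
#' theoretical auROC of `pnorm(mean_gap / sqrt(2))`, making the set a
#' calibrated fixture for classifier-evaluation code.
#'
#' @param d dimension.
#' @param n_pos,n_neg per-class counts (>= 1).
#' @param mean_gap class-mean distance in units of the common scale.
#' @param seed integer seed.
#' @return An [embedding_set()] at epoch 0.
#' @export
simulate_classification_set <- function(d, n_pos, n_neg, mean_gap, seed = 1L) {
  d <- as.integer(d)
  if (d < 1L) stop_emb("config", "d must be >= 1")
  if (n_pos < 1L || n_neg < 1L)
    stop_emb("config", "n_pos and n_neg must be >= 1")
  with_seed(seed, {
    pos <- matrix(rnorm(n_pos * d), n_pos, d)
    pos[, 1L] <- pos[, 1L] + mean_gap
    neg <- matrix(rnorm(n_neg * d), n_neg, d)
    embedding_set(rbind(pos, neg), rep(c(1L, 0L), c(n_pos, n_neg)),
                  c(sprintf("pos_%05d", seq_len(n_pos)),
                    sprintf("neg_%05d", seq_len(n_neg))),
                  epoch = 0L)
  })
}

#' Write a simulated trajectory to a directory
#'
#' One `epoch<k>.tsv` snapshot per epoch in the package's delimited format,
#' plus `truth.json` recording the planted profiles and seed.
#'
#' @param config a [trajectory_config()].
#' @param dir output directory (created if needed).
#' @return Character vector of snapshot paths, invisibly.
#' @export
write_trajectory <- function(config, dir) {
  sets <- simulate_trajectory(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sets, function(s) {
    p <- file.path(dir, sprintf("epoch%d.tsv", s$epoch))
    write_embedding_table(s, p)
    p
  }, character(1))
  jsonlite::write_json(
    list(d = config$d, n_pos = config$n_pos, n_neg = config$n_neg,
         epochs = config$epochs, sigma_neg = config$sigma_neg,
         gap_profile = config$gap_profile,
         planted_epoch = config$planted_epoch,
         mean_separation_profile = config$mean_separation_profile,
         seed = config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
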