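#' Construct an embedding set
#'
#' An `embedding_set` bundles one epoch snapshot of per-sample feature
#' vectors with binary labels: the unit of data every other function in the
#' package consumes. Epoch 0 denotes the un-fine-tuned baseline extractor.
#'
#' @param features numeric matrix, one row per sample, `d >= 1` columns; all
#'   entries must be finite.
#' @param labels binary vector (`1` = enhancer/positive, `0` =
#'   non-enhancer/negative), one per row of `features`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `s1..sN`.
#' @param epoch non-negative integer epoch index of the snapshot.
#' @param group_keys optional character vector (e.g. chromosome) used for
#'   grouped stratification in [stratified_split()].
#' @return An object of class `embedding_set` with fields `features`,
#'   `labels`, `sample_ids`, `epoch`, `group_keys`.
#' @examples
#' es <- embedding_set(matrix(rnorm(20), 10, 2), labels = rep(c(0, 1), 5))
#' dim(es$features)
#' @export
embedding_set <- function(features, labels, sample_ids = NULL, epoch = 0L,
                          group_keys = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  if (d < 1L || n < 1L)
    stop_emb("format", "features must be a non-empty matrix with d >= 1 columns")
  if (!all(is.finite(features)))
    stop_emb("format", "features contain non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop_emb("format", sprintf("length(labels) == %d but features have %d rows",
                               length(labels), n))
  if (!all(labels %in% c(0L, 1L)))
    stop_emb("label", "labels must contain only 0 and 1")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop_emb("format", "sample_ids length does not match number of samples")
  if (anyDuplicated(sample_ids))
    stop_emb("format", "duplicate sample IDs")
  if (!is.null(group_keys)) {
    group_keys <- as.character(group_keys)
    if (length(group_keys) != n)
      stop_emb("format", "group_keys length does not match number of samples")
  }
  epoch <- as.integer(epoch)
  if (length(epoch) != 1L || is.na(epoch) || epoch < 0L)
    stop_emb("format", "epoch must be a single non-negative integer")
  structure(
    list(features = features, labels = labels, sample_ids = sample_ids,
         epoch = epoch, group_keys = group_keys),
    class = "embedding_set"
  )
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("embedding_set: epoch %d, %d samples x %d features (%d pos / %d neg)\n",
              x$epoch, nrow(x$features), ncol(x$features),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.embedding_set <- function(x) dim(x$features)

# row subset preserving all metadata
subset_embedding_set <- function(set, idx) {
  embedding_set(set$features[idx, , drop = FALSE], set$labels[idx],
                set$sample_ids[idx], set$epoch,
                if (is.null(set$group_keys)) NULL else set$group_keys[idx])
}

infer_epoch_from_path <- function(path) {
  m <- regmatches(basename(path), regexpr("epoch([0-9]+)", basename(path)))
  if (length(m) == 1L) as.integer(sub("epoch", "", m)) else NA_integer_
}

#' Read an embedding snapshot from delimited text
#'
#' The on-disk format is delimited text (TSV by default; a comma delimiter is
#' auto-detected from the header line) with mandatory columns `id`, `label`
#' and then the feature columns `f1..fd` in order. The epoch index is taken
#' from the `epoch` argument when given, otherwise inferred from an
#' `epoch<k>` token in the file name (the explicit argument wins).
#'
#' @param path path to the snapshot file.
#' @param epoch optional integer epoch index overriding the file-name
#'   convention.
#' @return A validated [embedding_set()].
#' @seealso [write_embedding_table()]
#' @export
read_embedding_table <- function(path, epoch = NULL) {
  if (!file.exists(path))
    stop_emb("format", sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop_emb("format", sprintf("empty file: %s", path))
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = NA, fill = FALSE),
    error = function(e) stop_emb("format", conditionMessage(e))
  )
  cols <- names(df)
  if (length(cols) < 3L || cols[1L] != "id" || cols[2L] != "label")
    stop_emb("format",
             "expected columns 'id', 'label' and at least one feature column")
  ids <- as.character(df$id)
  if (anyDuplicated(ids))
    stop_emb("format", "duplicate sample IDs in embedding table")
  lab_raw <- df$label
  if (!all(lab_raw %in% c(0, 1)))
    stop_emb("label", "label column must contain only 0 and 1")
  feat <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(feat) || !all(is.finite(feat)))
    stop_emb("format", "feature columns contain non-numeric or non-finite values")
  if (is.null(epoch)) {
    epoch <- infer_epoch_from_path(path)
    if (is.na(epoch)) epoch <- 0L
  }
  embedding_set(feat, as.integer(lab_raw), ids, epoch)
}

#' Write an embedding snapshot to delimited text
#'
#' Writes the format read by [read_embedding_table()] (columns `id`, `label`,
#' `f1..fd`), with features at 17 significant digits so a read/write
#' round-trip preserves them beyond 12 significant digits.
#'
#' @param set an [embedding_set()].
#' @param path output path; contents are tab-separated with a LF terminator.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(set, path) {
  stopifnot(inherits(set, "embedding_set"))
  d <- ncol(set$features)
  header <- paste(c("id", "label", paste0("f", seq_len(d))), collapse = "\t")
  feat_chr <- apply(set$features, 1L,
                    function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  lines <- c(header, paste(set$sample_ids, set$labels, feat_chr, sep = "\t"))
  con <- file(path, open = "wb") # LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read sequence IDs and lengths from a FASTA file
#'
#' Sequence metadata only: embeddings are produced by an external feature
#' extractor, so the package never needs more than the identifier (first
#' whitespace-delimited token of each header) and the sequence length.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `id` (character) and `length` (integer),
#'   one row per record.
#' @export
read_fasta_ids <- function(path) {
  if (!file.exists(path))
    stop_emb("format", sprintf("file not found: %s", path))
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop_emb("format", conditionMessage(e)))
  if (length(seqs) == 0L)
    stop_emb("format", "FASTA file contains no records")
  widths <- Biostrings::width(seqs)
  if (any(widths == 0L))
    stop_emb("format", "FASTA record with empty sequence")
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_emb("format", sprintf("duplicate FASTA ID: %s",
                               ids[duplicated(ids)][1L]))
  data.frame(id = ids, length = as.integer(widths), row.names = NULL)
}

#' Split specification
#'
#' @param test_fraction fraction of each class assigned to the test part
#'   (default 0.3, the 7:3 protocol).
#' @param stratify_by_label keep per-class proportions (default `TRUE`).
#' @param group_key_stratify additionally preserve per-group (e.g. per
#'   chromosome) class proportions, as closely as integer rounding permits.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.3, stratify_by_label = TRUE,
                       group_key_stratify = FALSE, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop_emb("config", "test_fraction must lie in (0, 1)")
  structure(list(test_fraction = test_fraction,
                 stratify_by_label = isTRUE(stratify_by_label),
                 group_key_stratify = isTRUE(group_key_stratify),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Splits an embedding set into training and test parts. With label
#' stratification (the default) the test part receives
#' `round(test_fraction * n_c)` samples of each class `c`, rounding halves
#' up; the remainder stays in training. With `group_key_stratify` the same
#' rule is applied within each (group, label) cell, so per-group class
#' proportions are preserved up to integer rounding.
#'
#' @param set an [embedding_set()] with at least 4 samples and both classes
#'   present.
#' @param spec a [split_spec()].
#' @return A list with elements `train` and `test`, both `embedding_set`s
#'   forming a partition of `set`.
#' @examples
#' es <- simulate_classification_set(d = 2, n_pos = 10, n_neg = 24,
#'                                   mean_gap = 1, seed = 1)
#' parts <- stratified_split(es, split_spec(test_fraction = 0.3, seed = 1))
#' sum(parts$test$labels == 1) # round(0.3 * 10) = 3
#' @export
stratified_split <- function(set, spec = split_spec()) {
  stopifnot(inherits(set, "embedding_set"), inherits(spec, "split_spec"))
  n <- nrow(set$features)
  if (n < 4L)
    stop_emb("stratification", "need at least 4 samples to split")
  if (spec$stratify_by_label && length(unique(set$labels)) < 2L)
    stop_emb("stratification", "both classes must be present for a stratified split")

  strata <- if (!spec$stratify_by_label) {
    rep("all", n)
  } else if (spec$group_key_stratify && !is.null(set$group_keys)) {
    paste(set$group_keys, set$labels, sep = "\r")
  } else {
    as.character(set$labels)
  }

  test_idx <- with_seed(spec$seed, {
    unlist(lapply(split(seq_len(n), strata), function(idx) {
      k <- round_half_up(spec$test_fraction * length(idx))
      if (k == 0L) integer(0) else sample(idx, k)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (spec$stratify_by_label) {
    for (part in list(train_idx, test_idx))
      if (length(unique(set$labels[part])) < 2L)
        stop_emb("stratification",
                 "split leaves a part without one of the classes; adjust test_fraction")
  }
  list(train = subset_embedding_set(set, train_idx),
       test = subset_embedding_set(set, test_idx))
}

#' Summarize class balance of a dataset
#'
#' @param set an [embedding_set()].
#' @return An object of class `dataset_summary` with fields `n_pos`, `n_neg`
#'   and `ratio_neg_to_pos` (negative-to-positive ratio; `NA` when there are
#'   no positives). The printed ratio is rounded to 2 decimals.
#' @examples
#' es <- embedding_set(matrix(0:13, ncol = 1), labels = rep(c(1, 0), c(4, 10)))
#' summarize_dataset(es) # ratio 2.5
#' @export
summarize_dataset <- function(set) {
  stopifnot(inherits(set, "embedding_set"))
  n_pos <- sum(set$labels == 1L)
  n_neg <- sum(set$labels == 0L)
  ratio <- if (n_pos == 0L) NA_real_ else n_neg / n_pos
  structure(list(n_pos = n_pos, n_neg = n_neg, ratio_neg_to_pos = ratio),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  ratio <- if (is.na(x$ratio_neg_to_pos)) "undefined"
           else sprintf("1:%.2f", x$ratio_neg_to_pos)
  cat(sprintf("%d positives, %d negatives (pos:neg ratio %s)\n",
              x$n_pos, x$n_neg, ratio))
  invisible(x)
}
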