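#' Time-delta features
#'
#' Per-sample change of each feature relative to its day-0 baseline,
#' \eqn{\Delta X_t = X_t - X_0}. Differencing against the fruit's own
#' baseline cancels between-sample variation in the initial state, which is
#' the point of the delta datasets.
#'
#' @param x_t feature vector (or matrix) at storage time t.
#' @param x_0 baseline feature vector (or matrix), same names/shape.
#' @return elementwise difference with the layout of `x_t`.
#' @export
delta_features <- function(x_t, x_0) {
  if (!identical(dim(x_t), dim(x_0)) || length(x_t) != length(x_0)) {
    stop_bisfruit("baseline and time-t features are not aligned",
                  "bisfruit_alignment_error")
  }
  nt <- if (is.matrix(x_t)) colnames(x_t) else names(x_t)
  n0 <- if (is.matrix(x_0)) colnames(x_0) else names(x_0)
  if (!is.null(nt) && !is.null(n0) && !identical(nt, n0)) {
    stop_bisfruit("feature names differ between time t and baseline",
                  "bisfruit_alignment_error")
  }
  x_t - x_0
}

#' z-score normalisation with reusable statistics
#'
#' Centres and scales each feature (column) using reference statistics: the
#' mean and the population standard deviation (divide by n). When `stats` is
#' `NULL` the statistics are fitted from `x` itself (the training set) and
#' returned for reuse on held-out data, so test rows are transformed with
#' training statistics only. Zero-variance features are flagged, warned
#' about, and passed through centred only.
#'
#' @param x numeric matrix, instances x features.
#' @param stats optional statistics from a previous call.
#' @return list with `x` (normalised matrix) and `stats`
#'   (`mean`, `sd`, `zero_var`).
#' @export
zscore_normalize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    m <- colMeans(x)
    n <- nrow(x)
    sd_pop <- sqrt(colMeans(sweep(x, 2, m)^2))
    zero <- sd_pop == 0
    if (any(zero)) {
      warning(sprintf("zero-variance feature(s) passed through centred only: %s",
                      paste(colnames(x)[zero], collapse = ", ")))
    }
    stats <- list(mean = m, sd = sd_pop, zero_var = zero)
  }
  scale_by <- ifelse(stats$zero_var, 1, stats$sd)
  xn <- sweep(sweep(x, 2, stats$mean), 2, scale_by, "/")
  list(x = xn, stats = stats)
}

#' Feature table
#'
#' Container for one assembled dataset: numeric matrix `x` (instances x
#' features, row names are `sample_id` x day instance ids), label factor `y`
#' (storage, levels room/cold), instance metadata, and the dataset kind.
#'
#' @param x numeric matrix.
#' @param y factor of storage labels, aligned with rows of `x`.
#' @param instance data frame with `sample_id` and `day` per row.
#' @param kind dataset kind string.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(x, y, instance, kind) {
  stopifnot(nrow(x) == length(y), nrow(x) == nrow(instance))
  if (any(!is.finite(x))) {
    stop_bisfruit("feature table contains missing values",
                  "bisfruit_assembly_error")
  }
  structure(list(x = x, y = y, instance = instance, kind = kind),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table '%s': %d instances x %d features\n",
              x$kind, nrow(x$x), ncol(x$x)))
  print(table(storage = x$y))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

dataset_kinds <- c("bio-raw", "bio-delta", "bio-delta-diam",
                   "ec-raw", "ec-delta", "ec-delta-diam")

#' Assemble one of the six benchmark datasets
#'
#' Builds a [feature_table] from a measured cohort (and, for the circuit
#' kinds, a table of fitted circuit parameters). The six kinds pair two
#' feature families (bioimpedance: 30 magnitudes then 30 phases, in
#' ascending frequency; circuit: the seven parameters in the order
#' `r_e, q_e, alpha_e, r_ex, r_i, q_m, alpha_m`) with three variants (raw
#' day-1/2 values; per-fruit deltas against day 0; deltas plus the day-0
#' diameter appended as the last feature). Day-0 rows are consumed as
#' baselines and never emitted as instances, so the default design gives
#' 368 instances with 60/60/61 or 7/7/8 features.
#'
#' @param measurements a `bis_measurements` table (or a `bis_cohort`).
#' @param kind one of `"bio-raw"`, `"bio-delta"`, `"bio-delta-diam"`,
#'   `"ec-raw"`, `"ec-delta"`, `"ec-delta-diam"`.
#' @param ec_table for circuit kinds: data frame with `sample_id`, `day` and
#'   the seven parameter columns (e.g. `as.data.frame()` of an
#'   [fit_ec_batch()] result).
#' @return a [feature_table].
#' @export
assemble_dataset <- function(measurements, kind = dataset_kinds,
                             ec_table = NULL) {
  kind <- match.arg(kind)
  if (inherits(measurements, "bis_cohort")) {
    measurements <- measurements$measurements
  }
  stopifnot(inherits(measurements, "bis_measurements"))
  meas <- measurements
  days_t <- sort(setdiff(unique(meas$day), 0L))

  if (startsWith(kind, "bio")) {
    nf <- length(attr(meas, "freq"))
    fcols <- c(sprintf("zmod_%03d", seq_len(nf)), sprintf("phase_%03d", seq_len(nf)))
    feat <- as.matrix(meas[, fcols])
    key <- meas[, c("sample_id", "day", "storage", "diameter_mm")]
  } else {
    if (is.null(ec_table)) {
      stop_bisfruit("circuit-parameter kinds need `ec_table`",
                    "bisfruit_assembly_error")
    }
    feat <- as.matrix(ec_table[, ec_param_names])
    idx <- match(ec_table$sample_id, meas$sample_id)
    key <- data.frame(sample_id = ec_table$sample_id, day = ec_table$day,
                      storage = meas$storage[idx],
                      diameter_mm = meas$diameter_mm[idx])
  }
  rows_t <- which(key$day %in% days_t)
  rows_t <- rows_t[order(key$day[rows_t], key$sample_id[rows_t])]

  if (grepl("delta", kind)) {
    rows_0 <- which(key$day == 0L)
    base_idx <- match(key$sample_id[rows_t], key$sample_id[rows_0])
    if (any(is.na(base_idx))) {
      stop_bisfruit("missing day-0 baseline for a delta dataset",
                    "bisfruit_assembly_error")
    }
    x <- delta_features(feat[rows_t, , drop = FALSE],
                        feat[rows_0[base_idx], , drop = FALSE])
  } else {
    x <- feat[rows_t, , drop = FALSE]
  }
  if (endsWith(kind, "diam")) {
    x <- cbind(x, diameter_mm = key$diameter_mm[rows_t])
  }
  rownames(x) <- sprintf("%s_d%d", key$sample_id[rows_t], key$day[rows_t])
  feature_table(
    x = x,
    y = factor(key$storage[rows_t], levels = c("room", "cold")),
    instance = data.frame(sample_id = key$sample_id[rows_t],
                          day = key$day[rows_t], stringsAsFactors = FALSE),
    kind = kind)
}

#' Stratified train/test split
#'
#' Splits a [feature_table] into train and test sets, stratified by the
#' storage label. Within each stratum the train size is
#' `round(train_frac * n)` with halves rounded up, so the default design
#' (368 instances, 0.8) gives 294 train and 74 test rows.
#'
#' @param table a [feature_table].
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list with `train` and `test` feature tables and the row indices
#'   `train_idx`, `test_idx` (relative to `table`).
#' @export
split_table <- function(table, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), train_frac > 0, train_frac < 1)
  idx_by_class <- split(seq_along(table$y), table$y)
  train_idx <- integer(0)
  with_seed(derive_seed(seed, "split_table"), {
    for (cls in names(idx_by_class)) {
      ids <- idx_by_class[[cls]]
      n_tr <- round_half_up(train_frac * length(ids))
      if (n_tr < 1 || n_tr >= length(ids)) {
        stop_bisfruit("group too small to stratify the split",
                      "bisfruit_split_error")
      }
      train_idx <- c(train_idx, sample(ids, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(table$y), train_idx)
  subset_ft <- function(i) {
    feature_table(table$x[i, , drop = FALSE], table$y[i],
                  table$instance[i, , drop = FALSE], table$kind)
  }
  list(train = subset_ft(train_idx), test = subset_ft(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
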