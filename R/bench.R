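#' Classifier families of the benchmark
#'
#' The eight model families compared by the benchmark: support vector
#' machine, logistic regression, multi-layer perceptron, k-nearest
#' neighbours, random forest, linear discriminant analysis, Gaussian naive
#' Bayes and decision tree.
#'
#' @return character vector of family codes.
#' @export
bis_model_families <- function() {
  c("svm", "lr", "mlp", "knn", "rf", "lda", "nb", "dt")
}

#' Default hyperparameter grids
#'
#' Small conventional grids per family, used by [grid_search_cv()] when no
#' grid is supplied. `gamma = "scale"` for the SVM RBF kernel means
#' `1 / (n_features * var(x))` computed on the training rows.
#'
#' @return named list of data frames, one grid row per candidate.
#' @export
default_grids <- function() {
  list(
    svm = rbind(
      expand.grid(cost = c(0.1, 1, 10, 100), kernel = "linear",
                  gamma = "scale", stringsAsFactors = FALSE),
      expand.grid(cost = c(0.1, 1, 10, 100), kernel = "radial",
                  gamma = c("scale", "0.01", "0.001"), stringsAsFactors = FALSE)),
    lr = data.frame(C = c(0.01, 0.1, 1, 10)),
    mlp = expand.grid(size = c(4L, 8L, 16L), decay = c(1e-4, 1e-3)),
    knn = data.frame(k = c(3L, 5L, 7L, 9L, 11L)),
    rf = expand.grid(num_trees = c(100L, 300L), max_depth = c(0L, 5L, 10L)),
    lda = data.frame(dummy = 1),
    nb = data.frame(dummy = 1),
    dt = data.frame(max_depth = c(30L, 3L, 5L, 10L))
  )
}

# fit on (x_tr, y_tr), predict classes for x_va; deterministic given seed
fit_predict <- function(family, hyper, x_tr, y_tr, x_va, seed = 1L) {
  lev <- levels(y_tr)
  with_seed(seed, {
    pred <- switch(family,
      svm = {
        g <- hyper$gamma %||% "scale"
        gamma <- if (identical(g, "scale")) {
          1 / (ncol(x_tr) * max(stats::var(as.vector(x_tr)), 1e-12))
        } else as.numeric(g)
        m <- e1071::svm(x_tr, y_tr, cost = hyper$cost, kernel = hyper$kernel,
                        gamma = gamma, scale = FALSE)
        stats::predict(m, x_va)
      },
      lr = {
        lam <- 1 / (nrow(x_tr) * hyper$C)
        m <- glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 0,
                            lambda = lam, standardize = FALSE)
        p <- stats::predict(m, x_va, type = "class")
        factor(as.vector(p), levels = lev)
      },
      mlp = {
        y01 <- as.numeric(y_tr == lev[2])
        m <- nnet::nnet(x_tr, y01, size = hyper$size, decay = hyper$decay,
                        maxit = 150, entropy = TRUE, trace = FALSE,
                        MaxNWts = 10000)
        p <- as.vector(stats::predict(m, x_va))
        factor(lev[(p > 0.5) + 1], levels = lev)
      },
      knn = class::knn(x_tr, x_va, y_tr, k = hyper$k),
      rf = {
        m <- ranger::ranger(x = as.data.frame(x_tr), y = y_tr,
                            num.trees = hyper$num_trees,
                            max.depth = hyper$max_depth,
                            seed = seed, num.threads = 1)
        stats::predict(m, data = as.data.frame(x_va),
                       num.threads = 1)$predictions
      },
      lda = {
        m <- suppressWarnings(MASS::lda(x_tr, grouping = y_tr))
        stats::predict(m, x_va)$class
      },
      nb = {
        m <- e1071::naiveBayes(x_tr, y_tr)
        stats::predict(m, x_va)
      },
      dt = {
        df_tr <- data.frame(.y = y_tr, x_tr, check.names = TRUE)
        df_va <- data.frame(x_va, check.names = TRUE)
        m <- rpart::rpart(.y ~ ., data = df_tr, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = hyper$max_depth, cp = 0.005,
                            xval = 0))
        stats::predict(m, df_va, type = "class")
      },
      stop_bisfruit(paste("unknown model family:", family),
                    "bisfruit_config_error"))
    factor(as.character(pred), levels = lev)
  })
}

#' Stratified repeated cross-validation folds
#'
#' One fold-assignment matrix shared by every model and dataset in a run:
#' this identical pairing is what makes the per-fold accuracies comparable
#' with a paired signed-rank test. Each repeat uses a seed derived from the
#' master seed; folds are stratified by class.
#'
#' @param y label factor of the training instances.
#' @param repeats,folds repetition and fold counts (default 5 x 10).
#' @param seed integer master seed.
#' @return integer matrix `length(y)` x `repeats` of fold ids, class
#'   `cv_folds`.
#' @export
make_folds <- function(y, repeats = 5L, folds = 10L, seed = 1L) {
  n <- length(y)
  out <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    with_seed(derive_seed(seed, paste0("folds_rep", r)), {
      for (cls in levels(y)) {
        ids <- which(y == cls)
        out[sample(ids), r] <- rep_len(seq_len(folds), length(ids))
      }
    })
    for (f in seq_len(folds)) {
      tr <- y[out[, r] != f]
      if (length(unique(tr)) < 2 || length(unique(y[out[, r] == f])) < 1) {
        stop_bisfruit("a fold lost a class: too few instances to stratify",
                      "bisfruit_stratification_error")
      }
    }
  }
  structure(out, class = c("cv_folds", "matrix"),
            repeats = repeats, folds = folds, seed = seed)
}

#' Signature of a fold assignment
#'
#' Compact deterministic fingerprint used to assert that two benchmark runs
#' (or two datasets within one run) share the identical fold pairing.
#'
#' @param folds a [make_folds()] matrix.
#' @return character scalar.
#' @export
fold_signature <- function(folds) {
  v <- as.numeric(as.vector(folds))
  i <- seq_along(v)
  sprintf("%d:%d:%.0f:%.0f", nrow(folds), ncol(folds),
          sum(v * i), sum(v * v * i))
}

# accuracy over every repeat x fold; normalisation statistics are fitted on
# the fold's training rows only (unless the caller pre-normalised globally)
cv_accuracy <- function(x, y, folds, family, hyper,
                        normalize = c("fold", "none"), seed = 1L) {
  normalize <- match.arg(normalize)
  repeats <- attr(folds, "repeats")
  nfold <- attr(folds, "folds")
  acc <- numeric(repeats * nfold)
  k <- 0L
  for (r in seq_len(repeats)) {
    for (f in seq_len(nfold)) {
      va <- which(folds[, r] == f)
      tr <- which(folds[, r] != f)
      x_tr <- x[tr, , drop = FALSE]
      x_va <- x[va, , drop = FALSE]
      if (normalize == "fold") {
        z <- suppressWarnings(zscore_normalize(x_tr))
        x_tr <- z$x
        x_va <- zscore_normalize(x_va, z$stats)$x
      }
      pred <- fit_predict(family, hyper, x_tr, y[tr], x_va,
                          seed = derive_seed(seed, sprintf("%s_r%df%d",
                                                           family, r, f)))
      k <- k + 1L
      acc[k] <- mean(pred == y[va])
    }
  }
  acc
}

#' Grid search by repeated cross-validation
#'
#' Evaluates every grid candidate with the shared repeated-CV folds and
#' returns the candidate with the highest mean accuracy (first row on
#' ties). Only the training table is ever seen; held-out rows cannot reach
#' model selection through this interface.
#'
#' @param train a [feature_table] of training instances.
#' @param family one of [bis_model_families()].
#' @param folds a [make_folds()] matrix for `train$y`.
#' @param grid optional data frame of candidates (default
#'   `default_grids()[[family]]`).
#' @param normalize `"fold"` (statistics fitted per training fold;
#'   leak-free default) or `"none"` (input already normalised).
#' @param seed integer seed for the stochastic learners.
#' @return a `cv_result`: `family`, `best_hyper`, `accuracies` (one per
#'   repeat x fold), `mean`, `sd`, `grid_means`.
#' @export
grid_search_cv <- function(train, family, folds, grid = NULL,
                           normalize = c("fold", "none"), seed = 1L) {
  stopifnot(inherits(train, "feature_table"))
  normalize <- match.arg(normalize)
  grid <- grid %||% default_grids()[[family]]
  if (is.null(grid) || nrow(grid) == 0) {
    stop_bisfruit("empty hyperparameter grid", "bisfruit_config_error")
  }
  best <- NULL
  grid_means <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hyper <- as.list(grid[i, , drop = FALSE])
    acc <- cv_accuracy(train$x, train$y, folds, family, hyper,
                       normalize = normalize, seed = seed)
    grid_means[i] <- mean(acc)
    if (is.null(best) || grid_means[i] > best$mean + 1e-12) {
      best <- list(hyper = hyper, acc = acc, mean = mean(acc), index = i)
    }
  }
  structure(list(family = family, best_hyper = best$hyper,
                 best_index = best$index,
                 accuracies = best$acc, mean = mean(best$acc),
                 sd = stats::sd(best$acc),
                 grid = grid, grid_means = grid_means),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: CV accuracy %.3f (sd %.3f) over %d folds\n",
              toupper(x$family), x$mean, x$sd, length(x$accuracies)))
  h <- x$best_hyper[setdiff(names(x$best_hyper), "dummy")]
  if (length(h)) {
    cat("  best:", paste(names(h), unlist(h), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of two CV results
#'
#' Two-sided signed-rank test on the paired per-fold accuracy differences.
#' Requires both vectors to come from the identical fold assignment.
#' Zero differences are discarded first; with no remaining differences the
#' p-value is 1 by convention. The exact null distribution is used when at
#' most 25 nonzero differences remain and their magnitudes are untied,
#' otherwise the normal approximation with continuity correction.
#'
#' @param a,b `cv_result` objects or plain accuracy vectors of equal length.
#' @return list with `p_value`, `direction` (sign of the mean difference),
#'   `n_nonzero`, `statistic` (V, the positive-rank sum), `mean_diff`.
#' @export
wilcoxon_compare <- function(a, b) {
  va <- if (inherits(a, "cv_result")) a$accuracies else as.numeric(a)
  vb <- if (inherits(b, "cv_result")) b$accuracies else as.numeric(b)
  if (length(va) != length(vb)) {
    stop_bisfruit("accuracy vectors are not paired (unequal length)",
                  "bisfruit_pairing_error")
  }
  d <- va - vb
  dn <- d[d != 0]
  if (length(dn) == 0) {
    return(list(p_value = 1, direction = 0, n_nonzero = 0L,
                statistic = NA_real_, mean_diff = 0))
  }
  exact <- length(dn) <= 25 && !any(duplicated(abs(dn)))
  wt <- suppressWarnings(
    stats::wilcox.test(dn, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(p_value = min(unname(wt$p.value), 1),
       direction = sign(mean(d)),
       n_nonzero = length(dn),
       statistic = unname(wt$statistic),
       mean_diff = mean(d))
}

#' Compact significance letters
#'
#' Compact letter display over a set of conditions compared pairwise:
#' conditions that share a letter are not significantly different. Letters
#' are assigned from the maximal cliques of the "not significantly
#' different" graph, lettered `a, b, c, ...` in row order; an intransitive
#' significance pattern yields overlapping letters (e.g. `"ab"`) and a
#' warning.
#'
#' @param p_matrix symmetric matrix of pairwise p-values (diagonal ignored).
#' @param alpha significance level.
#' @return character vector of letters, one per row of `p_matrix`.
#' @export
assign_letters <- function(p_matrix, alpha = 0.05) {
  n <- nrow(p_matrix)
  stopifnot(ncol(p_matrix) == n)
  ns <- matrix(TRUE, n, n)  # not-significantly-different graph
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ns[i, j] <- p_matrix[i, j] >= alpha
  }
  # maximal cliques by brute force (n is small: 3 datasets)
  subsets <- lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    all(ns[s, s]) }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(cliques, function(s) {
    !any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, logical(1))]
  ord <- order(vapply(maximal, min, numeric(1)), -lengths(maximal))
  maximal <- maximal[ord]
  labels <- rep("", n)
  for (k in seq_along(maximal)) {
    for (i in maximal[[k]]) labels[i] <- paste0(labels[i], letters[k])
  }
  if (any(nchar(labels) > 1)) {
    warning("intransitive significance pattern: overlapping letters assigned")
  }
  labels
}

#' Confusion matrix for a binary storage classification
#'
#' @param truth,pred factors with the same levels; `positive` names the
#'   positive class (default `"room"`).
#' @param positive positive-class label.
#' @return object of class `confusion_matrix`: named counts
#'   `tp, fp, fn, tn`.
#' @export
confusion_matrix <- function(truth, pred, positive = "room") {
  stopifnot(length(truth) == length(pred))
  t_pos <- truth == positive
  p_pos <- pred == positive
  structure(c(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
              fn = sum(t_pos & !p_pos), tn = sum(!t_pos & !p_pos)),
            class = "confusion_matrix", positive = positive)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP); recall =
#' TP/(TP+FN); F1 = harmonic mean of precision and recall. An undefined
#' precision (no positive predictions) is returned as `NA`.
#'
#' @param cm a [confusion_matrix()] (or named vector with `tp,fp,fn,tn`).
#' @return named numeric vector `accuracy, precision, recall, f1`.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  if (tp + fp + fn + tn == 0) {
    stop_bisfruit("empty confusion matrix", "bisfruit_domain_error")
  }
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1)
}

# swap positive class of a confusion matrix
swap_confusion <- function(cm) {
  structure(c(tp = cm[["tn"]], fp = cm[["fn"]], fn = cm[["fp"]],
              tn = cm[["tp"]]),
            class = "confusion_matrix",
            positive = setdiff(c("room", "cold"), attr(cm, "positive"))[1])
}

#' Refit the selected model and evaluate on held-out data
#'
#' Refits the winning hyperparameters on the whole training table
#' (normalisation statistics from the training rows, unless `normalize =
#' "none"` because the caller normalised globally) and predicts the test
#' table once. Reports confusion matrices and metrics for both the training
#' and the test set, with per-class precision/recall/F1.
#'
#' @param train,test [feature_table]s with identical feature names.
#' @param family model family.
#' @param hyper list of winning hyperparameters.
#' @param normalize `"fold"`-style training statistics (default) or
#'   `"none"`.
#' @param seed integer seed.
#' @param positive positive class.
#' @return list with elements `train` and `test`, each holding `cm`,
#'   `metrics` (positive class) and `metrics_by_class`.
#' @export
evaluate_holdout <- function(train, test, family, hyper,
                             normalize = c("fold", "none"), seed = 1L,
                             positive = "room") {
  normalize <- match.arg(normalize)
  if (!identical(colnames(train$x), colnames(test$x))) {
    stop_bisfruit("train and test feature names differ",
                  "bisfruit_schema_error")
  }
  x_tr <- train$x
  x_te <- test$x
  if (normalize == "fold") {
    z <- suppressWarnings(zscore_normalize(x_tr))
    x_tr <- z$x
    x_te <- zscore_normalize(x_te, z$stats)$x
  }
  eval_one <- function(x, y, pred) {
    cm <- confusion_matrix(y, pred, positive = positive)
    list(cm = cm, metrics = confusion_metrics(cm),
         metrics_by_class = rbind(
           positive = confusion_metrics(cm),
           negative = confusion_metrics(swap_confusion(cm))))
  }
  pred_te <- fit_predict(family, hyper, x_tr, train$y, x_te,
                         seed = derive_seed(seed, paste0(family, "_holdout")))
  pred_tr <- fit_predict(family, hyper, x_tr, train$y, x_tr,
                         seed = derive_seed(seed, paste0(family, "_holdout")))
  list(train = eval_one(x_tr, train$y, pred_tr),
       test = eval_one(x_te, test$y, pred_te),
       family = family, hyper = hyper)
}

#' Principal-component embedding
#'
#' Standard PCA projection of a (normalised) feature matrix for
#' visualisation, with explained-variance fractions.
#'
#' @param x numeric matrix or [feature_table].
#' @param n_components number of components to keep.
#' @return list with `scores` (instances x components), `explained`
#'   (variance fractions, non-increasing), `rotation`, `center`.
#' @export
pca_embed <- function(x, n_components = 3L) {
  if (inherits(x, "feature_table")) x <- x$x
  if (n_components > ncol(x)) {
    stop_bisfruit("more components requested than features",
                  "bisfruit_dimension_error")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = (ev / sum(ev))[seq_len(n_components)],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center)
}

#' Run the full classifier benchmark
#'
#' For a named list of datasets (feature tables sharing the same instances)
#' runs grid-searched repeated CV for every model family, compares the
#' datasets per family with paired signed-rank tests inside each feature
#' group (bioimpedance kinds, circuit kinds), assigns compact letters, and
#' evaluates each winning model on the held-out split.
#'
#' @param datasets named list of [feature_table]s (same instances and
#'   order; names are dataset kinds).
#' @param families model families to run (default all eight).
#' @param seed master seed (split, folds, learners).
#' @param repeats,folds CV structure (default 5 x 10).
#' @param train_frac held-out split fraction.
#' @param paper_mode if `TRUE`, z-score the full table globally before
#'   splitting (replicates the common normalise-then-split practice); the
#'   default fits statistics on training folds only.
#' @param grids optional named list of hyperparameter grids.
#' @param alpha significance level for the letters.
#' @return a `bis_benchmark`: `results` (dataset x family means, sds,
#'   letters), `cv` (nested `cv_result`s), `p_values`, `holdout`,
#'   `fold_signature`, `settings`.
#' @export
run_benchmark <- function(datasets, families = bis_model_families(),
                          seed = 1L, repeats = 5L, folds = 10L,
                          train_frac = 0.8, paper_mode = FALSE,
                          grids = NULL, alpha = 0.05) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  inst <- datasets[[1]]$instance
  for (d in datasets) {
    if (!identical(d$instance, inst)) {
      stop_bisfruit("datasets do not share the same instances",
                    "bisfruit_pairing_error")
    }
  }
  norm_mode <- if (paper_mode) "none" else "fold"
  if (paper_mode) {
    datasets <- lapply(datasets, function(d) {
      d$x <- suppressWarnings(zscore_normalize(d$x))$x
      d
    })
  }
  sp0 <- split_table(datasets[[1]], train_frac = train_frac, seed = seed)
  splits <- lapply(datasets, function(d) {
    list(train = feature_table(d$x[sp0$train_idx, , drop = FALSE],
                               d$y[sp0$train_idx],
                               d$instance[sp0$train_idx, , drop = FALSE],
                               d$kind),
         test = feature_table(d$x[sp0$test_idx, , drop = FALSE],
                              d$y[sp0$test_idx],
                              d$instance[sp0$test_idx, , drop = FALSE],
                              d$kind))
  })
  fold_mat <- make_folds(splits[[1]]$train$y, repeats = repeats,
                         folds = folds, seed = seed)
  cv <- list()
  holdout <- list()
  rows <- list()
  for (ds in names(datasets)) {
    cv[[ds]] <- list()
    holdout[[ds]] <- list()
    for (fam in families) {
      res <- grid_search_cv(splits[[ds]]$train, fam, fold_mat,
                            grid = grids[[fam]], normalize = norm_mode,
                            seed = seed)
      cv[[ds]][[fam]] <- res
      holdout[[ds]][[fam]] <- evaluate_holdout(
        splits[[ds]]$train, splits[[ds]]$test, fam, res$best_hyper,
        normalize = norm_mode, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, family = fam, mean = res$mean, sd = res$sd,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  # letters: per family, across the datasets of each feature group
  results$letter <- NA_character_
  p_values <- list()
  for (grp in c("bio", "ec")) {
    ds_grp <- names(datasets)[startsWith(names(datasets), grp)]
    if (length(ds_grp) < 2) next
    for (fam in families) {
      k <- length(ds_grp)
      pm <- matrix(NA_real_, k, k, dimnames = list(ds_grp, ds_grp))
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i < j) {
          p <- wilcoxon_compare(cv[[ds_grp[i]]][[fam]],
                                cv[[ds_grp[j]]][[fam]])$p_value
          pm[i, j] <- pm[j, i] <- p
        }
      }
      p_values[[paste(grp, fam, sep = ".")]] <- pm
      lets <- withCallingHandlers(assign_letters(pm, alpha = alpha),
                                  warning = function(w) invokeRestart("muffleWarning"))
      for (i in seq_len(k)) {
        results$letter[results$dataset == ds_grp[i] &
                         results$family == fam] <- lets[i]
      }
    }
  }
  structure(list(results = results, cv = cv, p_values = p_values,
                 holdout = holdout, fold_signature = fold_signature(fold_mat),
                 folds = fold_mat,
                 split = list(train_idx = sp0$train_idx,
                              test_idx = sp0$test_idx),
                 settings = list(seed = seed, repeats = repeats,
                                 folds = folds, train_frac = train_frac,
                                 paper_mode = paper_mode, alpha = alpha)),
            class = "bis_benchmark")
}

#' @export
print.bis_benchmark <- function(x, digits = 2, ...) {
  cat(sprintf("BIS classifier benchmark: %d datasets x %d families, %dx%d-fold CV\n",
              length(unique(x$results$dataset)),
              length(unique(x$results$family)),
              x$settings$repeats, x$settings$folds))
  fams <- unique(x$results$family)
  for (ds in unique(x$results$dataset)) {
    sub <- x$results[x$results$dataset == ds, ]
    cells <- sprintf("%s %.2f%s(%.2f)", toupper(sub$family), sub$mean,
                     ifelse(is.na(sub$letter), "", paste0("^", sub$letter)),
                     sub$sd)
    cat(sprintf("  %-16s %s\n", ds, paste(cells, collapse = "  ")))
  }
  invisible(x)
}

#' @export
summary.bis_benchmark <- function(object, ...) object$results

#' Multi-seed ordering battery
#'
#' Repeats the cohort-to-CV pipeline over several seeds and checks, per
#' seed, whether the tuned classifier's mean CV accuracy is non-decreasing
#' from raw features to delta features to delta-plus-diameter features
#' (a decrease within one standard deviation of the earlier dataset's
#' accuracy distribution counts as a tie). Uses a condensed SVM grid so the
#' battery stays at interactive scale.
#'
#' @param seeds integer vector of cohort seeds.
#' @param design,params cohort design and generating parameters.
#' @param family model family (default `"svm"`).
#' @param grid hyperparameter grid for the battery (default condensed SVM
#'   grid: cost 1/10 x linear/RBF-scale).
#' @param repeats,folds,train_frac CV settings.
#' @return a data frame with one row per seed (means, sds, `concordant`)
#'   plus attribute `concordance`, the fraction of concordant seeds.
#' @export
ordering_battery <- function(seeds = 1:20, design = study_design(),
                             params = cohort_params(), family = "svm",
                             grid = NULL, repeats = 5L, folds = 10L,
                             train_frac = 0.8) {
  grid <- grid %||% expand.grid(cost = c(1, 10),
                                kernel = c("linear", "radial"),
                                gamma = "scale", stringsAsFactors = FALSE)
  kinds <- c("bio-raw", "bio-delta", "bio-delta-diam")
  rows <- lapply(seeds, function(s) {
    ch <- simulate_cohort(seed = s, design = design, params = params)
    datasets <- lapply(kinds, function(k) assemble_dataset(ch, k))
    names(datasets) <- kinds
    sp <- split_table(datasets[[1]], train_frac = train_frac, seed = s)
    fold_mat <- make_folds(datasets[[1]]$y[sp$train_idx], repeats = repeats,
                           folds = folds, seed = s)
    res <- lapply(datasets, function(d) {
      tr <- feature_table(d$x[sp$train_idx, , drop = FALSE],
                          d$y[sp$train_idx],
                          d$instance[sp$train_idx, , drop = FALSE], d$kind)
      grid_search_cv(tr, family, fold_mat, grid = grid, seed = s)
    })
    m <- vapply(res, `[[`, numeric(1), "mean")
    s_ <- vapply(res, `[[`, numeric(1), "sd")
    ok <- (m[2] >= m[1] - s_[1]) && (m[3] >= m[2] - s_[2])
    data.frame(seed = s, raw = m[1], delta = m[2], delta_diam = m[3],
               sd_raw = s_[1], sd_delta = s_[2], sd_delta_diam = s_[3],
               concordant = ok)
  })
  out <- do.call(rbind, rows)
  attr(out, "concordance") <- mean(out$concordant)
  out
}
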