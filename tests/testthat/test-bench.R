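test_that("fold assignment is stratified, seeded, and shared by signature", {
  y <- factor(rep(c("room", "cold"), each = 40), levels = c("room", "cold"))
  f1 <- make_folds(y, repeats = 5, folds = 10, seed = 3)
  f2 <- make_folds(y, repeats = 5, folds = 10, seed = 3)
  expect_identical(unclass(f1), unclass(f2))
  expect_identical(fold_signature(f1), fold_signature(f2))
  expect_false(fold_signature(f1) ==
                 fold_signature(make_folds(y, repeats = 5, folds = 10, seed = 4)))
  # every fold contains both classes in every repeat
  for (r in 1:5) for (k in 1:10) {
    expect_equal(sort(unique(as.character(y[f1[, r] == k]))),
                 c("cold", "room"))
  }
  tiny_y <- factor(c("room", "cold"), levels = c("room", "cold"))
  expect_error(make_folds(tiny_y, repeats = 1, folds = 3, seed = 1),
               class = "bisfruit_stratification_error")
})

test_that("grid search reaches perfect accuracy on separable blobs and chance on permuted labels", {
  ft <- blob_table(n_per_class = 30, seed = 2)
  folds <- make_folds(ft$y, repeats = 5, folds = 10, seed = 1)
  res <- grid_search_cv(ft, "svm", folds,
                        grid = data.frame(cost = 1, kernel = "linear",
                                          gamma = "scale"), seed = 1)
  expect_length(res$accuracies, 50)
  expect_equal(res$mean, 1)
  expect_equal(res$mean, mean(res$accuracies), tolerance = 1e-12)
  expect_equal(res$sd, sd(res$accuracies), tolerance = 1e-12)

  set.seed(99)
  ft_null <- ft
  ft_null$y <- sample(ft_null$y)
  res_null <- grid_search_cv(ft_null, "lda", folds, seed = 1)
  expect_lt(abs(res_null$mean - 0.5), 3 * max(res_null$sd, 0.05))
})

test_that("every model family runs and beats chance on separable data", {
  ft <- blob_table(n_per_class = 25, seed = 5)
  folds <- make_folds(ft$y, repeats = 2, folds = 5, seed = 2)
  for (fam in bis_model_families()) {
    res <- grid_search_cv(ft, fam, folds, seed = 2)
    expect_length(res$accuracies, 10)
    expect_gt(res$mean, 0.9)
  }
})

test_that("cross-validated accuracy vectors are reproducible bit-identically", {
  ch <- tiny_cohort(seed = 7, n_per_group = 8)
  ft <- assemble_dataset(ch, "bio-delta")
  sp <- split_table(ft, seed = 7)
  folds <- make_folds(sp$train$y, repeats = 2, folds = 5, seed = 7)
  g <- data.frame(cost = 1, kernel = "linear", gamma = "scale")
  r1 <- grid_search_cv(sp$train, "svm", folds, grid = g, seed = 7)
  r2 <- grid_search_cv(sp$train, "svm", folds, grid = g, seed = 7)
  expect_identical(r1$accuracies, r2$accuracies)
})

test_that("signed-rank comparison follows the stated conventions", {
  a <- rep(0.8, 50)
  expect_equal(wilcoxon_compare(a, a)$p_value, 1)

  set.seed(8)
  b <- a + runif(50, 0.001, 0.05)
  w <- wilcoxon_compare(b, a)
  expect_lt(w$p_value, 0.001)
  expect_equal(w$direction, 1)

  expect_error(wilcoxon_compare(1:5, 1:6), class = "bisfruit_pairing_error")
})

test_that("signed-rank p-values match exact enumeration at n = 8", {
  set.seed(17)
  for (i in 1:10) {
    d <- round(runif(8, -1, 1), 7)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(runif(8, -1, 1), 7)
    a <- 0.8 + d
    b <- rep(0.8, 8)
    expect_equal(wilcoxon_compare(a, b)$p_value, enum_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("compact letters reproduce the canonical patterns", {
  none_sig <- matrix(0.5, 3, 3)
  expect_equal(assign_letters(none_sig), c("a", "a", "a"))
  all_sig <- matrix(0.01, 3, 3)
  expect_equal(assign_letters(all_sig), c("a", "b", "c"))
  # the headline pattern: every pairwise difference significant -> a/b/c
  pm <- matrix(c(NA, 0.01, 0.001, 0.01, NA, 0.04, 0.001, 0.04, NA), 3, 3)
  expect_equal(assign_letters(pm), c("a", "b", "c"))
  # intransitive: 1~2, 2~3, but 1 != 3 -> overlapping letters and a warning
  pint <- matrix(c(NA, 0.5, 0.01, 0.5, NA, 0.5, 0.01, 0.5, NA), 3, 3)
  expect_warning(lets <- assign_letters(pint), "intransitive")
  expect_equal(lets, c("a", "ab", "b"))
})

test_that("confusion metrics implement the closed forms and the harmonic identity", {
  cm <- confusion_matrix(factor(c("room", "room", "cold", "cold")),
                         factor(c("room", "cold", "cold", "room")))
  expect_equal(sum(cm), 4)
  m <- confusion_metrics(c(tp = 8, fp = 2, fn = 2, tn = 8))
  expect_equal(unname(m), c(0.8, 0.8, 0.8, 0.8))
  perfect <- confusion_metrics(c(tp = 5, fp = 0, fn = 0, tn = 9))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  expect_true(is.na(confusion_metrics(c(tp = 0, fp = 0, fn = 3, tn = 7))[["precision"]]))
  set.seed(31)
  for (i in 1:200) {
    cm <- c(tp = rpois(1, 10) + 1, fp = rpois(1, 5), fn = rpois(1, 5),
            tn = rpois(1, 10) + 1)
    m <- confusion_metrics(cm)
    if (!is.na(m[["f1"]])) {
      expect_equal(m[["f1"]], 2 / (1 / m[["precision"]] + 1 / m[["recall"]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("holdout evaluation refits once and its matrix totals the test size", {
  ft <- blob_table(n_per_class = 40, seed = 3)
  sp <- split_table(ft, seed = 1)
  ev <- evaluate_holdout(sp$train, sp$test, "svm",
                         list(cost = 1, kernel = "linear", gamma = "scale"),
                         seed = 1)
  expect_equal(sum(ev$test$cm), nrow(sp$test$x))
  expect_equal(ev$test$metrics, confusion_metrics(ev$test$cm))
  expect_equal(rownames(ev$test$metrics_by_class), c("positive", "negative"))
  bad_test <- sp$test
  colnames(bad_test$x) <- paste0("g", seq_len(ncol(bad_test$x)))
  expect_error(evaluate_holdout(sp$train, bad_test, "svm",
                                list(cost = 1, kernel = "linear",
                                     gamma = "scale")),
               class = "bisfruit_schema_error")
})

test_that("PCA embedding has ordered explained variance and reconstructs exactly", {
  set.seed(41)
  x <- matrix(rnorm(200), 40, 5)
  emb <- pca_embed(x, 5)
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_lte(sum(emb$explained), 1 + 1e-12)
  recon <- emb$scores %*% t(emb$rotation) +
    matrix(emb$center, 40, 5, byrow = TRUE)
  expect_lt(max(abs(recon - x)), 1e-10)
  # rank-2 data: third component explains nothing
  basis <- matrix(rnorm(10), 5, 2)
  x2 <- matrix(rnorm(80), 40, 2) %*% t(basis)
  expect_lt(pca_embed(x2, 3)$explained[3], 1e-12)
  expect_error(pca_embed(x, 7), class = "bisfruit_dimension_error")
})

test_that("the benchmark shares one fold pairing and letters across dataset groups", {
  ch <- tiny_cohort(seed = 11, n_per_group = 8)
  kinds <- c("bio-raw", "bio-delta", "bio-delta-diam")
  ds <- lapply(kinds, function(k) assemble_dataset(ch, k))
  names(ds) <- kinds
  bm <- run_benchmark(ds, families = c("svm", "lda"), seed = 2,
                      repeats = 2, folds = 5,
                      grids = list(svm = data.frame(cost = 1, kernel = "linear",
                                                    gamma = "scale")))
  expect_equal(nrow(bm$results), 6)
  expect_true(all(!is.na(bm$results$letter)))
  # one fold matrix for the whole run, identical to an independent rebuild
  rebuilt <- make_folds(ds[[1]]$y[bm$split$train_idx], repeats = 2, folds = 5,
                        seed = 2)
  expect_identical(fold_signature(bm$folds), fold_signature(rebuilt))
  for (k in kinds) {
    expect_length(bm$cv[[k]][["svm"]]$accuracies, 10)
  }
  expect_output(print(bm), "benchmark")
})
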