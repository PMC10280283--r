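test_that("stratified folds reproduce the expected training/testing sizes", {
  # 3 classes of 50 -> 120 train / 30 test per fold
  plan <- stratified_kfold(rep(c("a", "b", "c"), each = 50), k_folds = 5, seed = 1)
  for (f in 1:5) {
    idx <- fold_split(plan, f)
    expect_length(idx$test, 30)
    expect_length(idx$train, 120)
    expect_equal(unname(table(plan$label[plan$fold == f])), rep(10L, 3),
                 ignore_attr = TRUE)
  }
  # 500 points -> 400 train / 100 test per fold
  plan2 <- stratified_kfold(rep(letters[1:10], each = 50), k_folds = 5, seed = 2)
  for (f in 1:5) {
    idx <- fold_split(plan2, f)
    expect_length(idx$test, 100)
    expect_length(idx$train, 400)
  }
})

test_that("folds partition the data and respect stratification within one point", {
  withr::with_seed(61, {
    labels <- sample(c("x", "y", "z"), 83, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    plan <- stratified_kfold(labels, k_folds = 5, seed = 7)
    expect_equal(sort(plan$index), 1:83)
    expect_equal(unname(colSums(table(plan$fold, plan$label))),
                 unname(as.vector(table(labels)[sort(unique(labels))])))
    for (cl in unique(labels)) {
      per_fold <- table(factor(plan$fold[plan$label == cl], levels = 1:5))
      expect_lte(diff(range(per_fold)), 1)
    }
  })
})

test_that("fold plans are deterministic in the seed", {
  labels <- rep(c("a", "b"), each = 25)
  p1 <- stratified_kfold(labels, seed = 3)
  p2 <- stratified_kfold(labels, seed = 3)
  p3 <- stratified_kfold(labels, seed = 4)
  expect_identical(p1$fold, p2$fold)
  expect_false(identical(p1$fold, p3$fold))
  expect_identical(table(p1$fold), table(p3$fold))
  expect_error(stratified_kfold(labels, k_folds = 1), class = "phca_invalid_input")
  expect_warning(stratified_kfold(c(rep("a", 10), rep("b", 3)), k_folds = 5),
                 "fewer than")
})

test_that("confusion matrices count correctly", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), levels = c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(truth = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = "class")
  perfect <- confusion_matrix(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  expect_equal(diag(perfect), c(A = 5L, B = 5L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)
  withr::with_seed(62, {
    truth <- sample(letters[1:4], 200, replace = TRUE)
    pred <- sample(letters[1:4], 200, replace = TRUE)
    cm2 <- confusion_matrix(truth, pred, levels = letters[1:4])
    for (i in letters[1:4]) {
      for (j in letters[1:4]) {
        expect_equal(cm2[i, j], sum(truth == i & pred == j))
      }
    }
  })
  expect_error(confusion_matrix(c("A", "B"), c("A", "C"), levels = c("A", "B")),
               class = "phca_invalid_input")
})

test_that("metrics reproduce the hand-worked binary example", {
  # TP=8, FP=2, FN=1, TN=9
  cm <- confusion_matrix(truth = rep(c("pos", "neg"), c(9, 11)),
                         predicted = c(rep("pos", 8), "neg",
                                       rep("pos", 2), rep("neg", 9)),
                         levels = c("pos", "neg"))
  m <- compute_metrics(cm)
  pos <- m$class_metrics[m$class_metrics$class == "pos", ]
  expect_equal(pos$precision, 0.8)
  expect_equal(pos$recall, 8 / 9, tolerance = 1e-12)
  expect_equal(pos$specificity, 9 / 11, tolerance = 1e-12)
  expect_equal(pos$accuracy, 0.85)
  expect_equal(pos$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-12)
  expect_equal(round(pos$f1, 4), 0.8421)
  expect_equal(m$accuracy, 0.85)
})

test_that("perfect predictions give all-1 metrics; never-predicted classes flag NA", {
  cm <- confusion_matrix(rep(c("a", "b", "c"), 4), rep(c("a", "b", "c"), 4))
  m <- compute_metrics(cm)
  expect_true(all(as.matrix(m$class_metrics[c("precision", "recall",
                                              "specificity", "f1")]) == 1))
  expect_equal(m$accuracy, 1)

  # class c never predicted: precision undefined, not silently zero
  cm2 <- confusion_matrix(c("a", "a", "b", "c"), c("a", "a", "b", "b"),
                          levels = c("a", "b", "c"))
  m2 <- compute_metrics(cm2)
  expect_true(is.na(m2$class_metrics$precision[3]))
  expect_false(is.na(m2$class_metrics$recall[3]))
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(63, {
    for (rep in 1:10) {
      k <- sample(2:5, 1)
      truth <- sample(letters[1:k], 120, replace = TRUE)
      pred <- sample(letters[1:k], 120, replace = TRUE)
      m <- compute_metrics(confusion_matrix(truth, pred, levels = letters[1:k]))
      cm <- m$class_metrics
      expect_true(all(cm$tp + cm$fp + cm$fn + cm$tn == m$n))
      expect_equal(sum(cm$tp) / m$n, m$accuracy)
      ok <- !is.na(cm$f1)
      expect_true(all(cm$f1[ok] >= pmin(cm$precision, cm$recall)[ok] - 1e-12))
      expect_true(all(cm$f1[ok] <= pmax(cm$precision, cm$recall)[ok] + 1e-12))
    }
  })
})

test_that("the Nemenyi comparison matches a hand-ranked oracle", {
  # two identical methods: zero rank difference, p = 1
  tbl <- rbind(m1 = c(0.9, 0.8, 0.7), m2 = c(0.9, 0.8, 0.7))
  nem <- nemenyi_test(tbl)
  expect_equal(nem$pairwise$mean_rank_diff, 0)
  expect_equal(nem$pairwise$p_value, 1)

  # a dominating first method over 13 metric means, 3 methods
  withr::with_seed(64, {
    k <- 3; n <- 13
    tbl2 <- rbind(best = runif(n, 0.9, 1), mid = runif(n, 0.5, 0.6),
                  worst = runif(n, 0.1, 0.2))
    nem2 <- nemenyi_test(tbl2)
    # hand ranks: best 1, mid 2, worst 3 in every column
    expect_equal(nem2$mean_ranks$mean_rank, c(1, 2, 3))
    bw <- nem2$pairwise[nem2$pairwise$method_a == "best" &
                          nem2$pairwise$method_b == "worst", ]
    expect_equal(bw$mean_rank_diff, -2)
    expect_equal(bw$statistic, -2 / sqrt(k * (n + 1) / 12), tolerance = 1e-12)
    q <- 2 / sqrt(k * (k + 1) / (6 * n))
    expect_equal(bw$p_value, ptukey(q * sqrt(2), k, Inf, lower.tail = FALSE),
                 tolerance = 1e-12)
  })
})

test_that("Nemenyi output on a random table is antisymmetric with valid p-values", {
  withr::with_seed(65, {
    tbl <- matrix(runif(6 * 13), 6, dimnames = list(paste0("m", 1:6), NULL))
    nem <- nemenyi_test(tbl)
    # independent oracle: base rank() per column, higher is better
    ranks <- apply(tbl, 2, function(col) rank(-col))
    expect_equal(nem$mean_ranks$mean_rank, unname(rowMeans(ranks)))
    pw <- nem$pairwise
    swap <- stats::setNames(pw$mean_rank_diff, paste(pw$method_a, pw$method_b))
    expect_equal(unname(swap["m1 m3"]),
                 -(rowMeans(ranks)["m3"] - rowMeans(ranks)["m1"]),
                 ignore_attr = TRUE)
    expect_true(all(pw$p_value >= 0 & pw$p_value <= 1))
  })
  expect_error(nemenyi_test(matrix(1, 1, 5)), class = "phca_invalid_input")
})

test_that("the benchmark harness is deterministic and solves separated blobs", {
  blobs <- generate_blobs(k_classes = 2, n_per_class = 25, separation = 30,
                          seed = 9)
  b1 <- run_benchmark(blobs, methods = "phca", k_folds = 5, seed = 5)
  expect_equal(b1$metrics$phca$accuracy, 1)
  b2 <- run_benchmark(blobs, methods = "phca", k_folds = 5, seed = 5)
  expect_identical(glance(b1), glance(b2))
  expect_identical(b1$folds$fold, b2$folds$fold)
})

test_that("a multi-method benchmark yields the full report shape", {
  blobs <- generate_blobs(k_classes = 3, n_per_class = 15, separation = 20,
                          seed = 10)
  b <- run_benchmark(blobs, methods = c("phca", "lda", "cart", "knn"),
                     k_folds = 5, seed = 6)
  expect_setequal(b$methods, c("phca", "lda", "cart", "knn"))
  expect_equal(dim(b$metric_table), c(4L, 1L + 4L * 3L))
  expect_s3_class(b$nemenyi, "phca_nemenyi")
  expect_equal(nrow(b$nemenyi$pairwise), choose(4, 2))
  td <- tidy(b)
  expect_equal(nrow(td), 4 * 3)
  # every method sees the same folds: per-method confusion totals agree
  expect_true(all(vapply(b$metrics, function(m) sum(m$confusion), numeric(1)) == 45))
})

test_that("per-fold aggregation averages metrics instead of pooling", {
  blobs <- generate_blobs(k_classes = 2, n_per_class = 20, separation = 30,
                          seed = 11)
  pooled <- run_benchmark(blobs, methods = "phca", seed = 2, aggregate = "pooled")
  byfold <- run_benchmark(blobs, methods = "phca", seed = 2, aggregate = "per_fold")
  expect_equal(pooled$metrics$phca$accuracy, 1)
  expect_equal(byfold$metrics$phca$accuracy, 1)
  expect_equal(unclass(pooled$metrics$phca$confusion),
               unclass(byfold$metrics$phca$confusion))
})

test_that("benchmark reports serialize to CSV", {
  blobs <- generate_blobs(k_classes = 2, n_per_class = 15, separation = 25,
                          seed = 12)
  b <- run_benchmark(blobs, methods = c("phca", "lda"), seed = 3)
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "nemenyi.csv")))
  back <- readr::read_csv(file.path(dir, "metrics.csv"), show_col_types = FALSE)
  expect_equal(nrow(back), 4)
})
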