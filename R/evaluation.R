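#' Stratified k-fold assignment
#'
#' Shuffles each class independently (under `seed`) and splits it into
#' `k_folds` contiguous, near-equal sections, so every fold preserves class
#' proportions to within one point and every point is tested exactly once.
#'
#' @param labels Vector of class labels, one per point.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for the per-class shuffles; `NULL` uses the
#'   current RNG state.
#'
#' @return A tibble of class `phca_folds` with columns `index`, `label` and
#'   `fold` (the fold in which the point is *tested*).
#'
#' @examples
#' plan <- stratified_kfold(rep(c("a", "b", "c"), each = 50), seed = 1)
#' table(plan$fold)
#' @export
stratified_kfold <- function(labels, k_folds = 5, seed = NULL) {
  if (!is.numeric(k_folds) || length(k_folds) != 1 || k_folds < 2) {
    stop_invalid("k_folds must be an integer >= 2")
  }
  k_folds <- as.integer(k_folds)
  labels <- as.character(labels)
  n <- length(labels)
  assign_folds <- function() {
    fold <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      m <- length(idx)
      if (m < k_folds) {
        warn(sprintf("class '%s' has %d points, fewer than %d folds; some folds will miss it",
                     cl, m, k_folds))
      }
      idx <- sample(idx, m)
      sizes <- rep(m %/% k_folds, k_folds) + (seq_len(k_folds) <= m %% k_folds)
      fold[idx] <- rep(seq_len(k_folds), times = sizes)
    }
    fold
  }
  fold <- if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
  out <- tibble::tibble(index = seq_len(n), label = labels, fold = fold)
  structure(out, class = c("phca_folds", class(out)), k_folds = k_folds,
            seed = seed)
}

#' Training and testing indices of one fold
#'
#' @param plan A [stratified_kfold()] plan.
#' @param fold Fold number.
#' @return A list with integer vectors `train` and `test`.
#' @export
fold_split <- function(plan, fold) {
  stopifnot(inherits(plan, "phca_folds"))
  list(train = plan$index[plan$fold != fold],
       test = plan$index[plan$fold == fold])
}

#' Confusion matrix
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels; every predicted label must belong
#'   to `levels`.
#' @param levels Class order (default: training/appearance order of `truth`).
#' @return A k x k integer matrix of class `phca_confusion`; rows are true
#'   classes, columns predicted classes.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_invalid("truth and predicted must have equal length")
  }
  if (is.null(levels)) levels <- unique(truth)
  if (!all(truth %in% levels)) stop_invalid("truth contains labels outside 'levels'")
  bad <- setdiff(unique(predicted), levels)
  if (length(bad) > 0) {
    stop_invalid(sprintf("predicted label(s) outside the class set: %s",
                         paste(bad, collapse = ", ")))
  }
  cm <- table(factor(truth, levels = levels), factor(predicted, levels = levels))
  cm <- matrix(as.integer(cm), nrow = length(levels),
               dimnames = list(truth = levels, predicted = levels))
  structure(cm, class = c("phca_confusion", class(cm)))
}

#' Per-class performance metrics from a confusion matrix
#'
#' For each class `i`: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, per-class accuracy `(TP+TN)/total` and F1 (the
#' harmonic mean of precision and recall). A zero denominator yields `NA`
#' (explicitly undefined, never silently 0); such cells are excluded from any
#' downstream rank aggregation. Overall accuracy is `trace/total`.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `phca_metrics`: a list with `class_metrics`
#'   (tibble), `accuracy`, `n` and the confusion matrix. `tidy()` returns the
#'   per-class tibble, `glance()` overall accuracy.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "phca_confusion"))
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  out <- list(
    class_metrics = tibble::tibble(
      class = rownames(cm), tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      precision = unname(precision), recall = unname(recall),
      specificity = unname(specificity),
      accuracy = unname((tp + tn) / total), f1 = unname(f1)),
    accuracy = sum(tp) / total,
    n = total,
    confusion = cm)
  structure(out, class = "phca_metrics")
}

#' @export
print.phca_metrics <- function(x, ...) {
  cat(sprintf("Classification metrics on %d points; overall accuracy %.4f\n",
              x$n, x$accuracy))
  print(x$class_metrics)
  invisible(x)
}

#' @method tidy phca_metrics
#' @export
tidy.phca_metrics <- function(x, ...) x$class_metrics

#' @method glance phca_metrics
#' @export
glance.phca_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n)
}

#' Nemenyi post-hoc pairwise comparison of methods
#'
#' Methods (rows) are ranked within every performance-metric column (rank 1 =
#' best, average ranks for ties, `NA` cells excluded) and summarised by their
#' mean rank. For every pair, two quantities are reported: the standardized
#' statistic `(Rbar_i - Rbar_j) / sqrt(k (n + 1) / 12)` with `k` methods and
#' `n` metric columns, and a p-value from the studentized-range reference
#' distribution of the usual Nemenyi test,
#' `q = |Rbar_i - Rbar_j| / sqrt(k (k + 1) / (6 n))`. A p-value below 0.05 is
#' conventionally read as the two methods differing significantly.
#'
#' @param metric_table Numeric matrix or data frame: rows = methods (named),
#'   columns = performance-metric means.
#' @param higher_is_better Whether larger metric values rank better
#'   (default `TRUE`).
#' @return An object of class `phca_nemenyi` with elements `mean_ranks`
#'   (tibble) and `pairwise` (tibble with `mean_rank_diff`, `statistic`,
#'   `p_value`); `tidy()` returns the pairwise tibble.
#' @export
nemenyi_test <- function(metric_table, higher_is_better = TRUE) {
  m <- as.matrix(metric_table)
  if (is.null(rownames(m))) rownames(m) <- paste0("method_", seq_len(nrow(m)))
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop_invalid("need at least 2 methods and 2 metric columns")
  }
  k <- nrow(m)
  n <- ncol(m)
  ranks <- apply(m, 2, function(col) {
    r <- rep(NA_real_, k)
    ok <- !is.na(col)
    r[ok] <- rank(if (higher_is_better) -col[ok] else col[ok],
                  ties.method = "average")
    r
  })
  mean_ranks <- stats::setNames(rowMeans(ranks, na.rm = TRUE), rownames(m))
  pairs <- utils::combn(rownames(m), 2)
  diff <- mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]
  statistic <- diff / sqrt(k * (n + 1) / 12)
  q <- abs(diff) / sqrt(k * (k + 1) / (6 * n))
  p_value <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf,
                           lower.tail = FALSE)
  out <- list(
    mean_ranks = tibble::tibble(method = rownames(m),
                                mean_rank = unname(mean_ranks)),
    pairwise = tibble::tibble(
      method_a = pairs[1, ], method_b = pairs[2, ],
      mean_rank_diff = unname(diff), statistic = unname(statistic),
      p_value = unname(p_value)),
    k = k, n_metrics = n)
  structure(out, class = "phca_nemenyi")
}

#' @export
print.phca_nemenyi <- function(x, ...) {
  cat(sprintf("Nemenyi pairwise comparison: %d methods over %d metric means\n",
              x$k, x$n_metrics))
  print(x$pairwise)
  invisible(x)
}

#' @method tidy phca_nemenyi
#' @export
tidy.phca_nemenyi <- function(x, ...) x$pairwise

# ---------------------------------------------------------------------------
# Benchmark adapters: every method is a closure (train_x, train_y, test_x)
# -> predicted labels. Off-the-shelf classifiers are used with their package
# defaults; they are harness plumbing, not part of the classifier itself.

benchmark_adapters <- function(maxdim = 0, scale = FALSE, knn_k = 5, ...) {
  list(
    phca = function(train_x, train_y, test_x) {
      d <- as.data.frame(train_x)
      d$.label <- train_y
      fit <- phca(d, label = ".label", maxdim = maxdim, scale = scale, ...)
      as.character(predict(fit, as.data.frame(test_x)))
    },
    lda = function(train_x, train_y, test_x) {
      fit <- MASS::lda(train_x, grouping = factor(train_y))
      as.character(predict(fit, test_x)$class)
    },
    cart = function(train_x, train_y, test_x) {
      d <- as.data.frame(train_x)
      d$.label <- factor(train_y)
      fit <- rpart::rpart(.label ~ ., data = d, method = "class")
      as.character(predict(fit, as.data.frame(test_x), type = "class"))
    },
    knn = function(train_x, train_y, test_x) {
      as.character(class::knn(train_x, test_x, cl = factor(train_y), k = knn_k))
    },
    svm = function(train_x, train_y, test_x) {
      fit <- e1071::svm(train_x, factor(train_y))
      as.character(predict(fit, test_x))
    },
    rf = function(train_x, train_y, test_x) {
      fit <- randomForest::randomForest(train_x, factor(train_y))
      as.character(predict(fit, test_x))
    })
}

#' Cross-validated benchmark of PHCA against standard classifiers
#'
#' Runs every requested method over one shared stratified k-fold plan,
#' aggregates predictions (by default pooling the fold confusion matrices,
#' the alternative averaging per-fold metrics), computes the per-class metric
#' report for each method, and compares methods with the Nemenyi test over
#' the table of metric means (accuracy plus per-class precision, recall,
#' specificity and F1; `NA` cells are excluded from ranking).
#'
#' @param data Data frame of features plus a label column.
#' @param label Label column name; defaults to the last column.
#' @param methods Subset of `c("phca", "lda", "cart", "knn", "svm", "rf")`.
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the fold plan and any stochastic method.
#' @param aggregate `"pooled"` (default): sum fold confusion matrices then
#'   compute metrics once; `"per_fold"`: average per-fold metrics.
#' @param maxdim,scale Passed to [phca()].
#' @param knn_k Neighbourhood size of the KNN benchmark (default 5).
#' @param ... Further arguments passed to [phca()].
#'
#' @return An object of class `phca_benchmark`: list with `metrics` (named
#'   list of [compute_metrics()] reports), `metric_table` (methods x metric
#'   means), `nemenyi`, `folds` and bookkeeping fields. `tidy()` gives a long
#'   per-class metric tibble; `glance()` one row per method with overall
#'   accuracy.
#' @export
run_benchmark <- function(data, label = NULL, methods = c("phca", "lda", "cart", "knn", "svm", "rf"),
                          k_folds = 5, seed = 1,
                          aggregate = c("pooled", "per_fold"),
                          maxdim = 0, scale = FALSE, knn_k = 5, ...) {
  aggregate <- match.arg(aggregate)
  if (!is.data.frame(data)) stop_invalid("data must be a data frame")
  if (is.null(label)) label <- names(data)[ncol(data)]
  if (!label %in% names(data)) stop_invalid(sprintf("label column '%s' not found", label))
  y <- as.character(data[[label]])
  classes <- if (is.factor(data[[label]])) levels(droplevels(data[[label]])) else unique(y)
  x <- as_cloud_matrix(data[setdiff(names(data), label)], arg = "data")

  adapters <- benchmark_adapters(maxdim = maxdim, scale = scale, knn_k = knn_k, ...)
  unknown <- setdiff(methods, names(adapters))
  if (length(unknown) > 0) {
    stop_invalid(sprintf("unknown method(s): %s", paste(unknown, collapse = ", ")))
  }

  plan <- stratified_kfold(y, k_folds = k_folds, seed = seed)
  metrics <- list()
  fold_metrics <- list()
  for (method in methods) {
    adapter <- adapters[[method]]
    truth_all <- character(0)
    pred_all <- character(0)
    per_fold <- list()
    failed <- FALSE
    for (f in seq_len(k_folds)) {
      idx <- fold_split(plan, f)
      pred <- tryCatch(
        withr::with_seed(seed + f,
          adapter(x[idx$train, , drop = FALSE], y[idx$train],
                  x[idx$test, , drop = FALSE])),
        error = function(e) e)
      if (inherits(pred, "error")) {
        warn(sprintf("method '%s' failed in fold %d (%s); method skipped",
                     method, f, conditionMessage(pred)))
        failed <- TRUE
        break
      }
      truth_all <- c(truth_all, y[idx$test])
      pred_all <- c(pred_all, pred)
      per_fold[[f]] <- compute_metrics(
        confusion_matrix(y[idx$test], pred, levels = classes))
    }
    if (failed) next
    metrics[[method]] <- if (aggregate == "pooled") {
      compute_metrics(confusion_matrix(truth_all, pred_all, levels = classes))
    } else {
      average_fold_metrics(per_fold)
    }
    fold_metrics[[method]] <- per_fold
  }
  if (length(metrics) == 0) stop_invalid("every method failed")

  metric_table <- do.call(rbind, lapply(metrics, metric_row))
  rownames(metric_table) <- names(metrics)
  nemenyi <- if (length(metrics) >= 2) nemenyi_test(metric_table) else NULL

  structure(list(
    metrics = metrics,
    fold_metrics = fold_metrics,
    metric_table = metric_table,
    nemenyi = nemenyi,
    folds = plan,
    classes = classes,
    methods = names(metrics),
    k_folds = k_folds,
    seed = seed,
    aggregate = aggregate
  ), class = "phca_benchmark")
}

# one row of metric means for the Nemenyi table
metric_row <- function(m) {
  cm <- m$class_metrics
  vals <- c(accuracy = m$accuracy,
            stats::setNames(cm$precision, paste0("precision_", cm$class)),
            stats::setNames(cm$recall, paste0("recall_", cm$class)),
            stats::setNames(cm$specificity, paste0("specificity_", cm$class)),
            stats::setNames(cm$f1, paste0("f1_", cm$class)))
  matrix(vals, nrow = 1, dimnames = list(NULL, names(vals)))
}

# per-fold aggregation: mean of each numeric metric over folds (NA dropped),
# counts summed, overall accuracy averaged
average_fold_metrics <- function(per_fold) {
  cms <- lapply(per_fold, function(m) m$class_metrics)
  counts <- Reduce(`+`, lapply(cms, function(d) as.matrix(d[c("tp", "fp", "fn", "tn")])))
  num <- c("precision", "recall", "specificity", "accuracy", "f1")
  avg <- Reduce(`+`, lapply(cms, function(d) {
    v <- as.matrix(d[num]); v[is.na(v)] <- 0; v
  })) / Reduce(`+`, lapply(cms, function(d) !is.na(as.matrix(d[num]))))
  out <- list(
    class_metrics = tibble::tibble(
      class = cms[[1]]$class,
      tp = as.integer(counts[, "tp"]), fp = as.integer(counts[, "fp"]),
      fn = as.integer(counts[, "fn"]), tn = as.integer(counts[, "tn"]),
      precision = avg[, "precision"], recall = avg[, "recall"],
      specificity = avg[, "specificity"], accuracy = avg[, "accuracy"],
      f1 = avg[, "f1"]),
    accuracy = mean(vapply(per_fold, function(m) m$accuracy, numeric(1))),
    n = sum(vapply(per_fold, function(m) m$n, numeric(1))),
    confusion = Reduce(`+`, lapply(per_fold, function(m) m$confusion)))
  structure(out, class = "phca_metrics")
}

#' @export
print.phca_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark over %d-fold stratified CV (seed %s, %s aggregation)\n",
              x$k_folds, format(x$seed), x$aggregate))
  print(glance(x))
  invisible(x)
}

#' @method glance phca_benchmark
#' @export
glance.phca_benchmark <- function(x, ...) {
  tibble::tibble(
    method = x$methods,
    accuracy = vapply(x$metrics, function(m) m$accuracy, numeric(1)),
    n = vapply(x$metrics, function(m) as.numeric(m$n), numeric(1)))
}

#' @method tidy phca_benchmark
#' @export
tidy.phca_benchmark <- function(x, ...) {
  purrr::map_dfr(x$methods, function(m) {
    dplyr::mutate(x$metrics[[m]]$class_metrics, method = m, .before = 1)
  })
}

#' Write benchmark reports to CSV
#'
#' Writes `metrics.csv` (one row per method and class) and, when available,
#' `nemenyi.csv` (pairwise comparisons) into `dir`.
#'
#' @param x A [run_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(x, dir) {
  stopifnot(inherits(x, "phca_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(x), file.path(dir, "metrics.csv"))
  if (!is.null(x$nemenyi)) {
    readr::write_csv(tidy(x$nemenyi), file.path(dir, "nemenyi.csv"))
  }
  invisible(dir)
}
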