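#' Fit a persistent-homology classifier
#'
#' Trains the total-persistence classifier: for every class, the Vietoris-Rips
#' persistence diagram of the class point cloud is computed up to `maxscale`,
#' capped, and summarised by its total persistence (the sum of feature
#' lifespans). A query point is later scored against class `i` by
#' `|total_persistence(X_i with query) - total_persistence(X_i)|` and assigned
#' to the class whose diagram changes least.
#'
#' With `maxdim = 0` (the default, and the regime the classifier's theory is
#' developed for) fitting and scoring use a union-find fast path: the capped
#' dimension-0 total persistence of a cloud is determined by its
#' minimum-spanning-forest edge values, and inserting a query only requires a
#' Kruskal pass over the stored forest edges plus the query's star. With
#' `maxdim >= 1` full boundary-matrix reduction is used.
#'
#' @param data A data frame with numeric feature columns and one label column.
#' @param label Name of the label column; defaults to the last column.
#' @param maxdim Highest homology dimension used (default 0).
#' @param maxscale Filtration cap, in filtration-scale units. `NULL` (default)
#'   resolves it from the training data according to `maxscale_policy`:
#'   half the maximum pairwise distance (radius convention) over the pooled
#'   training set (`"global"`, the default, which keeps per-class scores
#'   commensurable) or per class (`"per_class"`).
#' @param maxscale_policy `"global"` or `"per_class"`; ignored when `maxscale`
#'   is given.
#' @param steps Optional grid step count `m` (see [rips_filtration()]).
#' @param convention `"radius"` (default) or `"diameter"`.
#' @param scale If `TRUE`, z-scale features using means and standard
#'   deviations of the training data (applied to queries as well).
#'
#' @return An object of class `phca` with `predict()`, `tidy()`, `glance()`
#'   and `print()` methods.
#'
#' @examples
#' blobs <- generate_blobs(k_classes = 2, n_per_class = 10, seed = 1)
#' fit <- phca(blobs)
#' predict(fit, blobs[1:3, 1:2])
#' @export
phca <- function(data, label = NULL, maxdim = 0, maxscale = NULL,
                 maxscale_policy = c("global", "per_class"), steps = NULL,
                 convention = c("radius", "diameter"), scale = FALSE) {
  convention <- match.arg(convention)
  maxscale_policy <- match.arg(maxscale_policy)
  if (!is.data.frame(data)) stop_invalid("data must be a data frame")
  if (is.null(label)) label <- names(data)[ncol(data)]
  if (!label %in% names(data)) {
    stop_invalid(sprintf("label column '%s' not found", label))
  }
  y <- data[[label]]
  classes <- if (is.factor(y)) levels(droplevels(y)) else unique(as.character(y))
  y <- as.character(y)
  if (length(classes) < 2) stop_invalid("training data must contain at least 2 classes")
  feature_names <- setdiff(names(data), label)
  if (length(feature_names) == 0) stop_invalid("no feature columns")
  x <- as_cloud_matrix(data[feature_names], arg = "data")

  centers <- NULL
  scales <- NULL
  if (isTRUE(scale)) {
    centers <- colMeans(x)
    scales <- apply(x, 2, stats::sd)
    scales[!is.finite(scales) | scales == 0] <- 1
    x <- sweep(sweep(x, 2, centers), 2, scales, "/")
  }

  clouds <- lapply(classes, function(cl) x[y == cl, , drop = FALSE])
  names(clouds) <- classes
  small <- classes[vapply(clouds, nrow, integer(1)) < 2]
  if (length(small) > 0) {
    warn(sprintf("class(es) with fewer than 2 points: %s (their diagrams are single capped bars)",
                 paste(small, collapse = ", ")))
  }

  f <- scale_factor(convention)
  if (!is.null(maxscale)) {
    if (!is.numeric(maxscale) || length(maxscale) != 1 || maxscale < 0) {
      stop_invalid("maxscale must be a non-negative number")
    }
    ms <- rep(maxscale, length(classes))
  } else if (maxscale_policy == "global") {
    ms <- rep(f * max(dist(x)), length(classes))
  } else {
    ms <- vapply(clouds, function(cl) {
      if (nrow(cl) < 2) 0 else f * max(dist(cl))
    }, numeric(1))
  }
  names(ms) <- classes

  reference_diagrams <- vector("list", length(classes))
  reference_totals <- numeric(length(classes))
  mst_edges <- vector("list", length(classes))
  names(reference_diagrams) <- names(mst_edges) <- names(reference_totals) <- classes

  for (i in seq_along(classes)) {
    cl <- clouds[[i]]
    n <- nrow(cl)
    if (maxdim == 0) {
      dm <- if (n > 1) as.matrix(dist(cl)) else matrix(0, 1, 1)
      el <- dm_edge_list(dm, f, maxscale = ms[i], steps = steps)
      res <- kruskal_merges(n, el$i, el$j, el$value, keep_edges = TRUE)
      mst_edges[[i]] <- if (is.null(res$edges)) {
        matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "value")))
      } else {
        res$edges
      }
      deaths <- c(res$merges, rep(ms[i], res$n_components))
      reference_diagrams[[i]] <- persistence_diagram(
        rep(0L, n), rep(0, n), deaths, maxscale = ms[i], capped = TRUE)
    } else {
      filt <- rips_filtration(cl, maxdim = maxdim, maxscale = ms[i],
                              steps = steps, convention = convention)
      reference_diagrams[[i]] <- cap_diagram(compute_persistence(filt), ms[i])
    }
    reference_totals[i] <- total_persistence(reference_diagrams[[i]])
  }

  structure(list(
    classes = classes,
    clouds = clouds,
    label = label,
    feature_names = feature_names,
    params = list(maxdim = as.integer(maxdim), maxscale = ms,
                  maxscale_policy = maxscale_policy, steps = steps,
                  convention = convention, scale = isTRUE(scale),
                  centers = centers, scales = scales),
    reference_diagrams = reference_diagrams,
    reference_totals = reference_totals,
    mst_edges = mst_edges
  ), class = "phca")
}

# queries as a scaled matrix with columns matching the training features
prepare_queries <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, names(newdata))
    if (length(missing_cols) > 0) {
      stop_invalid(sprintf("query data lacks feature column(s): %s",
                           paste(missing_cols, collapse = ", ")))
    }
    newdata <- newdata[object$feature_names]
  }
  q <- as_cloud_matrix(newdata, arg = "newdata")
  if (ncol(q) != length(object$feature_names)) {
    stop_invalid(sprintf("queries have %d coordinates but the model expects %d",
                         ncol(q), length(object$feature_names)))
  }
  if (object$params$scale) {
    q <- sweep(sweep(q, 2, object$params$centers), 2, object$params$scales, "/")
  }
  q
}

#' Per-class classifier scores for query points
#'
#' For each query point and each class, the absolute change in capped total
#' persistence when the query is inserted into the class point cloud. Lower
#' means a smaller topological disturbance; `predict()` assigns the class with
#' the smallest score.
#'
#' @param object A fitted [phca()] model.
#' @param newdata A data frame (with the training feature columns) or a
#'   numeric matrix of query points.
#'
#' @return A tibble with one row per query: columns `score_<class>` and
#'   `.pred_class` (ties broken towards the earliest training class).
#' @export
phca_score <- function(object, newdata) {
  stopifnot(inherits(object, "phca"))
  q <- prepare_queries(object, newdata)
  k <- length(object$classes)
  scores <- matrix(0, nrow(q), k)
  f <- scale_factor(object$params$convention)
  steps <- object$params$steps
  for (i in seq_len(k)) {
    cl <- object$clouds[[i]]
    msi <- object$params$maxscale[i]
    n <- nrow(cl)
    if (object$params$maxdim == 0) {
      forest <- object$mst_edges[[i]]
      tcl <- t(cl)
      for (r in seq_len(nrow(q))) {
        star <- f * sqrt(colSums((tcl - q[r, ])^2))
        if (!is.null(steps)) star <- snap_to_grid(star, msi, steps)
        keep <- star <= msi + 1e-12
        ei <- c(forest[, 1], which(keep))
        ej <- c(forest[, 2], rep(n + 1L, sum(keep)))
        ev <- c(forest[, 3], star[keep])
        res <- kruskal_merges(n + 1L, ei, ej, ev)
        tot <- h0_capped_total(res$merges, n + 1L, msi)
        scores[r, i] <- abs(tot - object$reference_totals[i])
      }
    } else {
      for (r in seq_len(nrow(q))) {
        filt <- rips_filtration(rbind(cl, q[r, , drop = FALSE]),
                                maxdim = object$params$maxdim,
                                maxscale = msi, steps = steps,
                                convention = object$params$convention)
        tot <- total_persistence(cap_diagram(compute_persistence(filt), msi))
        scores[r, i] <- abs(tot - object$reference_totals[i])
      }
    }
  }
  out <- tibble::as_tibble(as.data.frame(scores))
  names(out) <- paste0("score_", object$classes)
  out$.pred_class <- factor(object$classes[apply(scores, 1, which.min)],
                            levels = object$classes)
  out
}

#' Predict classes (or scores) for new points
#'
#' @param object A fitted [phca()] model.
#' @param newdata Query points; see [phca_score()].
#' @param type `"class"` (default) for a factor of predicted labels,
#'   `"score"` for the full score tibble.
#' @param ... Unused.
#' @return A factor (`type = "class"`) or a tibble (`type = "score"`).
#' @export
predict.phca <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  sc <- phca_score(object, newdata)
  if (type == "class") sc$.pred_class else sc
}

#' @export
print.phca <- function(x, ...) {
  cat("Persistent-homology classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  points per class: %s\n",
              paste(vapply(x$clouds, nrow, integer(1)), collapse = ", ")))
  cat(sprintf("  maxdim %d, %s convention, maxscale %s%s\n",
              x$params$maxdim, x$params$convention,
              paste(signif(x$params$maxscale, 6), collapse = "/"),
              if (is.null(x$params$steps)) "" else sprintf(", %d grid steps", x$params$steps)))
  invisible(x)
}

#' @method tidy phca
#' @export
tidy.phca <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    n_points = unname(vapply(x$clouds, nrow, integer(1))),
    n_features = unname(vapply(x$reference_diagrams, nrow, integer(1))),
    maxscale = unname(x$params$maxscale),
    reference_total = unname(x$reference_totals))
}

#' @method glance phca
#' @export
glance.phca <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_points = sum(vapply(x$clouds, nrow, integer(1))),
    n_features_input = length(x$feature_names),
    maxdim = x$params$maxdim,
    convention = x$params$convention,
    scaled = x$params$scale)
}

#' Save and restore a fitted classifier as plain-text JSON
#'
#' The dump contains class labels, (scaled) training coordinates, filtration
#' parameters, spanning-forest edges and reference diagrams at full double
#' precision, and restores to a model with identical predictions.
#'
#' @param object A fitted [phca()] model.
#' @param path File path.
#' @return `write_phca_model()` returns `path` invisibly; `read_phca_model()`
#'   returns a `phca` object.
#' @export
write_phca_model <- function(object, path) {
  stopifnot(inherits(object, "phca"))
  ser_mat <- function(m) list(nrow = nrow(m), ncol = ncol(m),
                              data = as.numeric(m))
  payload <- list(
    format = "phca-model",
    version = 1L,
    classes = object$classes,
    label = object$label,
    feature_names = object$feature_names,
    params = list(
      maxdim = object$params$maxdim,
      maxscale = as.numeric(object$params$maxscale),
      maxscale_policy = object$params$maxscale_policy,
      steps = object$params$steps,
      convention = object$params$convention,
      scale = object$params$scale,
      centers = object$params$centers,
      scales = object$params$scales),
    reference_totals = as.numeric(object$reference_totals),
    clouds = lapply(object$clouds, ser_mat),
    mst_edges = lapply(object$mst_edges, ser_mat),
    reference_diagrams = lapply(object$reference_diagrams, function(d) {
      list(dimension = d$dimension, birth = d$birth, death = d$death,
           maxscale = attr(d, "maxscale"))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_phca_model
#' @export
read_phca_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(p$format, "phca-model")) {
    stop_invalid("not a phca model file")
  }
  de_mat <- function(m, dimnames = NULL) {
    matrix(as.numeric(m$data), nrow = m$nrow, ncol = m$ncol,
           dimnames = dimnames)
  }
  classes <- p$classes
  clouds <- lapply(p$clouds, de_mat)
  mst_edges <- lapply(p$mst_edges, function(m) {
    de_mat(m, dimnames = list(NULL, c("i", "j", "value")))
  })
  diags <- lapply(p$reference_diagrams, function(d) {
    persistence_diagram(d$dimension,
                        if (length(d$birth)) d$birth else numeric(),
                        if (length(d$death)) d$death else numeric(),
                        maxscale = d$maxscale, capped = TRUE)
  })
  names(clouds) <- names(mst_edges) <- names(diags) <- classes
  ms <- as.numeric(p$params$maxscale)
  names(ms) <- classes
  totals <- as.numeric(p$reference_totals)
  names(totals) <- classes
  structure(list(
    classes = classes,
    clouds = clouds,
    label = p$label,
    feature_names = p$feature_names,
    params = list(maxdim = as.integer(p$params$maxdim), maxscale = ms,
                  maxscale_policy = p$params$maxscale_policy,
                  steps = p$params$steps,
                  convention = p$params$convention,
                  scale = isTRUE(p$params$scale),
                  centers = if (length(p$params$centers)) unlist(p$params$centers),
                  scales = if (length(p$params$scales)) unlist(p$params$scales)),
    reference_diagrams = diags,
    reference_totals = totals,
    mst_edges = mst_edges
  ), class = "phca")
}
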