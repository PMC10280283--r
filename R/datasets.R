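#' Read a labeled feature table from CSV
#'
#' Expects a header row, one row per point, numeric attribute columns and one
#' label column (default: the last column).
#'
#' @param path CSV file path.
#' @param label_column Name of the label column; `NULL` uses the last column.
#' @param delim Field delimiter (default `","`); the decimal mark is always
#'   `"."`.
#' @return A tibble with the attribute columns and the label column; the
#'   label column name is recorded in the `"label"` attribute.
#' @export
read_feature_table <- function(path, label_column = NULL, delim = ",") {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (is.null(label_column)) label_column <- names(x)[ncol(x)]
  if (!label_column %in% names(x)) {
    stop_invalid(sprintf("label column '%s' not found in %s", label_column, path))
  }
  for (col in setdiff(names(x), label_column)) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        stop_invalid(sprintf("non-numeric attribute value in column '%s', row %d",
                             col, bad[1]))
      }
      x[[col]] <- num
    }
  }
  structure(x, label = label_column)
}

#' Write a labeled feature table to CSV
#'
#' @param data Data frame of attributes plus label column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Split a labeled table into per-class point clouds
#'
#' @param data Data frame of numeric features plus a label column.
#' @param label Label column name; `NULL` uses the last column.
#' @return A named list of numeric matrices, one per class, in label
#'   appearance (or factor level) order; row order within a class is
#'   preserved.
#' @export
as_point_clouds <- function(data, label = NULL) {
  if (!is.data.frame(data)) stop_invalid("data must be a data frame")
  if (is.null(label)) label <- names(data)[ncol(data)]
  if (!label %in% names(data)) stop_invalid(sprintf("label column '%s' not found", label))
  y <- data[[label]]
  classes <- if (is.factor(y)) levels(droplevels(y)) else unique(as.character(y))
  y <- as.character(y)
  x <- as_cloud_matrix(data[setdiff(names(data), label)], arg = "data")
  out <- lapply(classes, function(cl) x[y == cl, , drop = FALSE])
  names(out) <- classes
  out
}

#' Synthetic three-surface dataset
#'
#' Samples `n_per_surface` points uniformly from each of three surfaces in
#' 3-space: the circle `x^2 + y^2 = 25` in the plane `z = 0`, the unit sphere
#' `x^2 + y^2 + (z - 1)^2 = 1`, and the torus
#' `(3 - sqrt(x^2 + y^2))^2 + (z + 1)^2 = 1` (ring radius 3, tube radius 1,
#' centred at `z = -1`). The three coordinates are the attributes and the
#' surface is the class label.
#'
#' Circle points are uniform in arc length; sphere points are uniform by area
#' (normalised Gaussian method). Torus points are uniform by surface area by
#' default: the tube angle `phi` is drawn by rejection with acceptance
#' probability `(3 + cos(phi)) / 4`, matching the area element of a torus of
#' revolution; `torus_sampling = "parameter"` draws `phi` uniformly instead
#' (useful only for sensitivity checks, it over-represents the inner rim).
#'
#' @param n_per_surface Points per surface (default 200, giving 600 in all).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param torus_sampling `"area"` (default) or `"parameter"`.
#' @return A tibble with columns `x`, `y`, `z` and `label` (factor with
#'   levels `circle`, `sphere`, `torus`).
#'
#' @examples
#' head(generate_synthetic(10, seed = 1))
#' @export
generate_synthetic <- function(n_per_surface = 200, seed = NULL,
                               torus_sampling = c("area", "parameter")) {
  torus_sampling <- match.arg(torus_sampling)
  if (!is.numeric(n_per_surface) || n_per_surface < 1) {
    stop_invalid("n_per_surface must be a positive integer")
  }
  n <- as.integer(n_per_surface)
  gen <- function() {
    theta <- runif(n, 0, 2 * pi)
    circle <- cbind(x = 5 * cos(theta), y = 5 * sin(theta), z = 0)

    g <- matrix(rnorm(3 * n), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    sphere <- cbind(x = g[, 1], y = g[, 2], z = g[, 3] + 1)

    phi <- if (torus_sampling == "area") {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- runif(2 * n, 0, 2 * pi)
        acc <- runif(2 * n) <= (3 + cos(cand)) / 4
        out <- c(out, cand[acc])
      }
      out[seq_len(n)]
    } else {
      runif(n, 0, 2 * pi)
    }
    theta2 <- runif(n, 0, 2 * pi)
    r <- 3 + cos(phi)
    torus <- cbind(x = r * cos(theta2), y = r * sin(theta2), z = sin(phi) - 1)

    rbind(circle, sphere, torus)
  }
  pts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    label = factor(rep(c("circle", "sphere", "torus"), each = n),
                   levels = c("circle", "sphere", "torus")))
}

#' Isotropic Gaussian blob dataset
#'
#' Test-fixture generator: `k_classes` spherical Gaussian clusters of
#' `n_per_class` points in `d` dimensions with centres `separation` apart
#' along the first axis.
#'
#' @param k_classes Number of classes.
#' @param n_per_class Points per class.
#' @param d Dimension (default 2).
#' @param separation Distance between consecutive centres (default 10).
#' @param sd Within-class standard deviation (default 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with feature columns `x1..xd` and a `label` factor.
#' @export
generate_blobs <- function(k_classes = 2, n_per_class = 25, d = 2,
                           separation = 10, sd = 1, seed = NULL) {
  gen <- function() {
    pts <- lapply(seq_len(k_classes), function(i) {
      m <- matrix(rnorm(n_per_class * d, sd = sd), ncol = d)
      m[, 1] <- m[, 1] + (i - 1) * separation
      m
    })
    do.call(rbind, pts)
  }
  pts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  colnames(pts) <- paste0("x", seq_len(d))
  out <- tibble::as_tibble(as.data.frame(pts))
  out$label <- factor(rep(paste0("class_", seq_len(k_classes)),
                          each = n_per_class))
  out
}
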