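#' Vietoris-Rips filtration of a Euclidean point cloud
#'
#' Enumerates every simplex on at most `maxdim + 2` vertices whose appearance
#' scale does not exceed `maxscale`, ordered so that each simplex is preceded
#' by all of its faces. Simplices on one extra vertex beyond `maxdim + 1` are
#' included because they are needed to record the deaths of `maxdim`-dimensional
#' homology classes.
#'
#' Under the `radius` convention (the default) a simplex appears at half the
#' largest pairwise distance among its vertices, so that two points become
#' connected when balls of radius epsilon centred on them touch. The
#' `diameter` convention uses the full largest pairwise distance; the two
#' differ by a global factor of two only.
#'
#' When `steps = m` is given, appearance values are rounded up to the discrete
#' grid `eps_j = (j - 1) * maxscale / m`, `j = 1, ..., m + 1`, emulating a
#' filtration recorded at `m + 1` evenly spaced scales. The continuous
#' filtration is the limit of the grid as `m` grows.
#'
#' @inheritParams pairwise_distances
#' @param maxdim Highest homology dimension of interest (non-negative integer).
#' @param maxscale Largest appearance scale retained. Defaults to half the
#'   maximum pairwise distance (radius convention) or the maximum pairwise
#'   distance (diameter convention), so the full cloud becomes connected.
#' @param steps Optional number of grid steps `m`; `NULL` (default) keeps
#'   exact appearance values.
#' @param convention `"radius"` (default) or `"diameter"`.
#'
#' @return A tibble of class `rips_filtration` with columns `value`, `dim` and
#'   `vertices` (a list of 1-based integer vectors), sorted by
#'   `(value, dim, vertex tuple)`.
#'
#' @examples
#' rips_filtration(data.frame(x = c(0, 2, 6)), maxdim = 0, maxscale = 3)
#' @export
rips_filtration <- function(points, maxdim = 1, maxscale = NULL, steps = NULL,
                            convention = c("radius", "diameter")) {
  convention <- match.arg(convention)
  pts <- as_cloud_matrix(points)
  dm <- as.matrix(dist(pts))
  rips_filtration_dm(dm, maxdim = maxdim, maxscale = maxscale, steps = steps,
                     convention = convention)
}

#' Vietoris-Rips filtration from a precomputed distance matrix
#'
#' @param dm A symmetric distance matrix with zero diagonal.
#' @inheritParams rips_filtration
#' @return See [rips_filtration()].
#' @export
rips_filtration_dm <- function(dm, maxdim = 1, maxscale = NULL, steps = NULL,
                               convention = c("radius", "diameter")) {
  convention <- match.arg(convention)
  dm <- check_distance_matrix(dm)
  n <- nrow(dm)
  if (!is.numeric(maxdim) || length(maxdim) != 1 || maxdim < 0) {
    stop_invalid("maxdim must be a non-negative integer")
  }
  maxdim <- as.integer(maxdim)
  f <- scale_factor(convention)
  if (is.null(maxscale)) maxscale <- f * max(dm)
  if (!is.numeric(maxscale) || length(maxscale) != 1 || maxscale < 0) {
    stop_invalid("maxscale must be a non-negative number")
  }
  if (!is.null(steps)) {
    if (!is.numeric(steps) || length(steps) != 1 || steps < 1) {
      stop_invalid("steps must be a positive integer")
    }
    steps <- as.integer(steps)
  }

  # largest simplex size; one vertex beyond maxdim + 1, truncated to the cloud
  max_size <- min(maxdim + 2L, n)

  verts <- lapply(seq_len(n), identity)
  values <- rep(0, n)
  dims <- rep(0L, n)

  # edges below threshold
  if (max_size >= 2L && n >= 2L) {
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    dimnames(idx) <- NULL
    ev <- f * dm[idx]
    keep <- ev <= maxscale + 1e-12
    idx <- idx[keep, , drop = FALSE]
    ev <- ev[keep]
    if (nrow(idx) > 0) {
      verts <- c(verts, lapply(seq_len(nrow(idx)),
                               function(i) c(idx[i, 1], idx[i, 2])))
      values <- c(values, ev)
      dims <- c(dims, rep(1L, nrow(idx)))
    }
    # clique expansion for higher simplices
    prev <- lapply(seq_len(nrow(idx)), function(i) c(idx[i, 1], idx[i, 2]))
    prev_val <- ev
    adj <- matrix(FALSE, n, n)
    if (nrow(idx) > 0) {
      adj[idx] <- TRUE
      adj[idx[, c(2, 1), drop = FALSE]] <- TRUE
    }
    size <- 3L
    while (size <= max_size && length(prev) > 0) {
      cur <- list()
      cur_val <- numeric(0)
      for (i in seq_along(prev)) {
        s <- prev[[i]]
        top <- s[length(s)]
        if (top >= n) next
        for (v in seq.int(top + 1L, n)) {
          if (all(adj[s, v])) {
            val <- max(prev_val[i], f * dm[s, v])
            if (val <= maxscale + 1e-12) {
              cur[[length(cur) + 1L]] <- c(s, v)
              cur_val <- c(cur_val, val)
            }
          }
        }
      }
      if (length(cur) > 0) {
        verts <- c(verts, cur)
        values <- c(values, cur_val)
        dims <- c(dims, rep(size - 1L, length(cur)))
      }
      prev <- cur
      prev_val <- cur_val
      size <- size + 1L
    }
  }

  if (!is.null(steps)) values <- snap_to_grid(values, maxscale, steps)

  keys <- vapply(verts, function(v) paste(sprintf("%09d", v), collapse = ","),
                 character(1))
  ord <- order(values, dims, keys)
  out <- tibble::tibble(value = values[ord], dim = dims[ord],
                        vertices = verts[ord])
  structure(out,
            class = c("rips_filtration", class(out)),
            n_points = n, maxdim = maxdim, maxscale = maxscale,
            steps = steps, convention = convention)
}

scale_factor <- function(convention) {
  if (convention == "radius") 0.5 else 1
}

# Round values up to the smallest grid level eps_j = (j - 1) * maxscale / m
# that is >= value (within floating tolerance).
snap_to_grid <- function(values, maxscale, m) {
  if (maxscale == 0) return(values)
  j <- ceiling(values * m / maxscale - 1e-9)
  pmin(j, m) * maxscale / m
}

#' Write a filtration to a TSV file (debugging aid)
#'
#' Columns are `value`, `dim` and `vertices` (comma-joined 0-based indices).
#'
#' @param filt A [rips_filtration()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filtration <- function(filt, path) {
  stopifnot(inherits(filt, "rips_filtration"))
  out <- tibble::tibble(
    value = filt$value,
    dim = filt$dim,
    vertices = vapply(filt$vertices,
                      function(v) paste(v - 1L, collapse = ","), character(1)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
print.rips_filtration <- function(x, ...) {
  cat(sprintf(
    "Vietoris-Rips filtration: %d simplices on %d points (maxdim %d, maxscale %.6g, %s convention)\n",
    nrow(x), attr(x, "n_points"), attr(x, "maxdim"),
    attr(x, "maxscale"), attr(x, "convention")))
  NextMethod()
}
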