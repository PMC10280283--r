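#' Persistence diagrams
#'
#' A persistence diagram is stored as a tibble of class `persistence_diagram`
#' with columns `dimension` (integer), `birth` and `death` (`Inf` for
#' essential features of an uncapped diagram). The attribute `maxscale`
#' records the filtration cap and `capped` whether [cap_diagram()] has been
#' applied. Zero-length features (`birth == death`) are retained: they
#' contribute nothing to total persistence but keep the feature count of
#' dimension 0 equal to the number of points.
#'
#' @param dimension Integer vector of homological dimensions.
#' @param birth,death Numeric vectors of birth and death scales.
#' @param maxscale Filtration cap associated with the diagram.
#' @param capped Whether all deaths have been truncated at `maxscale`.
#'
#' @return A `persistence_diagram` tibble.
#' @export
persistence_diagram <- function(dimension = integer(), birth = numeric(),
                                death = numeric(), maxscale = Inf,
                                capped = FALSE) {
  if (any(death < birth - 1e-12)) stop_invalid("death scales must be >= birth scales")
  ord <- order(dimension, birth, death)
  out <- tibble::tibble(dimension = as.integer(dimension)[ord],
                        birth = as.numeric(birth)[ord],
                        death = as.numeric(death)[ord])
  structure(out, class = c("persistence_diagram", class(out)),
            maxscale = maxscale, capped = capped)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram: %d features (maxscale %.6g, %s)\n",
              nrow(x), attr(x, "maxscale"),
              if (isTRUE(attr(x, "capped"))) "capped" else "uncapped"))
  NextMethod()
}

#' Persistent homology by boundary-matrix reduction over F2
#'
#' The standard column-reduction algorithm: boundary columns are processed in
#' filtration order and each column is repeatedly added (mod 2) to by the
#' earlier column sharing its lowest nonzero row until it is empty (the
#' simplex creates a homology class) or its lowest row is unique (the simplex
#' kills the class created at that row). A pair `(sigma, tau)` contributes the
#' feature `(dim(sigma), value(sigma), value(tau))`; unpaired creators of
#' dimension at most `maxdim` are essential and reported with death `Inf`.
#'
#' @param filt A [rips_filtration()] (or any simplex table in valid
#'   filtration order with the same structure).
#'
#' @return An uncapped [persistence_diagram()].
#'
#' @examples
#' filt <- rips_filtration(data.frame(x = c(0, 2, 6)), maxdim = 0, maxscale = 3)
#' compute_persistence(filt)
#' @export
compute_persistence <- function(filt) {
  stopifnot(inherits(filt, "rips_filtration"))
  n <- nrow(filt)
  maxdim <- attr(filt, "maxdim")
  if (is.unsorted(filt$value)) {
    stop_invalid("filtration values are not non-decreasing")
  }

  key <- vapply(filt$vertices, paste, collapse = ",", FUN.VALUE = character(1))
  index <- new.env(hash = TRUE, size = max(n, 1L))
  for (i in seq_len(n)) assign(key[i], i, envir = index)

  cols <- vector("list", n)
  for (j in seq_len(n)) {
    v <- filt$vertices[[j]]
    if (length(v) == 1L) {
      cols[[j]] <- integer(0)
      next
    }
    fidx <- integer(length(v))
    for (r in seq_along(v)) {
      fk <- paste(v[-r], collapse = ",")
      fi <- get0(fk, envir = index, ifnotfound = NA_integer_)
      if (is.na(fi) || fi >= j) {
        stop_invalid(sprintf(
          "invalid filtration order: face (%s) of simplex (%s) does not precede it",
          fk, key[j]))
      }
      fidx[r] <- fi
    }
    cols[[j]] <- sort(fidx)
  }

  low_owner <- integer(n)
  death_of <- integer(n)
  creator <- logical(n)
  for (j in seq_len(n)) {
    col <- cols[[j]]
    repeat {
      if (length(col) == 0L) {
        creator[j] <- TRUE
        break
      }
      low <- col[length(col)]
      k <- low_owner[low]
      if (k == 0L) {
        low_owner[low] <- j
        death_of[low] <- j
        break
      }
      col <- xor_sorted(col, cols[[k]])
    }
    cols[[j]] <- col
  }

  dims <- filt$dim
  vals <- filt$value
  births <- which(creator)
  dimension <- integer(0); birth <- numeric(0); death <- numeric(0)
  for (b in births) {
    d <- death_of[b]
    if (d > 0L) {
      dimension <- c(dimension, dims[b])
      birth <- c(birth, vals[b])
      death <- c(death, vals[d])
    } else if (dims[b] <= maxdim) {
      dimension <- c(dimension, dims[b])
      birth <- c(birth, vals[b])
      death <- c(death, Inf)
    }
  }
  persistence_diagram(dimension, birth, death,
                      maxscale = attr(filt, "maxscale"), capped = FALSE)
}

# Symmetric difference of two sorted integer vectors (mod-2 column addition).
xor_sorted <- function(a, b) {
  x <- sort(c(a, b))
  x[!(duplicated(x) | duplicated(x, fromLast = TRUE))]
}

#' Dimension-0 persistence via union-find
#'
#' Fast path for connected-component (dimension-0) persistence: edges are
#' processed by ascending appearance scale and every merge of two distinct
#' components emits a feature `(0, 0, scale)`; components still alive at
#' `maxscale` are essential. The multiset of features is identical to the
#' dimension-0 restriction of [compute_persistence()].
#'
#' @inheritParams rips_filtration
#' @return An uncapped [persistence_diagram()] with `n` dimension-0 features
#'   for an `n`-point cloud.
#'
#' @examples
#' persistence_h0(data.frame(x = c(0, 2, 6)), maxscale = 3)
#' @export
persistence_h0 <- function(points, maxscale = NULL, steps = NULL,
                           convention = c("radius", "diameter")) {
  convention <- match.arg(convention)
  pts <- as_cloud_matrix(points)
  dm <- as.matrix(dist(pts))
  persistence_h0_dm(dm, maxscale = maxscale, steps = steps,
                    convention = convention)
}

#' @rdname persistence_h0
#' @inheritParams rips_filtration_dm
#' @export
persistence_h0_dm <- function(dm, maxscale = NULL, steps = NULL,
                              convention = c("radius", "diameter")) {
  convention <- match.arg(convention)
  dm <- check_distance_matrix(dm)
  n <- nrow(dm)
  f <- scale_factor(convention)
  if (is.null(maxscale)) maxscale <- f * max(dm)
  el <- dm_edge_list(dm, f, maxscale = maxscale, steps = steps)
  res <- kruskal_merges(n, el$i, el$j, el$value)
  deaths <- c(res$merges, rep(Inf, res$n_components))
  persistence_diagram(rep(0L, n), rep(0, n), deaths,
                      maxscale = maxscale, capped = FALSE)
}

#' Cap a persistence diagram at its maximum scale
#'
#' Replaces every death beyond `maxscale` (including `Inf`) by `maxscale`,
#' turning the diagram into the finite feature matrix used for scoring. The
#' operation is idempotent and leaves births untouched.
#'
#' @param diag A [persistence_diagram()].
#' @param maxscale Cap; defaults to the diagram's own `maxscale` attribute.
#' @return A capped `persistence_diagram`.
#' @export
cap_diagram <- function(diag, maxscale = NULL) {
  stopifnot(inherits(diag, "persistence_diagram"))
  if (is.null(maxscale)) maxscale <- attr(diag, "maxscale")
  if (!is.finite(maxscale)) {
    stop_invalid("a finite maxscale is required to cap a diagram")
  }
  persistence_diagram(diag$dimension, diag$birth, pmin(diag$death, maxscale),
                      maxscale = maxscale, capped = TRUE)
}

#' Total persistence of a capped diagram
#'
#' The sum of the lifespans `death - birth` over all features: the quantity
#' whose change under insertion of a query point drives the classifier score.
#'
#' @param diag A capped [persistence_diagram()].
#' @return A non-negative number.
#' @export
total_persistence <- function(diag) {
  stopifnot(inherits(diag, "persistence_diagram"))
  if (any(!is.finite(diag$death))) {
    stop_invalid("diagram has infinite deaths; apply cap_diagram() first")
  }
  sum(diag$death - diag$birth)
}

#' Read and write persistence diagrams as TSV
#'
#' Columns `dim`, `birth`, `death`; essential deaths are written as `"inf"`.
#' Writing then reading reproduces the diagram.
#'
#' @param diag A [persistence_diagram()].
#' @param path File path.
#' @return `write_diagram()` returns `path` invisibly; `read_diagram()`
#'   returns a `persistence_diagram`.
#' @export
write_diagram <- function(diag, path) {
  stopifnot(inherits(diag, "persistence_diagram"))
  out <- tibble::tibble(
    dim = diag$dimension, birth = diag$birth,
    death = ifelse(is.finite(diag$death),
                   sprintf("%.17g", diag$death), "inf"))
  out$birth <- sprintf("%.17g", out$birth)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_diagram
#' @param maxscale,capped Metadata to attach to the diagram read back.
#' @export
read_diagram <- function(path, maxscale = Inf, capped = FALSE) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    dim = readr::col_integer(),
    birth = readr::col_double(),
    death = readr::col_character()))
  death <- ifelse(tolower(x$death) == "inf", Inf, as.numeric(x$death))
  persistence_diagram(x$dim, x$birth, death, maxscale = maxscale,
                      capped = capped)
}
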