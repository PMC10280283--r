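#' Bottleneck distance between persistence diagrams
#'
#' The infimum over bijections (each diagram augmented with the diagonal taken
#' with infinite multiplicity) of the largest L-infinity displacement of any
#' matched pair. Matching is performed within each homological dimension and
#' the overall value is the maximum over dimensions; matching features across
#' dimensions is never meaningful for diagrams of a common construction.
#'
#' The value is computed exactly: the optimum is attained at one of finitely
#' many candidate costs (pairwise L-infinity distances and half-lifespans), so
#' a binary search over the sorted candidates combined with a bipartite
#' perfect-matching feasibility test yields the smallest feasible cost.
#'
#' Essential features (infinite death) can only be matched to essential
#' features of the other diagram: if the counts differ the distance is `Inf`,
#' otherwise they are matched by sorted birth.
#'
#' @param a,b Objects created by [persistence_diagram()] (or computed by
#'   [compute_persistence()] / [persistence_h0()]); cap both or neither.
#'
#' @return A non-negative number (possibly `Inf` for incompatible essential
#'   features).
#'
#' @examples
#' d1 <- persistence_diagram(0L, 0, 2)
#' d2 <- persistence_diagram(integer(), numeric(), numeric())
#' bottleneck_distance(d1, d2) # 1: (0, 2) projects to the diagonal
#' @export
bottleneck_distance <- function(a, b) {
  stopifnot(inherits(a, "persistence_diagram"), inherits(b, "persistence_diagram"))
  dims <- union(unique(a$dimension), unique(b$dimension))
  if (length(dims) == 0) return(0)
  max(vapply(dims, function(d) {
    pa <- diag_points(a, d)
    pb <- diag_points(b, d)
    ess <- essential_cost(pa, pb, p = Inf)
    if (!is.finite(ess) && is.na(ess)) return(Inf)
    max(ess, bottleneck_finite(pa$finite, pb$finite))
  }, numeric(1)))
}

# split features of one dimension into finite points and essential births
diag_points <- function(diag, d) {
  rows <- diag$dimension == d
  birth <- diag$birth[rows]
  death <- diag$death[rows]
  fin <- is.finite(death)
  list(finite = cbind(birth = birth[fin], death = death[fin]),
       essential = sort(birth[!fin]))
}

# cost contributed by essential features; NA marks incompatible counts
essential_cost <- function(pa, pb, p) {
  ea <- pa$essential
  eb <- pb$essential
  if (length(ea) != length(eb)) return(NA_real_)
  if (length(ea) == 0) return(0)
  d <- abs(ea - eb) # sorted matching is optimal on the line
  if (is.infinite(p)) max(d) else sum(d^p)
}

bottleneck_finite <- function(A, B) {
  A <- A[A[, 2] > A[, 1], , drop = FALSE] # zero-length points sit on the diagonal
  B <- B[B[, 2] > B[, 1], , drop = FALSE]
  na <- nrow(A)
  nb <- nrow(B)
  if (na == 0 && nb == 0) return(0)
  pa <- (A[, 2] - A[, 1]) / 2
  pb <- (B[, 2] - B[, 1]) / 2
  cross <- if (na > 0 && nb > 0) {
    outer(seq_len(na), seq_len(nb), function(i, j) {
      pmax(abs(A[i, 1] - B[j, 1]), abs(A[i, 2] - B[j, 2]))
    })
  } else {
    matrix(numeric(0), na, nb)
  }
  cand <- sort(unique(c(0, pa, pb, as.numeric(cross))))
  lo <- 1L
  hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (matching_feasible(cross, pa, pb, cand[mid])) hi <- mid else lo <- mid + 1L
  }
  cand[lo]
}

# Can every off-diagonal point be matched within delta, allowing projection
# to the diagonal? Perfect matching on the (na+nb) x (nb+na) augmented graph.
matching_feasible <- function(cross, pa, pb, delta) {
  tol <- delta + 1e-12
  na <- length(pa)
  nb <- length(pb)
  N <- na + nb
  M <- matrix(FALSE, N, N)
  if (na > 0 && nb > 0) M[seq_len(na), seq_len(nb)] <- cross <= tol
  if (na > 0) M[seq_len(na), nb + seq_len(na)] <- matrix(pa <= tol, na, na)
  if (nb > 0) M[na + seq_len(nb), seq_len(nb)] <- matrix(rep(pb <= tol, each = nb), nb, nb)
  if (na > 0 && nb > 0) M[na + seq_len(nb), nb + seq_len(na)] <- TRUE
  if (na == 0 || nb == 0) {
    # only diagonal projections are available
    return(all(c(pa, pb) <= tol))
  }
  g <- igraph::graph_from_biadjacency_matrix(M)
  igraph::max_bipartite_match(g)$matching_size == N
}

#' q-Wasserstein distance between persistence diagrams
#'
#' `(sum of matched L-infinity costs^p)^(1/p)` minimised over bijections with
#' diagonal projections allowed, computed per dimension on the augmented cost
#' matrix with an exact Hungarian assignment; the per-dimension sums of p-th
#' powers are added before the final root. `p = Inf` reduces to
#' [bottleneck_distance()].
#'
#' @inheritParams bottleneck_distance
#' @param p Order of the distance, a real number `>= 1` or `Inf`.
#' @return A non-negative number.
#' @export
wasserstein_distance <- function(a, b, p = 2) {
  stopifnot(inherits(a, "persistence_diagram"), inherits(b, "persistence_diagram"))
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 1) {
    stop_invalid("p must be a number >= 1 (or Inf)")
  }
  if (is.infinite(p)) return(bottleneck_distance(a, b))
  dims <- union(unique(a$dimension), unique(b$dimension))
  if (length(dims) == 0) return(0)
  total <- 0
  for (d in dims) {
    pa <- diag_points(a, d)
    pb <- diag_points(b, d)
    ess <- essential_cost(pa, pb, p = p)
    if (is.na(ess)) return(Inf)
    total <- total + ess + wasserstein_finite(pa$finite, pb$finite, p)
  }
  total^(1 / p)
}

wasserstein_finite <- function(A, B, p) {
  A <- A[A[, 2] > A[, 1], , drop = FALSE]
  B <- B[B[, 2] > B[, 1], , drop = FALSE]
  na <- nrow(A)
  nb <- nrow(B)
  if (na == 0 && nb == 0) return(0)
  pa <- ((A[, 2] - A[, 1]) / 2)^p
  pb <- ((B[, 2] - B[, 1]) / 2)^p
  if (na == 0) return(sum(pb))
  if (nb == 0) return(sum(pa))
  N <- na + nb
  C <- matrix(0, N, N)
  C[seq_len(na), seq_len(nb)] <- outer(seq_len(na), seq_len(nb), function(i, j) {
    pmax(abs(A[i, 1] - B[j, 1]), abs(A[i, 2] - B[j, 2]))
  })^p
  C[seq_len(na), nb + seq_len(na)] <- matrix(pa, na, na)
  C[na + seq_len(nb), seq_len(nb)] <- matrix(rep(pb, each = nb), nb, nb)
  hungarian_assignment(C)$cost
}

# Exact minimum-cost perfect assignment on a square cost matrix
# (shortest-augmenting-path Hungarian algorithm with potentials, O(n^3)).
hungarian_assignment <- function(a) {
  n <- nrow(a)
  u <- numeric(n)
  v <- numeric(n)
  assigned_row <- integer(n) # assigned_row[j] = row matched to column j
  for (i in seq_len(n)) {
    links <- integer(n)
    minv <- rep(Inf, n)
    used <- logical(n)
    cur_i <- i
    cur_j <- 0L
    j <- 0L
    repeat {
      j <- 0L
      delta <- Inf
      for (j1 in seq_len(n)) {
        if (!used[j1]) {
          cur <- a[cur_i, j1] - u[cur_i] - v[j1]
          if (cur < minv[j1]) {
            minv[j1] <- cur
            links[j1] <- cur_j
          }
          if (minv[j1] < delta) {
            delta <- minv[j1]
            j <- j1
          }
        }
      }
      for (j1 in seq_len(n)) {
        if (used[j1]) {
          u[assigned_row[j1]] <- u[assigned_row[j1]] + delta
          v[j1] <- v[j1] - delta
        } else {
          minv[j1] <- minv[j1] - delta
        }
      }
      u[i] <- u[i] + delta
      used[j] <- TRUE
      cur_j <- j
      if (assigned_row[j] == 0L) break
      cur_i <- assigned_row[j]
    }
    repeat {
      if (links[j] != 0L) {
        assigned_row[j] <- assigned_row[links[j]]
        j <- links[j]
      } else {
        assigned_row[j] <- i
        break
      }
    }
  }
  assignment <- integer(n)
  assignment[assigned_row] <- seq_len(n)
  list(cost = sum(a[cbind(assigned_row, seq_len(n))]), assignment = assignment)
}
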