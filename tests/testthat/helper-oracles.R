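# Independent oracles used to freeze expected values. Each is deliberately
# naive (brute force / enumeration) and shares no code with the package paths
# it checks.

random_cloud <- function(n, d = 2, range = 10) {
  matrix(runif(n * d, -range, range), ncol = d)
}

# entrywise double-loop Euclidean distances
brute_distances <- function(pts) {
  n <- nrow(pts)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    }
  }
  out
}

# minimum-spanning-tree total weight via vegan (independent of the package's
# Kruskal implementation)
mst_weight_vegan <- function(pts) {
  sum(vegan::spantree(dist(pts))$dist)
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exhaustive bottleneck / q-Wasserstein over all bijections of the augmented
# diagrams (off-diagonal points of a single dimension; diagonal projections
# allowed). A and B are 2-column (birth, death) matrices.
brute_diagram_distance <- function(A, B, p = Inf) {
  A <- A[A[, 2] > A[, 1], , drop = FALSE]
  B <- B[B[, 2] > B[, 1], , drop = FALSE]
  na <- nrow(A)
  nb <- nrow(B)
  N <- na + nb
  if (N == 0) return(0)
  # cost of matching left slot i (a-point or diagonal) to right slot j
  cost <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i <= na && j <= nb) {
        cost[i, j] <- max(abs(A[i, 1] - B[j, 1]), abs(A[i, 2] - B[j, 2]))
      } else if (i <= na) {
        cost[i, j] <- (A[i, 2] - A[i, 1]) / 2
      } else if (j <= nb) {
        cost[i, j] <- (B[j, 2] - B[j, 1]) / 2
      }
    }
  }
  best <- Inf
  for (perm in all_perms(N)) {
    c_ij <- cost[cbind(seq_len(N), perm)]
    val <- if (is.infinite(p)) max(c_ij) else sum(c_ij^p)
    best <- min(best, val)
  }
  if (is.infinite(p)) best else best^(1 / p)
}

# random small persistence diagram of a single dimension
random_diagram <- function(n, dim = 0L, range = 5) {
  b <- runif(n, 0, range)
  d <- b + runif(n, 0, range)
  persistence_diagram(rep(dim, n), b, d)
}

# rank of a 0/1 matrix over F2 by Gaussian elimination
gf2_rank <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2
  r <- 0L
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] == 1 & seq_len(nrow(M)) > r)
    if (length(piv) == 0) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    hit <- which(M[, j] == 1 & seq_len(nrow(M)) != r)
    if (length(hit) > 0) M[hit, ] <- (M[hit, , drop = FALSE] + rep(M[r, ], each = length(hit))) %% 2
  }
  r
}

# Brute-force Betti numbers of the Rips sublevel complex at scale s:
# enumerate all simplices up to dimension maxdim + 1 whose appearance value
# (factor * max pairwise distance) is <= s, build dense F2 boundary matrices
# and take ranks.
brute_betti <- function(pts, s, maxdim, convention = "radius") {
  f <- if (convention == "radius") 0.5 else 1
  dm <- as.matrix(dist(pts))
  n <- nrow(pts)
  simplices <- vector("list", maxdim + 2L) # by vertex-count
  simplices[[1]] <- as.list(seq_len(n))
  for (size in 2:(maxdim + 2L)) {
    if (size > n) {
      simplices[[size]] <- list()
      next
    }
    combs <- combn(n, size, simplify = FALSE)
    keep <- Filter(function(v) f * max(dm[v, v]) <= s + 1e-12, combs)
    simplices[[size]] <- keep
  }
  betti <- integer(maxdim + 1L)
  for (k in 0:maxdim) {
    ck <- simplices[[k + 1L]]
    ck1 <- simplices[[k + 2L]]
    nk <- length(ck)
    # rank of boundary_k : C_k -> C_{k-1}
    rank_k <- if (k == 0 || nk == 0) 0L else {
      ckm1 <- simplices[[k]]
      keymap <- stats::setNames(seq_along(ckm1),
                                vapply(ckm1, paste, collapse = ",", FUN.VALUE = ""))
      M <- matrix(0L, length(ckm1), nk)
      for (j in seq_len(nk)) {
        v <- ck[[j]]
        for (r in seq_along(v)) {
          M[keymap[[paste(v[-r], collapse = ",")]], j] <- 1L
        }
      }
      gf2_rank(M)
    }
    rank_k1 <- if (length(ck1) == 0 || nk == 0) 0L else {
      keymap <- stats::setNames(seq_len(nk),
                                vapply(ck, paste, collapse = ",", FUN.VALUE = ""))
      M <- matrix(0L, nk, length(ck1))
      for (j in seq_along(ck1)) {
        v <- ck1[[j]]
        for (r in seq_along(v)) {
          M[keymap[[paste(v[-r], collapse = ",")]], j] <- 1L
        }
      }
      gf2_rank(M)
    }
    betti[k + 1L] <- nk - rank_k - rank_k1
  }
  betti
}

# Betti numbers read off a diagram: features alive at scale s
betti_from_diagram <- function(diag, s, maxdim) {
  vapply(0:maxdim, function(k) {
    sum(diag$dimension == k & diag$birth <= s + 1e-12 & diag$death > s + 1e-12)
  }, integer(1))
}

# diagram-path classifier score: build the class and class+query filtrations
# explicitly and difference their capped total persistences (oracle for the
# union-find fast path)
diagram_path_score <- function(cloud, query, maxscale, maxdim = 0,
                               convention = "radius", steps = NULL) {
  ref <- total_persistence(cap_diagram(compute_persistence(
    rips_filtration(cloud, maxdim = maxdim, maxscale = maxscale,
                    steps = steps, convention = convention)), maxscale))
  aug <- total_persistence(cap_diagram(compute_persistence(
    rips_filtration(rbind(cloud, query), maxdim = maxdim, maxscale = maxscale,
                    steps = steps, convention = convention)), maxscale))
  abs(aug - ref)
}
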