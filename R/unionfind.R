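# Union-find (Kruskal) internals shared by the dimension-0 persistence fast
# path and the classifier. Edge values are in filtration-scale units, i.e.
# already multiplied by the convention factor and snapped to the grid when a
# step count is in force.

# Process edges in ascending value order; every union of two distinct
# components emits the edge, which is exactly a minimum-spanning-forest edge.
# Returns a list with the merge values (ascending) and, when `keep_edges`,
# the (i, j, value) matrix of the spanning forest.
kruskal_merges <- function(n, ei, ej, ev, keep_edges = FALSE) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[[parent[i]]]
      i <- parent[i]
    }
    i
  }
  ord <- order(ev)
  merges <- numeric(0)
  keep <- integer(0)
  n_merge <- 0L
  for (e in ord) {
    ri <- find(ei[e])
    rj <- find(ej[e])
    if (ri != rj) {
      parent[ri] <- rj
      n_merge <- n_merge + 1L
      merges[n_merge] <- ev[e]
      if (keep_edges) keep[n_merge] <- e
      if (n_merge == n - 1L) break
    }
  }
  list(
    merges = merges,
    edges = if (keep_edges) {
      cbind(i = ei[keep], j = ej[keep], value = ev[keep])
    },
    n_components = n - n_merge
  )
}

# All-pairs edge list of a distance matrix in filtration units.
dm_edge_list <- function(dm, factor, maxscale = Inf, steps = NULL) {
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  ev <- factor * dm[idx]
  if (!is.null(steps)) ev <- snap_to_grid(ev, maxscale, steps)
  keep <- ev <= maxscale + 1e-12
  list(i = idx[keep, 1], j = idx[keep, 2], value = ev[keep])
}

# Total persistence of the capped dimension-0 diagram of an n-point cloud
# whose minimum-spanning-forest merge values are `merges`: bars dying at or
# below maxscale keep their death, every other bar is capped at maxscale.
h0_capped_total <- function(merges, n, maxscale) {
  fin <- merges[merges <= maxscale + 1e-12]
  # single sum() pass so the result is bit-identical to total_persistence()
  # on the corresponding capped diagram (same ascending order of deaths)
  sum(c(fin, rep(maxscale, n - length(fin))))
}
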