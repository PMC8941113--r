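## Fixtures and independent oracles used across the suite.

## K4 with one pendant vertex attached to node 0; ids 0..4.
k4_pendant <- function() {
  brain_graph(0:4, rbind(c(0, 1), c(0, 2), c(0, 3), c(1, 2), c(1, 3),
                         c(2, 3), c(0, 4)))
}

complete_graph <- function(n) {
  brain_graph(seq_len(n) - 1L, t(utils::combn(seq_len(n) - 1L, 2)))
}

star_graph <- function(n_leaves) {
  brain_graph(0:n_leaves, cbind(0L, seq_len(n_leaves)))
}

er_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n) - 1L))
}

## Naive k-core pruning oracle: for ascending k, repeatedly delete any vertex
## of degree < k; a vertex deleted while building the k-core has coreness
## k - 1. Independent of the bucket implementation.
naive_coreness <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0L
  while (any(alive)) {
    k <- k + 1L
    repeat {
      deg <- as.vector(A %*% alive)
      low <- alive & deg < k
      if (!any(low)) break
      core[low] <- k - 1L
      alive[low] <- FALSE
    }
  }
  stats::setNames(core, igraph::V(g)$name)
}

## TRUE when the node sequence sorted by angle is a cyclic rotation (possibly
## reversed) of the natural order 1..n.
is_cyclic_order <- function(theta) {
  n <- length(theta)
  ord <- order(theta)
  fwd <- diff(c(ord, ord[1]))
  rev_ <- diff(c(rev(ord), rev(ord)[1]))
  ok <- function(d) sum(d == 1L) == n - 1L && sum(d == 1L - n) == 1L
  ok(fwd) || ok(rev_)
}

## simple label map over voxel ids with one label each
simple_labels <- function(ids, labels, scheme = "functional-7",
                          label_order = NULL) {
  label_map(scheme, stats::setNames(as.list(labels), as.character(ids)),
            label_order = label_order)
}

## small deterministic bold matrix
toy_bold <- function(values, tr = 0.72) {
  n <- nrow(values)
  bold_matrix(values, seq_len(n) - 1L, cbind(seq_len(n) - 1L, 0L, 0L),
              cbind(seq_len(n) - 1L, 0L, 0L), tr)
}
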