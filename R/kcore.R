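## k-core percolation. The k-core of a graph is the maximal subgraph in which
## every node keeps degree >= k; iteratively deleting nodes of degree < k and
## recomputing degrees reaches it. Coreness of a node is the largest k whose
## k-core contains it; k_max is the largest k with a non-empty k-core, and the
## k_max-core is the innermost surviving set.

## Batagelj-Zaversnik bucket decomposition on an adjacency list. Order of
## removals never changes the result (coreness is well-defined); the contract
## is verified against a naive pruning oracle in the tests.
core_numbers <- function(adj, deg) {
  n <- length(deg)
  if (n == 0L) stop_hc("empty graph")
  md <- max(deg)
  bin <- integer(md + 2L)                    # 1-based buckets for degrees 0..md
  for (d in deg) bin[d + 1L] <- bin[d + 1L] + 1L
  start <- cumsum(c(1L, bin))[1:(md + 1L)]   # start[d+1] = first slot of degree d
  pos <- integer(n)
  vert <- integer(n)
  nxt <- start
  for (v in seq_len(n)) {
    d <- deg[v]
    pos[v] <- nxt[d + 1L]
    vert[pos[v]] <- v
    nxt[d + 1L] <- nxt[d + 1L] + 1L
  }
  core <- deg
  for (i in seq_len(n)) {
    v <- vert[i]
    for (u in adj[[v]]) {
      if (core[u] > core[v]) {
        du <- core[u]
        pu <- pos[u]
        pw <- start[du + 1L]
        w <- vert[pw]
        if (u != w) {                        # swap u to the front of its bucket
          vert[pu] <- w; vert[pw] <- u
          pos[u] <- pw; pos[w] <- pu
        }
        start[du + 1L] <- start[du + 1L] + 1L
        core[u] <- du - 1L
      }
    }
  }
  core
}

#' k-core decomposition of a brain graph
#'
#' Assigns every voxel its coreness, reports \eqn{k_{max}} (the largest k with
#' a non-empty k-core; the (k_max + 1)-core is empty), the core-size curve
#' S(k), the k_max-core member set, and the number of connected components the
#' k_max-core splits into (audit of how the innermost structure fragments).
#'
#' @param g a \code{\link{brain_graph}} (simple, undirected).
#' @return An object of class \code{core_decomposition} with elements
#'   \code{coreness} (named by voxel id), \code{k_max}, \code{core_sizes}
#'   (S(k) for k = 1..k_max), \code{kmax_core} (integer voxel ids) and
#'   \code{n_components_kmax}.
#' @export
kcore_decomposition <- function(g) {
  if (igraph::vcount(g) == 0L) stop_hc("empty graph")
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  deg <- as.integer(igraph::degree(g))
  core <- core_numbers(adj, deg)
  ids <- graph_ids(g)
  names(core) <- as.character(ids)
  k_max <- max(core)
  ks <- seq_len(k_max)
  core_sizes <- vapply(ks, function(k) sum(core >= k), integer(1))
  names(core_sizes) <- as.character(ks)
  kmax_core <- ids[core == k_max]
  ncomp <- if (k_max >= 1L) {
    sub <- igraph::induced_subgraph(g, which(core == k_max))
    igraph::components(sub)$no
  } else 1L
  structure(list(coreness = core, k_max = k_max, core_sizes = core_sizes,
                 kmax_core = kmax_core, n_components_kmax = ncomp),
            class = "core_decomposition")
}

#' @export
print.core_decomposition <- function(x, ...) {
  cat(sprintf("k-core decomposition: %d voxels, k_max = %d, |k_max-core| = %d (%d component%s)\n",
              length(x$coreness), x$k_max, length(x$kmax_core),
              x$n_components_kmax, if (x$n_components_kmax == 1L) "" else "s"))
  invisible(x)
}

#' @export
summary.core_decomposition <- function(object, ...) {
  cat(sprintf("Voxels: %d\nk_max: %d\nk_max-core size: %d\n",
              length(object$coreness), object$k_max, length(object$kmax_core)))
  cat("Coreness distribution:\n")
  print(summary(as.numeric(object$coreness)))
  invisible(object)
}

#' @export
plot.core_decomposition <- function(x, ...) {
  S <- core_size_curve(x)
  graphics::plot(as.integer(names(S)), S, type = "s", xlab = "k",
                 ylab = "S(k)", main = "k-core size curve", ...)
  invisible(x)
}

#' Members of the k-core
#'
#' @param g a \code{\link{brain_graph}}.
#' @param k nonnegative integer; \code{k = 0} returns every node and
#'   \code{k > k_max} returns an empty set.
#' @return integer vector of voxel ids with coreness >= k.
#' @export
k_core <- function(g, k) {
  if (k < 0) stop_hc("k must be >= 0")
  ids <- graph_ids(g)
  if (k == 0) return(ids)
  d <- kcore_decomposition(g)
  ids[d$coreness >= k]
}

#' Core-size curve S(k)
#'
#' @param d a \code{core_decomposition}.
#' @return named integer vector S(k) for k = 1..k_max+1, with
#'   S(k_max + 1) = 0; non-increasing in k.
#' @export
core_size_curve <- function(d) {
  stopifnot(inherits(d, "core_decomposition"))
  S <- c(d$core_sizes, 0L)
  names(S) <- seq_len(d$k_max + 1L)
  S
}

#' Detect abrupt drops in a core-size curve
#'
#' @param S non-increasing core-size series indexed by k (as from
#'   \code{\link{core_size_curve}}).
#' @param min_drop minimum step size S(k-1) - S(k) to flag; defaults to 5\% of
#'   S(1), rounded up.
#' @return ascending integer vector of k values where the drop into k is at
#'   least \code{min_drop}.
#' @export
detect_abrupt_drops <- function(S, min_drop = NULL) {
  if (is.unsorted(rev(S))) stop_hc("S must be non-increasing")
  if (is.null(min_drop)) min_drop <- ceiling(0.05 * S[[1]])
  ks <- if (is.null(names(S))) seq_along(S) else as.integer(names(S))
  if (length(S) < 2L) return(integer(0))
  drops <- -diff(S)
  ks[-1][drops >= min_drop]
}

#' Per-voxel flag-plot records
#'
#' One record per (voxel, label) pair with the voxel's coreness: the data
#' behind a flag plot, where within each label the bars are sorted in
#' descending coreness. Voxels with no label are tagged \code{"none"}; voxels
#' with several labels yield one record per label.
#'
#' @param d a \code{core_decomposition}.
#' @param labels a \code{\link{label_map}} over the graph's voxel universe.
#' @return data frame with columns \code{voxel_id}, \code{label},
#'   \code{coreness}, ordered by label (label_order, then "none") and
#'   descending coreness within label.
#' @export
flag_data <- function(d, labels) {
  stopifnot(inherits(d, "core_decomposition"), inherits(labels, "label_map"))
  ids <- as.integer(names(d$coreness))
  recs <- lapply(seq_along(ids), function(i) {
    labs <- labels_of(labels, ids[i])
    if (!length(labs)) labs <- "none"
    data.frame(voxel_id = ids[i], label = labs,
               coreness = unname(d$coreness[i]))
  })
  out <- do.call(rbind, recs)
  order_levels <- c(labels$label_order, "none")
  out <- out[order(match(out$label, order_levels), -out$coreness, out$voxel_id), ]
  rownames(out) <- NULL
  out
}
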