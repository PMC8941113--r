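## Network construction: Pearson correlation matrices, positive-edge
## thresholding, largest component, and the scale-freeness criterion used to
## pick the operating threshold. Graphs are igraph objects whose vertex names
## are the voxel ids.

#' Build a brain graph from voxel ids and an edge list
#'
#' @param voxel_ids integer vector of node identifiers.
#' @param edges two-column matrix of voxel-id pairs (undirected); may have
#'   zero rows.
#' @return An undirected simple \code{igraph} graph with vertex attribute
#'   \code{name} set to the voxel ids.
#' @export
brain_graph <- function(voxel_ids, edges) {
  voxel_ids <- as.integer(voxel_ids)
  g <- igraph::make_empty_graph(n = length(voxel_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(voxel_ids))
  if (length(edges)) {
    edges <- matrix(as.character(edges), ncol = 2)
    if (any(edges[, 1] == edges[, 2])) stop_hc("self-loops are not allowed")
    g <- igraph::add_edges(g, t(edges))
  }
  if (any(igraph::count_multiple(g) > 1)) stop_hc("multi-edges are not allowed")
  g
}

## Voxel ids of a brain graph, as integers.
graph_ids <- function(g) as.integer(igraph::V(g)$name)

#' Unbiased sample variance
#'
#' \eqn{\hat\sigma^2(X) = \frac{1}{N-1}\sum_i (X_i - \bar X)^2}.
#'
#' @param x numeric vector, length >= 2.
#' @return nonnegative scalar.
#' @export
sample_variance <- function(x) {
  if (length(x) < 2L) stop_hc("need at least 2 observations")
  stats::var(x)
}

#' Sample Pearson correlation between two time series
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return correlation in [-1, 1].
#' @export
sample_pearson <- function(x, y) {
  if (length(x) != length(y)) stop_hc("series lengths differ")
  if (length(x) < 2L) stop_hc("need at least 2 observations")
  if (sample_variance(x) == 0 || sample_variance(y) == 0)
    stop_hc("undefined correlation: constant series")
  stats::cor(x, y)
}

#' Voxel-by-voxel Pearson correlation matrix
#'
#' @param b a \code{\link{bold_matrix}}.
#' @return An object of class \code{correlation_matrix}: list with the
#'   symmetric unit-diagonal \code{values} matrix and \code{voxel_ids}.
#' @export
correlation_matrix <- function(b) {
  stopifnot(inherits(b, "bold_matrix"))
  v <- apply(b$values, 1, stats::var)
  if (any(v == 0))
    stop_hc("undefined correlation: constant series at voxel id(s) ",
            paste(b$voxel_ids[v == 0], collapse = ", "))
  cm <- stats::cor(t(b$values))
  diag(cm) <- 1
  structure(list(values = cm, voxel_ids = b$voxel_ids),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d voxels\n", length(x$voxel_ids)))
  invisible(x)
}

#' Threshold a correlation matrix into a binary graph
#'
#' Keeps an edge (i, j) iff the correlation strictly exceeds the threshold;
#' only positive correlations can ever produce edges, and ties at exactly the
#' threshold are excluded.
#'
#' @param c a \code{\link{correlation_matrix}}.
#' @param rho_threshold threshold in (0, 1).
#' @return A \code{\link{brain_graph}}.
#' @export
threshold_graph <- function(c, rho_threshold) {
  stopifnot(inherits(c, "correlation_matrix"))
  check_scalar(rho_threshold, "rho_threshold")
  if (rho_threshold <= 0 || rho_threshold >= 1)
    stop_hc("rho_threshold must lie in (0, 1)")
  m <- c$values
  idx <- which(upper.tri(m) & m > rho_threshold, arr.ind = TRUE)
  edges <- cbind(c$voxel_ids[idx[, 1]], c$voxel_ids[idx[, 2]])
  brain_graph(c$voxel_ids, edges)
}

#' Largest connected component
#'
#' @param g a \code{\link{brain_graph}}.
#' @return list with \code{graph} (induced subgraph on the largest component;
#'   size ties broken towards the component containing the smallest voxel id)
#'   and \code{fraction} = |LCC| / |V|.
#' @export
largest_component <- function(g) {
  if (igraph::vcount(g) == 0L) stop_hc("empty graph")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    ids <- graph_ids(g)
    min_id <- vapply(best, function(b) min(ids[comp$membership == b]), numeric(1))
    best <- best[which.min(min_id)]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  list(graph = sub, fraction = max(comp$csize) / igraph::vcount(g))
}

#' Test a degree sequence for scale-freeness
#'
#' Bins the nonzero degrees logarithmically (bin ratio 2), estimates the
#' degree PDF per bin, and fits an ordinary least-squares line to the
#' decaying tail of the log-log plot: bins from the modal (peak-density) bin
#' onward, excluding bins holding fewer than \code{min_count} observations
#' (sparse-tail noise). The sequence passes when the fit retains at least 3
#' bins, the nonzero degrees span at least one decade, R^2 >= r2_min and the
#' slope is below slope_max — i.e. the log-log plot is straight and
#' decreasing over its body. Sequences whose trimmed fit has fewer than 3
#' bins (e.g. Poisson-like degree piles) fail rather than error; a hard error
#' is reserved for degenerate inputs (under 20 nonzero degrees, or fewer than
#' 3 distinct occupied bins before trimming).
#'
#' @param degrees integer degree sequence.
#' @param r2_min minimum R^2 for a pass (default 0.90).
#' @param slope_max the fitted slope must be strictly below this (default -1).
#' @param min_count minimum observations per fitted bin (default 5).
#' @return list with \code{slope}, \code{r_squared}, \code{passes_scalefree},
#'   \code{n_bins} (fitted bins) and the binned \code{pdf} data frame (all
#'   occupied bins, with a \code{fitted} flag).
#' @export
check_scale_freeness <- function(degrees, r2_min = 0.90, slope_max = -1,
                                 min_count = 5) {
  k <- degrees[degrees > 0]
  if (length(k) < 20L) stop_hc("need at least 20 nonzero degrees")
  lo <- min(k)
  nb <- ceiling(log2(max(k) / lo + 1e-9)) + 1L
  breaks <- lo * 2^(0:nb)
  bin <- findInterval(k, breaks, rightmost.closed = FALSE)
  cnt <- tabulate(bin, nbins = nb)
  width <- diff(breaks)
  centre <- sqrt(breaks[-length(breaks)] * breaks[-1])   # geometric mid
  occupied <- which(cnt > 0)
  if (length(occupied) < 3L) stop_hc("degenerate distribution: fewer than 3 bins")
  dens <- cnt / (length(k) * width)
  peak <- which.max(dens)
  fitted_bins <- occupied[occupied >= peak & cnt[occupied] >= min_count]
  pdf <- data.frame(k = centre[occupied], p = dens[occupied],
                    n = cnt[occupied], fitted = occupied %in% fitted_bins)
  spans_decade <- max(k) / lo >= 10
  if (length(fitted_bins) < 3L)
    return(list(slope = NA_real_, r_squared = NA_real_,
                passes_scalefree = FALSE, n_bins = length(fitted_bins),
                pdf = pdf))
  fit <- stats::lm(log10(dens[fitted_bins]) ~ log10(centre[fitted_bins]))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(slope = slope, r_squared = r2,
       passes_scalefree = spans_decade && r2 >= r2_min && slope < slope_max,
       n_bins = length(fitted_bins), pdf = pdf)
}

## One audit row for a candidate threshold.
threshold_report <- function(c, t, lcc_min, ...) {
  g <- threshold_graph(c, t)
  lc <- largest_component(g)
  sf <- tryCatch(check_scale_freeness(igraph::degree(g), ...),
                 error = function(e) list(slope = NA_real_,
                                          r_squared = NA_real_,
                                          passes_scalefree = FALSE))
  list(threshold = t, slope = sf$slope, r_squared = sf$r_squared,
       lcc_fraction = lc$fraction, n_edges = igraph::ecount(g),
       passes_scalefree = isTRUE(sf$passes_scalefree),
       passes_lcc = lc$fraction >= lcc_min)
}

#' Select the operating correlation threshold
#'
#' Tries each candidate in ascending order and returns the smallest threshold
#' whose binary graph has a scale-free degree distribution and a largest
#' connected component holding at least \code{lcc_min} of the voxels. All
#' candidate reports are returned for audit.
#'
#' @param c a \code{\link{correlation_matrix}}.
#' @param candidates ascending numeric vector of thresholds
#'   (default \code{c(0.30, 0.35, 0.40, 0.45, 0.50)}).
#' @param lcc_min minimum LCC fraction (default 0.8).
#' @param ... passed to \code{\link{check_scale_freeness}}.
#' @return list with \code{rho} (selected threshold) and \code{reports}.
#' @export
select_threshold <- function(c, candidates = c(0.30, 0.35, 0.40, 0.45, 0.50),
                             lcc_min = 0.8, ...) {
  if (is.unsorted(candidates)) stop_hc("candidates must be sorted ascending")
  reports <- lapply(candidates, function(t) threshold_report(c, t, lcc_min, ...))
  ok <- vapply(reports, function(r) r$passes_scalefree && r$passes_lcc, logical(1))
  if (!any(ok)) {
    near <- vapply(reports, function(r)
      sprintf("t=%.2f (scale-free: %s, lcc=%.2f)", r$threshold,
              r$passes_scalefree, r$lcc_fraction), character(1))
    stop_hc("no admissible threshold; near-misses: ", paste(near, collapse = "; "))
  }
  list(rho = candidates[which(ok)[1]], reports = reports)
}
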