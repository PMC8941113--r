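#' Run the core-composition pipeline on one subject
#'
#' Correlation matrix, positive-edge thresholding, largest component, k-core
#' percolation, k_max-core composition on the seven-category functional
#' scheme, and dominance classification. The hyperbolic embedding is a
#' separate, optional stage (\code{\link{hyper_embed}} on the returned largest
#' component) since coherence, not core detection, needs it.
#'
#' @param bold a \code{\link{bold_matrix}}.
#' @param labels a \code{\link{label_map}}; \code{"functional-15"} maps are
#'   merged to seven categories first.
#' @param rho_threshold correlation threshold (default 0.4, the operating
#'   point); pass \code{"auto"} to run \code{\link{select_threshold}} over the
#'   default candidate grid.
#' @return list with \code{graph} (thresholded graph), \code{lcc},
#'   \code{lcc_fraction}, \code{decomposition}, \code{profile} (classified
#'   \code{composition_profile}) and \code{pattern}.
#' @export
analyze_subject <- function(bold, labels, rho_threshold = 0.4) {
  stopifnot(inherits(bold, "bold_matrix"), inherits(labels, "label_map"))
  if (labels$scheme == "functional-15") labels <- combine_to_seven(labels)
  cm <- correlation_matrix(bold)
  if (identical(rho_threshold, "auto"))
    rho_threshold <- select_threshold(cm)$rho
  g <- threshold_graph(cm, rho_threshold)
  lc <- largest_component(g)
  d <- kcore_decomposition(lc$graph)
  prof <- kmaxcore_composition(d$kmax_core, labels, d$k_max)
  prof <- classify_pattern(prof)
  list(graph = g, lcc = lc$graph, lcc_fraction = lc$fraction,
       decomposition = d, profile = prof, pattern = prof$pattern)
}
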