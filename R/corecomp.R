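## k_max-core composition: which labelled subnetworks the innermost core is
## made of, whether one dominates, and which voxels recur across subjects.

#' Label composition of a k_max-core
#'
#' Counts, for every label, the core voxels carrying it; a voxel in several
#' categories increments every one of them (duplicates are kept, so fractions
#' can sum above 1). Fractions are counts over the core size.
#'
#' @param core integer vector of k_max-core voxel ids (non-empty).
#' @param labels a \code{\link{label_map}}.
#' @param kmax the coreness level of the core.
#' @return An object of class \code{composition_profile}: list with
#'   \code{scheme}, \code{counts}, \code{fractions}, \code{kmax},
#'   \code{core_size} and \code{pattern} (unset, \code{NA}).
#' @export
kmaxcore_composition <- function(core, labels, kmax) {
  stopifnot(inherits(labels, "label_map"))
  if (!length(core)) stop_hc("empty core")
  counts <- stats::setNames(integer(length(labels$label_order)),
                            labels$label_order)
  for (v in core) {
    for (lab in intersect(labels_of(labels, v), labels$label_order))
      counts[lab] <- counts[lab] + 1L
  }
  structure(list(scheme = labels$scheme, counts = as.list(counts),
                 fractions = as.list(counts / length(core)),
                 kmax = as.integer(kmax), core_size = length(core),
                 pattern = NA_character_),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("k_max-core composition [%s]: k_max = %d, core size = %d\n",
              x$scheme, x$kmax, x$core_size))
  fr <- unlist(x$fractions)
  for (lab in names(fr))
    cat(sprintf("  %-6s %4d  (%.1f%%)\n", lab, x$counts[[lab]], 100 * fr[lab]))
  if (!is.na(x$pattern)) cat("pattern:", x$pattern, "\n")
  invisible(x)
}

#' Classify the dominance pattern of a composition profile
#'
#' A subject is VN-dominant (resp. DMN-dominant) when more than 40\% of the
#' k_max-core voxels lie in the VN (resp. DMN) category; if both exceed the
#' cutoff the larger fraction wins, with an exact tie falling back to
#' distributed; otherwise the pattern is distributed. Defined only on the
#' seven-category functional scheme.
#'
#' @param p a \code{composition_profile} with scheme \code{"functional-7"}.
#' @param cutoff dominance cutoff (default 0.40, strict).
#' @return the profile with \code{pattern} set to one of
#'   \code{"DMN-dominant"}, \code{"VN-dominant"}, \code{"distributed"}.
#' @export
classify_pattern <- function(p, cutoff = 0.40) {
  stopifnot(inherits(p, "composition_profile"))
  if (p$scheme != "functional-7")
    stop_hc("classify_pattern requires the functional-7 scheme")
  f_dmn <- p$fractions[["DMN"]] %||% 0
  f_vn <- p$fractions[["VN"]] %||% 0
  p$pattern <- if (f_dmn > cutoff && f_vn > cutoff) {
    if (f_dmn > f_vn) "DMN-dominant"
    else if (f_vn > f_dmn) "VN-dominant"
    else "distributed"
  } else if (f_dmn > cutoff) "DMN-dominant"
  else if (f_vn > cutoff) "VN-dominant"
  else "distributed"
  p
}

#' Cross-subject common core
#'
#' Voxels present in the k_max-cores of at least \code{share_fraction} of the
#' subjects (inclusive: at 0.6 with 30 subjects, 18 hits qualify).
#'
#' @param cores list (>= 2) of integer voxel-id vectors, one per subject.
#' @param share_fraction required fraction of subjects in (0, 1] (default 0.6).
#' @return list with \code{voxels} (sorted ids), \code{share_fraction} and
#'   \code{counts} (per-voxel subject counts, all voxels ever in a core).
#' @export
common_core <- function(cores, share_fraction = 0.6) {
  if (length(cores) < 2L) stop_hc("need at least 2 subjects")
  if (!(share_fraction > 0 && share_fraction <= 1))
    stop_hc("share_fraction must be in (0, 1]")
  tab <- table(unlist(lapply(cores, unique)))
  need <- share_fraction * length(cores)
  counts <- stats::setNames(as.integer(tab), names(tab))
  vox <- sort(as.integer(names(counts)[counts >= need - 1e-9]))
  list(voxels = vox, share_fraction = share_fraction, counts = counts)
}

#' Degree records of k_max-core voxels in the original graph
#'
#' Reads each core voxel's degree off the full original graph (not the
#' core-induced subgraph) and tags it with its categories: the data behind a
#' stacked degree histogram. A voxel in several categories yields one record
#' per category; unlabeled voxels are tagged \code{"none"}.
#'
#' @param core integer k_max-core voxel ids, all present in \code{g}.
#' @param g the original \code{\link{brain_graph}}.
#' @param labels a \code{\link{label_map}} (seven-category functional scheme
#'   in the standard workflow).
#' @return data frame with columns \code{voxel_id}, \code{degree},
#'   \code{category}.
#' @export
kmaxcore_degree_histogram <- function(core, g, labels) {
  stopifnot(inherits(labels, "label_map"))
  ids <- graph_ids(g)
  if (!all(core %in% ids)) stop_hc("core voxel missing from graph")
  deg <- igraph::degree(g)[match(as.character(core), igraph::V(g)$name)]
  recs <- lapply(seq_along(core), function(i) {
    labs <- intersect(labels_of(labels, core[i]), labels$label_order)
    if (!length(labs)) labs <- "none"
    data.frame(voxel_id = core[i], degree = as.integer(deg[i]), category = labs)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
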