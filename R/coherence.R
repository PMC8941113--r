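## Angular coherence: the mean resultant length of a set of angles on the
## disc. xi e^{i phi} = (1/N) sum_k e^{i theta_k}; xi = 1 means perfectly
## concentrated, xi = 0 a balanced spread.

#' Angular coherence of a set of angles
#'
#' @param angles numeric vector of angles (radians), length >= 1.
#' @return list with \code{xi} in [0, 1] (mean resultant length) and
#'   \code{phi} in [0, 2 pi) (mean direction; 0 when xi = 0).
#' @export
angular_coherence <- function(angles) {
  if (!length(angles)) stop_hc("empty angle set")
  z <- mean(exp(1i * angles))
  list(xi = Mod(z), phi = if (Mod(z) > 0) wrap_angle(Arg(z)) else 0)
}

#' Angular coherence per label group on an embedded disc
#'
#' Computes the coherence of each label's voxels among those present in the
#' embedding (voxels outside the embedded largest component are excluded);
#' multi-membership voxels contribute to every label they carry. Labels with
#' no embedded member are absent from the output.
#'
#' @param e a \code{hyper_embedding} (or named angle vector).
#' @param labels a \code{\link{label_map}}.
#' @return data frame with columns \code{label}, \code{xi}, \code{phi},
#'   \code{n_voxels}, in \code{label_order}.
#' @export
group_coherence <- function(e, labels) {
  stopifnot(inherits(labels, "label_map"))
  theta <- angles_of(e)
  ids <- names(theta)
  rows <- lapply(labels$label_order, function(lab) {
    member <- vapply(ids, function(v) lab %in% labels_of(labels, v), logical(1))
    if (!any(member)) return(NULL)
    ac <- angular_coherence(theta[member])
    data.frame(label = lab, xi = ac$xi, phi = ac$phi, n_voxels = sum(member))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = character(0), xi = numeric(0), phi = numeric(0),
                      n_voxels = integer(0))
  rownames(out) <- NULL
  out
}

#' Cohort summary of per-subject angular coherences
#'
#' @param results list of per-subject \code{\link{group_coherence}} data
#'   frames.
#' @return long-format data frame with per-label \code{mean}, \code{median},
#'   \code{sd} and \code{n} (number of subjects contributing the label).
#' @export
cohort_coherence_table <- function(results) {
  if (!length(results)) stop_hc("need at least one subject")
  all_xi <- do.call(rbind, lapply(seq_along(results), function(i)
    cbind(results[[i]][, c("label", "xi")], subject = i)))
  labs <- unique(all_xi$label)
  out <- do.call(rbind, lapply(labs, function(lab) {
    x <- all_xi$xi[all_xi$label == lab]
    data.frame(label = lab, mean = mean(x), median = stats::median(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x))
  }))
  rownames(out) <- NULL
  out
}

#' Paired left-right comparison of angular coherence
#'
#' Two-sided paired Wilcoxon signed-rank test on per-subject (left - right)
#' coherence differences; alpha is conventionally 0.05 and no multiplicity
#' correction is applied (per-region reporting).
#'
#' @param left_xi,right_xi per-subject coherences, paired, length >= 6.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
laterality_test <- function(left_xi, right_xi) {
  if (length(left_xi) != length(right_xi)) stop_hc("samples must be paired")
  if (length(left_xi) < 6L) stop_hc("insufficient pairs (need >= 6)")
  d <- left_xi - right_xi
  if (all(d == 0)) return(list(statistic = 0, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(left_xi, right_xi, paired = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
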