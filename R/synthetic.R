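## Synthetic inputs with the statistical structure the analysis assumes:
## S1-model networks with known coordinates, block-correlated BOLD series,
## planted dense cores, and multi-subject cohorts with prescribed dominance
## patterns. All generators are pure functions of their seed.

#' Sample a network from the S1 model with known ground truth
#'
#' Angles are uniform on the circle; hidden degrees follow a Pareto(gamma)
#' law truncated at the natural cutoff kappa_0 n^{1/(gamma-1)}, with the
#' minimum kappa_0 solved so the expected hidden degree — hence the expected
#' mean degree — equals \code{mean_degree}; each pair connects independently
#' with the S1 connection probability.
#'
#' @param n number of nodes (>= 10).
#' @param gamma power-law exponent of the hidden-degree distribution (> 2).
#' @param mean_degree target mean degree.
#' @param beta clustering parameter (> 1).
#' @param seed RNG seed.
#' @return list with \code{graph} (a \code{\link{brain_graph}} on voxel ids
#'   0..n-1) and \code{truth}: theta_true, kappa_true, beta_true, gamma,
#'   mean_degree_target, kappa_0, mu, seed.
#' @export
sample_s1_network <- function(n, gamma, mean_degree, beta, seed = 1) {
  if (n < 10) stop_hc("n must be >= 10")
  if (gamma <= 2) stop_hc("gamma must be > 2 (finite mean)")
  if (beta <= 1) stop_hc("beta must be > 1 (no clustering regime otherwise)")
  set.seed(as.integer(seed))
  theta <- stats::runif(n, 0, 2 * pi)
  w <- n^(1 / (gamma - 1))                 # natural cutoff kappa_c / kappa_0
  trunc_mean <- ((gamma - 1) / (gamma - 2)) *
    (1 - w^(2 - gamma)) / (1 - w^(1 - gamma))
  kappa0 <- mean_degree / trunc_mean
  u <- stats::runif(n)
  kappa <- kappa0 * (1 - u * (1 - w^(1 - gamma)))^(-1 / (gamma - 1))
  mu <- s1_mu(beta, mean_degree)
  ed <- s1_sample_edges(theta, kappa, beta, mu)
  ids <- seq_len(n) - 1L
  g <- brain_graph(ids, cbind(ids[ed[, 1]], ids[ed[, 2]]))
  truth <- list(theta_true = stats::setNames(theta, as.character(ids)),
                kappa_true = stats::setNames(kappa, as.character(ids)),
                beta_true = beta, gamma = gamma,
                mean_degree_target = mean_degree,
                kappa_0 = kappa0, mu = mu, seed = seed)
  list(graph = g, truth = truth)
}

#' Simulate block-correlated BOLD time series
#'
#' Draws time points from a zero-mean, unit-variance block covariance:
#' correlation \code{within_r} inside a label block (optionally per-block) and
#' \code{between_r} across blocks, realised exactly through shared Gaussian
#' factors (one global, one per block, plus voxel noise), which guarantees a
#' positive semi-definite covariance whenever
#' \code{0 <= between_r <= within_r < 1}.
#'
#' @param n_voxels number of voxels.
#' @param partition a \code{\link{label_map}} assigning every voxel id
#'   (0..n_voxels-1) exactly one block label.
#' @param within_r within-block correlation; scalar or named vector by label.
#' @param between_r between-block correlation.
#' @param n_timepoints number of time points (default 1200).
#' @param noise_sd overall amplitude of the series (default 1; correlations
#'   are scale-free).
#' @param tr_seconds repetition time (default 0.72).
#' @param seed RNG seed.
#' @return A \code{\link{bold_matrix}}.
#' @export
simulate_bold <- function(n_voxels, partition, within_r, between_r,
                          n_timepoints = 1200, noise_sd = 1,
                          tr_seconds = 0.72, seed = 1) {
  stopifnot(inherits(partition, "label_map"))
  ids <- seq_len(n_voxels) - 1L
  block <- vapply(ids, function(v) {
    labs <- labels_of(partition, v)
    if (length(labs) != 1L) stop_hc("partition must give every voxel exactly one label")
    labs
  }, character(1))
  labs <- unique(block)
  wr <- if (length(within_r) == 1L && is.null(names(within_r)))
    stats::setNames(rep(within_r, length(labs)), labs) else within_r
  if (!all(labs %in% names(wr))) stop_hc("within_r missing for some blocks")
  wr <- wr[labs]
  if (any(between_r < 0) || any(wr >= 1) || any(between_r > wr))
    stop_hc("need 0 <= between_r <= within_r < 1 for a valid covariance")
  set.seed(as.integer(seed))
  t_g <- stats::rnorm(n_timepoints)                      # global factor
  x <- matrix(0, n_voxels, n_timepoints)
  for (b in labs) {
    vox <- which(block == b)
    t_b <- stats::rnorm(n_timepoints)                    # block factor
    shared <- sqrt(between_r) * t_g + sqrt(wr[[b]] - between_r) * t_b
    eps <- matrix(stats::rnorm(length(vox) * n_timepoints), length(vox))
    x[vox, ] <- rep(shared, each = length(vox)) + sqrt(1 - wr[[b]]) * eps
  }
  bold_matrix(noise_sd * x, ids, cbind(ids, 0L, 0L), cbind(ids, 0L, 0L),
              tr_seconds)
}

#' Plant a dense core in a background graph
#'
#' Connects all pairs inside \code{core_nodes} (a clique) or densifies them to
#' the stated edge density, leaving the rest of the graph untouched. Ground
#' truth for k_max-core recovery.
#'
#' @param background a \code{\link{brain_graph}}.
#' @param core_nodes voxel ids to densify; must exist in the graph.
#' @param density target within-core edge density (default 1 = clique).
#' @param seed RNG seed (used only when \code{density < 1}).
#' @return The augmented \code{\link{brain_graph}}.
#' @export
plant_core <- function(background, core_nodes, density = 1, seed = 1) {
  ids <- graph_ids(background)
  if (!all(core_nodes %in% ids)) stop_hc("core_nodes not all present in graph")
  if (length(core_nodes) < 2L) return(background)
  cn <- as.character(sort(as.integer(core_nodes)))
  pairs <- t(utils::combn(cn, 2))
  if (density < 1) {
    set.seed(as.integer(seed))
    pairs <- pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
  }
  have <- igraph::get_edge_ids(background, t(pairs), error = FALSE) > 0
  add <- pairs[!have, , drop = FALSE]
  if (nrow(add)) background <- igraph::add_edges(background, t(add))
  background
}

#' Cohort specification for the synthetic multi-subject generator
#'
#' Defaults mirror the regime of resting-state acquisitions with TR = 0.72 s
#' and 1200 time points; the correlation levels are chosen so that, at the
#' 0.4 operating threshold and this series length, the dominant block of a
#' dominant-pattern subject forms the k_max-core while the other blocks stay
#' clearly below it, and distributed subjects split the core evenly.
#'
#' @param n_subjects total subjects.
#' @param pattern_mix named integer vector with counts for
#'   \code{DMN-dominant}, \code{VN-dominant} and \code{distributed}; must sum
#'   to \code{n_subjects}.
#' @param n_voxels voxels per subject (default 140: seven blocks of 20).
#' @param n_timepoints series length (default 1200).
#' @param noise_sd series amplitude (default 1).
#' @param within_r baseline within-block correlation of distributed subjects
#'   (default 0.55).
#' @param between_r between-block correlation (default 0.36).
#' @param seed RNG seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 9,
                        pattern_mix = c("DMN-dominant" = 3, "VN-dominant" = 3,
                                        "distributed" = 3),
                        n_voxels = 140, n_timepoints = 1200, noise_sd = 1,
                        within_r = 0.55, between_r = 0.36, seed = 1) {
  if (sum(pattern_mix) != n_subjects)
    stop_hc("pattern_mix counts must sum to n_subjects")
  if (!(between_r >= 0 && between_r < within_r && within_r < 1))
    stop_hc("need 0 <= between_r < within_r < 1")
  structure(list(n_subjects = n_subjects, pattern_mix = pattern_mix,
                 n_voxels = n_voxels, n_timepoints = n_timepoints,
                 noise_sd = noise_sd, within_r = within_r,
                 between_r = between_r, seed = seed),
            class = "cohort_spec")
}

## Internal effect sizes of the dominance construction (see vignette):
## the dominant block is lifted to a correlation that survives thresholding as
## a complete block; non-dominant blocks of dominant-pattern subjects sit just
## above the operating threshold so they thin out and lose the coreness race.
dominant_r <- 0.70
background_r <- 0.42

#' Generate a synthetic cohort with prescribed dominance patterns
#'
#' Each subject is a block-structured BOLD matrix over the seven functional
#' categories. DMN-dominant (resp. VN-dominant) subjects get an elevated
#' within-block correlation in the DMN (resp. VN) block so that, after
#' thresholding, its voxels own the k_max-core; distributed subjects get
#' symmetric blocks.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list of subjects, each a list with \code{bold}
#'   (\code{\link{bold_matrix}}), \code{labels} (functional-7
#'   \code{\link{label_map}}) and \code{intended_pattern}.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labs7 <- scheme_labels("functional-7")
  n <- spec$n_voxels
  ## block sizes: equal sevenths for distributed subjects; for dominant
  ## subjects the dominant block takes a double share, so its clique outranks
  ## any incidental cross-block structure in coreness (and is the largest
  ## component even if the graph disconnects)
  partition_for <- function(dominant = NULL) {
    if (is.null(dominant)) {
      sizes <- stats::setNames(rep(n %/% 7L, 7L), labs7)
      sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1L
    } else {
      base <- n %/% 8L
      sizes <- stats::setNames(rep(base, 7L), labs7)
      sizes[dominant] <- 2L * base
      extra <- n - sum(sizes)
      others <- setdiff(labs7, dominant)
      sizes[others[seq_len(extra)]] <- sizes[others[seq_len(extra)]] + 1L
    }
    block_of <- rep(labs7, times = sizes[labs7])
    label_map("functional-7",
              stats::setNames(as.list(block_of), as.character(seq_len(n) - 1L)))
  }
  patterns <- rep(names(spec$pattern_mix), spec$pattern_mix)
  lapply(seq_along(patterns), function(i) {
    pat <- patterns[i]
    dominant <- switch(pat, "DMN-dominant" = "DMN", "VN-dominant" = "VN", NULL)
    partition <- partition_for(dominant)
    wr <- stats::setNames(rep(spec$within_r, length(labs7)), labs7)
    if (!is.null(dominant)) {
      wr[] <- background_r
      wr[dominant] <- dominant_r
    }
    bold <- simulate_bold(n, partition, wr, spec$between_r,
                          n_timepoints = spec$n_timepoints,
                          noise_sd = spec$noise_sd,
                          seed = (spec$seed %% 1000000L) * 1000L + i)
    list(bold = bold, labels = partition, intended_pattern = pat)
  })
}
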