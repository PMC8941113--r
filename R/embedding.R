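## S1/H2 hyperbolic embedding. A network is modelled by giving every node an
## angular (similarity) coordinate theta on the circle and a hidden degree
## kappa (popularity); pairs connect independently with the Fermi probability
##   p_ij = 1 / (1 + exp((beta/2) (d_ij - R_hat)))
## of their hyperbolic distance d_ij, which in the equivalent S1 form reads
##   p_ij = 1 / (1 + chi^beta),  chi = R dtheta / (mu kappa_i kappa_j),
## with R = n / (2 pi) the similarity-circle radius and mu the density
## constant tying expected degrees to the kappas. The embedding maximises the
## Bernoulli likelihood of the observed adjacency over the angles, after
## fitting beta to the observed clustering and the kappas to the observed
## degrees, starting from a Laplacian-eigenmap layout.

## density constant: E[degree_i] = kappa_i when angles are uniform
s1_mu <- function(beta, mean_degree) {
  beta * sin(pi / beta) / (2 * pi * mean_degree)
}

#' Exact hyperbolic distance (hyperbolic law of cosines)
#'
#' \eqn{\cosh(\zeta d) = \cosh(\zeta r_1)\cosh(\zeta r_2)
#'   (1 - \tanh(\zeta r_1)\tanh(\zeta r_2)\cos\Delta\theta)}.
#'
#' @param r1,r2 nonnegative radial coordinates (vectorized).
#' @param dtheta angular separation; wrapped into [0, pi].
#' @param curvature the curvature parameter zeta > 0 (default 1).
#' @return nonnegative distance(s).
#' @export
hyperbolic_distance_exact <- function(r1, r2, dtheta, curvature = 1) {
  if (any(r1 < 0) || any(r2 < 0)) stop_hc("radial coordinates must be >= 0")
  if (curvature <= 0) stop_hc("curvature must be > 0")
  dt <- angle_sep(0, dtheta)
  z <- curvature
  ch <- cosh(z * r1) * cosh(z * r2) *
    (1 - tanh(z * r1) * tanh(z * r2) * cos(dt))
  acosh(pmax(ch, 1)) / z
}

#' Approximate hyperbolic distance
#'
#' \eqn{d \approx r_1 + r_2 + 2\ln(\Delta\theta/2)}, valid when
#' \eqn{\Delta\theta > \sqrt{e^{-2 r_1} + e^{-2 r_2}}}.
#'
#' @param r1,r2 radial coordinates.
#' @param dtheta angular separation in (0, pi].
#' @return approximate distance.
#' @export
hyperbolic_distance_approx <- function(r1, r2, dtheta) {
  dt <- angle_sep(0, dtheta)
  if (any(dt <= sqrt(exp(-2 * r1) + exp(-2 * r2))))
    stop_hc("validity bound violated: dtheta <= sqrt(exp(-2 r1) + exp(-2 r2)); ",
            "use the exact form")
  r1 + r2 + 2 * log(dt / 2)
}

#' Fermi connection probability of the S1/H2 model
#'
#' @param d hyperbolic distance(s).
#' @param beta clustering (inverse temperature) parameter, > 1.
#' @param R_hat outermost radial coordinate (distance scale); p = 1/2 at
#'   d = R_hat.
#' @return probability in (0, 1), monotone decreasing in d.
#' @export
connection_probability <- function(d, beta, R_hat) {
  if (beta <= 1) stop_hc("beta must be > 1")
  1 / (1 + exp(pmin((beta / 2) * (d - R_hat), 700)))
}

## Interpolator for I(L) = int_0^L du / (1 + u^beta), the angular integral of
## the S1 connection probability; built once per beta on a log grid.
make_chi_integral <- function(beta) {
  v <- seq(-30, 30, length.out = 4001)
  bv <- beta * v
  li <- v - ifelse(bv > 30, bv, log1p(exp(bv)))
  f <- exp(li)
  cumI <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(v))) + exp(v[1])
  function(L) {
    vq <- log(L)
    out <- numeric(length(L))
    small <- vq < -25
    out[small] <- L[small]
    out[!small] <- stats::approx(v, cumI, pmin(vq[!small], 30), rule = 2)$y
    out
  }
}

## Model-expected degrees for hidden degrees kappa under beta (angles
## integrated out): E[p_ij] = (c/pi) I(pi/c), c = mu kappa_i kappa_j / R.
expected_degrees <- function(kappa, beta, mu, R, Ifun = make_chi_integral(beta)) {
  cmat <- (mu / R) * outer(kappa, kappa)
  ep <- (cmat / pi) * Ifun(pi / cmat)
  diag(ep) <- 0
  rowSums(ep)
}

#' Infer hidden degrees from an observed graph
#'
#' Fixed-point adjustment of each node's hidden degree kappa until the
#' model-expected degree (with angles integrated out) matches the observed
#' degree to within \code{tol} in sup-norm.
#'
#' @param g a connected \code{\link{brain_graph}}.
#' @param beta model clustering parameter, > 1.
#' @param tol sup-norm tolerance on expected vs observed degree (default 0.1).
#' @param max_iter iteration cap (default 1000).
#' @return numeric vector of hidden degrees named by voxel id, with attributes
#'   \code{mu} and \code{residual}.
#' @export
infer_hidden_degrees <- function(g, beta, tol = 0.1, max_iter = 1000) {
  if (igraph::vcount(g) == 0L) stop_hc("empty graph")
  if (beta <= 1) stop_hc("beta must be > 1")
  k_obs <- as.numeric(igraph::degree(g))
  n <- length(k_obs)
  R <- n / (2 * pi)
  mu <- s1_mu(beta, mean(k_obs))
  Ifun <- make_chi_integral(beta)
  kappa <- pmax(k_obs, 1e-3)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    ek <- expected_degrees(kappa, beta, mu, R, Ifun)
    resid <- max(abs(ek - k_obs))
    if (resid <= tol) break
    kappa <- pmax(kappa * (pmax(k_obs, 1e-3) / pmax(ek, 1e-6))^0.5, 1e-3)
  }
  if (resid > tol)
    stop_hc(sprintf(
      "hidden-degree inference did not converge: residual %.3g > tol %.3g",
      resid, tol))
  names(kappa) <- igraph::V(g)$name
  attr(kappa, "mu") <- mu
  attr(kappa, "residual") <- resid
  kappa
}

## Sample one S1 graph with fixed hidden degrees and given angles.
s1_sample_edges <- function(theta, kappa, beta, mu) {
  n <- length(theta)
  R <- n / (2 * pi)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dt <- angle_sep(theta[ut[, 1]], theta[ut[, 2]])
  chi <- R * dt / (mu * kappa[ut[, 1]] * kappa[ut[, 2]])
  p <- 1 / (1 + chi^beta)
  ut[stats::runif(nrow(ut)) < p, , drop = FALSE]
}

## Mean local clustering coefficient, NaN (degree < 2) nodes dropped.
mean_local_clustering <- function(g) {
  tr <- igraph::transitivity(g, type = "local")
  mean(tr, na.rm = TRUE)
}

#' Estimate the clustering parameter beta
#'
#' Bisection on beta in (1, 10]: for each candidate, hidden degrees are fitted
#' to the observed degree sequence and synthetic S1 graphs with those hidden
#' degrees (uniform angles) are sampled; beta is adjusted until the model's
#' mean local clustering matches the graph's, to within \code{tol}. Expected
#' clustering is monotone increasing in beta.
#'
#' @param g a \code{\link{brain_graph}} containing at least one triangle.
#' @param tol tolerance on the clustering match (default 0.01).
#' @param n_samples synthetic graphs per candidate beta (default 2).
#' @param seed RNG seed for the synthetic samples (default 1).
#' @return estimated beta in (1, 10], with attribute \code{clustering_obs}.
#' @export
estimate_beta <- function(g, tol = 0.01, n_samples = 2, seed = 1) {
  c_obs <- igraph::transitivity(g, type = "global")
  if (!is.finite(c_obs) || c_obs <= 0) stop_hc("graph has no triangles")
  c_obs <- mean_local_clustering(g)
  k_obs <- as.numeric(igraph::degree(g))
  n <- length(k_obs)
  model_clustering <- function(beta) {
    kap <- tryCatch(infer_hidden_degrees(g, beta, tol = max(0.1, 0.001 * n)),
                    error = function(e) NULL)
    if (is.null(kap)) kap <- pmax(k_obs, 1e-3)
    mu <- attr(kap, "mu") %||% s1_mu(beta, mean(k_obs))
    mean(vapply(seq_len(n_samples), function(s) {
      theta <- stats::runif(n, 0, 2 * pi)
      ed <- s1_sample_edges(theta, as.numeric(kap), beta, mu)
      mean_local_clustering(brain_graph(seq_len(n) - 1L,
                                        cbind(ed[, 1] - 1L, ed[, 2] - 1L)))
    }, numeric(1)))
  }
  set.seed(as.integer(seed))
  lo <- 1.05; hi <- 10
  c_lo <- model_clustering(lo)
  if (c_lo >= c_obs) return(structure(lo, clustering_obs = c_obs))
  c_hi <- model_clustering(hi)
  if (c_hi <= c_obs) return(structure(hi, clustering_obs = c_obs))
  for (it in seq_len(20)) {
    mid <- (lo + hi) / 2
    c_mid <- model_clustering(mid)
    if (abs(c_mid - c_obs) <= tol || (hi - lo) < 0.01) {
      lo <- hi <- mid
      break
    }
    if (c_mid < c_obs) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, clustering_obs = c_obs)
}

#' Laplacian-eigenmap initialization of the angular coordinates
#'
#' Takes the two leading nontrivial eigenvectors of the symmetric normalized
#' graph Laplacian (in the D^{-1/2}-scaled coordinates) and reads initial
#' angles off their 2D plane with atan2.
#'
#' @param g a connected \code{\link{brain_graph}}.
#' @return numeric vector of angles in [0, 2 pi), named by voxel id.
#' @export
initialize_angles_le <- function(g) {
  if (!igraph::is_connected(g)) stop_hc("graph must be connected")
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  dsq <- 1 / sqrt(pmax(rowSums(A), 1))
  L <- diag(n) - (dsq * A) * rep(dsq, each = n)   # I - D^-1/2 A D^-1/2
  es <- eigen(L, symmetric = TRUE)
  v1 <- dsq * es$vectors[, n - 1L]
  v2 <- dsq * es$vectors[, n - 2L]
  theta <- wrap_angle(atan2(v2, v1))
  names(theta) <- igraph::V(g)$name
  theta
}

## Shared scale constants of a fitted S1 model on graph g.
s1_scales <- function(n, mean_degree, beta) {
  mu <- s1_mu(beta, mean_degree)
  R <- n / (2 * pi)
  list(mu = mu, R = R, lmuR = log(R) - log(mu))
}

## Hyperbolic radii from hidden degrees: r_i = R_hat - 2 ln(kappa_i/kappa_0),
## R_hat = 2 ln(2R / (mu kappa_0^2)); densest node innermost.
radial_coordinates <- function(kappa, mu, R) {
  kappa0 <- min(kappa)
  R_hat <- 2 * log(2 * R / (mu * kappa0^2))
  list(r = R_hat - 2 * log(kappa / kappa0), R_hat = R_hat, kappa0 = kappa0)
}

#' Maximum-likelihood refinement of the angular coordinates
#'
#' Coordinate-wise hill climbing of the Bernoulli log-likelihood of the
#' observed adjacency under the S1 connection probability: each sweep visits
#' the nodes in random order and moves each node to the best of its current
#' angle and \code{n_candidates - 1} von Mises proposals concentrated around
#' the degree-weighted circular mean of its neighbours' angles (proposal
#' spread tightens over sweeps). The likelihood trace is non-decreasing;
#' sweeps stop when the per-sweep improvement falls below \code{tol}.
#'
#' @param g a connected \code{\link{brain_graph}}.
#' @param theta0 initial angles (same order as the graph's vertices).
#' @param kappa hidden degrees (e.g. from \code{\link{infer_hidden_degrees}}).
#' @param beta clustering parameter, > 1.
#' @param seed RNG seed for proposal draws and sweep order.
#' @param max_sweeps sweep cap (default 30).
#' @param n_candidates candidate angles per node per sweep (default 20).
#' @param tol minimal per-sweep log-likelihood improvement (default 1e-4).
#' @return A \code{hyper_embedding} object; see \code{\link{hyper_embed}}.
#' @export
refine_angles_ml <- function(g, theta0, kappa, beta, seed = 1, max_sweeps = 30,
                             n_candidates = 20, tol = 1e-4) {
  if (beta <= 1) stop_hc("beta must be > 1")
  n <- igraph::vcount(g)
  stopifnot(length(theta0) == n, length(kappa) == n)
  kappa <- as.numeric(kappa)
  deg <- as.numeric(igraph::degree(g))
  sc <- s1_scales(n, mean(deg), beta)
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  lkap <- log(kappa)
  theta <- as.numeric(theta0)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  ll <- .s1_loglik_cpp(theta, lkap, edges, beta, sc$lmuR)
  trace <- ll
  set.seed(as.integer(seed))
  for (s in seq_len(max_sweeps)) {
    # degree-weighted circular mean of neighbour angles
    zre <- as.vector(A %*% (deg * cos(theta)))
    zim <- as.vector(A %*% (deg * sin(theta)))
    mu_nb <- ifelse(zre^2 + zim^2 < 1e-24, theta, atan2(zim, zre))
    sigma <- max(0.05, (pi / 2) * 0.8^(s - 1))
    kvm <- 1 / sigma^2
    prop <- matrix(rvonmises(n * (n_candidates - 1L), rep(mu_nb, n_candidates - 1L),
                             kvm), nrow = n)
    ord <- sample.int(n)
    res <- .s1_sweep_cpp(theta, lkap, edges, beta, sc$lmuR, prop, ord)
    if (!is.finite(res$loglik)) stop_hc("non-finite likelihood during refinement")
    improvement <- res$loglik - ll
    theta <- res$theta
    ll <- res$loglik
    trace <- c(trace, ll)
    if (improvement < tol) break
  }
  rad <- radial_coordinates(kappa, sc$mu, sc$R)
  new_hyper_embedding(g, wrap_angle(theta), kappa, beta, rad, ll, trace)
}

new_hyper_embedding <- function(g, theta, kappa, beta, rad, loglik, trace) {
  structure(list(
    voxel_id = graph_ids(g),
    r = unname(rad$r), theta = unname(theta), kappa = unname(kappa),
    degree = as.numeric(igraph::degree(g)),
    beta = as.numeric(beta), R_hat = rad$R_hat, curvature = 1,
    loglik = loglik, trace = trace, n = igraph::vcount(g),
    graph = g), class = "hyper_embedding")
}

#' Embed a brain graph on the hyperbolic disc (S1/H2 model)
#'
#' The full embedding pipeline: fit beta to the observed clustering, infer
#' hidden degrees from the degree sequence, initialize angles with Laplacian
#' eigenmaps, refine them by maximum likelihood, and convert hidden degrees to
#' radial coordinates (curvature fixed at 1; the densest node sits innermost,
#' the outermost radius is \code{R_hat}).
#'
#' @param g a connected \code{\link{brain_graph}} (e.g. a largest component
#'   from \code{\link{largest_component}}).
#' @param seed RNG seed controlling every stochastic step.
#' @param beta optional fixed beta; when NULL (default) it is estimated.
#' @param ... passed to \code{\link{refine_angles_ml}}.
#' @return An object of class \code{hyper_embedding} with per-node
#'   \code{r}, \code{theta}, \code{kappa}, \code{degree}, the model parameters
#'   \code{beta}, \code{R_hat}, \code{curvature}, the final \code{loglik} and
#'   its sweep \code{trace}.
#' @export
hyper_embed <- function(g, seed = 1, beta = NULL, ...) {
  if (!igraph::is_connected(g)) stop_hc("graph must be connected; embed the largest component")
  if (is.null(beta)) beta <- estimate_beta(g, seed = seed)
  kappa <- infer_hidden_degrees(g, as.numeric(beta))
  theta0 <- initialize_angles_le(g)
  refine_angles_ml(g, theta0, kappa, as.numeric(beta), seed = seed, ...)
}

#' Align two embeddings under disc symmetries
#'
#' The hyperbolic disc is only identified up to rotation and reflection.
#' This finds the rotation (and optional reflection) of the second embedding
#' that best matches the first, by maximizing the modulus of the mean phasor
#' of the angle differences (the circular correlation of the two angle sets at
#' the optimal rotation).
#'
#' @param e1,e2 \code{hyper_embedding} objects over the same voxel set.
#' @return list with \code{rotation} (radians), \code{reflected} (flag),
#'   \code{similarity} in [0, 1], and \code{aligned_theta}: e2's angles mapped
#'   into e1's frame.
#' @export
align_embeddings <- function(e1, e2) {
  t1 <- angles_of(e1); t2 <- angles_of(e2)
  if (!identical(names(t1), names(t2))) {
    if (!setequal(names(t1), names(t2))) stop_hc("node sets differ")
    t2 <- t2[names(t1)]
  }
  z_dir <- mean(exp(1i * (t2 - t1)))
  z_ref <- mean(exp(1i * (t2 + t1)))
  if (Mod(z_ref) > Mod(z_dir)) {
    rot <- wrap_angle(Arg(z_ref))
    list(rotation = rot, reflected = TRUE, similarity = Mod(z_ref),
         aligned_theta = wrap_angle(rot - t2))
  } else {
    rot <- wrap_angle(Arg(z_dir))
    list(rotation = rot, reflected = FALSE, similarity = Mod(z_dir),
         aligned_theta = wrap_angle(t2 - rot))
  }
}

## Named angle vector from an embedding (or a bare named vector of angles).
angles_of <- function(e) {
  if (inherits(e, "hyper_embedding")) {
    out <- e$theta
    names(out) <- as.character(e$voxel_id)
    out
  } else if (is.numeric(e) && !is.null(names(e))) e
  else stop_hc("expected a hyper_embedding or a named angle vector")
}

#' @export
print.hyper_embedding <- function(x, ...) {
  cat(sprintf("S1/H2 hyperbolic embedding: %d nodes\n", x$n))
  cat(sprintf("  beta = %.3f, R_hat = %.3f, curvature = %g\n",
              x$beta, x$R_hat, x$curvature))
  cat(sprintf("  log-likelihood = %.2f after %d sweep(s)\n",
              x$loglik, length(x$trace) - 1L))
  invisible(x)
}

#' @export
summary.hyper_embedding <- function(object, ...) {
  print(object)
  cat(sprintf("  kappa in [%.2f, %.2f]; degree in [%d, %d]\n",
              min(object$kappa), max(object$kappa),
              min(object$degree), max(object$degree)))
  cat(sprintf("  radius in [%.2f, %.2f]\n", min(object$r), max(object$r)))
  invisible(object)
}

#' @export
coef.hyper_embedding <- function(object, ...) {
  m <- cbind(r = object$r, theta = object$theta, kappa = object$kappa)
  rownames(m) <- as.character(object$voxel_id)
  m
}

#' @export
logLik.hyper_embedding <- function(object, ...) {
  structure(object$loglik, df = object$n + 1, class = "logLik")
}

#' Fitted connection probabilities of an embedding
#'
#' @param object a \code{hyper_embedding}.
#' @param pairs optional 2-column matrix of voxel-id pairs; by default all
#'   edges of the embedded graph.
#' @param ... unused.
#' @return data frame with the pair, its hyperbolic distance and the model
#'   connection probability.
#' @export
predict.hyper_embedding <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) pairs <- igraph::as_edgelist(object$graph, names = TRUE)
  i <- match(as.character(pairs[, 1]), as.character(object$voxel_id))
  j <- match(as.character(pairs[, 2]), as.character(object$voxel_id))
  if (anyNA(i) || anyNA(j)) stop_hc("pair voxel ids not in embedding")
  d <- hyperbolic_distance_exact(object$r[i], object$r[j],
                                 angle_sep(object$theta[i], object$theta[j]),
                                 object$curvature)
  data.frame(voxel_i = object$voxel_id[i], voxel_j = object$voxel_id[j],
             distance = d,
             p = connection_probability(d, object$beta, object$R_hat))
}

#' Simulate graphs from a fitted embedding
#'
#' Draws Bernoulli adjacencies from the fitted connection probabilities.
#'
#' @param object a \code{hyper_embedding}.
#' @param nsim number of graphs (default 1).
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of \code{\link{brain_graph}} objects.
#' @export
simulate.hyper_embedding <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- object$n
  sc <- s1_scales(n, mean(object$degree), object$beta)
  out <- lapply(seq_len(nsim), function(s) {
    ed <- s1_sample_edges(object$theta, object$kappa, object$beta, sc$mu)
    brain_graph(object$voxel_id,
                cbind(object$voxel_id[ed[, 1]], object$voxel_id[ed[, 2]]))
  })
  if (nsim == 1) out[[1]] else out
}

#' Degree residuals of a fitted embedding
#'
#' Observed minus model-expected degree per node (angles integrated out):
#' large residuals flag nodes whose popularity the fit misses.
#'
#' @param object a \code{hyper_embedding}.
#' @param ... unused.
#' @return numeric vector named by voxel id.
#' @export
residuals.hyper_embedding <- function(object, ...) {
  sc <- s1_scales(object$n, mean(object$degree), object$beta)
  ek <- expected_degrees(object$kappa, object$beta, sc$mu, sc$R)
  out <- object$degree - ek
  names(out) <- as.character(object$voxel_id)
  out
}

#' @export
plot.hyper_embedding <- function(x, highlight = NULL, labels = NULL, ...) {
  disc_scatter(x, highlight = highlight, labels = labels, ...)
  invisible(x)
}

#' Empirical connection-probability calibration of an embedding
#'
#' Bins all node pairs by embedded hyperbolic distance and compares the
#' empirical link frequency per bin with the model's Fermi curve; the mean
#' absolute deviation over the populated bins measures how faithfully the
#' embedding reproduces the connection rule.
#'
#' @param e a \code{hyper_embedding}.
#' @param n_bins number of distance bins (default 20).
#' @param min_pairs minimum pairs per bin to enter the comparison (default 50).
#' @return list with the per-bin table and \code{mean_abs_dev}.
#' @export
calibration_curve <- function(e, n_bins = 20, min_pairs = 50) {
  n <- e$n
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- hyperbolic_distance_exact(e$r[ut[, 1]], e$r[ut[, 2]],
                                 angle_sep(e$theta[ut[, 1]], e$theta[ut[, 2]]),
                                 e$curvature)
  A <- igraph::as_adjacency_matrix(e$graph, sparse = TRUE)
  a <- A[cbind(ut[, 1], ut[, 2])] > 0
  br <- seq(min(d), max(d), length.out = n_bins + 1L)
  bin <- findInterval(d, br, rightmost.closed = TRUE)
  tab <- data.frame(
    d_mid = (br[-1] + br[-length(br)]) / 2,
    n_pairs = tabulate(bin, n_bins),
    freq = vapply(seq_len(n_bins), function(b) mean(a[bin == b]), numeric(1)))
  tab$p_model <- connection_probability(tab$d_mid, e$beta, e$R_hat)
  keep <- tab$n_pairs >= min_pairs
  list(table = tab,
       mean_abs_dev = mean(abs(tab$freq[keep] - tab$p_model[keep])))
}
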