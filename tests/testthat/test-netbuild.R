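test_that("sample variance and Pearson correlation match direct evaluation", {
  expect_equal(sample_variance(c(1, 1, 1)), 0)
  expect_equal(sample_variance(c(1, 2, 3)), 1.0)
  expect_equal(sample_variance(c(0, 2)), 2.0)
  expect_error(sample_variance(3), "at least 2")

  expect_equal(sample_pearson(1:5, 1:5), 1.0)
  expect_equal(sample_pearson(1:5, -(1:5)), -1.0)
  # direct evaluation of the defining formula as the oracle
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    ((length(x) - 1) * sqrt(sample_variance(x)) * sqrt(sample_variance(y)))
  expect_equal(sample_pearson(x, y), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.9819805, tolerance = 1e-6)
  # affine invariance with positive slope
  expect_equal(sample_pearson(2 * x + 7, y), sample_pearson(x, y),
               tolerance = 1e-12)
  expect_error(sample_pearson(c(1, 1, 1), y), "constant")
})

test_that("correlation_matrix equals the brute-force pairwise loop", {
  set.seed(42)
  b <- toy_bold(matrix(rnorm(30 * 40), 30))
  cm <- correlation_matrix(b)
  expect_equal(cm$values, t(cm$values), tolerance = 1e-12)
  expect_equal(diag(cm$values), rep(1, 30))
  for (i in 1:29) for (j in (i + 1):30)
    expect_equal(cm$values[i, j],
                 sample_pearson(b$values[i, ], b$values[j, ]),
                 tolerance = 1e-12)
  bad <- toy_bold(rbind(matrix(rnorm(10), 2, 5), rep(1, 5)))
  expect_error(correlation_matrix(bad), "constant series at voxel id\\(s\\) 2")
})

test_that("thresholding keeps only strictly positive supra-threshold edges", {
  v <- diag(3)
  v[1, 2] <- v[2, 1] <- 0.5
  v[1, 3] <- v[3, 1] <- 0.3
  v[2, 3] <- v[3, 2] <- -0.8
  cm <- structure(list(values = v, voxel_ids = 0:2),
                  class = "correlation_matrix")
  g <- threshold_graph(cm, 0.4)
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "0", "1"))
  # strong negative correlation never becomes an edge at any threshold
  for (t in c(0.05, 0.5, 0.79))
    expect_false(igraph::are_adjacent(threshold_graph(cm, t), "1", "2"))
  expect_equal(igraph::ecount(threshold_graph(cm, 0.999)), 0)
  # ties at exactly the threshold are excluded
  expect_false(igraph::are_adjacent(threshold_graph(cm, 0.5), "0", "1"))
  expect_error(threshold_graph(cm, 1.2), "\\(0, 1\\)")
  # degree of a node equals the count of supra-threshold partners
  set.seed(7)
  b <- toy_bold(matrix(rnorm(20 * 100), 20))
  cm2 <- correlation_matrix(b)
  g2 <- threshold_graph(cm2, 0.1)
  deg <- igraph::degree(g2)[as.character(0:19)]
  for (i in 1:20)
    expect_equal(unname(deg[i]), sum(cm2$values[i, -i] > 0.1))
})

test_that("largest_component extracts the right subgraph and fraction", {
  path5 <- brain_graph(0:4, cbind(0:3, 1:4))
  expect_equal(largest_component(path5)$fraction, 1.0)

  cliques <- brain_graph(0:7, rbind(t(utils::combn(0:4, 2)),
                                    t(utils::combn(5:7, 2))))
  lc <- largest_component(cliques)
  expect_equal(lc$fraction, 5 / 8)
  expect_setequal(hypercore:::graph_ids(lc$graph), 0:4)

  isolated <- brain_graph(0:9, matrix(integer(0), ncol = 2))
  lc2 <- largest_component(isolated)
  expect_equal(lc2$fraction, 1 / 10)
  expect_equal(igraph::vcount(lc2$graph), 1)
  # size tie broken towards the component with the smallest voxel id
  tie <- brain_graph(0:3, rbind(c(2, 3), c(0, 1)))
  expect_setequal(hypercore:::graph_ids(largest_component(tie)$graph), 0:1)
})

test_that("scale-freeness check separates power laws from Poisson degrees", {
  set.seed(2)
  k_pl <- sample(1:1000, 2000, replace = TRUE, prob = (1:1000)^(-2.5))
  r <- check_scale_freeness(k_pl)
  expect_gte(r$r_squared, 0.95)
  expect_lt(abs(r$slope + 2.5), 0.3)
  expect_true(r$passes_scalefree)

  k_er <- igraph::degree(er_graph(2000, 20 / 1999, seed = 3))
  r2 <- check_scale_freeness(k_er)
  expect_false(r2$passes_scalefree)

  expect_error(check_scale_freeness(rep(6, 100)), "degenerate")
  expect_error(check_scale_freeness(c(1, 2, 3)), "at least 20")
})

test_that("threshold selection returns the smallest admissible candidate", {
  # correlation matrix engineered from a scale-free graph: edges at 0.5,
  # non-edges at 0.1, so 0.4 passes both criteria and 0.6 yields no edges
  s <- sample_s1_network(300, 2.5, 10, 2.5, seed = 5)
  g <- s$graph
  n <- igraph::vcount(g)
  v <- matrix(0.1, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  v[el] <- 0.5; v[el[, 2:1]] <- 0.5
  diag(v) <- 1
  cm <- structure(list(values = v, voxel_ids = 0:(n - 1)),
                  class = "correlation_matrix")
  sel <- select_threshold(cm, candidates = c(0.4, 0.6))
  expect_equal(sel$rho, 0.4)
  expect_length(sel$reports, 2)
  expect_false(sel$reports[[2]]$passes_lcc)
  expect_error(select_threshold(cm, candidates = c(0.6, 0.7)),
               "no admissible threshold")
  sel1 <- select_threshold(cm, candidates = 0.4)
  expect_equal(sel1$rho, 0.4)
  expect_length(sel1$reports, 1)
})

test_that("edge sets and LCC sizes shrink monotonically in the threshold", {
  part <- simple_labels(0:34, rep(scheme_labels("functional-7"), length.out = 35))
  b <- simulate_bold(35, part, within_r = 0.5, between_r = 0.2,
                     n_timepoints = 300, seed = 9)
  cm <- correlation_matrix(b)
  grid <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  edges <- numeric(0); lcc <- numeric(0); prev_edges <- NULL
  for (t in grid) {
    g <- threshold_graph(cm, t)
    el <- igraph::as_edgelist(g, names = TRUE)
    el <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    if (!is.null(prev_edges)) expect_true(all(el %in% prev_edges))
    prev_edges <- el
    edges <- c(edges, igraph::ecount(g))
    lcc <- c(lcc, igraph::vcount(largest_component(g)$graph))
  }
  expect_false(is.unsorted(rev(edges)))
  expect_false(is.unsorted(rev(lcc)))
})
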