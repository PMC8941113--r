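test_that("exact hyperbolic distance obeys its closed-form special cases", {
  expect_equal(hyperbolic_distance_exact(3, 3, 0), 0, tolerance = 1e-6)
  # antipodal points at curvature 1: d = r1 + r2
  expect_equal(hyperbolic_distance_exact(2, 5, pi), 7, tolerance = 1e-9)
  # one point at the origin: d = r2 for any angle
  for (dt in c(0, 1, pi))
    expect_equal(hyperbolic_distance_exact(0, 4, dt), 4, tolerance = 1e-9)
  expect_equal(hyperbolic_distance_exact(2, 3, 0.7),
               hyperbolic_distance_exact(3, 2, 0.7), tolerance = 1e-12)
  expect_error(hyperbolic_distance_exact(-1, 2, 1), ">= 0")
})

test_that("exact distance satisfies the triangle inequality on random triples", {
  set.seed(61)
  for (i in 1:2000) {
    r <- runif(3, 0, 12)
    th <- runif(3, 0, 2 * pi)
    d12 <- hyperbolic_distance_exact(r[1], r[2], hypercore:::angle_sep(th[1], th[2]))
    d13 <- hyperbolic_distance_exact(r[1], r[3], hypercore:::angle_sep(th[1], th[3]))
    d23 <- hyperbolic_distance_exact(r[2], r[3], hypercore:::angle_sep(th[2], th[3]))
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("the log-approximation tracks the exact distance in its regime", {
  expect_equal(hyperbolic_distance_approx(10, 10, pi), 20 + 2 * log(pi / 2),
               tolerance = 1e-12)
  expect_error(hyperbolic_distance_approx(0.1, 0.1, 1e-6), "validity bound")
  # relative error < 1% in the small-angle regime the expansion comes from;
  # the deviation grows like 2 log((dt/2)/sin(dt/2)) towards dt = pi
  for (r1 in seq(5, 15, by = 2.5)) for (r2 in seq(5, 15, by = 2.5))
    for (dt in seq(0.1, 1.0, length.out = 8)) {
      ex <- hyperbolic_distance_exact(r1, r2, dt)
      ap <- hyperbolic_distance_approx(r1, r2, dt)
      expect_lt(abs(ap - ex) / ex, 0.01,
                label = sprintf("r1=%g r2=%g dt=%g", r1, r2, dt))
    }
  # the antipodal overshoot is exactly the log-sine correction
  err <- hyperbolic_distance_approx(12, 12, pi) -
    hyperbolic_distance_exact(12, 12, pi)
  expect_equal(err, 2 * log((pi / 2) / sin(pi / 2)), tolerance = 1e-3)
})

test_that("connection probability is a Fermi function of distance", {
  expect_equal(connection_probability(7.3, 2.5, 7.3), 0.5)
  expect_equal(connection_probability(12, 2, 10), 1 / (1 + exp(2)),
               tolerance = 1e-12)
  d <- seq(0, 40, by = 0.5)
  p <- connection_probability(d, 3, 20)
  expect_true(all(diff(p) < 0))
  expect_lt(connection_probability(1e6, 2, 10), 1e-12)
  expect_error(connection_probability(1, 0.9, 10), "beta")
})

test_that("hidden-degree inference matches symmetry and the generator", {
  ring4 <- igraph::connect(igraph::make_ring(60), 2)
  ring4 <- igraph::set_vertex_attr(ring4, "name", value = as.character(0:59))
  kap <- infer_hidden_degrees(ring4, beta = 2.5)
  expect_lt(diff(range(kap)), 1e-6)      # regular graph: all kappa equal

  s <- sample_s1_network(500, 2.5, 10, 2.5, seed = 4)
  lcc <- largest_component(s$graph)$graph
  kap2 <- infer_hidden_degrees(lcc, beta = 2.5)
  truth <- s$truth$kappa_true[names(kap2)]
  expect_gte(stats::cor(as.numeric(kap2), as.numeric(truth)), 0.9)
  # expected degrees reproduce observed degrees within the tolerance
  expect_lt(max(abs(residuals_of <- as.numeric(igraph::degree(lcc)) -
                    hypercore:::expected_degrees(
                      as.numeric(kap2), 2.5, attr(kap2, "mu"),
                      igraph::vcount(lcc) / (2 * pi)))), 0.1 + 1e-9)
  empty <- brain_graph(integer(0), matrix(integer(0), ncol = 2))
  expect_error(infer_hidden_degrees(empty, 2), "empty graph")
})

test_that("Laplacian eigenmaps recover circular and path orderings", {
  ring <- igraph::connect(igraph::make_ring(100), 2)
  ring <- igraph::set_vertex_attr(ring, "name", value = as.character(0:99))
  th <- initialize_angles_le(ring)
  expect_true(is_cyclic_order(th))

  path <- brain_graph(0:39, cbind(0:38, 1:39))
  thp <- initialize_angles_le(path)
  expect_true(is_cyclic_order(thp))

  expect_silent(initialize_angles_le(complete_graph(12)))
  disc <- brain_graph(0:3, rbind(c(0, 1), c(2, 3)))
  expect_error(initialize_angles_le(disc), "connected")
})

test_that("likelihood refinement is monotone, deterministic and beats the start", {
  s <- sample_s1_network(150, 2.5, 8, 2.5, seed = 6)
  lcc <- largest_component(s$graph)$graph
  kap <- infer_hidden_degrees(lcc, 2.5)
  th0 <- initialize_angles_le(lcc)
  e <- refine_angles_ml(lcc, th0, kap, 2.5, seed = 2, max_sweeps = 8)
  expect_false(is.unsorted(e$trace))          # non-decreasing trace
  expect_gte(e$loglik, e$trace[1])
  expect_equal(e$R_hat, max(e$r), tolerance = 1e-9)
  expect_true(all(e$theta >= 0 & e$theta < 2 * pi))
  e2 <- refine_angles_ml(lcc, th0, kap, 2.5, seed = 2, max_sweeps = 8)
  expect_identical(e$theta, e2$theta)         # same seed, same embedding
  e3 <- refine_angles_ml(lcc, th0, kap, 2.5, seed = 3, max_sweeps = 8)
  al <- align_embeddings(e, e3)
  expect_gte(al$similarity, 0.9)              # reproducibility across seeds
})

test_that("alignment resolves rotations and reflections exactly", {
  set.seed(91)
  th <- stats::setNames(runif(200, 0, 2 * pi), as.character(0:199))
  rot <- hypercore:::wrap_angle(th + 1.0)
  al <- align_embeddings(th, rot)
  expect_false(al$reflected)
  expect_equal(al$rotation, 1.0, tolerance = 1e-6)
  expect_equal(al$similarity, 1.0, tolerance = 1e-9)
  expect_equal(unname(al$aligned_theta), unname(th), tolerance = 1e-9)

  mir <- hypercore:::wrap_angle(-th)
  alm <- align_embeddings(th, mir)
  expect_true(alm$reflected)
  expect_equal(alm$similarity, 1.0, tolerance = 1e-9)

  ind <- stats::setNames(runif(500, 0, 2 * pi), as.character(0:499))
  ind2 <- stats::setNames(runif(500, 0, 2 * pi), as.character(0:499))
  expect_lt(align_embeddings(ind, ind2)$similarity, 0.2)
})

test_that("model clustering rises with beta in the generator", {
  cl <- vapply(c(1.5, 5), function(b)
    hypercore:::mean_local_clustering(
      sample_s1_network(300, 2.5, 10, b, seed = 8)$graph), numeric(1))
  expect_lt(cl[1], cl[2])
  expect_error(estimate_beta(brain_graph(0:2, rbind(c(0, 1), c(1, 2)))),
               "triangle")
})

test_that("embedding methods expose the fitted model coherently", {
  s <- sample_s1_network(120, 2.5, 8, 2.5, seed = 10)
  lcc <- largest_component(s$graph)$graph
  e <- hyper_embed(lcc, seed = 1, beta = 2.5, max_sweeps = 5)
  cf <- coef(e)
  expect_identical(colnames(cf), c("r", "theta", "kappa"))
  expect_equal(nrow(cf), e$n)
  expect_s3_class(stats::logLik(e), "logLik")
  pr <- predict(e)
  expect_true(all(pr$p > 0 & pr$p < 1))
  expect_equal(nrow(pr), igraph::ecount(lcc))
  sim <- simulate(e, seed = 4)
  expect_setequal(hypercore:::graph_ids(sim), e$voxel_id)
  res <- residuals(e)
  expect_length(res, e$n)
  expect_output(print(e), "hyperbolic embedding")
})
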