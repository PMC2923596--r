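test_that("the Poisson reference matches closed forms and bounds its tail", {
  ref <- poisson_reference(2, kmax = 20)
  expect_equal(unname(ref$p["2"]), 2 * exp(-2), tolerance = 1e-12)
  expect_equal(unname(ref$p["0"]), exp(-2), tolerance = 1e-12)
  expect_lt(poisson_reference(2, kmax = 20)$tail_mass, 1e-6)
  expect_error(poisson_reference(-1, 10), "positive")
})

test_that("complexity terms are KL divergences: regular and uncorrelated limits", {
  # point-mass degrees: KL from Poisson(c) is -log pi_c(c); c = 2
  cyc <- network_complexity(generate_network("cycle", N = 40))
  expect_equal(cyc$degree_per_node, -log(dpois(2, 2)), tolerance = 1e-9)
  expect_equal(cyc$wiring_per_node, 0, tolerance = 1e-12)

  # large uncorrelated graph: both terms near zero
  er <- network_complexity(generate_network("er", N = 5000, mean_degree = 6,
                                            seed = 71))
  expect_lt(er$degree_per_node, 0.01)
  expect_lt(er$wiring_per_node, 0.05)

  # hand-built W == 1 kernel: wiring complexity identically zero
  e1 <- network_complexity(generate_network("matching", N = 20))
  expect_equal(e1$wiring_per_node, 0, tolerance = 1e-12)
})

test_that("complexity is non-negative and per-link = per-node / (kbar/2)", {
  for (s in 1:5) {
    g <- generate_network("planted_disassortative", N = 400, mean_degree = 5,
                          strength = 0.3, seed = 80 + s)
    cr <- network_complexity(g)
    expect_gte(cr$degree_per_node, 0)
    expect_gte(cr$wiring_per_node, 0)
    expect_equal(cr$degree_per_link, cr$degree_per_node / (cr$mean_degree / 2))
    expect_equal(cr$wiring_per_link, cr$wiring_per_node / (cr$mean_degree / 2))
  }
})

test_that("directional ensemble divergence from the ER ensemble reproduces the complexity", {
  g <- generate_network("planted_disassortative", N = 500, mean_degree = 5,
                        strength = 0.3, seed = 91)
  st <- degree_stats(g)
  cr <- network_complexity(st)
  ref <- er_reference_stats(st$mean_degree, kmax = 200)
  st_pad <- smooth_stats(st, sigma = 1e-6, kmax = 200)  # same grid, ~exact
  expect_equal(ppinet:::kl_ensemble(st_pad, ref),
               cr$degree_per_node + cr$wiring_per_node, tolerance = 1e-4)
})

test_that("distance axioms: identity, symmetry, positivity, degree-only blindness to rewiring", {
  st4 <- generate_network("star", N = 4)
  cy4 <- generate_network("cycle", N = 4)
  expect_equal(network_distance(st4, st4, sigma = 1)$full, 0)
  d1 <- network_distance(st4, cy4, sigma = 1)
  d2 <- network_distance(cy4, st4, sigma = 1)
  expect_lt(abs(d1$full - d2$full), 1e-12)
  expect_lt(abs(d1$degree_only - d2$degree_only), 1e-12)
  expect_gt(d1$full, 0)

  # degree-preserving rewiring: degree-only distance exactly 0, full >= 0
  g <- generate_network("planted_disassortative", N = 400, mean_degree = 5,
                        strength = 0.3, seed = 101)
  r <- randomise_network(g, accepted_per_link = 30, seed = 102)$graph
  d <- network_distance(g, r, sigma = 1)
  expect_equal(d$degree_only, 0)
  expect_gt(d$full, 0)
  expect_equal(d$full, d$ddc_contribution)

  expect_error(network_distance(st4, cy4, sigma = 0), "positive")
})

test_that("distance is zero iff the characterisations coincide", {
  # identical degree sequence AND identical wiring statistics -> 0
  g <- generate_network("er", N = 100, mean_degree = 4, seed = 111)
  perm <- igraph::permute(g, sample(igraph::vcount(g)))
  expect_lt(network_distance(g, perm, sigma = 1)$full, 1e-12)
  # different wiring at matched degrees -> strictly positive
  a <- generate_network("planted_disassortative", N = 500, mean_degree = 5,
                        strength = 0.35, seed = 112)
  b <- randomise_network(a, accepted_per_link = 50, seed = 113)$graph
  expect_gt(network_distance(a, b, sigma = 1)$full, 1e-4)
})

test_that("the full distance matches an independent term-by-term oracle", {
  st4 <- generate_network("star", N = 4)
  cy4 <- generate_network("cycle", N = 4)
  expect_equal(network_distance(st4, cy4, sigma = 1)$full,
               oracle_full_distance(st4, cy4, sigma = 1), tolerance = 1e-9)
  a <- generate_network("er", N = 80, mean_degree = 3, seed = 121)
  b <- generate_network("er", N = 60, mean_degree = 5, seed = 122)
  expect_equal(network_distance(a, b, sigma = 1)$full,
               oracle_full_distance(a, b, sigma = 1), tolerance = 1e-9)
})

test_that("distance matrices are symmetric, zero-diagonal and label-stable", {
  nets <- list(
    s = generate_network("star", N = 6),
    c = generate_network("cycle", N = 6),
    p = generate_network("path", N = 6))
  D <- distance_matrix(nets, sigma = 1)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D["s", "c"],
               network_distance(nets$s, nets$c, sigma = 1,
                                kmax = max(igraph::degree(nets$s),
                                           igraph::degree(nets$c)))$full)
  # permuting the collection permutes the matrix
  D2 <- distance_matrix(nets[c(3, 1, 2)], sigma = 1)
  expect_equal(D2[rownames(D), colnames(D)], D)
  # three copies of one graph: zero matrix
  D3 <- distance_matrix(list(a = nets$s, b = nets$s, c = nets$s), sigma = 1)
  expect_equal(max(abs(D3)), 0)
  expect_error(distance_matrix(nets[1]), "at least 2")

  f <- withr::local_tempfile()
  write_triangular_tsv(D, f)
  expect_equal(length(readLines(f)), 4L)
})
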