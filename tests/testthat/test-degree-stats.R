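test_that("toy graphs give the hand-counted degree laws", {
  st <- degree_stats(generate_network("star", N = 4))
  expect_equal(unname(st$p[c("1", "3")]), c(0.75, 0.25))
  expect_equal(st$mean_degree, 1.5)

  cy <- degree_stats(generate_network("cycle", N = 3))
  expect_equal(unname(cy$p["2"]), 1)
  expect_equal(cy$mean_degree, 2)
  expect_equal(unname(cy$joint["2", "2"]), 1)

  emp <- igraph::make_empty_graph(5, directed = FALSE)
  emp <- igraph::set_vertex_attr(emp, "name", value = letters[1:5])
  es <- degree_stats(emp)
  expect_equal(unname(es$p["0"]), 1)
  expect_equal(es$mean_degree, 0)
  expect_equal(length(es$joint), 0L)
})

test_that("degree-law invariants hold on generated graphs", {
  for (s in 1:5) {
    g <- generate_network("er", N = 300, mean_degree = 4, seed = 20 + s)
    st <- degree_stats(g)
    expect_equal(sum(st$p), 1, tolerance = 1e-12)
    expect_equal(st$mean_degree, sum(as.integer(names(st$p)) * st$p),
                 tolerance = 1e-12)
    expect_equal(st$mean_degree, 2 * st$E / st$N, tolerance = 1e-12)
    expect_equal(sum(st$joint), 1, tolerance = 1e-12)
    expect_equal(st$joint, t(st$joint))
    # edge-end marginal identity: sum_k' Pi(k,k') = k p(k)/<k>
    k <- as.integer(rownames(st$joint))
    pk <- numeric(length(k))
    avail <- k[k <= length(st$p) - 1L]
    pk[match(avail, k)] <- st$p[as.character(avail)]
    expect_equal(rowSums(st$joint), k * pk / st$mean_degree,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the DDC kernel matches hand evaluation and separates no-data from zero", {
  st <- degree_stats(generate_network("star", N = 4))
  W <- normalized_ddc(st)$W
  expect_equal(W["1", "3"], 2, ignore_attr = TRUE)
  expect_equal(W["3", "1"], 2, ignore_attr = TRUE)
  expect_equal(W["1", "1"], 0, ignore_attr = TRUE)  # in-support, unobserved
  expect_equal(W["3", "3"], 0, ignore_attr = TRUE)
  expect_true(is.na(W["2", "2"]))                   # no degree-2 nodes: no data

  e1 <- degree_stats(generate_network("matching", N = 2))
  expect_equal(normalized_ddc(e1)$W["1", "1"], 1, ignore_attr = TRUE)

  # weighted-average-1 normalisation of W
  g <- generate_network("er", N = 400, mean_degree = 5, seed = 33)
  st2 <- degree_stats(g)
  W2 <- normalized_ddc(st2)$W
  m <- rowSums(st2$joint)
  expect_equal(sum(outer(m, m) * W2, na.rm = TRUE), 1, tolerance = 1e-10)
})

test_that("W is near 1 on well-populated bins of an uncorrelated graph", {
  g <- generate_network("er", N = 5000, mean_degree = 6, seed = 44)
  st <- degree_stats(g)
  counts <- st$joint * 2 * st$E
  W <- normalized_ddc(st)$W
  pop <- which(counts >= 50 & !is.na(W))
  # each bin's estimator has relative MC error ~ 1/sqrt(count)
  dev <- mean(W[pop] - 1)
  se <- sqrt(sum(1 / counts[pop])) / length(pop)
  expect_lt(abs(dev), 3 * se)
})

test_that("Gaussian smoothing preserves mass, is positive, and matches the convolution oracle", {
  g <- generate_network("er", N = 200, mean_degree = 4, seed = 55)
  st <- degree_stats(g)
  sm <- smooth_stats(st, sigma = 1)
  expect_equal(sum(sm$p), 1, tolerance = 1e-12)
  expect_equal(sum(sm$joint), 1, tolerance = 1e-12)
  expect_true(all(sm$p > 0))
  expect_true(all(sm$joint > 0))
  kmax <- length(sm$p) - 1L
  expect_equal(unname(sm$p),
               oracle_smooth_vec(c(st$p, rep(0, kmax + 1 - length(st$p))),
                                 0:kmax, 1),
               tolerance = 1e-12)
  # sigma -> 0+ recovers the input
  tiny <- smooth_stats(st, sigma = 0.05)
  expect_equal(unname(tiny$p[seq_along(st$p)]), unname(st$p), tolerance = 1e-8)
  # a delta distribution smooths to a symmetric peak at its location
  delta <- st
  delta$p <- setNames(c(rep(0, 5), 1, rep(0, 5)), 0:10)
  sd1 <- smooth_stats(delta, sigma = 1, kmax = 10)
  expect_equal(which.max(sd1$p), 6L, ignore_attr = TRUE)
  expect_equal(unname(sd1$p[5]), unname(sd1$p[7]), tolerance = 1e-12)
  expect_error(smooth_stats(st, sigma = 0), "positive")
})

test_that("assortativity agrees across its two formulas and with brute force", {
  expect_equal(net_assortativity(generate_network("star", N = 4)), -1)
  g <- igraph::graph_from_literal(A - B, B - C, C - D, D - E, B - D)
  expect_equal(net_assortativity(g), oracle_assortativity(g), tolerance = 1e-12)
  for (s in 1:5) {
    gr <- generate_network("planted_disassortative", N = 300, mean_degree = 5,
                           strength = 0.2, seed = 60 + s)
    st <- degree_stats(gr)
    expect_equal(net_assortativity(st, route = "joint"),
                 net_assortativity(st, route = "kernel"), tolerance = 1e-10)
    expect_equal(net_assortativity(st), oracle_assortativity(gr),
                 tolerance = 1e-10)
  }
})

test_that("assortativity of a regular graph is reported undefined, not zero", {
  expect_warning(r <- net_assortativity(generate_network("cycle", N = 4)),
                 "undefined")
  expect_true(is.na(r))
})
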