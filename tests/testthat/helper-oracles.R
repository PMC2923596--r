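# Independent oracle implementations, coded as plain loops directly from the
# definitions. These deliberately share no code with the package internals:
# they are the second path in every dual-implementation check.

# Pearson correlation of the degree pairs over all ordered edge ends.
oracle_assortativity <- function(g) {
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  stats::cor(x, y)
}

# Clipped discrete Gaussian smoothing of a distribution on grid 0..kmax (or
# 1..kmax), each source bin's weights renormalised over the grid.
oracle_smooth_vec <- function(p, grid, sigma) {
  out <- numeric(length(grid))
  for (src in seq_along(grid)) {
    w <- exp(-(grid - grid[src])^2 / (2 * sigma^2))
    w <- w / sum(w)
    out <- out + p[src] * w
  }
  out / sum(out)
}

# Term-by-term evaluation of the symmetrised ensemble Kullback-Leibler
# distance between two graphs, from scratch: count degrees, build p and the
# edge-end joint law, smooth each with the clipped Gaussian, re-form W from
# the smoothed joint's own marginals, and accumulate the four terms of the
# distance with explicit loops over the degree grid.
oracle_full_distance <- function(ga, gb, sigma) {
  char <- function(g, kmax) {
    deg <- igraph::degree(g)
    n <- length(deg)
    p <- numeric(kmax + 1)
    for (d in deg) p[d + 1] <- p[d + 1] + 1 / n
    el <- igraph::as_edgelist(g, names = FALSE)
    J <- matrix(0, kmax, kmax)
    for (e in seq_len(nrow(el))) {
      k1 <- deg[el[e, 1]]; k2 <- deg[el[e, 2]]
      J[k1, k2] <- J[k1, k2] + 1
      J[k2, k1] <- J[k2, k1] + 1
    }
    J <- J / sum(J)
    # smooth p along its axis, J along both axes
    ps <- oracle_smooth_vec(p, 0:kmax, sigma)
    Js <- matrix(0, kmax, kmax)
    for (i in 1:kmax) for (j in 1:kmax) {
      if (J[i, j] == 0) next
      wi <- exp(-((1:kmax) - i)^2 / (2 * sigma^2)); wi <- wi / sum(wi)
      wj <- exp(-((1:kmax) - j)^2 / (2 * sigma^2)); wj <- wj / sum(wj)
      Js <- Js + J[i, j] * outer(wi, wj)
    }
    Js <- Js / sum(Js)
    m <- rowSums(Js)
    W <- Js / outer(m, m)
    list(p = ps, J = Js, W = W, kbar = sum((0:kmax) * ps))
  }
  kmax <- max(igraph::degree(ga), igraph::degree(gb))
  A <- char(ga, kmax); B <- char(gb, kmax)
  d_deg <- 0
  for (k in 0:kmax) {
    d_deg <- d_deg + 0.5 * (A$p[k + 1] - B$p[k + 1]) * log(A$p[k + 1] / B$p[k + 1])
  }
  d_deg <- d_deg - 0.25 * (A$kbar - B$kbar) * log(A$kbar / B$kbar)
  d_wir <- 0
  for (i in 1:kmax) for (j in 1:kmax) {
    d_wir <- d_wir +
      0.25 * A$kbar * A$J[i, j] * log(A$W[i, j] / B$W[i, j]) +
      0.25 * B$kbar * B$J[i, j] * log(B$W[i, j] / A$W[i, j])
  }
  d_deg + d_wir
}

# All perfect matchings on an even set of 0-based node indices, as the same
# canonical signatures the sampler emits (sorted keys lo*N+hi, comma-joined).
oracle_matchings <- function(n) {
  rec <- function(nodes) {
    if (length(nodes) == 0) return(list(integer(0)))
    a <- nodes[1]
    out <- list()
    for (b in nodes[-1]) {
      rest <- setdiff(nodes, c(a, b))
      for (tail in rec(rest)) {
        out[[length(out) + 1]] <- c(min(a, b) * n + max(a, b), tail)
      }
    }
    out
  }
  sigs <- vapply(rec(0:(n - 1)),
                 function(k) paste(sort(k), collapse = ","), "")
  sort(sigs)
}

# A degree_stats-shaped object for the uncorrelated (ER-like) ensemble with a
# Poissonian degree law, used to check that the directional ensemble
# divergence from it reproduces the complexity formula.
er_reference_stats <- function(kbar, kmax) {
  p <- dpois(0:kmax, kbar)
  p <- p / sum(p)
  names(p) <- 0:kmax
  m <- (1:kmax) * p[-1] / sum((0:kmax) * p)
  m <- m / sum(m)
  J <- outer(m, m)
  dimnames(J) <- list(1:kmax, 1:kmax)
  structure(list(p = p, mean_degree = sum((0:kmax) * p), joint = J,
                 N = NA, E = 1, kmax = kmax, sigma = 0),
            class = "degree_stats")
}
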