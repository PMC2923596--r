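#' Degree statistics of a network
#'
#' Computes the macroscopic degree characterisation of an undirected simple
#' graph: the degree distribution p(k) (including the k = 0 bin), the mean
#' degree, and the edge-end joint degree law Pi(k, k') — the probability that
#' a uniformly drawn interaction, read in a uniformly drawn orientation,
#' connects nodes of degrees k and k'. Both orientations of every edge are
#' counted, so Pi is symmetric and its marginal is the edge-end degree law
#' k p(k) / <k>.
#'
#' @param net An igraph object (validated with [check_network()]).
#' @param kmax Optional truncation degree for the joint law's axes; defaults
#'   to the maximum observed degree. Degrees above `kmax` are not clipped in
#'   `p`, only the matrix extent of `joint` is limited.
#' @return An object of class `degree_stats`: a list with elements
#'   `p` (named numeric vector over k = 0..max degree), `mean_degree`,
#'   `joint` (symmetric matrix over k = 1..kmax, summing to 1; a 0 x 0 matrix
#'   when the graph has no edges), `N`, `E`, `kmax`, and `sigma` (0 for exact
#'   counting statistics).
#' @examples
#' st <- degree_stats(generate_network("star", N = 4))
#' st$p                      # p(1) = 0.75, p(3) = 0.25
#' normalized_ddc(st)$W      # W(1,3) = 2: hub-leaf enrichment
#' @export
degree_stats <- function(net, kmax = NULL) {
  check_network(net)
  deg <- igraph::degree(net)
  N <- length(deg)
  E <- igraph::ecount(net)
  kobs <- if (N > 0) max(deg) else 0L
  p <- tabulate(deg + 1L, nbins = kobs + 1L) / N
  names(p) <- 0:kobs
  if (is.null(kmax)) kmax <- kobs
  if (E > 0L) {
    el <- igraph::as_edgelist(net, names = FALSE)
    d1 <- deg[el[, 1L]]
    d2 <- deg[el[, 2L]]
    joint <- matrix(0, nrow = kmax, ncol = kmax,
                    dimnames = list(1:kmax, 1:kmax))
    # both orientations of each edge; total mass 2E before normalisation
    idx <- rbind(cbind(d1, d2), cbind(d2, d1))
    keep <- idx[, 1L] <= kmax & idx[, 2L] <= kmax
    tab <- table(factor(idx[keep, 1L], levels = 1:kmax),
                 factor(idx[keep, 2L], levels = 1:kmax))
    joint <- unclass(tab) / (2 * E)
    dimnames(joint) <- list(1:kmax, 1:kmax)
  } else {
    joint <- matrix(numeric(0), 0L, 0L)
  }
  structure(
    list(p = p, mean_degree = 2 * E / N, joint = joint,
         N = N, E = E, kmax = kmax, sigma = 0),
    class = "degree_stats"
  )
}

#' @export
print.degree_stats <- function(x, ...) {
  cat("Degree statistics:", x$N, "nodes,", x$E, "edges\n")
  cat("  mean degree <k> =", format(x$mean_degree, digits = 6), "\n")
  cat("  degree support: 0..", length(x$p) - 1L, "; joint law on 1..",
      x$kmax, if (x$sigma > 0) sprintf("; smoothed (sigma = %g)", x$sigma),
      "\n", sep = "")
  invisible(x)
}

#' Normalised degree--degree correlation kernel W(k, k')
#'
#' The ratio between the likelihood that two nodes of degrees k and k' are
#' connected and what that likelihood would be in a large random graph with
#' the same degree distribution:
#' \deqn{W(k,k') = \Pi(k,k') \langle k\rangle^2 / [k\,p(k)\, k'\,p(k')]}
#' W = 1 for all degree pairs signals the absence of degree correlations
#' beyond those forced by the degree distribution itself.
#'
#' Degree pairs outside the support of the edge-end marginal carry no data
#' and are returned as `NA` ("undefined"); pairs inside the support with no
#' observed edges are true zeros (suppressed interaction propensity).
#'
#' @param stats A `degree_stats` object (exact or smoothed) with `E >= 1`.
#' @return An object of class `ddc`: list with `W` (matrix over 1..kmax,
#'   `NA` off-support), `sigma`, and `support_max` (largest degree with
#'   positive edge-end marginal).
#' @export
normalized_ddc <- function(stats) {
  stopifnot(inherits(stats, "degree_stats"))
  if (stats$E < 1) stop("W is undefined for an edgeless network")
  J <- stats$joint
  m <- rowSums(J)  # edge-end degree marginal; equals k p(k)/<k> for exact stats
  W <- J / outer(m, m)
  W[outer(m, m) == 0] <- NA_real_
  structure(
    list(W = W, sigma = stats$sigma,
         support_max = max(which(m > 0))),
    class = "ddc"
  )
}

#' @export
print.ddc <- function(x, ...) {
  cat("Normalised degree-degree correlation kernel on 1..",
      nrow(x$W), "\n", sep = "")
  cat("  defined on", sum(!is.na(x$W)), "degree pairs; support up to k =",
      x$support_max, "\n")
  if (x$sigma > 0) cat("  smoothed with sigma =", x$sigma, "\n")
  invisible(x)
}

# Column-stochastic clipped Gaussian kernel on an integer grid.
# Each source bin spreads its mass with weights exp(-(k-k'')^2 / 2 sigma^2),
# renormalised over the retained range, so total probability is conserved
# exactly even where the window is clipped at the boundaries.
gaussian_kernel <- function(grid, sigma) {
  K <- outer(grid, grid, function(k, kk) exp(-(k - kk)^2 / (2 * sigma^2)))
  sweep(K, 2L, colSums(K), "/")
}

#' Gaussian smoothing of degree statistics
#'
#' Applies a weak discrete Gaussian smoothing of width `sigma` to the degree
#' distribution (along its degree axis) and to the edge-end joint law (along
#' both axes), each on its truncated range, renormalising to total mass 1.
#' Smoothing makes both laws strictly positive on the whole retained grid,
#' which is required before the information-theoretic distance can be
#' evaluated (it prevents zero probabilities, which reflect finite-size
#' effects, from producing infinite log-ratios).
#'
#' @param stats A `degree_stats` object with exact (unsmoothed) counts.
#' @param sigma Positive smoothing width, in degree units.
#' @param kmax Optional common grid extent (p on 0..kmax, joint on 1..kmax);
#'   defaults to the object's own extent. Used to place two networks on a
#'   shared degree grid before a distance computation.
#' @return A `degree_stats` object with smoothed `p` and `joint` and the
#'   `sigma` field set.
#' @export
smooth_stats <- function(stats, sigma, kmax = NULL) {
  stopifnot(inherits(stats, "degree_stats"))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (is.null(kmax)) kmax <- max(stats$kmax, length(stats$p) - 1L)
  p <- numeric(kmax + 1L)
  names(p) <- 0:kmax
  old <- pmin(seq_along(stats$p) - 1L, kmax)  # degrees beyond kmax fold into top bin
  for (i in seq_along(stats$p)) p[old[i] + 1L] <- p[old[i] + 1L] + stats$p[i]
  K0 <- gaussian_kernel(0:kmax, sigma)
  p_s <- as.numeric(K0 %*% p)
  p_s <- p_s / sum(p_s)
  names(p_s) <- 0:kmax
  if (stats$E > 0L) {
    J <- matrix(0, kmax, kmax, dimnames = list(1:kmax, 1:kmax))
    old_n <- min(nrow(stats$joint), kmax)
    if (old_n > 0) J[1:old_n, 1:old_n] <- stats$joint[1:old_n, 1:old_n]
    J <- J / sum(J)  # restore mass clipped by truncation, if any
    K1 <- gaussian_kernel(1:kmax, sigma)
    J_s <- K1 %*% J %*% t(K1)
    J_s <- (J_s + t(J_s)) / 2   # enforce exact symmetry against fp error
    J_s <- J_s / sum(J_s)
    dimnames(J_s) <- list(1:kmax, 1:kmax)
  } else {
    J_s <- stats$joint
  }
  structure(
    list(p = p_s, mean_degree = sum((0:kmax) * p_s), joint = J_s,
         N = stats$N, E = stats$E, kmax = kmax, sigma = sigma),
    class = "degree_stats"
  )
}

#' Assortativity of a network
#'
#' Pearson-type correlation of the degrees at the two ends of a uniformly
#' drawn interaction (Newman's assortativity coefficient for undirected
#' graphs). Positive values indicate like-degree mixing, negative values
#' hub--leaf mixing. Computable along two algebraically equivalent routes:
#' directly from the edge-end joint law Pi (`route = "joint"`), or from the
#' degree distribution and the normalised correlation kernel W
#' (`route = "kernel"`), using Pi(k,k') = W(k,k') k p(k) k' p(k') / <k>^2.
#'
#' @param x A `degree_stats` object, or an igraph object (characterised
#'   internally).
#' @param route `"joint"` (default) or `"kernel"`.
#' @return The assortativity in \[-1, 1\], or `NA` with a warning when the
#'   edge-end degree marginal has zero variance (regular graphs), for which
#'   the coefficient is undefined.
#' @export
net_assortativity <- function(x, route = c("joint", "kernel")) {
  route <- match.arg(route)
  if (igraph::is_igraph(x)) x <- degree_stats(x)
  stopifnot(inherits(x, "degree_stats"))
  if (x$E < 1) stop("assortativity requires at least one edge")
  k <- as.numeric(rownames(x$joint))
  if (route == "joint") {
    J <- x$joint
  } else {
    W <- normalized_ddc(x)$W
    kk <- seq_len(x$kmax)
    pk <- numeric(x$kmax)
    avail <- kk[kk <= length(x$p) - 1L]
    pk[avail] <- x$p[as.character(avail)]
    m <- kk * pk / x$mean_degree
    J <- outer(m, m) * W
    J[is.na(J)] <- 0
  }
  m1 <- rowSums(x$joint)           # marginal always from Pi itself
  mu <- sum(k * m1)
  v <- sum(k^2 * m1) - mu^2
  if (v <= .Machine$double.eps * max(1, mu^2)) {
    warning("zero-variance edge-end degree marginal: assortativity undefined")
    return(NA_real_)
  }
  (sum(outer(k, k) * J) - mu^2) / v
}
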