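#' Generate synthetic interaction networks with known structure
#'
#' Programmatic graph generators used throughout the package's tests and
#' examples, so that every analysis can be exercised on networks whose
#' statistical structure is known by construction:
#' \describe{
#'   \item{`er`}{Erdős–Rényi G(N, p) with p chosen to give the target mean
#'     degree; degree distribution converges to Poisson, W converges to 1.}
#'   \item{`configuration`}{Uniform simple graph with a prescribed degree
#'     sequence: a deterministic Havel–Hakimi realisation randomised by the
#'     unbiased edge-swap sampler ([randomise_network()]).}
#'   \item{`planted_assortative` / `planted_disassortative`}{Configuration-
#'     model start, then biased degree-preserving swaps that drive the
#'     assortativity to +/- `strength` within a tolerance band, planting
#'     degree--degree correlations at fixed degrees.}
#'   \item{`star`, `cycle`, `path`, `matching`, `regular`}{Exact
#'     deterministic (or, for `regular`, uniformly sampled) toy graphs.}
#' }
#'
#' @param family One of the families above.
#' @param N Number of nodes.
#' @param mean_degree Target mean degree (`er`, planted families).
#' @param degree_sequence Integer degree sequence (`configuration`, planted
#'   families may take one instead of `mean_degree`); checked for
#'   graphicality (Erdős–Gallai) before construction.
#' @param strength Absolute target assortativity for planted families
#'   (default 0.3).
#' @param k Degree for `regular` (default 3).
#' @param seed Optional integer seed.
#' @param accepted_per_link Equilibration target for the configuration
#'   sampler (default 20; the start is already degree-exact, swaps only mix
#'   the wiring).
#' @param tol Assortativity tolerance band for planted families (default
#'   0.02).
#' @return igraph object with vertex names `n1..nN`.
#' @export
generate_network <- function(family = c("er", "configuration",
                                        "planted_assortative",
                                        "planted_disassortative",
                                        "star", "cycle", "path",
                                        "matching", "regular"),
                             N = NULL, mean_degree = NULL,
                             degree_sequence = NULL, strength = 0.3,
                             k = 3, seed = NULL, accepted_per_link = 20,
                             tol = 0.02) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(
    family,
    er = {
      stopifnot(!is.null(N), !is.null(mean_degree))
      igraph::sample_gnp(N, p = min(1, mean_degree / (N - 1)))
    },
    configuration = sample_configuration(degree_sequence, accepted_per_link),
    planted_assortative = planted_graph(N, mean_degree, degree_sequence,
                                        +abs(strength), tol,
                                        accepted_per_link),
    planted_disassortative = planted_graph(N, mean_degree, degree_sequence,
                                           -abs(strength), tol,
                                           accepted_per_link),
    star = { stopifnot(!is.null(N), N >= 2)
             igraph::make_star(N, mode = "undirected", center = 1) },
    cycle = { stopifnot(!is.null(N), N >= 3)
              igraph::make_ring(N, circular = TRUE) },
    path = { stopifnot(!is.null(N), N >= 2)
             igraph::make_ring(N, circular = FALSE) },
    matching = { stopifnot(!is.null(N), N %% 2 == 0)
                 igraph::make_graph(rbind(seq(1, N, by = 2),
                                          seq(2, N, by = 2)),
                                    n = N, directed = FALSE) },
    regular = { stopifnot(!is.null(N))
                igraph::sample_k_regular(N, k) }
  )
  igraph::set_vertex_attr(g, "name", value = paste0("n", seq_len(igraph::vcount(g))))
}

# Havel–Hakimi realisation + unbiased edge-swap mixing = uniform sample from
# the simple graphs with the given degree sequence.
sample_configuration <- function(degree_sequence, accepted_per_link) {
  stopifnot(!is.null(degree_sequence))
  if (!igraph::is_graphical(degree_sequence)) {
    stop("degree sequence is not graphical (Erdős–Gallai condition fails)")
  }
  g <- igraph::realize_degseq(degree_sequence, method = "smallest")
  g <- igraph::set_vertex_attr(g, "name",
                               value = paste0("n", seq_len(igraph::vcount(g))))
  if (igraph::ecount(g) < 2) return(g)
  randomise_network(g, accepted_per_link = accepted_per_link)$graph
}

planted_graph <- function(N, mean_degree, degree_sequence, target, tol,
                          accepted_per_link) {
  if (is.null(degree_sequence)) {
    stopifnot(!is.null(N), !is.null(mean_degree))
    repeat {
      degree_sequence <- stats::rpois(N, mean_degree)
      if (sum(degree_sequence) %% 2 == 0 &&
          igraph::is_graphical(degree_sequence)) break
    }
  }
  g <- sample_configuration(degree_sequence, accepted_per_link)
  deg <- igraph::degree(g)
  E <- igraph::ecount(g)
  mu <- sum(deg^2) / (2 * E)
  v <- sum(deg^3) / (2 * E) - mu^2
  if (v <= 0) stop("regular degree sequence: assortativity target unreachable")
  target_Se <- E * (v * target + mu^2)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  res <- cpp_drive_assortativity(el, igraph::vcount(g), target_Se,
                                 band = tol * E * v,
                                 max_proposals = 2000 * E + 1e6)
  g2 <- igraph::make_graph(t(res$edges + 1L), n = igraph::vcount(g),
                           directed = FALSE)
  g2 <- igraph::set_vertex_attr(g2, "name", value = igraph::V(g)$name)
  if (!res$reached) {
    warning(sprintf(
      "assortativity target %.3f unreachable; achieved %.3f", target,
      (res$Se / E - mu^2) / v))
  }
  g2
}
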