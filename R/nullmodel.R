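#' Degree-preserving randomisation of a network (null model)
#'
#' Draws a null model — a graph sampled uniformly from all simple graphs
#' with the observed degree sequence — by edge-swap Markov chain Monte
#' Carlo. A naive always-accept swap chain samples this space non-uniformly;
#' here the proposal is drawn uniformly from a state-independent candidate
#' set (ordered pairs of edges times the two re-pairings) and, in the default
#' `hold_counting` mode, proposals that would create a self-loop or duplicate
#' edge are executed as "stay" moves, making the chain symmetric with the
#' uniform distribution as its stationary law. The `mobility_ratio` mode
#' instead accepts an executable swap with probability
#' min(1, n(current)/n(proposed)), where n() counts executable swaps; it
#' targets the same uniform law at O(E^2) cost per proposal and is meant for
#' small graphs and cross-checks.
#'
#' The chain is run until the number of accepted (edge-changing) moves
#' reaches `accepted_per_link` times the number of edges; observables
#' (assortativity, normalised Hamming distance to the original) are logged
#' along the way so equilibration can be assessed.
#'
#' @param net igraph object with at least 2 edges.
#' @param accepted_per_link Target accepted moves per edge (default 100,
#'   an equilibration criterion validated by observable monitoring).
#' @param seed Optional integer seed; all randomness flows through R's RNG.
#' @param mode `"hold_counting"` (default) or `"mobility_ratio"`.
#' @param monitor_interval Accepted moves between trace records (default:
#'   one tenth of the target, at least 1).
#' @return Object of class `randomisation`: list with `graph` (igraph),
#'   `accepted`, `proposed`, `hamming_to_original`, and `trace`
#'   (data.frame: accepted, assortativity, hamming).
#' @examples
#' g <- generate_network("er", N = 200, mean_degree = 4, seed = 1)
#' r <- randomise_network(g, accepted_per_link = 20, seed = 2)
#' identical(igraph::degree(r$graph), igraph::degree(g))
#' r$hamming_to_original     # near 1: almost no shared edges
#' @export
randomise_network <- function(net, accepted_per_link = 100, seed = NULL,
                              mode = c("hold_counting", "mobility_ratio"),
                              monitor_interval = NULL) {
  mode <- match.arg(mode)
  check_network(net)
  E <- igraph::ecount(net)
  if (E < 2) stop("randomisation requires at least 2 edges")
  if (!is.null(seed)) set.seed(seed)
  target <- accepted_per_link * E
  if (is.null(monitor_interval)) monitor_interval <- max(1, floor(target / 10))
  el <- igraph::as_edgelist(net, names = FALSE) - 1L
  res <- cpp_mcmc(el, igraph::vcount(net), target,
                  mode = if (mode == "hold_counting") 0L else 1L,
                  monitor_every = as.integer(monitor_interval),
                  sample_every = 0L,
                  max_proposals = max(1e6, 400 * target))
  if (res$stalled && res$accepted == 0) {
    warning("degree sequence admits no executable swap; returned unchanged")
  } else if (res$stalled) {
    warning("proposal budget exhausted before the accepted-move target")
  }
  g2 <- igraph::make_graph(t(res$edges + 1L), n = igraph::vcount(net),
                           directed = FALSE)
  g2 <- igraph::set_vertex_attr(g2, "name", value = igraph::V(net)$name)
  structure(
    list(graph = g2, accepted = res$accepted, proposed = res$proposed,
         hamming_to_original = res$hamming,
         trace = data.frame(accepted = res$trace_accepted,
                            assortativity = res$trace_assortativity,
                            hamming = res$trace_hamming),
         mode = mode, accepted_per_link = accepted_per_link),
    class = "randomisation"
  )
}

#' @export
print.randomisation <- function(x, ...) {
  cat("Degree-preserving randomisation (", x$mode, ")\n", sep = "")
  cat(sprintf("  accepted %g of %g proposed moves (%.1f per link)\n",
              x$accepted, x$proposed,
              x$accepted / igraph::ecount(x$graph)))
  cat(sprintf("  normalised Hamming distance to original: %.4f\n",
              x$hamming_to_original))
  invisible(x)
}

#' Sample states of the edge-swap chain (for distributional checks)
#'
#' Runs the randomising chain and records a canonical signature of the edge
#' set every `thin` proposals, so the visit distribution over a small graph
#' space can be compared with the uniform law by exhaustive enumeration.
#'
#' @param net igraph object.
#' @param n_samples Number of recorded states.
#' @param thin Proposals between records.
#' @param seed Optional seed.
#' @param mode Acceptance mode, as in [randomise_network()].
#' @return Character vector of `n_samples` edge-set signatures (comma-joined
#'   sorted edge keys).
#' @export
sample_chain_states <- function(net, n_samples, thin = 10, seed = NULL,
                                mode = c("hold_counting", "mobility_ratio")) {
  mode <- match.arg(mode)
  check_network(net)
  if (!is.null(seed)) set.seed(seed)
  el <- igraph::as_edgelist(net, names = FALSE) - 1L
  res <- cpp_mcmc(el, igraph::vcount(net), Inf,
                  mode = if (mode == "hold_counting") 0L else 1L,
                  monitor_every = 0L, sample_every = as.integer(thin),
                  max_proposals = as.numeric(n_samples) * thin + 0.5)
  res$signatures[seq_len(n_samples)]
}

#' Normalised Hamming distance between two networks on the same node set
#'
#' Counts adjacency disagreements between two graphs matched by node
#' identifier and scales by the total number of edges,
#' \deqn{\Delta = \sum_{i<j} |c_{ij} - c'_{ij}| / (E + E'),}
#' so that identical networks give 0, edge-disjoint networks give 1, and two
#' statistically independent degree-matched sparse graphs give 1 in
#' expectation up to their O(1/N) chance overlap (see
#' [expected_hamming_independent()]).
#'
#' @param a,b igraph objects over the same node identifiers.
#' @return Non-negative real.
#' @export
hamming_distance <- function(a, b) {
  check_network(a); check_network(b)
  na <- sort(igraph::V(a)$name)
  nb <- sort(igraph::V(b)$name)
  if (length(na) != length(nb) || any(na != nb)) {
    stop("Hamming distance requires identical node sets")
  }
  ka <- edge_keys(a); kb <- edge_keys(b)
  disagreements <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  if (length(ka) + length(kb) == 0) return(0)
  disagreements / (length(ka) + length(kb))
}

edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character(0))
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
}

#' Expected Hamming distance between independent degree-matched graphs
#'
#' For two graphs drawn independently from the degree-constrained null
#' ensemble, a pair of nodes with degrees k_i, k_j is linked in each with
#' probability close to k_i k_j / 2E, so the expected edge overlap is
#' \eqn{\sum_{i<j} (k_i k_j / 2E)^2} and the expected normalised Hamming
#' distance falls short of 1 by that overlap divided by E. This finite-size
#' expectation tends to 1 as N grows at fixed mean degree.
#'
#' @param net igraph object (only its degree sequence is used).
#' @return Expected normalised Hamming distance, slightly below 1.
#' @export
expected_hamming_independent <- function(net) {
  k <- igraph::degree(net)
  E <- igraph::ecount(net)
  s1 <- sum(k); s2 <- sum(k^2)
  # sum over i<j of (k_i k_j)^2 = ((sum k^2)^2 - sum k^4) / 2
  overlap <- ((s2^2 - sum(k^4)) / 2) / (2 * E)^2
  1 - overlap / E
}

#' Original-versus-null-model comparison report
#'
#' Convenience bundle for the canonical use of the null model: draw a
#' degree-preserving randomisation and report its assortativity and wiring
#' complexity next to the original network's, together with the Hamming
#' distance between the two.
#'
#' @inheritParams randomise_network
#' @param sigma Smoothing width for the complexity computation (0 = exact).
#' @return List with `randomisation`, `original` and `null` sub-lists
#'   (each: `assortativity`, `complexity`), and `hamming`.
#' @export
null_model_report <- function(net, accepted_per_link = 100, seed = NULL,
                              mode = "hold_counting", sigma = 0) {
  r <- randomise_network(net, accepted_per_link, seed = seed, mode = mode)
  list(
    randomisation = r,
    original = list(assortativity = net_assortativity(net),
                    complexity = network_complexity(net, sigma = sigma)),
    null = list(assortativity = net_assortativity(r$graph),
                complexity = network_complexity(r$graph, sigma = sigma)),
    hamming = r$hamming_to_original
  )
}
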