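#' Average-linkage hierarchical clustering of a network distance matrix
#'
#' Clusters a collection of networks from their pairwise information-
#' theoretic distances with the 'average' agglomeration method (UPGMA), the
#' routine used to build network dendrograms from the distance measure.
#'
#' @param D Symmetric, zero-diagonal, non-negative distance matrix with
#'   labelled rows/columns (from [distance_matrix()]).
#' @return An [stats::hclust] object.
#' @export
cluster_networks <- function(D) {
  if (!is.matrix(D) || nrow(D) < 2L) stop("need a matrix over >= 2 networks")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(D < -1e-12)) stop("distance matrix must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  stats::hclust(stats::as.dist(D), method = "average")
}

#' Export a dendrogram as a Newick tree
#'
#' Converts an average-linkage dendrogram to a phylogenetic-tree object and
#' writes it in Newick format with branch lengths, so the clustering can be
#' compared against external reference trees with standard phylogenetics
#' tools.
#'
#' @param hc An `hclust` object from [cluster_networks()].
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
export_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Sub-sampling robustness curve
#'
#' Emulates incomplete interactome sampling: for each removal fraction f,
#' deletes floor(f N) uniformly chosen nodes, takes the induced subgraph
#' (retaining any nodes isolated by the removal), and measures the
#' information-theoretic distance between the subsample and the original
#' network. Repeated draws give a mean and standard deviation per fraction.
#' Networks with high wiring complexity are expected to drift away from
#' themselves faster under sub-sampling than low-complexity networks of the
#' same size.
#'
#' @param net igraph object.
#' @param fractions Removal fractions (default 0.1..0.9 by 0.1).
#' @param repeats Independent removal draws per fraction (default 10).
#' @param seed Optional seed.
#' @param sigma Smoothing width for the distances (default 1).
#' @param mode `"full"` (default) or `"degree_only"` distance.
#' @return Object of class `subsample_curve`: data.frame with columns
#'   `fraction`, `mean`, `sd`, `n_effective` (repeats that retained at least
#'   one edge).
#' @export
subsample_curve <- function(net, fractions = seq(0.1, 0.9, by = 0.1),
                            repeats = 10, seed = NULL, sigma = 1,
                            mode = c("full", "degree_only")) {
  mode <- match.arg(mode)
  check_network(net)
  stopifnot(all(fractions > 0), all(fractions < 1),
            all(diff(fractions) > 0), repeats >= 1)
  if (!is.null(seed)) set.seed(seed)
  s0 <- degree_stats(net)
  N <- igraph::vcount(net)
  rows <- lapply(fractions, function(f) {
    vals <- numeric(0)
    skipped <- 0L
    for (r in seq_len(repeats)) {
      drop <- sample.int(N, size = floor(f * N))
      sub <- igraph::delete_vertices(net, drop)
      if (igraph::ecount(sub) == 0L) {
        skipped <- skipped + 1L
        next
      }
      d <- network_distance(s0, degree_stats(sub), sigma = sigma)
      vals <- c(vals, if (mode == "full") d$full else d$degree_only)
    }
    if (skipped > 0L) {
      warning(sprintf("fraction %.2f: %d repeat(s) left no edges, skipped",
                      f, skipped))
    }
    data.frame(fraction = f,
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
               n_effective = length(vals))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subsample_curve", "data.frame")
  attr(out, "sigma") <- sigma
  attr(out, "mode") <- mode
  out
}

#' @export
plot.subsample_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    graphics::plot(x$fraction, x$mean, type = "b", col = col,
                   xlab = "fraction of nodes removed",
                   ylab = sprintf("distance to original (nats, sigma = %g)",
                                  attr(x, "sigma")),
                   ylim = c(0, max(x$mean + ifelse(is.na(x$sd), 0, x$sd),
                                   na.rm = TRUE)), ...)
  } else {
    graphics::lines(x$fraction, x$mean, type = "b", col = col, ...)
  }
  ok <- !is.na(x$sd)
  graphics::arrows(x$fraction[ok], x$mean[ok] - x$sd[ok],
                   x$fraction[ok], x$mean[ok] + x$sd[ok],
                   angle = 90, code = 3, length = 0.03, col = col)
  invisible(x)
}

#' Export a degree distribution or DDC kernel as TSV
#'
#' @param x A `degree_stats` or `ddc` object.
#' @param path Output path. Degree distributions are written as two columns
#'   (k, p); kernels as a degree-labelled matrix.
#' @return Invisibly, `path`.
#' @export
write_stats_tsv <- function(x, path) {
  if (inherits(x, "degree_stats")) {
    utils::write.table(
      data.frame(k = as.integer(names(x$p)), p = as.numeric(x$p)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "ddc")) {
    utils::write.table(x$W, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else stop("unsupported object")
  invisible(path)
}

#' Heat-map of a DDC kernel
#'
#' Renders W(k, k') with a dark-to-light scale: light regions indicate a
#' strongly enhanced propensity for the corresponding degree pair to be
#' linked, dark regions a suppressed one; W = 1 is the uncorrelated
#' reference. Undefined (off-support) pairs are left blank.
#'
#' @param ddc A `ddc` object.
#' @param kmax Largest degree displayed (default 35, where the kernel's
#'   estimator is still populated in typical interactomes).
#' @param ... Passed to [graphics::image()].
#' @export
plot_ddc <- function(ddc, kmax = 35, ...) {
  stopifnot(inherits(ddc, "ddc"))
  kk <- min(kmax, nrow(ddc$W))
  W <- ddc$W[seq_len(kk), seq_len(kk), drop = FALSE]
  graphics::image(1:kk, 1:kk, W, col = grDevices::grey.colors(64, 0.05, 0.97),
                  xlab = "k", ylab = "k'", useRaster = TRUE, ...)
  graphics::box()
  invisible(W)
}
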