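#' Read an undirected interaction network from a plain-text edge list
#'
#' Parses a two-column edge list (whitespace- or tab-separated node
#' identifiers, one interaction per line) into a clean undirected simple
#' graph. Any bait--prey orientation in the raw records is discarded: records
#' are symmetrised, self-interactions are dropped, and duplicate records (in
#' either orientation) are collapsed to a single edge. Lines starting with
#' `#` or `!` are treated as comments. A line with a single token declares an
#' isolated node, so that degree-zero proteins can be represented explicitly.
#'
#' @param path Path to the edge-list file.
#' @param strict If `TRUE`, a malformed line (more than 0 but otherwise
#'   unusable tokens never occurs here; kept for interface symmetry) raises an
#'   error instead of a warning. Default `FALSE` (lenient).
#' @param keep_isolated If `TRUE` (default) single-token lines declare
#'   isolated nodes that are retained; if `FALSE` they are ignored.
#'
#' @return An [igraph][igraph::igraph-package] object with character vertex
#'   names. Graph attributes `dropped_self` and `dropped_dup` record how many
#'   records were removed as self-interactions or duplicates.
#' @export
read_edge_list <- function(path, strict = FALSE, keep_isolated = TRUE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^[#!]", lines)]
  if (length(lines) == 0L) stop("zero parsable records in ", path)
  toks <- strsplit(lines, "[ \t]+")
  nfld <- lengths(toks)
  singles <- character(0)
  if (any(nfld == 1L)) {
    if (keep_isolated) singles <- vapply(toks[nfld == 1L], `[`, "", 1L)
    toks <- toks[nfld >= 2L]
  }
  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, `[`, "", 2L)
  build_network(a, b, singles = singles, what = path)
}

#' Read a minimal PSI-MI TAB (MITAB) file
#'
#' Extracts the interactor A and interactor B identifier columns (columns 1
#' and 2) of a tab-separated MITAB file and applies the same normalisation as
#' [read_edge_list()]: symmetrisation, self-interaction removal, duplicate
#' collapsing. Identifiers are kept verbatim (after whitespace trimming);
#' no accession mapping is attempted. All other MITAB columns are ignored.
#'
#' @param path Path to the MITAB file.
#' @return An igraph object; see [read_edge_list()].
#' @export
read_mitab <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^[#!]", lines)]
  if (length(lines) == 0L) stop("zero parsable records in ", path)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 2L)) {
    stop("MITAB record with fewer than 2 tab-separated columns in ", path)
  }
  a <- trimws(vapply(toks, `[`, "", 1L))
  b <- trimws(vapply(toks, `[`, "", 2L))
  build_network(a, b, singles = character(0), what = path)
}

# Shared normalisation: symmetrise, drop self-loops, collapse duplicates.
build_network <- function(a, b, singles = character(0), what = "input") {
  a <- trimws(a); b <- trimws(b)
  self <- a == b
  n_self <- sum(self)
  a2 <- a[!self]; b2 <- b[!self]
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  nodes <- unique(c(a, b, trimws(singles)))
  if (length(nodes) == 0L) stop("zero parsable records in ", what)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  if (n_self > 0L) {
    warning(sprintf("%d self-interaction record(s) dropped", n_self))
  }
  g$dropped_self <- n_self
  g$dropped_dup <- n_dup
  g
}

#' Write a network as a plain-text edge list
#'
#' Writes one edge per line (two tab-separated node identifiers). Isolated
#' nodes are written as single-token lines so that the file round-trips
#' through [read_edge_list()] with the node set intact.
#'
#' @param net An igraph object with named vertices.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net, names = TRUE)
  iso <- igraph::V(net)$name[igraph::degree(net) == 0L]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(el) > 0L) {
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  }
  if (length(iso) > 0L) writeLines(iso, con)
  invisible(path)
}

#' Validate the simple-graph invariants of an interaction network
#'
#' Checks that a graph is undirected, has no self-loops and no multi-edges,
#' and carries character vertex names — the representation every other
#' function in this package assumes (the symmetric adjacency matrix with a
#' zero diagonal).
#'
#' @param net An igraph object.
#' @return `net`, invisibly; errors if an invariant is violated.
#' @export
check_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("not an igraph object")
  if (igraph::is_directed(net)) stop("network must be undirected")
  if (any(igraph::which_loop(net))) stop("network must not contain self-loops")
  if (any(igraph::which_multiple(net))) stop("network must be a simple graph")
  if (is.null(igraph::V(net)$name)) stop("vertices must be named")
  invisible(net)
}
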