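#' Pearson correlation matrix across samples
#'
#' Correlation of each pair of genes across all samples (replicates as
#' separate points). Constant genes have undefined correlation; their entries
#' are NA with a warning and yield no edges downstream.
#'
#' @param scaled Numeric matrix (genes x samples), typically centered CPM
#'   from [center_genes()]; correlation is invariant to per-gene affine
#'   transforms, so centering only matters downstream.
#' @param gene_subset Optional character vector of genes to restrict to.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(scaled, gene_subset = NULL) {
  x <- as.matrix(scaled)
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0) stop("'gene_subset' is empty")
    missing <- setdiff(gene_subset, rownames(x))
    if (length(missing) > 0) {
      stop("gene(s) not in matrix: ", paste(utils::head(missing, 5),
                                            collapse = ", "))
    }
    x <- x[gene_subset, , drop = FALSE]
  }
  if (ncol(x) < 3) stop("need at least 3 samples to correlate")
  sds <- apply(x, 1, stats::sd)
  pcc <- suppressWarnings(stats::cor(t(x)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) have undefined PCC (NA)")
  }
  diag(pcc) <- 1
  pcc
}

#' Construct a co-expression graph from an edge table or node set
#'
#' Low-level constructor used by [build_graph()] and by the community
#' detection tests. Edges are stored with endpoints ordered so `a < b`
#' lexicographically and sorted; the node set defaults to the union of edge
#' endpoints.
#'
#' @param edges Data.frame with columns `a`, `b` (character) and optionally
#'   `weight`.
#' @param nodes Optional node IDs (isolated nodes allowed here; the
#'   high-level [build_graph()] excludes them).
#' @return An object of class `coex_graph`: list with `nodes` (character)
#'   and `edges` (data.frame `a`, `b`, `weight`).
#' @export
coex_graph <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(a = character(0), b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    a <- as.character(edges$a); b <- as.character(edges$b)
    if (any(a == b)) stop("self-loops are not allowed")
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, length(a))
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges <- data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE)
    if (anyDuplicated(paste(a, b, sep = "\r"))) stop("duplicate edge(s)")
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$a, edges$b)))
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "coex_graph")
}

#' @export
#' @method print coex_graph
print.coex_graph <- function(x, ...) {
  cat(sprintf("coex_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Threshold a correlation matrix into a co-expression graph
#'
#' An edge connects two genes iff their PCC strictly exceeds `threshold`
#' (signed rule: anti-correlated pairs are not connected; set
#' `absolute = TRUE` to threshold |PCC| instead). Genes with no edge are
#' excluded from the node set, since they can never belong to a community of
#' the minimum size.
#'
#' @param pcc Symmetric correlation matrix from [pcc_matrix()].
#' @param genes Gene IDs (default: rownames of `pcc`).
#' @param threshold Correlation threshold in (-1, 1), default 0.9.
#' @param absolute Threshold on absolute correlation (default FALSE).
#' @return A `coex_graph` whose edge weights are the correlations.
#' @export
build_graph <- function(pcc, genes = rownames(pcc), threshold = 0.9,
                        absolute = FALSE) {
  if (threshold <= -1 || threshold >= 1) stop("'threshold' must be in (-1, 1)")
  pcc <- as.matrix(pcc)
  stopifnot(nrow(pcc) == ncol(pcc), length(genes) == nrow(pcc))
  val <- if (absolute) abs(pcc) else pcc
  idx <- which(upper.tri(val) & !is.na(val) & val > threshold, arr.ind = TRUE)
  edges <- data.frame(a = genes[idx[, 1]], b = genes[idx[, 2]],
                      weight = pcc[idx], stringsAsFactors = FALSE)
  coex_graph(edges)
}

#' Write a graph edge list as TSV
#'
#' @param g A `coex_graph`.
#' @param path Output path; columns `gene_a`, `gene_b`, `pcc`.
#' @export
write_graph_edges <- function(g, path) {
  stopifnot(inherits(g, "coex_graph"))
  d <- data.frame(gene_a = g$edges$a, gene_b = g$edges$b, pcc = g$edges$weight)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph to GraphML
#'
#' Minimal GraphML serialization (undirected, edge weight attribute) for use
#' in external network viewers.
#'
#' @param g A `coex_graph`.
#' @param path Output path.
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "coex_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', g$nodes), con)
  if (nrow(g$edges) > 0) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
      g$edges$a, g$edges$b, g$edges$weight), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}
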