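# Node-removal (RCA) and betweenness (BCA) centrality with Z-scoring.
#
# Disconnection convention: the average shortest path length L averages
# over connected node pairs only; pairs in different components drop out of
# both numerator and denominator, and a graph with no connected pair has
# L = 0.  Node removal that disconnects the graph is thereby penalized or
# rewarded through the changed pair set.  The convention is recorded in the
# result metadata.

#' Average shortest path length over connected pairs
#'
#' Mean of unweighted shortest-path lengths over all unordered node pairs
#' that are connected; pairs in different components are excluded from both
#' numerator and denominator.  If no connected pair exists the value is 0.
#'
#' @param g A [RIN-class] or an \pkg{igraph} graph with at least 2 nodes.
#' @return The mean path length (dimensionless edge count).
#' @examples
#' averageShortestPathLength(RIN(c("A", "B", "C"),
#'   data.frame(from = c("A", "B"), to = c("B", "C"))))  # 4/3
#' @export
averageShortestPathLength <- function(g) {
  if (is(g, "RIN")) g <- asIgraph(g)
  if (igraph::vcount(g) < 2) stop("need at least 2 nodes")
  .aspl(g)
}

.aspl <- function(g) {
  if (igraph::vcount(g) < 2) return(0)
  m <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (!is.finite(m)) 0 else m
}

#' Population Z-scores
#'
#' Standardizes values against the mean and \emph{population} standard
#' deviation (divisor \eqn{n}) of the whole population.  Zero spread maps
#' every value to Z = 0.  Z-scores are invariant under adding a constant to
#' all values and under scaling by a positive constant.
#'
#' @param values Named numeric vector (names are node labels).
#' @param population Labels defining the normalization population; default
#'   all of \code{values}.  Every value label must belong to it.
#' @return Named numeric vector of Z-scores for \code{values}.
#' @export
zScores <- function(values, population = names(values)) {
  if (length(population) == 0) stop("population must be non-empty")
  if (!all(names(values) %in% population))
    stop("values outside the normalization population: ",
         paste(setdiff(names(values), population), collapse = ", "))
  if (!all(population %in% names(values)))
    stop("values missing for population members")
  x <- values[population]
  s <- .popSD(x)
  if (s == 0 || !is.finite(s))
    return(stats::setNames(rep(0, length(values)), names(values)))
  (values - mean(x)) / s
}

.centralityResult <- function(rin, method, raw) {
  n <- rin@nodes
  z <- zScores(stats::setNames(raw, n$label))
  new("CentralityResult", method = method,
      table = data.frame(label = n$label, kind = n$kind, chain = n$chain,
                         interface = n$interface, raw = as.numeric(raw),
                         z = as.numeric(z)),
      metadata = c(rin@metadata,
                   list(population = nrow(n),
                        disconnection = "mean over connected pairs only")))
}

#' Residue centrality analysis (node-removal centrality)
#'
#' Scores each node by the effect of its removal on the network's average
#' shortest path length: \eqn{raw_i = L(G - i) - L(G)}, with \eqn{L} as in
#' [averageShortestPathLength()] and \eqn{G - i} the graph without node
#' \eqn{i} and its incident edges.  Nodes whose removal lengthens
#' communication paths get positive raw values.  Z-scores are computed over
#' all nodes of the network -- water nodes included when present, so
#' residue and water scores share one normalization population.
#'
#' @param rin A [RIN-class] with at least 3 nodes.
#' @return A [CentralityResult-class] with \code{method = "RCA"}.
#' @export
rca <- function(rin) {
  g <- asIgraph(rin)
  nv <- igraph::vcount(g)
  if (nv < 3) stop("RCA needs at least 3 nodes")
  L0 <- .aspl(g)
  raw <- vapply(seq_len(nv), function(i) {
    .aspl(igraph::delete_vertices(g, i)) - L0
  }, numeric(1))
  .centralityResult(rin, "RCA", raw)
}

#' Betweenness centrality analysis
#'
#' Scores each node by its unnormalized shortest-path betweenness: the sum
#' over unordered node pairs \eqn{(s, t)} (both distinct from \eqn{i}) of
#' the fraction of shortest \eqn{s}-\eqn{t} paths passing through \eqn{i}
#' (Brandes' algorithm via \pkg{igraph}).  The normalization choice cancels
#' in Z-scoring, which is invariant under positive rescaling.  Z-scores use
#' the same all-node population as [rca()].
#'
#' @param rin A [RIN-class] with at least 3 nodes.
#' @return A [CentralityResult-class] with \code{method = "BCA"}.
#' @export
bca <- function(rin) {
  g <- asIgraph(rin)
  if (igraph::vcount(g) < 3) stop("BCA needs at least 3 nodes")
  raw <- igraph::betweenness(g, directed = FALSE, weights = NULL,
                             normalized = FALSE)
  .centralityResult(rin, "BCA", raw)
}

#' @rdname CentralityResult-class
#' @export
setMethod("centralityTable", "CentralityResult", function(x) x@table)

#' @rdname CentralityResult-class
#' @export
setMethod("centralityMethod", "CentralityResult", function(x) x@method)

#' @export
setMethod("centralNodes", "CentralityResult", function(x, threshold = 2) {
  tb <- x@table[x@table$z >= threshold, , drop = FALSE]
  tb$label[order(-tb$z, tb$label)]
})

setMethod("show", "CentralityResult", function(object) {
  tb <- object@table
  cen <- centralNodes(object)
  cat(object@method, " on RIN [", object@metadata$variant %||% "?", "]: ",
      nrow(tb), " nodes, ", length(cen), " central (Z >= 2)",
      if (length(cen)) paste0(": ", paste(utils::head(cen, 8), collapse = ", "),
                              if (length(cen) > 8) ", ..."),
      "\n", sep = "")
})

#' Write a centrality result as a TSV table
#'
#' Columns \code{label}, \code{kind}, \code{chain}, \code{raw}, \code{z},
#' \code{central} (logical, Z at or above the cutoff).
#'
#' @param x A [CentralityResult-class].
#' @param path Output path.
#' @param threshold Central-node cutoff (default 2).
#' @return \code{path}, invisibly.
#' @export
writeCentralityTable <- function(x, path, threshold = 2) {
  tb <- x@table
  tb$central <- tb$z >= threshold
  utils::write.table(format(tb, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
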