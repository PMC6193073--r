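# Shared helpers: node labels, canonical edges, distance kernels.

#' Node label for a residue or water
#'
#' Formats the conventional RIN node label
#' \code{"<ResName><resno><insert>.<chain>"}, with the residue name in
#' title case: \code{nodeLabel("ARG", 98, "B")} is \code{"Arg98.B"} and a
#' water oxygen becomes e.g. \code{"Hoh354.A"}.  Insertion codes, when
#' present, are appended to the residue number.
#'
#' @param resname Three-letter residue name(s).
#' @param resno Author residue number(s).
#' @param chain Chain identifier(s).
#' @param insert Insertion code(s); blank or NA for none.
#' @return Character vector of labels.
#' @export
nodeLabel <- function(resname, resno, chain, insert = "") {
  insert[is.na(insert) | insert == " "] <- ""
  rn <- paste0(toupper(substr(resname, 1, 1)),
               tolower(substr(resname, 2, nchar(resname))))
  paste0(rn, resno, insert, ".", chain)
}

# Canonical undirected edge storage: smaller label first, sorted, unique.
canonicalEdges <- function(edges) {
  if (NROW(edges) == 0)
    return(data.frame(from = character(), to = character()))
  from <- pmin(edges$from, edges$to)
  to <- pmax(edges$from, edges$to)
  e <- unique(data.frame(from = from, to = to))
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# Squared-distance matrix between two coordinate matrices (rows = points).
.crossDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # guard against round-off
  d2
}

# Minimum Euclidean distance between two atom coordinate matrices.
.minCrossDist <- function(A, B) sqrt(min(.crossDist2(A, B)))

# Split an atom table into per-residue coordinate matrices plus a
# residue-level summary (label, kind, chain, centroid, bounding radius).
.residueGeometry <- function(atoms) {
  idx <- split(seq_len(nrow(atoms)), atoms$label)
  first <- vapply(idx, `[`, integer(1), 1L)
  # preserve order of first appearance
  ord <- order(first)
  idx <- idx[ord]
  first <- first[ord]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  coords <- lapply(idx, function(i) xyz[i, , drop = FALSE])
  cen <- t(vapply(coords, colMeans, numeric(3)))
  rad <- vapply(seq_along(coords), function(k) {
    d <- coords[[k]] - matrix(cen[k, ], nrow(coords[[k]]), 3, byrow = TRUE)
    sqrt(max(rowSums(d^2)))
  }, numeric(1))
  list(label = names(idx),
       kind = atoms$kind[first],
       chain = atoms$chain[first],
       coords = coords, centroid = cen, radius = rad)
}

# All residue pairs whose minimum heavy-atom distance is below `cutoff`
# (strict) or at most `cutoff` (inclusive = TRUE).  Pairs are pre-screened
# by centroid distance minus bounding radii, then resolved exactly; a
# brute-force all-pairs oracle in the test suite guards this pruning.
# `mask` optionally restricts to pairs (i in rows, j in cols) where TRUE.
.contactPairs <- function(geom, cutoff, inclusive = FALSE, mask = NULL) {
  n <- length(geom$label)
  if (n < 2) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  cend <- sqrt(.crossDist2(geom$centroid, geom$centroid))
  bound <- outer(geom$radius, geom$radius, "+") + cutoff
  cand <- which(upper.tri(cend) & cend <= bound + 1e-9, arr.ind = TRUE)
  if (!is.null(mask)) {
    keep <- mask[cand] | mask[cand[, c(2, 1), drop = FALSE]]
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0)
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  d <- vapply(seq_len(nrow(cand)), function(k) {
    .minCrossDist(geom$coords[[cand[k, 1]]], geom$coords[[cand[k, 2]]])
  }, numeric(1))
  ok <- if (inclusive) d <= cutoff else d < cutoff
  data.frame(i = cand[ok, 1], j = cand[ok, 2], dist = d[ok])
}

# Population standard deviation (divisor n).
.popSD <- function(x) sqrt(mean((x - mean(x))^2))
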