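# Independent graph oracles, deliberately igraph-free: plain-R BFS,
# exhaustive shortest-path enumeration and remove-and-recompute ASPL.
# These validate the package's centrality path from a second route.

# adjacency matrix (0/1, symmetric) -> all-pairs BFS distance matrix
oracleDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] > 0 & !is.finite(dist))
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# mean shortest path length over connected unordered pairs; 0 if none
oracleASPL <- function(adj) {
  D <- oracleDistances(adj)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (length(v) == 0) 0 else mean(v)
}

# enumerate all shortest s-t paths by recursive backtracking on BFS levels
.allShortestPaths <- function(adj, s, t, dist) {
  if (!is.finite(dist[t])) return(list())
  recurse <- function(v) {
    if (v == s) return(list(s))
    preds <- which(adj[v, ] > 0 & dist == dist[v] - 1)
    out <- list()
    for (p in preds)
      for (pp in recurse(p)) out <- c(out, list(c(pp, v)))
    out
  }
  recurse(t)
}

# unnormalized betweenness over unordered pairs by full path enumeration
oracleBetweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    dist <- oracleDistances(adj)[s, ]
    for (t in (s + 1):n) {
      paths <- .allShortestPaths(adj, s, t, dist)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

# naive node-removal RCA raw values: L(G - i) - L(G)
oracleRCA <- function(adj) {
  base <- oracleASPL(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    oracleASPL(adj[-i, -i, drop = FALSE]) - base
  }, numeric(1))
}

# population-SD z-scores
oracleZ <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

# Erdos-Renyi-ish random graph, resampled until connected
randomConnectedAdj <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0, n, n)
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- 1
    adj <- adj + t(adj)
    if (all(is.finite(oracleDistances(adj)[1, ]))) return(adj)
  }
}

# RIN from a 0/1 adjacency matrix with labels n01, n02, ...
rinFromAdj <- function(adj, kind = NULL) {
  n <- nrow(adj)
  labels <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  nodes <- data.frame(label = labels,
                      kind = if (is.null(kind)) "residue" else kind)
  RIN(nodes, data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]]))
}

# RIN from an edge list given as a character vector c("A-B", "B-C")
rinFromEdges <- function(edgeSpec, nodes = NULL, kind = NULL) {
  parts <- strsplit(edgeSpec, "-", fixed = TRUE)
  e <- data.frame(from = vapply(parts, `[`, character(1), 1),
                  to = vapply(parts, `[`, character(1), 2))
  if (is.null(nodes)) nodes <- sort(unique(c(e$from, e$to)))
  nd <- data.frame(label = nodes)
  if (!is.null(kind)) nd$kind <- kind
  RIN(nd, e)
}
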