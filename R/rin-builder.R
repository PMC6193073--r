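# Residue interaction network construction.
#
# Contact rules: residue-residue edge when the minimum heavy-atom distance
# is strictly below d_rr (5 A); water-water and water-residue edges strictly
# below d_w (3.5 A).  Interface residues are those with any atom within
# (inclusive) d_int = 7 A of any atom of the partner chain group.

#' Contact and interface distance thresholds
#'
#' @param d_rr Residue-residue contact cutoff in Angstrom (strict
#'   "below"); default 5.
#' @param d_w Water-water and water-residue contact cutoff in Angstrom
#'   (strict "below"); default 3.5.
#' @param d_int Interface cutoff in Angstrom (inclusive "within");
#'   default 7.
#' @return A list of class \code{ContactThresholds}.
#' @export
contactThresholds <- function(d_rr = 5, d_w = 3.5, d_int = 7) {
  stopifnot(d_rr > 0, d_w > 0, d_int > 0)
  structure(list(d_rr = d_rr, d_w = d_w, d_int = d_int),
            class = "ContactThresholds")
}

#' Build a residue interaction network
#'
#' Constructs one of four network variants from a structure:
#' \describe{
#'   \item{\code{"dry"}}{water nodes dropped before edge detection;
#'     residue-residue edges only.}
#'   \item{\code{"wet"}}{waters included as nodes; residue-residue edges
#'     below \code{d_rr}, water-involving edges below \code{d_w}.}
#'   \item{\code{"wet_uniform"}}{as \code{"wet"} but with a single uniform
#'     contact cutoff \code{d_w} (default 3.5 Angstrom) for all node pairs
#'     -- a control that removes the threshold asymmetry between residue
#'     and water contacts.}
#'   \item{\code{"interface_waters"}}{as \code{"wet"}, but only waters
#'     adjacent to at least one interface residue are retained; edges are
#'     recomputed among the survivors (water-water contacts between
#'     surviving interface waters are kept).  Requires \code{chainGroups}.}
#' }
#' Edges use the strict "below" convention, so a pair at exactly the cutoff
#' distance is not in contact.  Water inclusion never alters the
#' residue-residue edge set: a wet RIN restricted to residue nodes equals
#' the dry RIN.
#'
#' @param x A [Structure-class] with at least 2 residues.
#' @param variant One of \code{"wet"}, \code{"dry"}, \code{"wet_uniform"},
#'   \code{"interface_waters"}.
#' @param thresholds A [contactThresholds()] list.
#' @param chainGroups Optional list of two character vectors partitioning
#'   the protein chains; when supplied, interface residues are annotated
#'   with [annotateInterface()] and flagged on the nodes.  Mandatory for
#'   \code{variant = "interface_waters"}.
#' @return A [RIN-class].
#' @examples
#' s <- generateComplex(synthParams(nResPerChain = 8, nWaters = 10, seed = 3))
#' buildRIN(s, "wet", chainGroups = list("A", "B"))
#' @export
buildRIN <- function(x, variant = c("wet", "dry", "wet_uniform", "interface_waters"),
                     thresholds = contactThresholds(), chainGroups = NULL) {
  variant <- match.arg(variant)
  a <- x@atoms
  if (variant == "dry") a <- a[a$kind != "water", , drop = FALSE]
  rt <- unique(a$label)
  if (length(rt) < 2) stop("structure error: need at least 2 residues")
  if (variant == "interface_waters" && is.null(chainGroups))
    stop("variant 'interface_waters' requires chainGroups")

  interfaceLabels <- character()
  if (!is.null(chainGroups))
    interfaceLabels <- annotateInterface(x, chainGroups[[1]], chainGroups[[2]],
                                         thresholds$d_int)

  t <- thresholds
  if (variant == "wet_uniform") t$d_rr <- t$d_w

  rin <- .detectEdges(a, t, x@id, variant, interfaceLabels)

  if (variant == "interface_waters") {
    keepW <- interfaceWaters(rin)
    dropW <- setdiff(rin@nodes$label[rin@nodes$kind == "water"], keepW)
    rin <- .induceSubgraph(rin, setdiff(rin@nodes$label, dropW))
    rin@metadata$interfaceWaterCount <- length(keepW)
  }
  rin
}

.detectEdges <- function(atoms, t, id, variant, interfaceLabels) {
  geom <- .residueGeometry(atoms)
  nodes <- data.frame(label = geom$label, kind = geom$kind, chain = geom$chain,
                      interface = geom$label %in% interfaceLabels)
  cutMax <- max(t$d_rr, t$d_w)
  pairs <- .contactPairs(geom, cutMax, inclusive = FALSE)
  if (nrow(pairs)) {
    hasWater <- geom$kind[pairs$i] == "water" | geom$kind[pairs$j] == "water"
    cut <- ifelse(hasWater, t$d_w, t$d_rr)
    pairs <- pairs[pairs$dist < cut, , drop = FALSE]
  }
  edges <- canonicalEdges(data.frame(from = geom$label[pairs$i],
                                     to = geom$label[pairs$j]))
  new("RIN", nodes = nodes, edges = edges,
      metadata = list(variant = variant, thresholds = unclass(t),
                      structureId = id))
}

.induceSubgraph <- function(rin, keep) {
  nodes <- rin@nodes[rin@nodes$label %in% keep, , drop = FALSE]
  rownames(nodes) <- NULL
  e <- rin@edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  new("RIN", nodes = nodes, edges = e, metadata = rin@metadata)
}

#' Annotate interface residues between two chain groups
#'
#' A protein residue is at the interface if any of its heavy atoms lies
#' within \code{d_int} (inclusive) of any heavy atom of a residue in the
#' other chain group.  Waters never enter the computation: the interface is
#' defined by protein atoms only.
#'
#' @param x A [Structure-class].
#' @param group1,group2 Character vectors of chain identifiers; both groups
#'   must contain protein residues.
#' @param d_int Interface cutoff in Angstrom (default 7).
#' @return Character vector of interface residue labels (both groups).
#' @export
annotateInterface <- function(x, group1, group2, d_int = 7) {
  if (length(intersect(group1, group2)))
    stop("chain groups must be disjoint")
  a <- x@atoms
  a <- a[a$kind == "residue" & a$chain %in% c(group1, group2), , drop = FALSE]
  inG1 <- unique(a$label[a$chain %in% group1])
  inG2 <- unique(a$label[a$chain %in% group2])
  if (length(inG1) == 0 || length(inG2) == 0)
    stop("structure error: a chain group contains no protein residues")
  geom <- .residueGeometry(a)
  g1 <- geom$label %in% inG1
  mask <- outer(g1, !g1, "&")  # cross-group pairs only
  pairs <- .contactPairs(geom, d_int, inclusive = TRUE, mask = mask)
  sort(unique(c(geom$label[pairs$i], geom$label[pairs$j])))
}

#' Interface waters of a wet RIN
#'
#' A water molecule belongs to the interface if it is adjacent (one edge)
#' to at least one interface residue in the network.
#'
#' @param rin A [RIN-class] whose nodes carry interface flags.
#' @param interface Character vector of interface residue labels; defaults
#'   to the nodes flagged in \code{rin}.
#' @return Character vector of water node labels (possibly empty).
#' @export
interfaceWaters <- function(rin, interface = NULL) {
  n <- rin@nodes
  if (is.null(interface)) interface <- n$label[n$interface & n$kind == "residue"]
  waters <- n$label[n$kind == "water"]
  if (length(waters) == 0) return(character())
  e <- rin@edges
  touch <- c(e$from[e$to %in% interface], e$to[e$from %in% interface])
  sort(intersect(waters, touch))
}

#' Remove water nodes from a wet RIN
#'
#' Three selectors mirror the water-removal experiments: the single water
#' of maximum degree (ties broken by lexicographic node label), all waters
#' of degree at least \code{k}, or an explicit label list (e.g. waters
#' conserved across a protein family).  Selected waters and their incident
#' edges are removed; the selector and removed labels are recorded in the
#' metadata.
#'
#' @param rin A wet [RIN-class].
#' @param selector \code{"max_degree"}, \code{"degree_ge"} or
#'   \code{"explicit"}.
#' @param k Degree cutoff for \code{"degree_ge"}.
#' @param labels Water labels for \code{"explicit"}.
#' @return A [RIN-class] without the selected waters.
#' @export
removeWaterNodes <- function(rin, selector = c("max_degree", "degree_ge", "explicit"),
                             k = NULL, labels = NULL) {
  selector <- match.arg(selector)
  n <- rin@nodes
  waters <- n$label[n$kind == "water"]
  deg <- nodeDegrees(rin)
  remove <- switch(selector,
    max_degree = {
      if (length(waters) == 0) character() else {
        wd <- deg[waters]
        sort(names(wd)[wd == max(wd)])[1]
      }
    },
    degree_ge = {
      if (is.null(k)) stop("selector 'degree_ge' requires k")
      waters[deg[waters] >= k]
    },
    explicit = {
      if (is.null(labels)) stop("selector 'explicit' requires labels")
      bad <- setdiff(labels, waters)
      if (length(bad))
        stop("not water nodes of this RIN: ", paste(bad, collapse = ", "))
      labels
    })
  out <- .induceSubgraph(rin, setdiff(n$label, remove))
  out@metadata$waterRemoval <- list(selector = selector, k = k,
                                    removed = sort(remove))
  out
}

#' Node degrees of a RIN
#'
#' @param rin A [RIN-class].
#' @return Named integer vector over all nodes (isolated nodes have 0).
#' @export
nodeDegrees <- function(rin) {
  d <- table(factor(c(rin@edges$from, rin@edges$to), levels = rin@nodes$label))
  stats::setNames(as.integer(d), names(d))
}

#' @rdname RIN-class
#' @export
setMethod("nodeTable", "RIN", function(x) x@nodes)

#' @rdname RIN-class
#' @export
setMethod("edgeTable", "RIN", function(x) x@edges)

#' @rdname RIN-class
#' @export
setMethod("rinMetadata", "RIN", function(x) x@metadata)

#' @export
setMethod("asIgraph", "RIN", function(x) {
  igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                vertices = x@nodes)
})

setMethod("show", "RIN", function(object) {
  n <- object@nodes
  cat("RIN [", object@metadata$variant, "] on '",
      object@metadata$structureId %||% "?", "': ",
      sum(n$kind == "residue"), " residue + ",
      sum(n$kind == "water"), " water nodes, ",
      nrow(object@edges), " edges, ",
      sum(n$interface), " interface-flagged nodes\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a RIN as a SIF edge list
#'
#' Writes the standard simple-interaction-format edge list
#' (\code{label<TAB>contact<TAB>label}), loadable by common network
#' visualization tools.  Isolated nodes are appended as single-column rows
#' so the full node set survives a round trip.
#'
#' @param rin A [RIN-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSIF <- function(rin, path) {
  e <- rin@edges
  lines <- if (nrow(e)) paste(e$from, "contact", e$to, sep = "\t") else character()
  iso <- setdiff(rin@nodes$label, c(e$from, e$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a SIF edge list back into node and edge tables
#'
#' Inverse of [writeSIF()] for round-trip checks and interchange.
#'
#' @param path SIF file path.
#' @return List with \code{nodes} (character) and \code{edges} (data frame).
#' @export
readSIF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  isEdge <- lengths(parts) >= 3
  edges <- data.frame(
    from = vapply(parts[isEdge], `[`, character(1), 1),
    to = vapply(parts[isEdge], `[`, character(1), 3))
  nodes <- sort(unique(c(edges$from, edges$to,
                         vapply(parts[!isEdge], `[`, character(1), 1))))
  list(nodes = nodes, edges = canonicalEdges(edges))
}

#' Export the node attribute table of a RIN
#'
#' Tab-separated table with columns \code{label}, \code{kind},
#' \code{chain}, \code{interface}, \code{degree}.
#'
#' @param rin A [RIN-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeNodeTable <- function(rin, path) {
  n <- rin@nodes
  n$degree <- nodeDegrees(rin)[n$label]
  utils::write.table(n, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
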