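#' @import methods
NULL

#' Structure: a normalized atomic model of a protein complex
#'
#' A \code{Structure} holds heavy atoms of one or more protein chains plus
#' crystallographic water molecules, in a flat atom table.  Each residue
#' (protein or water) carries a unique node label of the form
#' \code{"<ResName><resno><insert>.<chain>"}, e.g. \code{"Arg98.B"} or
#' \code{"Hoh354.A"}; these labels name the nodes of every network derived
#' from the structure.
#'
#' @slot id Free-text structure identifier (e.g. a PDB accession).
#' @slot atoms A \code{data.frame} with one row per atom and columns
#'   \code{chain}, \code{resno}, \code{insert}, \code{resname}, \code{kind}
#'   (\code{"residue"} or \code{"water"}), \code{label}, \code{elety} (atom
#'   name), \code{element}, \code{x}, \code{y}, \code{z}, \code{occupancy},
#'   \code{altloc}.
#' @slot metadata List of provenance and policy records (source file,
#'   filtering decisions, chain selection).
#'
#' @seealso [readPDB()], [Structure()], [generateComplex()]
#' @export
setClass("Structure",
  representation(id = "character", atoms = "data.frame", metadata = "list"),
  prototype(id = NA_character_, atoms = data.frame(), metadata = list()))

.atomCols <- c("chain", "resno", "insert", "resname", "kind", "label",
               "elety", "element", "x", "y", "z", "occupancy", "altloc")

setValidity("Structure", function(object) {
  a <- object@atoms
  msg <- character()
  missing <- setdiff(.atomCols, names(a))
  if (length(missing))
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(c(a$x, a$y, a$z))))
      msg <- c(msg, "atom coordinates must be finite")
    if (any(a$occupancy < 0 | a$occupancy > 1, na.rm = TRUE))
      msg <- c(msg, "occupancy must lie in [0, 1]")
    isw <- toupper(a$resname) == "HOH"
    if (!all((a$kind == "water") == isw))
      msg <- c(msg, "kind must be 'water' exactly for residue name HOH")
    if (!all(a$kind %in% c("residue", "water")))
      msg <- c(msg, "kind must be 'residue' or 'water'")
    key <- paste(a$chain, a$resno, a$insert, a$resname)
    lab <- tapply(key, a$label, function(k) length(unique(k)))
    if (any(lab > 1))
      msg <- c(msg, "node labels must be unique across residues")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a Structure from an atom table
#'
#' Low-level constructor used by the PDB reader, the synthetic-structure
#' generator and test fixtures.  Node labels are (re)computed from residue
#' name, number, insertion code and chain.
#'
#' @param atoms Data frame with at least \code{chain}, \code{resno},
#'   \code{resname}, \code{x}, \code{y}, \code{z}.  Missing \code{insert},
#'   \code{elety}, \code{element}, \code{occupancy}, \code{altloc} columns
#'   are filled with defaults.
#' @param id Structure identifier.
#' @param metadata Optional list of provenance records.
#' @return A validated [Structure-class] object.
#' @export
Structure <- function(atoms, id = "structure", metadata = list()) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$elety)) atoms$elety <- "CA"
  if (is.null(atoms$element)) atoms$element <- "C"
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  atoms$kind <- ifelse(toupper(atoms$resname) == "HOH", "water", "residue")
  atoms$label <- nodeLabel(atoms$resname, atoms$resno, atoms$chain, atoms$insert)
  atoms <- atoms[, .atomCols]
  rownames(atoms) <- NULL
  new("Structure", id = id, atoms = atoms, metadata = metadata)
}

#' RIN: a residue interaction network
#'
#' An undirected contact graph over residue and water nodes of one
#' [Structure-class].  Edges are stored canonically (lexicographically
#' smaller label first); the metadata records the variant tag
#' (\code{"dry"}, \code{"wet"}, \code{"wet_uniform"} or
#' \code{"interface_waters"}) and every distance threshold used, so a
#' network is reproducible from its provenance alone.
#'
#' @slot nodes \code{data.frame} with columns \code{label}, \code{kind},
#'   \code{chain}, \code{interface} (logical).
#' @slot edges \code{data.frame} with columns \code{from}, \code{to}
#'   (canonical node-label pairs, no self-edges).
#' @slot metadata List: \code{variant}, \code{thresholds}, \code{structureId},
#'   plus records appended by [removeWaterNodes()].
#'
#' @seealso [buildRIN()], [RIN()]
#' @export
setClass("RIN",
  representation(nodes = "data.frame", edges = "data.frame", metadata = "list"))

setValidity("RIN", function(object) {
  n <- object@nodes; e <- object@edges
  msg <- character()
  if (!all(c("label", "kind", "chain", "interface") %in% names(n)))
    return("node table needs columns label, kind, chain, interface")
  if (!all(c("from", "to") %in% names(e)))
    return("edge table needs columns from, to")
  if (anyDuplicated(n$label)) msg <- c(msg, "duplicate node labels")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (!all(c(e$from, e$to) %in% n$label))
      msg <- c(msg, "edges reference unknown nodes")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be stored canonically")
    if (anyDuplicated(paste(e$from, e$to))) msg <- c(msg, "duplicate edges")
  }
  variant <- object@metadata$variant
  if (identical(variant, "dry") && any(n$kind == "water"))
    msg <- c(msg, "a dry RIN cannot contain water nodes")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a RIN from node and edge tables
#'
#' Mainly for tests and for assembling small hand-built graphs; real
#' networks come from [buildRIN()].  Edges are canonicalized and
#' deduplicated; missing node columns get defaults (\code{kind="residue"},
#' \code{interface=FALSE}).
#'
#' @param nodes Data frame with a \code{label} column, or a character vector
#'   of labels.
#' @param edges Two-column data frame (or matrix) of node-label pairs.
#' @param metadata List of provenance fields.
#' @return A validated [RIN-class] object.
#' @export
RIN <- function(nodes, edges = NULL, metadata = list()) {
  if (is.character(nodes)) nodes <- data.frame(label = nodes)
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$kind)) nodes$kind <- "residue"
  if (is.null(nodes$chain)) nodes$chain <- NA_character_
  if (is.null(nodes$interface)) nodes$interface <- FALSE
  nodes <- nodes[, c("label", "kind", "chain", "interface")]
  rownames(nodes) <- NULL
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(from = character(), to = character())
  } else {
    edges <- as.data.frame(edges)
    names(edges)[1:2] <- c("from", "to")
    edges <- canonicalEdges(edges)
  }
  if (is.null(metadata$variant)) metadata$variant <- "custom"
  new("RIN", nodes = nodes, edges = edges, metadata = metadata)
}

#' CentralityResult: per-node centrality values and Z-scores
#'
#' Result of one centrality analysis (RCA or BCA) on one network.  Raw
#' values are standardized into Z-scores against the mean and population
#' standard deviation over \emph{all} nodes of that network -- water nodes
#' included when present, so residue and water scores share one population.
#'
#' @slot method \code{"RCA"} or \code{"BCA"}.
#' @slot table \code{data.frame} with columns \code{label}, \code{kind},
#'   \code{chain}, \code{interface}, \code{raw}, \code{z}.
#' @slot metadata Provenance copied from the input network plus the
#'   disconnection convention in force.
#'
#' @seealso [rca()], [bca()], [centralNodes()]
#' @export
setClass("CentralityResult",
  representation(method = "character", table = "data.frame", metadata = "list"))

setValidity("CentralityResult", function(object) {
  if (!object@method %in% c("RCA", "BCA")) return("method must be RCA or BCA")
  tb <- object@table
  if (!all(c("label", "raw", "z") %in% names(tb)))
    return("table needs columns label, raw, z")
  if (anyDuplicated(tb$label)) return("duplicate node labels in result")
  TRUE
})

#' DifferentialReport: wet-versus-dry centrality comparison
#'
#' Summarizes, for each centrality method, which nodes become central when
#' water molecules are added to the network (\code{added}) and which stop
#' being central (\code{lost}), the per-residue Z-score shift
#' \eqn{\Delta Z = Z_{wet} - Z_{dry}} with its summary statistics, and the
#' union/intersection of the added sets across methods.  An exclusion
#' policy (e.g. affinity-tag residues) filters the reported label sets only;
#' it never enters any statistic.
#'
#' @slot rca,bca Per-method lists with elements \code{added}, \code{lost},
#'   \code{deltaZ} (data frame), \code{stats}, \code{addedShift}.
#' @slot combined List with \code{union} and \code{intersection} of the
#'   across-method added sets.
#' @slot exclusions \code{data.frame} of excluded labels and reasons.
#' @slot metadata Provenance (structure id, threshold, interface summary).
#'
#' @seealso [differentialReport()], [interfaceReport()]
#' @export
setClass("DifferentialReport",
  representation(rca = "list", bca = "list", combined = "list",
                 exclusions = "data.frame", metadata = "list"))
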