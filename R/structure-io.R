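# PDB input/output and structure filtering policies.
#
# Parsing is delegated to bio3d::read.pdb; this module normalizes the atom
# record into the Structure container and applies the filtering policies
# (hydrogens, altloc conformers, non-water heteroatoms, water name aliases).

#' Default water residue-name aliases
#'
#' Residue names mapped onto the canonical water name \code{HOH} at parse
#' time.  Deuterated and alternative water names occur in some deposited
#' structures.
#' @export
waterAliases <- function() c("HOH", "WAT", "H2O", "DOD", "D2O", "TIP", "SOL")

#' Read a PDB file into a Structure
#'
#' Parses fixed-column \code{ATOM}/\code{HETATM} records (first model only
#' for multi-model files).  \code{ATOM} records become protein residues;
#' \code{HETATM} records whose residue name is \code{HOH} (or an alias, see
#' [waterAliases()]) become single-oxygen water nodes.  The filtering policy
#' of [filterComponents()] is applied: hydrogens removed, highest-occupancy
#' altloc conformer kept, non-water heteroatoms (ions, cryoprotectants)
#' dropped unless \code{keepHetero = TRUE}.
#'
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @param keepHydrogens Keep hydrogen/deuterium atoms (default \code{FALSE};
#'   contact detection is defined on heavy atoms).
#' @param keepHetero Retain non-water \code{HETATM} entities as
#'   residue-kind nodes (default \code{FALSE}).
#' @param aliases Residue names treated as water.
#' @return A [Structure-class].
#' @examples
#' s <- generateComplex(synthParams(nResPerChain = 5, nWaters = 4, seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' writePDB(s, f)
#' readPDB(f)
#' @export
readPDB <- function(path, id = NULL, keepHydrogens = FALSE,
                    keepHetero = FALSE, aliases = waterAliases()) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("no ATOM or HETATM records in ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  resname <- toupper(trimws(a$resid))
  isWater <- resname %in% toupper(aliases)
  resname[isWater] <- "HOH"
  kind <- ifelse(a$type == "ATOM" & !isWater, "residue",
                 ifelse(isWater, "water", "hetero"))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resname = resname,
    kind = kind,
    elety = trimws(a$elety),
    element = toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", a$alt))
  atoms$occupancy <- pmin(pmax(atoms$occupancy, 0), 1)
  # infer element from the atom name when the element column is blank
  blank <- atoms$element == ""
  atoms$element[blank] <-
    toupper(substr(sub("^[0-9']+", "", atoms$elety[blank]), 1, 1))

  atoms <- .filterAtoms(atoms, removeHydrogens = !keepHydrogens,
                        keepHetero = keepHetero)
  s <- new("Structure", id = id, atoms = .finalizeAtoms(atoms),
           metadata = list(source = path,
                           filterPolicy = list(
                             removeHydrogens = !keepHydrogens,
                             keepHetero = keepHetero)))
  if (sum(residueTable(s)$kind == "residue") == 0)
    stop("structure error: no protein residues parsed from ", path)
  s
}

# recompute labels and column order after any atom-level edit
.finalizeAtoms <- function(atoms) {
  atoms$label <- nodeLabel(atoms$resname, atoms$resno, atoms$chain, atoms$insert)
  rownames(atoms) <- NULL
  atoms[, intersect(c(.atomCols, "type"), names(atoms))]
}

#' Apply atom-level filtering policies
#'
#' Three policies, each independently switchable: (i) hydrogens (and
#' deuteriums) removed -- crystallographic inputs generally lack them and
#' their inclusion would change contact counts; (ii) for alternate-location
#' groups, the highest-occupancy conformer is kept, ties broken by altloc
#' code order; (iii) non-water heteroatom entities are dropped, or retained
#' as residue-kind nodes with \code{keepHetero = TRUE}.
#'
#' @param x A [Structure-class] (its atom table may still carry a
#'   transient \code{kind = "hetero"} marker from parsing).
#' @param removeHydrogens Drop H/D atoms (default \code{TRUE}).
#' @param keepHetero Keep non-water HETATM entities (default \code{FALSE}).
#' @return A filtered [Structure-class]; the applied policy is recorded in
#'   its metadata.
#' @export
filterComponents <- function(x, removeHydrogens = TRUE, keepHetero = FALSE) {
  a <- .filterAtoms(x@atoms, removeHydrogens, keepHetero)
  md <- x@metadata
  md$filterPolicy <- list(removeHydrogens = removeHydrogens,
                          keepHetero = keepHetero)
  new("Structure", id = x@id, atoms = .finalizeAtoms(a), metadata = md)
}

.filterAtoms <- function(a, removeHydrogens = TRUE, keepHetero = FALSE) {
  if (removeHydrogens) a <- a[!a$element %in% c("H", "D"), , drop = FALSE]
  if ("hetero" %in% a$kind) {
    if (keepHetero) a$kind[a$kind == "hetero"] <- "residue"
    else a <- a[a$kind != "hetero", , drop = FALSE]
  }
  # altloc resolution: per residue+atom-name group keep max occupancy,
  # ties broken by altloc code order (blank sorts first)
  if (any(a$altloc != "")) {
    reskey <- paste(a$chain, a$resno, a$insert, sep = "\r")
    resOrder <- unique(reskey)
    grp <- paste(reskey, a$resname, a$elety, sep = "\r")
    ord <- order(grp, -a$occupancy, a$altloc)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(grp[ord]), , drop = FALSE]
    a$altloc <- ""
    a <- a[order(match(paste(a$chain, a$resno, a$insert, sep = "\r"),
                       resOrder)), , drop = FALSE]
  }
  a
}

#' Restrict a Structure to selected chains
#'
#' Protein residues are restricted to the listed chains.  Water handling is
#' a policy: \code{"all"} (default) keeps every water in the file regardless
#' of its chain label -- deposited waters are often assigned to chains
#' arbitrarily -- while \code{"matching"} keeps only waters whose chain
#' label is in the selection.  The policy is recorded in the output
#' metadata.
#'
#' @param x A [Structure-class].
#' @param chains Non-empty character vector of chain identifiers.
#' @param waters Water retention policy, \code{"all"} or \code{"matching"}.
#' @return A [Structure-class].
#' @export
selectChains <- function(x, chains, waters = c("all", "matching")) {
  waters <- match.arg(waters)
  if (length(chains) == 0) stop("chain selection must be non-empty")
  a <- x@atoms
  keepRes <- a$kind == "residue" & a$chain %in% chains
  keepWat <- a$kind == "water" &
    (waters == "all" | a$chain %in% chains)
  a <- a[keepRes | keepWat, , drop = FALSE]
  if (!any(a$kind == "residue"))
    stop("structure error: no protein residues on chain(s) ",
         paste(chains, collapse = ", "))
  md <- x@metadata
  md$chainSelection <- list(chains = chains, waterPolicy = waters)
  new("Structure", id = x@id, atoms = .finalizeAtoms(a), metadata = md)
}

#' Write a Structure as a PDB file
#'
#' Minimal writer (via \pkg{bio3d}): protein residues as \code{ATOM}
#' records, waters as \code{HETATM}, with the element column filled.
#' Intended for synthetic fixtures and round-tripping; coordinates are
#' written at the format's 3-decimal precision.
#'
#' @param x A [Structure-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(x, path) {
  a <- x@atoms
  if (nrow(a) == 0) stop("empty structure")
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$kind == "water", "HETATM", "ATOM"),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element,
    verbose = FALSE)
  invisible(path)
}

#' @rdname Structure-class
#' @export
setMethod("structureId", "Structure", function(x) x@id)

#' @rdname Structure-class
#' @export
setMethod("atomTable", "Structure", function(x) x@atoms)

#' @describeIn Structure-class One row per residue/water: \code{label},
#'   \code{chain}, \code{resno}, \code{resname}, \code{kind}, \code{natoms}.
#' @export
setMethod("residueTable", "Structure", function(x) {
  a <- x@atoms
  first <- !duplicated(a$label)
  data.frame(label = a$label[first], chain = a$chain[first],
             resno = a$resno[first], resname = a$resname[first],
             kind = a$kind[first],
             natoms = as.vector(table(factor(a$label, levels = a$label[first]))),
             row.names = NULL)
})

setMethod("show", "Structure", function(object) {
  rt <- residueTable(object)
  cat("Structure '", object@id, "': ",
      sum(rt$kind == "residue"), " residues, ",
      sum(rt$kind == "water"), " waters, ",
      nrow(object@atoms), " atoms, chains: ",
      paste(sort(unique(rt$chain[rt$kind == "residue"])), collapse = ", "),
      "\n", sep = "")
})

#' Minimum heavy-atom distance between two residues
#'
#' The distance between two residues (or waters) is the minimum Euclidean
#' distance over all heavy-atom pairs, the quantity every contact rule in
#' the network construction is defined on.
#'
#' @param x A [Structure-class].
#' @param label1,label2 Node labels of the two residues.
#' @return Distance in Angstrom.
#' @export
minAtomDistance <- function(x, label1, label2) {
  a <- x@atoms
  A <- as.matrix(a[a$label == label1, c("x", "y", "z"), drop = FALSE])
  B <- as.matrix(a[a$label == label2, c("x", "y", "z"), drop = FALSE])
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("structure error: no atoms for ",
         if (nrow(A) == 0) label1 else label2)
  .minCrossDist(A, B)
}
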