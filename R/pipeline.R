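# End-to-end orchestration: build the requested network variants, run both
# centrality analyses, and serialize every artifact (SIF + node tables,
# centrality TSVs, differential JSON/TSV, run metadata).
#
# Output files are written deterministically: re-running an identical
# configuration on identical inputs reproduces them byte for byte, except
# for the timestamp field of the metadata JSON.

#' Run the full wet-versus-dry RIN pipeline
#'
#' Reads (or accepts) a structure, optionally restricts chains, annotates
#' the interface between two chain groups, builds the requested network
#' variants, runs RCA and BCA on each, and -- when both wet and dry
#' variants are present -- assembles the differential report, its
#' interface restriction and optional water-removal experiments.  All
#' artifacts are written under \code{outDir} when given.
#'
#' @param input A [Structure-class] or a path to a PDB file.
#' @param chains Optional chain selection (see [selectChains()]).
#' @param chainGroups List of two character vectors partitioning the
#'   protein chains for interface annotation; defaults to the two chains of
#'   a two-chain structure, otherwise interface annotation is skipped.
#' @param variants Network variants to build (subset of \code{"dry"},
#'   \code{"wet"}, \code{"wet_uniform"}, \code{"interface_waters"}).
#' @param thresholds A [contactThresholds()] list.
#' @param zThreshold Central-node Z cutoff (default 2).
#' @param exclude Labels excluded from reported central-node sets (e.g.
#'   [hisTagExclusion()]); statistics are unaffected.
#' @param waterRemoval Optional list of selector requests for
#'   [waterRemovalExperiment()], each a list with \code{selector} and
#'   optionally \code{k} or \code{labels}.
#' @param outDir Output directory (created if missing); \code{NULL} for no
#'   file output.
#' @param waterPolicy Water retention policy for chain selection.
#' @return Invisibly, a list with \code{structure}, \code{interface},
#'   \code{rins}, \code{centralities} (nested by variant and method),
#'   \code{report} (a [DifferentialReport-class] or \code{NULL}),
#'   \code{waterRemoval} and \code{files}.
#' @export
runPipeline <- function(input, chains = NULL, chainGroups = NULL,
                        variants = c("dry", "wet", "interface_waters"),
                        thresholds = contactThresholds(), zThreshold = 2,
                        exclude = character(), waterRemoval = NULL,
                        outDir = NULL, waterPolicy = "all") {
  variants <- match.arg(variants,
    c("dry", "wet", "wet_uniform", "interface_waters"), several.ok = TRUE)
  s <- if (is(input, "Structure")) input else readPDB(input)
  if (!is.null(chains)) s <- selectChains(s, chains, waters = waterPolicy)

  protChains <- sort(unique(s@atoms$chain[s@atoms$kind == "residue"]))
  if (is.null(chainGroups) && length(protChains) == 2)
    chainGroups <- list(protChains[1], protChains[2])
  interface <- if (!is.null(chainGroups))
    annotateInterface(s, chainGroups[[1]], chainGroups[[2]], thresholds$d_int)
  else character()
  if (is.null(chainGroups) && "interface_waters" %in% variants) {
    warning("no chain groups available; skipping the interface_waters variant")
    variants <- setdiff(variants, "interface_waters")
  }

  rins <- lapply(stats::setNames(variants, variants), function(v)
    buildRIN(s, v, thresholds, chainGroups = chainGroups))
  centralities <- lapply(rins, function(r) list(RCA = rca(r), BCA = bca(r)))

  report <- NULL
  if (all(c("wet", "dry") %in% variants)) {
    report <- differentialReport(
      centralities$wet$RCA, centralities$dry$RCA,
      centralities$wet$BCA, centralities$dry$BCA,
      threshold = zThreshold, exclude = exclude)
    if (length(interface)) report <- interfaceReport(report, interface)
  } else {
    warning("wet and dry variants not both requested; ",
            "no differential report produced")
  }

  removal <- NULL
  if (!is.null(waterRemoval) && "wet" %in% variants) {
    removal <- lapply(waterRemoval, function(sel)
      waterRemovalExperiment(rins$wet, selector = sel$selector,
                             k = sel$k, labels = sel$labels,
                             threshold = zThreshold))
  }

  files <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(outDir, paste0(...))
    for (v in variants) {
      files <- c(files, writeSIF(rins[[v]], out(v, ".sif")),
                 writeNodeTable(rins[[v]], out(v, "_nodes.tsv")))
      for (m in c("RCA", "BCA"))
        files <- c(files, writeCentralityTable(
          centralities[[v]][[m]], out("centrality_", v, "_", tolower(m), ".tsv"),
          threshold = zThreshold))
    }
    if (!is.null(report)) {
      files <- c(files,
        writeDifferentialReport(report, out("differential_report.json")),
        .writeDeltaZ(report, out("delta_z.tsv")))
    }
    meta <- list(
      structureId = s@id, chains = chains, chainGroups = chainGroups,
      thresholds = unclass(thresholds), variants = variants,
      zThreshold = zThreshold, exclude = exclude,
      waterPolicy = waterPolicy,
      interfaceResidues = interface,
      nodeCounts = lapply(rins, function(r) nrow(r@nodes)),
      edgeCounts = lapply(rins, function(r) nrow(r@edges)),
      packageVersion = as.character(utils::packageVersion("hydroRIN")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(meta, out("run_metadata.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    files <- c(files, out("run_metadata.json"))
  }
  invisible(list(structure = s, interface = interface, rins = rins,
                 centralities = centralities, report = report,
                 waterRemoval = removal, files = files))
}

#' Serialize a differential report as JSON
#'
#' @param report A [DifferentialReport-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDifferentialReport <- function(report, path) {
  asList <- function(m) {
    s <- slot(report, m)
    list(added = s$added, lost = s$lost, stats = s$stats,
         addedShift = s$addedShift)
  }
  jsonlite::write_json(
    list(structureId = report@metadata$structureId,
         threshold = report@metadata$threshold,
         rca = asList("rca"), bca = asList("bca"),
         union = report@combined$union,
         intersection = report@combined$intersection,
         interfaceUnionCount = report@metadata$interfaceUnionCount,
         exclusions = report@exclusions),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

.writeDeltaZ <- function(report, path) {
  dz <- merge(report@rca$deltaZ, report@bca$deltaZ, by = "label",
              suffixes = c(".rca", ".bca"), sort = TRUE)
  utils::write.table(format(dz, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Four-column Z-score table for selected residues
#'
#' One row per requested label with the BCA and RCA Z-scores in the dry
#' ("no water") and wet analyses -- the layout used when comparing
#' individual residues across the two conditions.
#'
#' @param wetRca,dryRca,wetBca,dryBca [CentralityResult-class] objects.
#' @param labels Character vector of node labels; each must exist in all
#'   four analyses.
#' @param path Optional output path for a TSV copy.
#' @return A data frame with columns \code{label}, \code{bcaDry},
#'   \code{rcaDry}, \code{bcaWet}, \code{rcaWet}.
#' @export
exportTable2Style <- function(wetRca, dryRca, wetBca, dryBca, labels,
                              path = NULL) {
  zOf <- function(res, lab) {
    i <- match(lab, res@table$label)
    if (anyNA(i))
      stop("label(s) not found in ", res@method, " result: ",
           paste(lab[is.na(i)], collapse = ", "))
    res@table$z[i]
  }
  df <- data.frame(label = labels,
                   bcaDry = zOf(dryBca, labels), rcaDry = zOf(dryRca, labels),
                   bcaWet = zOf(wetBca, labels), rcaWet = zOf(wetRca, labels))
  if (length(labels) == 0)
    df <- df[0, , drop = FALSE]
  if (!is.null(path))
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
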