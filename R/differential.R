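# Wet-versus-dry differential analysis.
#
# DeltaZ = Z_wet - Z_dry is defined over residue nodes only: waters have no
# dry counterpart.  Summary statistics use the population standard
# deviation.  Exclusion policies filter reported label sets only and never
# enter a statistic.

.checkSameMethod <- function(wet, dry) {
  if (wet@method != dry@method)
    stop("method mismatch: ", wet@method, " vs ", dry@method)
}

#' Added and lost central nodes between wet and dry analyses
#'
#' \code{added} are nodes central in the wet analysis but not the dry one
#' (this can include water nodes, which are absent from the dry network);
#' \code{lost} are central in the dry analysis only.
#'
#' @param wet,dry [CentralityResult-class] objects for the same structure
#'   and method.
#' @param threshold Central-node Z cutoff (default 2, inclusive).
#' @return List with character vectors \code{added} and \code{lost}.
#' @export
diffCentral <- function(wet, dry, threshold = 2) {
  .checkSameMethod(wet, dry)
  cw <- centralNodes(wet, threshold)
  cd <- centralNodes(dry, threshold)
  list(added = setdiff(cw, cd), lost = setdiff(cd, cw))
}

#' Union and intersection of added sets across methods
#'
#' @param rcaAdded,bcaAdded Character vectors of added central nodes from
#'   the RCA and BCA comparisons.
#' @return List with \code{union} and \code{intersection} (sorted).
#' @export
combineMethods <- function(rcaAdded, bcaAdded) {
  list(union = sort(union(rcaAdded, bcaAdded)),
       intersection = sort(intersect(rcaAdded, bcaAdded)))
}

#' Z-score shift statistics between wet and dry analyses
#'
#' Computes \eqn{\Delta Z = Z_{wet} - Z_{dry}} for every residue node
#' present in both analyses, and summarizes: mean and population SD of
#' \eqn{\Delta Z} over residues, plus mean and population SD of the wet
#' Z-scores of the water nodes (the peripheral population that compensates
#' the residue shift).
#'
#' @param wet,dry [CentralityResult-class] objects, same structure/method.
#' @return List: \code{deltaZ} (data frame \code{label}, \code{zWet},
#'   \code{zDry}, \code{deltaZ}), \code{muDeltaZ}, \code{sigmaDeltaZ},
#'   \code{muWaterZ}, \code{sigmaWaterZ} (the last two \code{NA} when the
#'   wet network has no waters).
#' @export
deltaZStats <- function(wet, dry) {
  .checkSameMethod(wet, dry)
  tw <- wet@table; td <- dry@table
  res <- tw[tw$kind == "residue" & tw$label %in% td$label, , drop = FALSE]
  if (nrow(res) == 0) stop("no residue nodes common to both analyses")
  zd <- stats::setNames(td$z, td$label)[res$label]
  dz <- data.frame(label = res$label, zWet = res$z, zDry = as.numeric(zd),
                   deltaZ = res$z - as.numeric(zd))
  wz <- tw$z[tw$kind == "water"]
  list(deltaZ = dz,
       muDeltaZ = mean(dz$deltaZ), sigmaDeltaZ = .popSD(dz$deltaZ),
       muWaterZ = if (length(wz)) mean(wz) else NA_real_,
       sigmaWaterZ = if (length(wz)) .popSD(wz) else NA_real_)
}

#' Shift of the added central residues relative to the global mean
#'
#' Measures, in units of the global \eqn{\Delta Z} spread, how far the mean
#' \eqn{\Delta Z} of the added central residues lies above the mean over
#' all residues: \eqn{(\bar{\Delta Z}_{added} - \mu) / \sigma}.  Water
#' nodes in \code{added} are ignored (they have no \eqn{\Delta Z}).
#'
#' @param added Character vector of added central node labels.
#' @param stats Result of [deltaZStats()].
#' @return A single number; \code{NA} with a warning when
#'   \eqn{\sigma(\Delta Z) = 0}.
#' @export
addedResidueShift <- function(added, stats) {
  addedRes <- intersect(added, stats$deltaZ$label)
  if (length(addedRes) == 0)
    stop("no added residue nodes (after excluding waters)")
  if (stats$sigmaDeltaZ == 0) {
    warning("sigma(deltaZ) is zero; shift undefined")
    return(NA_real_)
  }
  dz <- stats$deltaZ$deltaZ[match(addedRes, stats$deltaZ$label)]
  (mean(dz) - stats$muDeltaZ) / stats$sigmaDeltaZ
}

#' Full wet-versus-dry differential report
#'
#' Runs [diffCentral()], [deltaZStats()] and [addedResidueShift()] for both
#' methods and combines the added sets across methods.  Labels in
#' \code{exclude} (e.g. affinity-tag residues that are central only through
#' a crystallization artifact) are removed from the reported added/lost/
#' union/intersection sets; all statistics are computed before exclusion
#' and are unaffected by it.
#'
#' @param wetRca,dryRca,wetBca,dryBca [CentralityResult-class] objects from
#'   the wet and dry networks of one structure.
#' @param threshold Central-node Z cutoff (default 2).
#' @param exclude Character vector of labels to drop from reported sets.
#' @param excludeReason Single reason string recorded alongside.
#' @return A [DifferentialReport-class].
#' @export
differentialReport <- function(wetRca, dryRca, wetBca, dryBca, threshold = 2,
                               exclude = character(),
                               excludeReason = "excluded by policy") {
  oneMethod <- function(wet, dry) {
    d <- diffCentral(wet, dry, threshold)
    st <- deltaZStats(wet, dry)
    shift <- if (length(intersect(d$added, st$deltaZ$label)))
      addedResidueShift(d$added, st) else NA_real_
    c(d, list(stats = st[c("muDeltaZ", "sigmaDeltaZ", "muWaterZ", "sigmaWaterZ")],
              deltaZ = st$deltaZ, addedShift = shift))
  }
  r <- oneMethod(wetRca, dryRca)
  b <- oneMethod(wetBca, dryBca)
  comb <- combineMethods(r$added, b$added)
  filt <- function(x) setdiff(x, exclude)
  for (f in c("added", "lost")) {
    r[[f]] <- filt(r[[f]]); b[[f]] <- filt(b[[f]])
  }
  comb <- lapply(comb, filt)
  new("DifferentialReport", rca = r, bca = b, combined = comb,
      exclusions = data.frame(
        label = exclude,
        reason = rep(excludeReason, length.out = length(exclude))),
      metadata = list(structureId = wetRca@metadata$structureId,
                      threshold = threshold))
}

#' @export
setMethod("addedCentral", "DifferentialReport", function(x, method) {
  switch(toupper(method), RCA = x@rca$added, BCA = x@bca$added,
         stop("method must be RCA or BCA"))
})

#' @export
setMethod("lostCentral", "DifferentialReport", function(x, method) {
  switch(toupper(method), RCA = x@rca$lost, BCA = x@bca$lost,
         stop("method must be RCA or BCA"))
})

setMethod("show", "DifferentialReport", function(object) {
  cat("Differential wet-vs-dry report ('",
      object@metadata$structureId %||% "?", "', Z >= ",
      object@metadata$threshold, ")\n", sep = "")
  for (m in c("rca", "bca")) {
    s <- slot(object, m)
    cat("  ", toupper(m), ": +", length(s$added), " / -", length(s$lost),
        " central nodes; mean deltaZ = ", signif(s$stats$muDeltaZ, 4),
        " (sd ", signif(s$stats$sigmaDeltaZ, 4), ")\n", sep = "")
  }
  cat("  union: ", length(object@combined$union),
      ", intersection: ", length(object@combined$intersection), "\n", sep = "")
  if (!is.null(object@metadata$interfaceUnionCount))
    cat("  interface members of union: ",
        object@metadata$interfaceUnionCount, "\n", sep = "")
})

#' Restrict a differential report to the interface
#'
#' Flags each added/lost label as interface or not and counts the interface
#' residues (waters excluded) in the across-method union -- the headline
#' number when asking what water inclusion changes at the binding site.
#'
#' @param report A [DifferentialReport-class].
#' @param interface Character vector of interface residue labels.
#' @return The report with \code{interfaceFlags} and
#'   \code{interfaceUnionCount} added to its metadata.
#' @export
interfaceReport <- function(report, interface) {
  flag <- function(x) stats::setNames(x %in% interface, x)
  report@metadata$interfaceFlags <- list(
    rcaAdded = flag(report@rca$added), rcaLost = flag(report@rca$lost),
    bcaAdded = flag(report@bca$added), bcaLost = flag(report@bca$lost),
    union = flag(report@combined$union))
  report@metadata$interfaceUnionCount <-
    length(intersect(report@combined$union, interface))
  report
}

#' His-tag exclusion labels
#'
#' Convenience builder for the common reporting exclusion: histidine
#' affinity-tag residues whose centrality is a construct artifact rather
#' than a property of the native complex.
#'
#' @param chain Chain identifier.
#' @param resno Residue numbers of the tag histidines.
#' @return Character vector of node labels.
#' @export
hisTagExclusion <- function(chain = "A", resno = 92:94) {
  nodeLabel("HIS", resno, chain)
}

#' Water-removal experiment
#'
#' Removes water nodes from a wet network by the given selector, recomputes
#' both (or selected) centralities, and compares the central \emph{residue}
#' sets before and after removal (water nodes are excluded from the
#' comparison).  An empty symmetric difference means the removed waters had
#' a global rather than a specific effect on residue centrality.
#'
#' @param rin A wet [RIN-class].
#' @param selector,k,labels Passed to [removeWaterNodes()].
#' @param methods Character subset of \code{c("RCA", "BCA")}.
#' @param threshold Central-node Z cutoff (default 2).
#' @return List with \code{removed} (labels) and per-method lists
#'   \code{before}, \code{after}, \code{symmetricDifference},
#'   \code{identical}.
#' @export
waterRemovalExperiment <- function(rin, selector = "max_degree", k = NULL,
                                   labels = NULL, methods = c("RCA", "BCA"),
                                   threshold = 2) {
  methods <- match.arg(methods, c("RCA", "BCA"), several.ok = TRUE)
  reduced <- removeWaterNodes(rin, selector, k = k, labels = labels)
  residuesOnly <- function(result) {
    cen <- centralNodes(result, threshold)
    tb <- result@table
    setdiff(cen, tb$label[tb$kind == "water"])
  }
  out <- list(removed = reduced@metadata$waterRemoval$removed)
  for (m in methods) {
    fn <- if (m == "RCA") rca else bca
    before <- residuesOnly(fn(rin))
    after <- residuesOnly(fn(reduced))
    out[[m]] <- list(before = sort(before), after = sort(after),
                     symmetricDifference = sort(c(setdiff(before, after),
                                                  setdiff(after, before))),
                     identical = setequal(before, after))
  }
  out
}
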