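# Deterministic generator of two-chain protein-like complexes with water
# shells.  Residues are clustered pseudo-atom groups laid out on a compact
# serpentine path; waters are single oxygens rejection-sampled into a
# hydrogen-bond-like shell around the protein surface.

#' Parameters for the synthetic complex generator
#'
#' Defaults emulate a small, compact two-chain complex as seen by the
#' contact rules: C-alpha-like 3.8 Angstrom backbone spacing, three heavy
#' atoms per residue clustered within 1.5 Angstrom of the residue center,
#' two chains facing each other across a 5 Angstrom backbone gap (so a
#' 7 Angstrom interface exists), and a shell of waters at hydrogen-bond
#' distance (2.8-3.4 Angstrom) from the nearest protein atom, mutually
#' separated by at least 2.6 Angstrom.
#'
#' @param nResPerChain Residues per chain (>= 3; default 30).
#' @param residueSpacing Backbone spacing in Angstrom (default 3.8).
#' @param atomsPerResidue Heavy atoms per residue (default 3).
#' @param atomJitter Maximum atom offset from the residue center (default 1.5).
#' @param chainGap Gap between the facing backbone layers of the two
#'   chains, in Angstrom (default 5).
#' @param nWaters Number of water molecules (default 120).
#' @param waterMinSpacing Minimum water-water distance (default 2.6).
#' @param waterShellOffset Length-2 range of allowed distances from a water
#'   to its nearest protein atom (default \code{c(2.8, 3.4)}).
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   seed.
#' @param maxRetries Rejection-sampling attempts per water before the
#'   generator aborts (default 5000).
#' @return A validated list of class \code{SynthParams}.
#' @export
synthParams <- function(nResPerChain = 30, residueSpacing = 3.8,
                        atomsPerResidue = 3, atomJitter = 1.5, chainGap = 5,
                        nWaters = 120, waterMinSpacing = 2.6,
                        waterShellOffset = c(2.8, 3.4), seed = 1,
                        maxRetries = 5000) {
  stopifnot(nResPerChain >= 3, residueSpacing > 0, atomsPerResidue >= 1,
            atomJitter >= 0, chainGap > 0, nWaters >= 0,
            waterMinSpacing > 0, length(waterShellOffset) == 2,
            all(waterShellOffset > 0),
            waterShellOffset[1] <= waterShellOffset[2], maxRetries >= 1)
  structure(as.list(environment()), class = "SynthParams")
}

.aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")

# Serpentine path through a near-cubic grid: consecutive residues are
# always grid neighbors (one spacing apart), so the 5 A residue-residue
# rule keeps each chain connected; adjacent rows and layers pack within
# contact range, giving the dense residue subgraph of a folded domain.
.serpentine <- function(n, spacing) {
  k <- ceiling(n^(1 / 3))
  pts <- matrix(0, n, 3)
  i <- 0
  row <- 0  # rows visited so far; parity drives the x sweep direction
  for (iz in 0:(k - 1)) {
    ys <- 0:(k - 1); if (iz %% 2 == 1) ys <- rev(ys)
    for (iy in ys) {
      xs <- 0:(k - 1)
      if (row %% 2 == 1) xs <- rev(xs)
      row <- row + 1
      for (ix in xs) {
        i <- i + 1
        if (i > n) return(pts * spacing)
        pts[i, ] <- c(ix, iy, iz)
      }
    }
  }
  pts * spacing
}

.unitSphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a synthetic two-chain complex with a water shell
#'
#' Builds chains A and B as compact serpentine residue layouts facing each
#' other across \code{chainGap}, with clustered pseudo-atoms (first atom at
#' the residue center, the rest jittered within \code{atomJitter}), then
#' places single-oxygen waters by rejection sampling: a candidate position
#' is drawn at a shell offset from a random protein atom and accepted only
#' if its nearest protein atom lies within the shell-offset band (which
#' guarantees at least one contact under the 3.5 Angstrom rule) and it
#' keeps \code{waterMinSpacing} from every accepted water.  Waters inherit
#' the chain label of their nearest protein atom and are numbered from
#' 1001.  Deterministic given \code{seed}.
#'
#' @param p A [synthParams()] list.
#' @return A [Structure-class].
#' @examples
#' s <- generateComplex(synthParams(nResPerChain = 10, nWaters = 15, seed = 7))
#' s
#' @export
generateComplex <- function(p) {
  stopifnot(inherits(p, "SynthParams"))
  set.seed(p$seed)
  centersA <- .serpentine(p$nResPerChain, p$residueSpacing)
  centersB <- centersA
  # chain A extends downward in z, chain B upward from the facing layer
  centersA[, 3] <- -centersA[, 3]
  centersB[, 3] <- centersB[, 3] + p$chainGap
  # lateral half-spacing offset avoids mirror-symmetric atom stacking
  centersB[, 1] <- centersB[, 1] + p$residueSpacing / 2
  centersB[, 2] <- centersB[, 2] + p$residueSpacing / 2

  mkChain <- function(centers, chain) {
    n <- nrow(centers)
    atomNames <- c("CA", "CB", "CG", "CD", "CE", "CZ", "NH", "OH")
    rows <- lapply(seq_len(n), function(i) {
      napr <- p$atomsPerResidue
      offs <- matrix(0, napr, 3)
      if (napr > 1) {
        r <- p$atomJitter * stats::runif(napr - 1)^(1 / 3)
        offs[-1, ] <- .unitSphere(napr - 1) * r
      }
      data.frame(chain = chain, resno = i,
                 resname = .aa20[(i - 1) %% 20 + 1],
                 elety = rep_len(atomNames, napr),
                 element = substr(rep_len(atomNames, napr), 1, 1),
                 x = centers[i, 1] + offs[, 1],
                 y = centers[i, 2] + offs[, 2],
                 z = centers[i, 3] + offs[, 3])
    })
    do.call(rbind, rows)
  }
  atoms <- rbind(mkChain(centersA, "A"), mkChain(centersB, "B"))
  P <- as.matrix(atoms[, c("x", "y", "z")])

  lo <- p$waterShellOffset[1]; hi <- p$waterShellOffset[2]
  waters <- matrix(numeric(), 0, 3)
  for (w in seq_len(p$nWaters)) {
    placed <- FALSE
    for (try in seq_len(p$maxRetries)) {
      anchor <- P[sample.int(nrow(P), 1), ]
      pos <- anchor + as.vector(.unitSphere(1)) * stats::runif(1, lo, hi)
      dProt <- sqrt(min(.crossDist2(matrix(pos, 1), P)))
      if (dProt < lo - 1e-9 || dProt > hi + 1e-9) next
      if (nrow(waters) &&
          min(.crossDist2(matrix(pos, 1), waters)) < p$waterMinSpacing^2) next
      waters <- rbind(waters, pos)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("generator error: could not place water ", w, " of ", p$nWaters,
           " within ", p$maxRetries, " attempts; reduce nWaters or widen",
           " the shell-offset band")
  }
  if (p$nWaters > 0) {
    nearestChain <- atoms$chain[apply(.crossDist2(waters, P), 1, which.min)]
    watDf <- data.frame(chain = nearestChain,
                        resno = 1000 + seq_len(nrow(waters)),
                        resname = "HOH", elety = "O", element = "O",
                        x = waters[, 1], y = waters[, 2], z = waters[, 3])
    atoms <- rbind(atoms, watDf)
  }
  Structure(atoms, id = sprintf("synthetic-complex-seed%d", p$seed),
            metadata = list(generator = unclass(p)))
}

#' Jitter water positions of a structure
#'
#' Adds an independent uniform random displacement of magnitude at most
#' \code{jitter} (ball-uniform) to each water oxygen; protein atoms are
#' untouched.  Supports robustness checks of how sensitive central-residue
#' sets are to exact water positioning.  Deterministic given \code{seed}.
#'
#' @param x A [Structure-class].
#' @param jitter Maximum displacement in Angstrom (>= 0).
#' @param seed Integer RNG seed.
#' @return A [Structure-class] with perturbed waters.
#' @export
perturbWaters <- function(x, jitter, seed = 1) {
  stopifnot(jitter >= 0)
  a <- x@atoms
  w <- which(a$kind == "water")
  if (jitter > 0 && length(w)) {
    set.seed(seed)
    disp <- .unitSphere(length(w)) * (jitter * stats::runif(length(w))^(1 / 3))
    a[w, c("x", "y", "z")] <- a[w, c("x", "y", "z")] + disp
  }
  md <- x@metadata
  md$waterJitter <- list(jitter = jitter, seed = seed)
  new("Structure", id = x@id, atoms = a, metadata = md)
}
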