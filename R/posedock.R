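# Pose transfer, clash screening, a simple physics-based interaction score,
# rigid-body local optimization, normalized docking scores and contact
# analysis.
#
# The interaction score here is deliberately simple (LJ + Coulomb with a
# distance-dependent dielectric + a hydrogen-bond bonus): the toolkit's
# filtering logic (clash removal, NDS normalization) is what matters, and
# externally computed raw scores can be imported via TSV and normalized the
# same way.

#' Transfer a ligand pose through a site-alignment transform
#'
#' Applies the rigid map \code{x -> R x + t} (e.g. from
#' \code{\link{alignSites}}) to a ligand, producing its pose in the target
#' receptor frame.
#'
#' @param ligand Structure (ligand heavy atoms).
#' @param transform list with \code{rotation} (3 x 3, det +1) and
#'   \code{translation} (length 3).
#' @param provenance character label recorded on the pose.
#' @return Structure with transformed coordinates and a \code{provenance}
#'   attribute.
#' @export
transferPose <- function(ligand, transform, provenance = "transfer") {
  R <- transform$rotation
  if (abs(det(R) - 1) > 1e-6) stop("transform must be a proper rotation")
  xyz <- .applyTransform(coordMatrix(ligand), R, transform$translation)
  a <- ligand@atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  out <- new("Structure", atoms = a)
  attr(out, "provenance") <- provenance
  out
}

#' Count severe steric clashes between receptor and pose
#'
#' @param receptor,pose Structure objects.
#' @param dClash clash distance, Angstrom (default 1.5); heavy-atom pairs
#'   closer than this count as clashes.
#' @return list with \code{count} and logical \code{severe} (count > 0).
#' @export
clashReport <- function(receptor, pose, dClash = 1.5) {
  ra <- receptor@atoms[.heavyIdx(receptor@atoms), , drop = FALSE]
  la <- pose@atoms[.heavyIdx(pose@atoms), , drop = FALSE]
  D <- .pairdist(unname(as.matrix(ra[, c("x", "y", "z")])),
                 unname(as.matrix(la[, c("x", "y", "z")])))
  count <- sum(D < dClash)
  list(count = count, severe = count > 0L)
}

.ljParams <- function(atoms, ff) {
  ty <- ff@atomTypes[atoms$name]
  if (anyNA(ty)) {
    # fall back to element-level typing for foreign structures
    el <- toupper(atoms$element)
    ty[is.na(ty)] <- c(C = "LC", N = "LN", O = "LO")[el[is.na(ty)]]
  }
  if (anyNA(ty))
    stop("cannot parameterize atoms: ",
         paste(unique(atoms$name[is.na(ty)]), collapse = ", "))
  eps <- vapply(ty, function(t) ff@types[[t]]$eps, numeric(1))
  rmin2 <- vapply(ty, function(t) ff@types[[t]]$rmin2, numeric(1))
  q <- vapply(ty, function(t) ff@types[[t]]$charge, numeric(1))
  list(eps = eps, rmin2 = rmin2, q = q)
}

#' Raw receptor--ligand interaction score
#'
#' Intermolecular Lennard-Jones 12-6 plus Coulomb with distance-dependent
#' dielectric \code{eps(r) = 4 r}, plus a hydrogen-bond bonus of -1.0
#' kcal/mol per donor/acceptor (N/O) heavy-atom pair within 3.5 Angstrom.
#' Lower is better.
#'
#' @param receptor,pose Structure objects (heavy atoms used).
#' @param ff ForceFieldSpec supplying charges and LJ parameters.
#' @param hbondMax hydrogen-bond distance cutoff, Angstrom.
#' @return numeric score, kcal/mol-like.
#' @export
rawInteractionScore <- function(receptor, pose, ff, hbondMax = 3.5) {
  ra <- receptor@atoms[.heavyIdx(receptor@atoms), , drop = FALSE]
  la <- pose@atoms[.heavyIdx(pose@atoms), , drop = FALSE]
  pr <- .ljParams(ra, ff); pl <- .ljParams(la, ff)
  D <- .pairdist(unname(as.matrix(ra[, c("x", "y", "z")])),
                 unname(as.matrix(la[, c("x", "y", "z")])))
  D <- pmax(D, 0.4)  # guard against singular overlaps
  rmin <- outer(pr$rmin2, pl$rmin2, "+")
  epsij <- sqrt(outer(pr$eps, pl$eps))
  lj <- sum(epsij * ((rmin / D)^12 - 2 * (rmin / D)^6))
  kc <- ff@globals$coulomb
  elec <- sum(kc * outer(pr$q, pl$q) / (4 * D * D))  # eps(r) = 4 r
  dn <- toupper(ra$element) %in% c("N", "O")
  an <- toupper(la$element) %in% c("N", "O")
  hb <- -1.0 * sum(D[dn, an, drop = FALSE] <= hbondMax)
  lj + elec + hb
}

.rigidMove <- function(xyz, par) {
  # par = (tx, ty, tz, rx, ry, rz); rotations about the centroid, radians
  cen <- colMeans(xyz)
  Xc <- sweep(xyz, 2, cen)
  cx <- cos(par[4]); sx <- sin(par[4])
  cy <- cos(par[5]); sy <- sin(par[5])
  cz <- cos(par[6]); sz <- sin(par[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  sweep(tcrossprod(Xc, Rz %*% Ry %*% Rx), 2, cen + par[1:3], "+")
}

#' Rigid-body local pose optimization
#'
#' Coordinate-descent over the six rigid degrees of freedom (3 translations,
#' 3 rotations about the ligand centroid), minimizing
#' \code{\link{rawInteractionScore}}. Local by contract: the centroid never
#' moves more than \code{maxShift} from its start, and the returned score is
#' never worse than the starting score.
#'
#' @param receptor Structure.
#' @param pose Structure (starting pose).
#' @param ff ForceFieldSpec.
#' @param maxShift displacement bound, Angstrom (default 5).
#' @param step0 initial step (Angstrom / radians).
#' @param tol convergence tolerance on the score.
#' @param maxIter sweep limit.
#' @return the optimized pose (Structure) with attributes \code{score} and
#'   \code{initial_score}.
#' @export
localOptimizePose <- function(receptor, pose, ff, maxShift = 5.0,
                              step0 = 0.5, tol = 1e-4, maxIter = 50L) {
  base <- coordMatrix(pose)
  cen0 <- colMeans(base)
  evalPar <- function(par) {
    if (sqrt(sum(par[1:3]^2)) > maxShift) return(Inf)
    tmp <- pose
    xyz <- .rigidMove(base, par)
    tmp@atoms$x <- xyz[, 1]; tmp@atoms$y <- xyz[, 2]; tmp@atoms$z <- xyz[, 3]
    rawInteractionScore(receptor, tmp, ff)
  }
  par <- numeric(6)
  f0 <- evalPar(par)
  if (!is.finite(f0)) stop("non-finite interaction score at starting pose")
  f <- f0
  steps <- rep(step0, 6); steps[4:6] <- step0 * 0.2
  for (it in seq_len(maxIter)) {
    improved <- FALSE
    for (d in 1:6) {
      for (sgn in c(1, -1)) {
        cand <- par; cand[d] <- cand[d] + sgn * steps[d]
        fc <- evalPar(cand)
        if (fc < f - tol) { par <- cand; f <- fc; improved <- TRUE }
      }
    }
    if (!improved) {
      steps <- steps / 2
      if (max(steps) < 1e-3) break
    }
  }
  xyz <- .rigidMove(base, par)
  out <- pose
  out@atoms$x <- xyz[, 1]; out@atoms$y <- xyz[, 2]; out@atoms$z <- xyz[, 3]
  attr(out, "score") <- f
  attr(out, "initial_score") <- f0
  out
}

#' Normalized docking score (NDS)
#'
#' Standardizes a raw docking score against a background of decoy scores for
#' the same receptor: \code{nds = (s - mean(background)) / sd(background)}.
#' Systematic biases common to the score and its background cancel; a large
#' negative NDS means more favorable than random, a positive NDS worse than
#' random.
#'
#' @param s raw score (vectorized).
#' @param background numeric decoy scores, >= 20, non-constant.
#' @export
normalizedDockingScore <- function(s, background) {
  if (length(background) < 20L) stop("NDS background requires >= 20 scores")
  sdev <- stats::sd(background)
  if (sdev < 1e-12) stop("NDS background is constant")
  (s - mean(background)) / sdev
}

#' Decoy background scores for a receptor
#'
#' Scores of randomly re-placed rigid copies of the ligand (random rotation,
#' random translation within a shell around the pose) against the same
#' receptor, for use as the NDS background.
#'
#' @param receptor Structure.
#' @param pose Structure (reference pose).
#' @param ff ForceFieldSpec.
#' @param n number of decoys (default 50).
#' @param seed RNG seed.
#' @param shell max random displacement of the decoy centroid, Angstrom.
#' @export
decoyScoreBackground <- function(receptor, pose, ff, n = 50L, seed = 1L,
                                 shell = 8.0) {
  base <- coordMatrix(pose)
  .withSeed(seed, {
    vapply(seq_len(n), function(k) {
      par <- c(stats::runif(3, -shell, shell), stats::runif(3, 0, 2 * pi))
      tmp <- pose
      xyz <- .rigidMove(base, par)
      tmp@atoms$x <- xyz[, 1]; tmp@atoms$y <- xyz[, 2]; tmp@atoms$z <- xyz[, 3]
      rawInteractionScore(receptor, tmp, ff)
    }, numeric(1))
  })
}

#' Filter hits by NDS and severe clashes
#'
#' Retains hits with \code{nds < ndsMax} (default 0.0, i.e. better than the
#' decoy mean) and no severe clash. A hit with positive NDS docks worse than
#' randomly placed molecules and is removed.
#'
#' @param hits data.frame with columns \code{nds} and \code{severe} (logical)
#'   (extra columns pass through).
#' @param ndsMax retention threshold (default 0.0).
#' @return the retained rows, with a logical \code{retained} column added to
#'   the full table in attribute \code{all}.
#' @export
ndsFilter <- function(hits, ndsMax = 0.0) {
  keep <- hits$nds < ndsMax & !hits$severe
  all <- hits; all$retained <- keep
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all
  out
}

#' Protein--ligand contact report
#'
#' Distance-criterion contacts: hydrogen bonds as donor/acceptor (N/O)
#' heavy-atom pairs within \code{hbondMax} (no angle term, since poses may
#' lack hydrogens), hydrophobic contacts as carbon--carbon pairs within
#' \code{hydrophobicMax}.
#'
#' @param receptor,pose Structure objects.
#' @param hbondMax Angstrom, default 3.5.
#' @param hydrophobicMax Angstrom, default 4.5.
#' @return list of two data.frames, \code{hbonds} (receptor_atom, ligand_atom,
#'   distance) and \code{hydrophobic}.
#' @export
analyzeContacts <- function(receptor, pose, hbondMax = 3.5,
                            hydrophobicMax = 4.5) {
  ra <- receptor@atoms[.heavyIdx(receptor@atoms), , drop = FALSE]
  la <- pose@atoms[.heavyIdx(pose@atoms), , drop = FALSE]
  D <- .pairdist(unname(as.matrix(ra[, c("x", "y", "z")])),
                 unname(as.matrix(la[, c("x", "y", "z")])))
  lab <- function(a, i) sprintf("%s:%s%d:%s", a$chain[i], a$resname[i],
                                a$resno[i], a$name[i])
  collect <- function(selR, selL, cutoff) {
    idx <- which(outer(selR, selL, "&") & D <= cutoff, arr.ind = TRUE)
    if (!nrow(idx)) return(data.frame(receptor_atom = character(0),
                                      ligand_atom = character(0),
                                      distance = numeric(0)))
    df <- data.frame(receptor_atom = lab(ra, idx[, 1]),
                     ligand_atom = lab(la, idx[, 2]),
                     distance = D[idx], stringsAsFactors = FALSE)
    df <- unique(df[order(df$distance), , drop = FALSE])
    rownames(df) <- NULL
    df
  }
  no_r <- toupper(ra$element) %in% c("N", "O")
  no_l <- toupper(la$element) %in% c("N", "O")
  c_r <- toupper(ra$element) == "C"
  c_l <- toupper(la$element) == "C"
  list(hbonds = collect(no_r, no_l, hbondMax),
       hydrophobic = collect(c_r, c_l, hydrophobicMax))
}

#' Import externally computed raw docking scores
#'
#' @param path TSV with columns \code{target_id, raw_score}.
#' @export
readScoreTSV <- function(path) {
  df <- .readTSV(path)
  need <- c("target_id", "raw_score")
  if (!all(need %in% names(df)))
    stop("score TSV must have columns: ", paste(need, collapse = ", "))
  df
}
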