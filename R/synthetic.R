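# Deterministic synthetic complexes and snapshot ensembles.
#
# The generator stands in for crystallographic complexes and MD output so the
# whole pipeline can be exercised without external engines: a concave
# C-alpha/side-chain-dummy receptor shell with a ligand chain placed in the
# pocket, plus a matching minimal force-field block.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Generate a synthetic receptor--ligand complex
#'
#' Builds a self-avoiding fold of C-alpha atoms (plus one side-chain dummy CB
#' per residue, pointing away from the pocket) arranged as a concave shell
#' around a central pocket, and threads a heavy-atom ligand chain inside the
#' pocket such that no receptor--ligand heavy-atom pair comes closer than
#' 2.5 Angstrom. Bit-reproducible for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param nResidues number of receptor residues (>= 4).
#' @param nLigandAtoms number of ligand heavy atoms (>= 1).
#' @param pocketDepth pocket radius control, Angstrom; the shell radius is
#'   \code{2.5 + pocketDepth}, enlarged if needed to keep the fold
#'   self-avoiding.
#' @return ComplexModel (receptor chain A, ligand residue LIG on chain L).
#' @seealso \code{\link{syntheticForcefield}} for the matching parameters.
#' @export
makeSyntheticComplex <- function(seed, nResidues, nLigandAtoms,
                                 pocketDepth = 4.0) {
  stopifnot(nResidues >= 4L, nLigandAtoms >= 1L, pocketDepth > 0)
  .withSeed(seed, {
    capFrac <- 0.70  # fraction of the sphere used by the shell (opening at +z)
    rShell <- max(2.5 + pocketDepth, 4.1 * sqrt(nResidues / (capFrac * 4 * pi)))
    # Fibonacci lattice over the spherical cap z/r in [-1, 2*capFrac - 1]
    golden <- pi * (3 - sqrt(5))
    k <- seq_len(nResidues) - 0.5
    zfrac <- -1 + 2 * capFrac * k / nResidues
    phi <- golden * (seq_len(nResidues) - 1L)
    ca <- cbind(rShell * sqrt(1 - zfrac^2) * cos(phi),
                rShell * sqrt(1 - zfrac^2) * sin(phi),
                rShell * zfrac)
    ca <- ca + matrix(stats::rnorm(3 * nResidues, 0, 0.15), ncol = 3)
    cb <- ca * (1 + 1.5 / sqrt(rowSums(ca^2)))
    # ligand: random walk inside a ball that keeps >= 2.5 A from the shell,
    # seeded close to the shell wall so the pocket always has contact
    # residues within the 5.0 A site cutoff
    rLig <- max(1.0, rShell - 4.0)
    lig <- matrix(NA_real_, nLigandAtoms, 3)
    dir0 <- stats::rnorm(3); dir0[3] <- -abs(dir0[3])
    dir0 <- dir0 / sqrt(sum(dir0^2))
    lig[1, ] <- dir0 * max(0, rShell - 4.3)
    rec <- rbind(ca, cb)
    for (i in seq_len(nLigandAtoms)[-1]) {
      placed <- FALSE
      for (try in 1:500) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- lig[i - 1L, ] + 1.45 * dir
        if (sqrt(sum(cand^2)) > rLig) next
        if (i > 2L && min(.pairdist(matrix(cand, 1), lig[seq_len(i - 2L), ,
                                                         drop = FALSE])) < 1.8) next
        if (min(.pairdist(matrix(cand, 1), rec)) < 2.5) next
        lig[i, ] <- cand; placed <- TRUE; break
      }
      if (!placed) stop("synthetic ligand placement failed after bounded retries")
    }
    resnames <- sample(.AA3, nResidues, replace = TRUE)
    recAtoms <- data.frame(
      serial = seq_len(2L * nResidues),
      name = rep(c("CA", "CB"), nResidues),
      element = "C",
      chain = "A",
      resno = rep(seq_len(nResidues), each = 2L),
      resname = rep(resnames, each = 2L),
      record = "protein",
      x = as.vector(rbind(ca[, 1], cb[, 1])),
      y = as.vector(rbind(ca[, 2], cb[, 2])),
      z = as.vector(rbind(ca[, 3], cb[, 3])),
      stringsAsFactors = FALSE)
    ligEl <- rep(c("C", "C", "N", "O"), length.out = nLigandAtoms)
    ligAtoms <- data.frame(
      serial = 2L * nResidues + seq_len(nLigandAtoms),
      name = paste0("L", seq_len(nLigandAtoms)),
      element = ligEl,
      chain = "L",
      resno = 1L,
      resname = "LIG",
      record = "hetero",
      x = lig[, 1], y = lig[, 2], z = lig[, 3],
      stringsAsFactors = FALSE)
    new("ComplexModel",
        receptor = new("Structure", atoms = recAtoms),
        ligand = new("Structure", atoms = ligAtoms))
  })
}

#' Minimal force field matching a synthetic complex
#'
#' Emits a \code{ForceFieldSpec} whose atom-type map and explicit topology
#' cover exactly the atoms of a generated complex: harmonic bonds along the
#' C-alpha trace, to side-chain dummies and along the ligand chain (rest
#' lengths taken from the generated geometry, so the complex sits near its
#' gas-phase minimum), angles and torsions derived from the bond graph, and
#' per-element nonbonded, generalized-Born (mbondi2-style radii) and LCPO
#' parameters.
#'
#' @param complex a ComplexModel from \code{\link{makeSyntheticComplex}}.
#' @param bondK,angleK,torsionV force constants (kcal/mol/A^2, kcal/mol/rad^2,
#'   kcal/mol).
#' @return ForceFieldSpec with topology resolved against the complex's atom
#'   order (receptor atoms first, then ligand atoms).
#' @export
syntheticForcefield <- function(complex, bondK = 300, angleK = 50,
                                torsionV = 0.2) {
  ra <- complex@receptor@atoms; la <- complex@ligand@atoms
  all <- rbind(ra, la)
  xyz <- unname(as.matrix(all[, c("x", "y", "z")]))
  nR <- nrow(ra)
  # bond graph
  caIdx <- which(all$name == "CA")
  bonds <- list()
  for (i in seq_along(caIdx)[-1]) bonds[[length(bonds) + 1L]] <- c(caIdx[i - 1L], caIdx[i])
  for (i in seq_along(caIdx)) {
    cbi <- which(all$name == "CB" & all$resno == all$resno[caIdx[i]] &
                   all$chain == all$chain[caIdx[i]])
    if (length(cbi)) bonds[[length(bonds) + 1L]] <- c(caIdx[i], cbi[1])
  }
  ligIdx <- nR + seq_len(nrow(la))
  for (i in seq_along(ligIdx)[-1]) bonds[[length(bonds) + 1L]] <- c(ligIdx[i - 1L], ligIdx[i])
  bmat <- do.call(rbind, bonds)
  blen <- sqrt(rowSums((xyz[bmat[, 1], , drop = FALSE] -
                          xyz[bmat[, 2], , drop = FALSE])^2))
  bondTab <- cbind(bmat, k = bondK, r0 = blen)
  # angles and torsions from the bond graph
  adj <- vector("list", nrow(all))
  for (b in seq_len(nrow(bmat))) {
    adj[[bmat[b, 1]]] <- c(adj[[bmat[b, 1]]], bmat[b, 2])
    adj[[bmat[b, 2]]] <- c(adj[[bmat[b, 2]]], bmat[b, 1])
  }
  angles <- list()
  for (j in seq_along(adj)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L)
      for (a in seq_along(nb)) for (b in seq_along(nb))
        if (a < b) angles[[length(angles) + 1L]] <- c(nb[a], j, nb[b])
  }
  angTab <- NULL
  if (length(angles)) {
    amat <- do.call(rbind, angles)
    th <- vapply(seq_len(nrow(amat)), function(r) {
      v1 <- xyz[amat[r, 1], ] - xyz[amat[r, 2], ]
      v2 <- xyz[amat[r, 3], ] - xyz[amat[r, 2], ]
      acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
    }, numeric(1))
    angTab <- cbind(amat, k = angleK, theta0 = th)
  }
  tors <- list()
  for (b in seq_len(nrow(bmat))) {
    j <- bmat[b, 1]; k <- bmat[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      if (i != l) tors[[length(tors) + 1L]] <- c(i, j, k, l)
  }
  torTab <- if (length(tors))
    cbind(do.call(rbind, tors), vn = torsionV, n = 3, phase = 0) else
      matrix(numeric(0), 0, 7)
  types <- list(
    CAB = list(charge = 0.10, eps = 0.086, rmin2 = 1.908, mass = 12.011,
               gb_radius = 1.70, gb_screen = 0.72,
               lcpo = c(0.56482, -0.19608, -0.0010219, 0.0002658),
               lcpo_radius = 1.70),
    CBS = list(charge = -0.10, eps = 0.086, rmin2 = 1.908, mass = 12.011,
               gb_radius = 1.70, gb_screen = 0.72,
               lcpo = c(0.56482, -0.19608, -0.0010219, 0.0002658),
               lcpo_radius = 1.70),
    LC = list(charge = 0.15, eps = 0.086, rmin2 = 1.908, mass = 12.011,
              gb_radius = 1.70, gb_screen = 0.72,
              lcpo = c(0.56482, -0.19608, -0.0010219, 0.0002658),
              lcpo_radius = 1.70),
    LN = list(charge = -0.30, eps = 0.17, rmin2 = 1.824, mass = 14.007,
              gb_radius = 1.55, gb_screen = 0.79,
              lcpo = c(0.41102, -0.12254, -0.000075448, 0.00011804),
              lcpo_radius = 1.65),
    LO = list(charge = -0.35, eps = 0.21, rmin2 = 1.6612, mass = 15.999,
              gb_radius = 1.50, gb_screen = 0.85,
              lcpo = c(0.77914, -0.25262, -0.0016056, 0.00035071),
              lcpo_radius = 1.60))
  atomTypes <- c(CA = "CAB", CB = "CBS")
  ligTypes <- c(C = "LC", N = "LN", O = "LO")[la$element]
  names(ligTypes) <- la$name
  atomTypes <- c(atomTypes, ligTypes)
  new("ForceFieldSpec", types = types, globals = .defaultGlobals(),
      atomTypes = atomTypes,
      topology = list(bonds = bondTab, angles = angTab, torsions = torTab))
}

#' Emulate MD snapshots around a complex
#'
#' Snapshot k is the base coordinates plus i.i.d. Gaussian noise of standard
#' deviation \code{sigma} per coordinate, plus a rigid translation of the
#' ligand by \code{k * drift} Angstrom along the pocket opening (+z). A
#' nonzero drift emulates a ligand leaving the binding pocket.
#'
#' @param c ComplexModel.
#' @param n number of snapshots (>= 1).
#' @param sigma thermal noise, Angstrom (>= 0).
#' @param drift ligand rigid-body drift per snapshot, Angstrom (>= 0).
#' @param seed integer RNG seed.
#' @param interval snapshot spacing in ps.
#' @return TrajectoryEnsemble (receptor atoms first, then ligand atoms).
#' @export
perturbEnsemble <- function(c, n, sigma, drift, seed, interval = 10) {
  stopifnot(n >= 1L, sigma >= 0, drift >= 0)
  all <- rbind(c@receptor@atoms, c@ligand@atoms)
  base <- unname(as.matrix(all[, c("x", "y", "z")]))
  nRec <- nrow(c@receptor@atoms)
  ligRows <- nRec + seq_len(nrow(c@ligand@atoms))
  .withSeed(seed, {
    coords <- lapply(seq_len(n), function(k) {
      m <- base + matrix(stats::rnorm(length(base), 0, sigma), ncol = 3)
      m[ligRows, 3] <- m[ligRows, 3] + k * drift
      m
    })
    new("TrajectoryEnsemble",
        roster = all[, setdiff(names(all), c("x", "y", "z"))],
        coords = coords, times = interval * seq_len(n))
  })
}
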