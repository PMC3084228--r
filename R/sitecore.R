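# C-alpha-level binding-site characterization.
#
# The geometric potential (GP) used here is a rotation-invariant,
# burial-sensitive surrogate: a distance-weighted neighbour density per
# residue, min-max scaled to [0, 100], with an environment direction pointing
# from each C-alpha toward its neighbour centroid.

#' Geometric potential over a C-alpha trace
#'
#' For residue i the raw score is \code{g_i = sum over j != i with d_ij < d_c
#' of (1 - d_ij / d_c)}; GP is the min-max scaling of g to [0, 100] (all-equal
#' profiles map to 50). Buried residues, with many close neighbours, score
#' high; exposed ones score low.
#'
#' @param caTrace a Structure; only atoms named CA are used (one per residue).
#' @param dC neighbour cutoff, Angstrom (default 10).
#' @return GeometricPotentialProfile.
#' @export
computeGeometricPotential <- function(caTrace, dC = 10) {
  stopifnot(dC > 0)
  a <- caTrace@atoms
  ca <- a[a$name == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("no C-alpha atoms in input")
  xyz <- unname(as.matrix(ca[, c("x", "y", "z")]))
  n <- nrow(xyz)
  g <- numeric(n)
  dir <- matrix(0, n, 3); hasDir <- logical(n)
  if (n > 1L) {
    D <- .pairdist(xyz, xyz)
    diag(D) <- Inf
    W <- ifelse(D < dC, 1 - D / dC, 0)
    g <- rowSums(W)
    for (i in seq_len(n)) {
      nb <- which(D[i, ] < dC)
      if (length(nb)) {
        v <- colMeans(xyz[nb, , drop = FALSE]) - xyz[i, ]
        nv <- sqrt(sum(v^2))
        if (nv > 1e-9) { dir[i, ] <- v / nv; hasDir[i] <- TRUE }
      }
    }
  }
  rng <- range(g)
  gp <- if (diff(rng) < 1e-12) rep(50, n) else 100 * (g - rng[1]) / diff(rng)
  new("GeometricPotentialProfile",
      profile = data.frame(chain = ca$chain, resno = ca$resno,
                           resname = ca$resname,
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           g_raw = g, gp = gp, dx = dir[, 1], dy = dir[, 2],
                           dz = dir[, 3], has_dir = hasDir,
                           stringsAsFactors = FALSE))
}

#' Define a binding site by ligand proximity
#'
#' Receptor residues with any heavy-atom distance to any ligand heavy atom
#' strictly below \code{cutoff} form the site (the 5.0-Angstrom convention).
#' GP scores are attached from a profile of the full receptor C-alpha trace.
#'
#' @param c ComplexModel.
#' @param cutoff Angstrom, default 5.0; membership is strict less-than.
#' @param profile optional precomputed GeometricPotentialProfile of the
#'   receptor; computed on the fly when NULL.
#' @param id parent structure id recorded on the site.
#' @return BindingSite (possibly empty, with a warning).
#' @export
defineSiteByLigand <- function(c, cutoff = 5.0, profile = NULL,
                               id = "structure") {
  ra <- c@receptor@atoms; la <- c@ligand@atoms
  rHeavy <- ra[toupper(ra$element) != "H", , drop = FALSE]
  lHeavy <- la[toupper(la$element) != "H", , drop = FALSE]
  if (!nrow(lHeavy)) stop("ligand has no heavy atoms")
  D <- .pairdist(unname(as.matrix(rHeavy[, c("x", "y", "z")])),
                 unname(as.matrix(lHeavy[, c("x", "y", "z")])))
  near <- apply(D, 1, min) < cutoff
  resKey <- paste(rHeavy$chain, rHeavy$resno)
  inSite <- unique(resKey[near])
  if (is.null(profile)) profile <- computeGeometricPotential(c@receptor)
  p <- profile@profile
  pKey <- paste(p$chain, p$resno)
  keep <- p[pKey %in% inSite, , drop = FALSE]
  keep <- keep[order(keep$chain, keep$resno), , drop = FALSE]
  if (!nrow(keep)) warning("empty binding site at cutoff ", cutoff, " A")
  xyz <- unname(as.matrix(keep[, c("x", "y", "z")]))
  new("BindingSite", parentId = id,
      residues = data.frame(chain = keep$chain, resno = keep$resno,
                            resname = keep$resname, gp = keep$gp,
                            stringsAsFactors = FALSE),
      caCoords = xyz,
      centroid = if (nrow(keep)) colMeans(xyz) else c(NA_real_, NA_real_, NA_real_))
}

#' Overlap between a reference and a predicted binding site
#'
#' Shared residues counted by residue id; the fraction is normalized by the
#' reference (known-ligand) site size, matching the convention of quoting
#' e.g. 16/22 = 73 percent recovery.
#'
#' @param reference,predicted BindingSite objects on the same parent
#'   structure.
#' @return list with \code{shared}, \code{reference_size}, \code{fraction}.
#' @export
siteOverlap <- function(reference, predicted) {
  if (!identical(reference@parentId, predicted@parentId))
    stop("sites from different parent structures are not comparable")
  kr <- paste(reference@residues$chain, reference@residues$resno)
  kp <- paste(predicted@residues$chain, predicted@residues$resno)
  shared <- length(intersect(kr, kp))
  list(shared = shared, reference_size = length(kr),
       fraction = if (length(kr)) shared / length(kr) else NA_real_)
}

#' Serialize binding sites as TSV
#'
#' @param site BindingSite.
#' @param path output file.
#' @export
writeSiteTSV <- function(site, path) {
  r <- site@residues
  .writeTSV(data.frame(structure_id = site@parentId, chain = r$chain,
                       residue_number = r$resno, residue_name = r$resname,
                       GP = r$gp), path)
  invisible(path)
}
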