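# Ensemble MM/GBSA binding free energies (single-trajectory convention),
# dG = dH - dTS bookkeeping, and trajectory stability diagnostics.

.breakdownFor <- function(sys, coords, entropy = FALSE, minimize = entropy,
                          temperature = NULL) {
  ts <- c(ts_trans = 0, ts_rot = 0, ts_vib = 0)
  x <- as.matrix(coords)
  if (entropy) {
    if (minimize) {
      # quasi-Newton gas-phase refinement so the Hessian is taken at a
      # proper minimum
      obj <- .objectiveFactory(sys, x, seq_len(nrow(x)), integer(0), 0, x)
      fit <- stats::optim(as.vector(x), obj$fn, obj$gr, method = "BFGS",
                          control = list(maxit = 2000L, reltol = 1e-14))
      x <- obj$assemble(fit$par)
    }
    ts <- normalModeEntropy(sys, x, temperature = temperature, gradTol = 1.0)
  }
  e <- mmEnergy(sys, as.matrix(coords))
  gb <- gbPolarEnergy(sys, as.matrix(coords))
  sa <- sasaLCPO(sys, as.matrix(coords))$g_sa
  new("EnergyBreakdown", bond = unname(e["bond"]), angle = unname(e["angle"]),
      torsion = unname(e["torsion"]), vdw = unname(e["vdw"]),
      elec = unname(e["elec"]), gb = gb, sa = sa,
      tsTrans = unname(ts["ts_trans"]), tsRot = unname(ts["ts_rot"]),
      tsVib = unname(ts["ts_vib"]), entropyComputed = entropy)
}

#' MM/GBSA energy breakdown of one snapshot
#'
#' Evaluates complex, receptor and ligand breakdowns from a single complex
#' snapshot (single-trajectory convention: receptor and ligand coordinates
#' are sliced from the complex snapshot, so intramolecular terms cancel in
#' the binding differences). Entropy is optional; when skipped the TS terms
#' are zero and flagged.
#'
#' @param sys ParameterizedSystem with receptor/ligand masks.
#' @param coords n x 3 complex snapshot.
#' @param entropy compute normal-mode entropy terms (slow).
#' @param minimize gas-phase minimize each state before the Hessian
#'   (default follows \code{entropy}).
#' @return list of EnergyBreakdown: \code{complex}, \code{receptor},
#'   \code{ligand}.
#' @export
snapshotMMGBSA <- function(sys, coords, entropy = FALSE, minimize = entropy) {
  recIdx <- subsystemIndices(sys, "receptor")
  ligIdx <- subsystemIndices(sys, "ligand")
  if (!length(ligIdx)) stop("ligand mask is empty")
  if (!length(recIdx)) stop("receptor mask is empty")
  x <- as.matrix(coords)
  list(complex = .breakdownFor(sys, x, entropy, minimize),
       receptor = .breakdownFor(subsetSystem(sys, recIdx),
                                x[recIdx, , drop = FALSE], entropy, minimize),
       ligand = .breakdownFor(subsetSystem(sys, ligIdx),
                              x[ligIdx, , drop = FALSE], entropy, minimize))
}

#' Assemble a binding free energy from enthalpy and entropy
#'
#' \code{dG = dH - dTS} (all kcal/mol); the bookkeeping used to combine
#' ensemble-averaged binding enthalpies with T-weighted entropy changes.
#'
#' @param dH binding enthalpy (vectorized).
#' @param dTS entropy term T*dS (vectorized).
#' @export
assembleDeltaG <- function(dH, dTS) {
  stopifnot(all(is.finite(dH)), all(is.finite(dTS)))
  dH - dTS
}

#' Ensemble-averaged MM/GBSA binding free energy
#'
#' Per snapshot, every term enters as complex minus receptor minus ligand;
#' the binding enthalpy is the ensemble mean of dE_MM + dG_GB + dG_SA, the
#' entropy term the mean of T*dS over the entropy snapshots (every
#' \code{entropyStride}-th snapshot), and dG = dH - dTS. Standard errors of
#' the means are reported.
#'
#' @param sys ParameterizedSystem.
#' @param traj TrajectoryEnsemble of complex snapshots (roster must match the
#'   system's atoms).
#' @param entropy include the normal-mode entropy term.
#' @param entropyStride entropy evaluated on every n-th snapshot (cost
#'   control).
#' @return BindingFreeEnergy.
#' @export
ensembleBindingFreeEnergy <- function(sys, traj, entropy = FALSE,
                                      entropyStride = 1L) {
  ns <- nSnapshots(traj)
  if (!ns) stop("empty trajectory")
  if (nrow(traj@roster) != nrow(sys@atoms))
    stop("trajectory roster does not match the parameterized system")
  rows <- lapply(seq_len(ns), function(k) {
    doTS <- entropy && ((k - 1L) %% entropyStride == 0L)
    b <- snapshotMMGBSA(sys, traj@coords[[k]], entropy = doTS)
    d <- function(f) f(b$complex) - f(b$receptor) - f(b$ligand)
    dEmm <- d(eMM)
    dGgb <- d(function(z) z@gb)
    dGsa <- d(function(z) z@sa)
    dTS <- if (doTS) d(function(z) z@tsTrans + z@tsRot + z@tsVib) else NA_real_
    data.frame(time = traj@times[k], dEmm = dEmm, dGgb = dGgb, dGsa = dGsa,
               dH = dEmm + dGgb + dGsa, dTS = dTS)
  })
  per <- do.call(rbind, rows)
  dH <- mean(per$dH)
  tsVals <- per$dTS[!is.na(per$dTS)]
  dTS <- if (length(tsVals)) mean(tsVals) else 0
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  seDH <- se(per$dH)
  seDTS <- if (length(tsVals)) se(tsVals) else 0
  per$dG <- per$dH - ifelse(is.na(per$dTS), dTS, per$dTS)
  new("BindingFreeEnergy", perSnapshot = per, dH = dH, dTS = dTS,
      dG = assembleDeltaG(dH, dTS), seDH = seDH, seDTS = seDTS,
      seDG = sqrt(seDH^2 + seDTS^2), n = as.integer(ns))
}

#' Read a published-style binding free-energy table
#'
#' TSV columns: \code{target, ligand, dH, dTS, dG} (kcal/mol).
#'
#' @param path TSV path; defaults to the kinase--inhibitor table bundled
#'   with the package.
#' @export
readEnergyTable <- function(path = system.file("extdata",
                                               "kinase_mmgbsa_energies.tsv",
                                               package = "offtargetr")) {
  df <- .readTSV(path)
  need <- c("target", "ligand", "dH", "dTS", "dG")
  if (!all(need %in% names(df)))
    stop("energy table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Check dG = dH - dTS consistency of an energy table
#'
#' Flags rows whose printed dG deviates from dH - dTS by more than \code{tol}
#' (default 0.01 kcal/mol, i.e. beyond two-decimal rounding drift).
#'
#' @param table data.frame as from \code{\link{readEnergyTable}}.
#' @param tol kcal/mol.
#' @return the table with added \code{residual} (dG - (dH - dTS)) and logical
#'   \code{consistent} columns.
#' @export
checkTableConsistency <- function(table, tol = 0.01) {
  res <- table$dG - assembleDeltaG(table$dH, table$dTS)
  out <- table
  out$residual <- res
  out$consistent <- abs(res) <= tol + 1e-12
  out
}

#' Trajectory stability diagnostics
#'
#' On an ensemble already superposed to its first frame: the receptor flag is
#' PASS when the maximum backbone RMSD stays below \code{rmsdPass}; the
#' ligand flag is POCKET_EXIT when the mean ligand heavy-atom RMSD exceeds
#' \code{exitThreshold} or the ligand centroid sits outside the
#' \code{siteEnvelope}-Angstrom sphere around its first-frame position in
#' more than half of the snapshots.
#'
#' @param traj TrajectoryEnsemble, superposed (see
#'   \code{\link{superposeToFirst}}).
#' @param backboneSelection receptor backbone atom names or predicate.
#' @param ligandSelection ligand heavy-atom predicate (default: hetero
#'   records, non-hydrogen).
#' @param rmsdPass receptor threshold, Angstrom (default 3.0).
#' @param exitThreshold ligand mean-RMSD threshold, Angstrom (default 4.0).
#' @param siteEnvelope pocket envelope radius, Angstrom (default 5.0).
#' @return list: \code{receptor_flag} (PASS/FAIL), \code{max_backbone_rmsd},
#'   \code{ligand_flag} (OK/POCKET_EXIT), \code{mean_ligand_rmsd},
#'   \code{fraction_outside_envelope}, plus both RMSD series.
#' @export
stabilityCheck <- function(traj, backboneSelection = c("N", "CA", "C", "O"),
                           ligandSelection = function(a)
                             a$record == "hetero" && toupper(a$element) != "H",
                           rmsdPass = 3.0, exitThreshold = 4.0,
                           siteEnvelope = 5.0) {
  bbIdx <- .selectionIdx(traj@roster, backboneSelection)
  ligIdx <- .selectionIdx(traj@roster, ligandSelection)
  if (!length(bbIdx) || !length(ligIdx)) stop("empty selection")
  bb <- rmsdSeries(traj, backboneSelection)
  # alignment precondition: no snapshot may be improvable by more than 10%
  # through an extra rigid fit of the backbone selection
  ref <- traj@coords[[1]][bbIdx, , drop = FALSE]
  for (k in seq_len(nSnapshots(traj))[-1]) {
    cur <- bb$rmsd[k]
    opt <- superposePoints(ref, traj@coords[[k]][bbIdx, , drop = FALSE])$rmsd
    if (cur > 1.1 * opt + 0.05)
      stop("trajectory is not aligned to its first frame (superpose first)")
  }
  lig <- rmsdSeries(traj, ligandSelection)
  cen0 <- colMeans(traj@coords[[1]][ligIdx, , drop = FALSE])
  outFrac <- mean(vapply(traj@coords, function(m)
    sqrt(sum((colMeans(m[ligIdx, , drop = FALSE]) - cen0)^2)) > siteEnvelope,
    logical(1)))
  exit <- mean(lig$rmsd) > exitThreshold || outFrac > 0.5
  list(receptor_flag = if (max(bb$rmsd) < rmsdPass) "PASS" else "FAIL",
       max_backbone_rmsd = max(bb$rmsd),
       ligand_flag = if (exit) "POCKET_EXIT" else "OK",
       mean_ligand_rmsd = mean(lig$rmsd),
       fraction_outside_envelope = outFrac,
       backbone_rmsd = bb, ligand_rmsd = lig)
}

#' Write ensemble binding free energies as TSV
#'
#' @param results named list of BindingFreeEnergy (names are target ids).
#' @param ligand ligand label column.
#' @param path output TSV.
#' @export
writeEnergyTSV <- function(results, ligand, path) {
  rows <- lapply(names(results), function(id) {
    s <- bindingSummary(results[[id]])
    data.frame(target = id, ligand = ligand, dH = s$dH, dTS = s$dTS,
               dG = s$dG, se_dG = s$se_dG, n_snapshots = s$n_snapshots)
  })
  .writeTSV(do.call(rbind, rows), path)
  invisible(path)
}
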