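# End-to-end off-target screening pipeline: site screen -> pose transfer and
# clash/NDS filtering -> stringent shortlist -> ensemble MM/GBSA and
# stability diagnostics -> signed-network propagation. Every stage writes a
# TSV and the manifest hash-chains inputs to outputs; identical seeds
# reproduce every output bit for bit.

#' Pipeline configuration
#'
#' All thresholds are configuration with conventional defaults: significance
#' on the site-screen p-value (1e-3, stringent 1e-4), NDS retention below
#' 0.0, the 5.0-Angstrom site cutoff and the 3.0-Angstrom backbone-RMSD pass
#' mark.
#'
#' @param pSignificant,pStringent screen p-value thresholds.
#' @param ndsMax NDS retention threshold.
#' @param siteCutoff binding-site distance cutoff, Angstrom.
#' @param rmsdPass backbone RMSD stability threshold, Angstrom.
#' @param nSnapshots snapshots generated per ensemble.
#' @param snapshotInterval spacing, ps.
#' @param entropy include normal-mode entropy in stage 4 (slow).
#' @param entropyStride entropy snapshot stride.
#' @param seed master seed; all stage seeds derive from it.
#' @param nDecoyTargets synthetic library size for the demo.
#' @param nBackground decoy alignments for the screen background.
#' @param nScoreDecoys decoy placements for the NDS background.
#' @param sigma ensemble thermal noise, Angstrom.
#' @param outDir output directory.
#' @return named list.
#' @export
pipelineConfig <- function(pSignificant = 1e-3, pStringent = 1e-4,
                           ndsMax = 0.0, siteCutoff = 5.0, rmsdPass = 3.0,
                           nSnapshots = 10L, snapshotInterval = 10,
                           entropy = FALSE, entropyStride = 1L, seed = 1L,
                           nDecoyTargets = 30L, nBackground = 100L,
                           nScoreDecoys = 50L, sigma = 0.25,
                           outDir = tempfile("offtarget_run_")) {
  stopifnot(pStringent <= pSignificant, pSignificant < 1, pStringent > 0,
            siteCutoff > 0, rmsdPass > 0)
  as.list(environment())
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}}; missing keys
#' take the defaults.
#'
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

.invertTransform <- function(tr)
  list(rotation = t(tr$rotation),
       translation = as.vector(-t(tr$rotation) %*% tr$translation))

.hashChain <- function(prev, path) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(prev, unname(tools::md5sum(path))), tmp)
  unname(tools::md5sum(tmp))
}

.randomRigidTransform <- function() {
  # uniform-ish proper rotation from QR, plus a translation
  M <- matrix(stats::rnorm(9), 3)
  qrd <- qr(M)
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = stats::runif(3, -20, 20))
}

.plantSimilarTarget <- function(query, seed) {
  # rigid copy of the query complex with one site residue mutated
  .withSeed(seed, {
    tr <- .randomRigidTransform()
    mv <- function(s) {
      xyz <- .applyTransform(coordMatrix(s), tr$rotation, tr$translation)
      a <- s@atoms; a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      new("Structure", atoms = a)
    }
    rec <- mv(query@receptor)
    mutRes <- sample(unique(rec@atoms$resno), 1L)
    cur <- rec@atoms$resname[rec@atoms$resno == mutRes][1]
    rec@atoms$resname[rec@atoms$resno == mutRes] <-
      sample(setdiff(.AA3, cur), 1L)
    new("ComplexModel", receptor = rec, ligand = mv(query@ligand))
  })
}

#' Run the off-target screening pipeline on synthetic inputs
#'
#' Builds a synthetic query complex and a target library (decoy folds plus
#' one planted near-copy of the query), then runs the five stages:
#' binding-site screen with Gumbel significance, pose transfer with
#' clash/NDS filtering, stringent shortlist, ensemble MM/GBSA with stability
#' diagnostics, and signed-network propagation of the surviving off-target
#' set. Each stage writes a TSV under \code{config$outDir} and the manifest
#' records seeds, parameters and an md5 hash chain over the stage outputs.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @return list with the per-stage tables, the manifest, and the output
#'   directory.
#' @export
runOfftargetScreen <- function(config = pipelineConfig()) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  out <- function(f) file.path(config$outDir, f)
  manifest <- list(config = config[setdiff(names(config), "outDir")],
                   stages = list())
  chain <- "seed"
  logStage <- function(name, path, t0) {
    manifest$stages[[name]] <<- list(
      output = basename(path), md5 = unname(tools::md5sum(path)),
      chain = (chain <<- .hashChain(chain, path)))
    message(sprintf("[%s] wrote %s (%.1f s)", name, basename(path),
                    as.numeric(Sys.time()) - t0))
  }

  # inputs: query complex + site, synthetic target library
  query <- makeSyntheticComplex(seed, nResidues = 40L, nLigandAtoms = 12L)
  queryFF <- syntheticForcefield(query)
  querySite <- defineSiteByLigand(query, config$siteCutoff, id = "query")
  targets <- list()
  planted <- .plantSimilarTarget(query, seed + 1000L)
  targets[["planted"]] <- planted
  for (k in seq_len(config$nDecoyTargets))
    targets[[sprintf("decoy%03d", k)]] <-
      makeSyntheticComplex(seed + 2000L + k, nResidues = 40L,
                           nLigandAtoms = 12L)
  sites <- lapply(names(targets), function(id)
    defineSiteByLigand(targets[[id]], config$siteCutoff, id = id))
  names(sites) <- names(targets)

  # stage 1: site screen
  t0 <- as.numeric(Sys.time())
  hits <- screenSites(querySite, sites, alpha = config$pSignificant,
                      alphaStringent = config$pStringent,
                      nDecoys = config$nBackground, seed = seed + 1L)
  .writeTSV(hits, out("stage1_screen.tsv"))
  logStage("screen", out("stage1_screen.tsv"), t0)
  sig <- hits[hits$p_value < config$pSignificant, , drop = FALSE]

  # stage 2: pose transfer, clash and NDS filtering
  t0 <- as.numeric(Sys.time())
  poseRows <- list(); poses <- list()
  for (id in sig$target_id) {
    aln <- alignSites(querySite, sites[[id]])
    if (!aln@hasTransform) next
    pose <- transferPose(query@ligand, .invertTransform(alignmentTransform(aln)),
                         provenance = paste0("query->", id))
    ffT <- syntheticForcefield(targets[[id]])
    pose <- localOptimizePose(targets[[id]]@receptor, pose, ffT)
    cl <- clashReport(targets[[id]]@receptor, pose)
    raw <- attr(pose, "score")
    bg <- decoyScoreBackground(targets[[id]]@receptor, pose, ffT,
                               n = config$nScoreDecoys, seed = seed + 2L)
    poseRows[[id]] <- data.frame(target_id = id, raw_score = raw,
                                 clash_count = cl$count, severe = cl$severe,
                                 nds = normalizedDockingScore(raw, bg))
    poses[[id]] <- pose
  }
  poseTab <- if (length(poseRows)) do.call(rbind, poseRows) else
    data.frame(target_id = character(0), raw_score = numeric(0),
               clash_count = integer(0), severe = logical(0), nds = numeric(0))
  retained <- ndsFilter(poseTab, config$ndsMax)
  .writeTSV(attr(retained, "all") %||% poseTab, out("stage2_poses.tsv"))
  logStage("pose", out("stage2_poses.tsv"), t0)

  # stage 3: stringent shortlist
  t0 <- as.numeric(Sys.time())
  shortlist <- retained[retained$target_id %in%
                          hits$target_id[hits$p_value < config$pStringent], ,
                        drop = FALSE]
  .writeTSV(shortlist, out("stage3_shortlist.tsv"))
  logStage("shortlist", out("stage3_shortlist.tsv"), t0)

  # stage 4: ensemble MM/GBSA + stability on generated ensembles
  t0 <- as.numeric(Sys.time())
  gbsaRows <- list()
  for (id in shortlist$target_id) {
    cplx <- targets[[id]]
    sys <- parameterizeSystem(cplx, syntheticForcefield(cplx))
    traj <- perturbEnsemble(cplx, config$nSnapshots, config$sigma, 0,
                            seed + 3L, config$snapshotInterval)
    traj <- superposeToFirst(traj, "CA")
    bfe <- ensembleBindingFreeEnergy(sys, traj, entropy = config$entropy,
                                     entropyStride = config$entropyStride)
    stab <- stabilityCheck(traj, "CA", rmsdPass = config$rmsdPass)
    s <- bindingSummary(bfe)
    gbsaRows[[id]] <- data.frame(target_id = id, dH = s$dH, dTS = s$dTS,
                                 dG = s$dG, se_dG = s$se_dG,
                                 n_snapshots = s$n_snapshots,
                                 receptor_flag = stab$receptor_flag,
                                 ligand_flag = stab$ligand_flag)
  }
  gbsaTab <- if (length(gbsaRows)) do.call(rbind, gbsaRows) else
    data.frame(target_id = character(0), dH = numeric(0), dTS = numeric(0),
               dG = numeric(0), se_dG = numeric(0), n_snapshots = integer(0),
               receptor_flag = character(0), ligand_flag = character(0))
  survivors <- gbsaTab$target_id[gbsaTab$receptor_flag == "PASS" &
                                   gbsaTab$ligand_flag == "OK"]
  .writeTSV(gbsaTab, out("stage4_mmgbsa.tsv"))
  logStage("mmgbsa", out("stage4_mmgbsa.tsv"), t0)

  # stage 5: network propagation (bundled illustrative network)
  t0 <- as.numeric(Sys.time())
  net <- offtargetNetwork()
  netTab <- NULL
  if (length(survivors)) {
    offNodes <- networkNodes(net)
    offNodes <- offNodes$id[offNodes$kind == "off_target"]
    res <- propagateInhibition(net, offNodes)
    netTab <- reportPerturbation(net, res, path = out("stage5_network.tsv"))
  } else {
    netTab <- data.frame(id = character(0), kind = character(0),
                         direction = character(0), n_up = integer(0),
                         n_down = integer(0))
    .writeTSV(netTab, out("stage5_network.tsv"))
  }
  logStage("network", out("stage5_network.tsv"), t0)

  manifest$survivors <- as.list(survivors)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(screen = hits, poses = poseTab, shortlist = shortlist,
       mmgbsa = gbsaTab, network = netTab, survivors = survivors,
       manifest = manifest, outDir = config$outDir)
}
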