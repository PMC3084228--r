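oneAtom <- function(name, element, x, record = "hetero", resname = "LIG",
                    chain = "L", resno = 1L, serial = 1L)
  structureFromRows(atomRow(serial, name, element, chain, resno, resname,
                            record, x[1], x[2], x[3]))

# two-type force field with known LJ parameters and zero charges
ljFF <- function(eps = 0.2, rmin2 = 1.9, q = 0) {
  tp <- list(charge = q, eps = eps, rmin2 = rmin2, mass = 12.011,
             gb_radius = 1.7, gb_screen = 0.72, lcpo = c(1, 0, 0, 0),
             lcpo_radius = 1.7)
  new("ForceFieldSpec", types = list(CX = tp),
      globals = offtargetr:::.defaultGlobals(),
      atomTypes = c(A1 = "CX", B1 = "CX"),
      topology = list(bonds = matrix(numeric(0), 0, 4),
                      angles = matrix(numeric(0), 0, 5),
                      torsions = matrix(numeric(0), 0, 7)))
}

test_that("pose transfer is an exact rigid map", {
  cx <- makeSyntheticComplex(11, 8, 6)
  lig <- ligand(cx)
  idt <- transferPose(lig, list(rotation = diag(3), translation = c(0, 0, 0)))
  expect_equal(coordMatrix(idt), coordMatrix(lig))
  shifted <- transferPose(lig, list(rotation = diag(3),
                                    translation = c(1, 0, 0)))
  expect_equal(colMeans(coordMatrix(shifted)) - colMeans(coordMatrix(lig)),
               c(1, 0, 0))
  set.seed(2)
  R <- randomRotation()
  rot <- transferPose(lig, list(rotation = R, translation = c(2, -1, 4)))
  expect_equal(as.numeric(dist(coordMatrix(rot))),
               as.numeric(dist(coordMatrix(lig))), tolerance = 1e-9)
  expect_error(transferPose(lig, list(rotation = diag(3) * 2,
                                      translation = numeric(3))),
               "proper rotation")
})

test_that("clash counting matches a brute-force all-pairs tally", {
  rec <- oneAtom("CA", "C", c(0, 0, 0), record = "protein", resname = "ALA",
                 chain = "A")
  near <- oneAtom("L1", "C", c(0.8, 0, 0))
  far <- oneAtom("L1", "C", c(4, 0, 0))
  expect_true(clashReport(rec, near)$severe)
  expect_gte(clashReport(rec, near)$count, 1L)
  expect_equal(clashReport(rec, far)$count, 0L)
  set.seed(31)
  for (k in 1:100) {
    nr <- sample(3:12, 1); nl <- sample(2:6, 1)
    rxyz <- matrix(runif(3 * nr, 0, 6), ncol = 3)
    lxyz <- matrix(runif(3 * nl, 0, 6), ncol = 3)
    rec <- new("Structure", atoms = atomRow(seq_len(nr), "CA", "C", "A",
                                            seq_len(nr), "ALA", "protein",
                                            rxyz[, 1], rxyz[, 2], rxyz[, 3]))
    lig <- new("Structure", atoms = atomRow(seq_len(nl), paste0("L", seq_len(nl)),
                                            "C", "L", 1L, "LIG", "hetero",
                                            lxyz[, 1], lxyz[, 2], lxyz[, 3]))
    want <- sum(offtargetr:::.pairdist(rxyz, lxyz) < 1.5)
    expect_equal(clashReport(rec, lig)$count, want)
  }
})

test_that("the interaction score has the stated LJ landmarks", {
  eps <- 0.25; rmin2 <- 1.9
  ff <- ljFF(eps, rmin2)
  rec <- oneAtom("A1", "C", c(0, 0, 0), record = "protein", resname = "ALA",
                 chain = "A")
  rmin <- 2 * rmin2
  sigma <- rmin / 2^(1 / 6)
  atSigma <- rawInteractionScore(rec, oneAtom("B1", "C", c(sigma, 0, 0)), ff)
  expect_equal(atSigma, 0, tolerance = 1e-10)
  atMin <- rawInteractionScore(rec, oneAtom("B1", "C", c(rmin, 0, 0)), ff)
  expect_equal(atMin, -eps, tolerance = 1e-10)
  # resolving a clash lowers the score
  cx <- makeSyntheticComplex(17, 12, 5)
  ffs <- syntheticForcefield(cx)
  lig <- ligand(cx)
  ra <- atomTable(receptor(cx))
  target <- unlist(ra[1, c("x", "y", "z")])
  clashPose <- transferPose(lig, list(
    rotation = diag(3),
    translation = as.numeric(target - colMeans(coordMatrix(lig)))))
  away <- transferPose(clashPose, list(rotation = diag(3),
                                       translation = c(0, 0, -2)))
  sClash <- rawInteractionScore(receptor(cx), clashPose, ffs)
  sAway <- rawInteractionScore(receptor(cx), away, ffs)
  expect_lt(sAway, sClash)
})

test_that("rigid local optimization is monotone and clash-reducing", {
  set.seed(12)
  for (k in 1:10) {
    cx <- makeSyntheticComplex(100 + k, 10, 4)
    ff <- syntheticForcefield(cx)
    # jitter the pose off its generated position
    pose <- transferPose(ligand(cx), list(rotation = diag(3),
                                          translation = runif(3, -1, 1)))
    out <- localOptimizePose(receptor(cx), pose, ff)
    expect_lte(attr(out, "score"), attr(out, "initial_score"))
    # bounded displacement (local contract)
    shift <- sqrt(sum((colMeans(coordMatrix(out)) -
                         colMeans(coordMatrix(pose)))^2))
    expect_lte(shift, 5 + 1e-6)
  }
  # clash fixture: optimization cannot add clashes
  cx <- makeSyntheticComplex(55, 12, 5)
  ff <- syntheticForcefield(cx)
  ra <- atomTable(receptor(cx))
  target <- unlist(ra[3, c("x", "y", "z")])
  pose <- transferPose(ligand(cx), list(
    rotation = diag(3),
    translation = as.numeric(target - colMeans(coordMatrix(ligand(cx)))) * 0.9))
  c0 <- clashReport(receptor(cx), pose)$count
  out <- localOptimizePose(receptor(cx), pose, ff)
  expect_lte(clashReport(receptor(cx), out)$count, c0)
})

test_that("NDS standardizes against the decoy background", {
  bg <- c(rnorm(30, -4, 2))
  expect_equal(normalizedDockingScore(mean(bg), bg), 0)
  expect_equal(normalizedDockingScore(mean(bg) - sd(bg), bg), -1)
  # affine recalibration of score and background cancels exactly
  s <- -7.3
  expect_equal(normalizedDockingScore(2.5 * s + 11, 2.5 * bg + 11),
               normalizedDockingScore(s, bg), tolerance = 1e-9)
  expect_error(normalizedDockingScore(0, rep(1, 25)), "constant")
  expect_error(normalizedDockingScore(0, bg[1:10]), ">= 20")
})

test_that("NDS filtering removes worse-than-random and clashing hits", {
  hits <- data.frame(target_id = c("a", "b", "c"),
                     nds = c(1.328, -2.0, -2.0),
                     severe = c(FALSE, FALSE, TRUE))
  kept <- ndsFilter(hits)
  expect_equal(kept$target_id, "b")   # positive NDS and clashes both removed
  all <- attr(kept, "all")
  expect_equal(all$retained, c(FALSE, TRUE, FALSE))
})

test_that("contact analysis applies the distance cutoffs", {
  rec <- structureFromRows(
    atomRow(1L, "N", "N", "A", 1L, "ALA", "protein", 0, 0, 0),
    atomRow(2L, "CB", "C", "A", 1L, "ALA", "protein", 0, 6, 0))
  lig <- structureFromRows(
    atomRow(3L, "O1", "O", "L", 1L, "LIG", "hetero", 3.16, 0, 0),
    atomRow(4L, "C1", "C", "L", 1L, "LIG", "hetero", 0, 6, 4.4),
    atomRow(5L, "O2", "O", "L", 1L, "LIG", "hetero", 0, 3.6, 0))
  rep <- analyzeContacts(rec, lig)
  expect_equal(nrow(rep$hbonds), 1L)  # the 3.16 A N...O pair only
  expect_equal(rep$hbonds$distance, 3.16, tolerance = 1e-9)
  expect_equal(nrow(rep$hydrophobic), 1L)  # the 4.4 A C...C pair
  expect_equal(rep$hydrophobic$distance, 4.4, tolerance = 1e-9)
})
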