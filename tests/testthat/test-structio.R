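test_that("PDB atom records parse with correct fields and round-trip", {
  line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  s <- readPDB(line)
  a <- atomTable(s)
  expect_equal(nrow(a), 1L)
  expect_equal(unlist(a[1, c("x", "y", "z")]), c(x = 1, y = 2, z = 3))
  expect_equal(a$name, "CA")
  expect_equal(a$resname, "ALA")
  expect_equal(a$record, "protein")

  cx <- makeSyntheticComplex(7, 6, 3)
  merged <- new("Structure",
                atoms = rbind(atomTable(receptor(cx)), atomTable(ligand(cx))))
  back <- readPDB(paste(writePDB(merged), collapse = "\n"))
  expect_equal(atomTable(back)$name, atomTable(merged)$name)
  expect_equal(atomTable(back)$element, atomTable(merged)$element)
  expect_equal(coordMatrix(back), round(coordMatrix(merged), 3),
               tolerance = 1e-9)
})

test_that("PDB parse errors are informative", {
  bad <- "ATOM      1  CA  ALA A   1       1.0xx   2.000   3.000"
  expect_error(readPDB(bad), "line 1")
  ins <- "ATOM      1  CA  ALA A   1A      1.000   2.000   3.000"
  expect_error(readPDB(ins), "insertion")
  expect_error(readPDB("REMARK nothing"), "no ATOM/HETATM")
})

test_that("multi-MODEL files become ensembles with consistent rosters", {
  cx <- makeSyntheticComplex(7, 6, 3)
  traj <- perturbEnsemble(cx, 5, 0.1, 0, 11)
  txt <- paste(writePDB(traj), collapse = "\n")
  back <- readPDB(txt, interval = 10)
  expect_s4_class(back, "TrajectoryEnsemble")
  expect_equal(nSnapshots(back), 5L)
  expect_equal(snapshotTimes(back), snapshotTimes(traj))
  expect_equal(coordMatrix(back, 3), round(coordMatrix(traj, 3), 3),
               tolerance = 1e-9)
  # roster mismatch across MODELs is rejected
  lines <- writePDB(traj)
  atomLines <- grep("^ATOM|^HETATM", lines)
  lines <- lines[-atomLines[length(atomLines)]]  # drop one atom of last MODEL
  expect_error(readPDB(paste(lines, collapse = "\n")), "roster")
})

test_that("splitComplex selects the ligand and rejects ambiguity", {
  cx <- makeSyntheticComplex(9, 6, 4)
  merged <- new("Structure",
                atoms = rbind(atomTable(receptor(cx)), atomTable(ligand(cx))))
  sp <- splitComplex(merged, "LIG")
  expect_equal(nAtoms(ligand(sp)), 4L)
  expect_true(all(atomTable(ligand(sp))$resname == "LIG"))
  expect_error(splitComplex(merged, "XYZ"), "matches no")
  # two ligand copies demand chain disambiguation
  dup <- atomTable(ligand(cx))
  dup$chain <- "M"; dup$serial <- dup$serial + 1000L
  merged2 <- new("Structure", atoms = rbind(atomTable(merged), dup))
  expect_error(splitComplex(merged2, "LIG"), "disambiguate")
  expect_equal(nAtoms(ligand(splitComplex(merged2, "LIG:M"))), 4L)
})

test_that("synthetic complexes are reproducible with a clear pocket geometry", {
  a <- makeSyntheticComplex(5, 30, 10)
  b <- makeSyntheticComplex(5, 30, 10)
  expect_identical(coordMatrix(receptor(a)), coordMatrix(receptor(b)))
  expect_identical(coordMatrix(ligand(a)), coordMatrix(ligand(b)))
  D <- offtargetr:::.pairdist(coordMatrix(receptor(a)), coordMatrix(ligand(a)))
  expect_gte(min(D), 2.5)
  # at least one residue within the 5.0 A site cutoff
  expect_gte(nrow(siteResidues(defineSiteByLigand(a, 5.0))), 1L)
})

test_that("perturbEnsemble applies noise and rigid ligand drift as stated", {
  cx <- makeSyntheticComplex(5, 10, 5)
  base <- rbind(coordMatrix(receptor(cx)), coordMatrix(ligand(cx)))
  still <- perturbEnsemble(cx, 4, 0, 0, 1)
  for (k in 1:4) expect_equal(coordMatrix(still, k), base)
  expect_identical(perturbEnsemble(cx, 4, 0.3, 0.1, 2)@coords,
                   perturbEnsemble(cx, 4, 0.3, 0.1, 2)@coords)
  drift <- perturbEnsemble(cx, 20, 0.05, 0.5, 3)
  ligRows <- 20 + seq_len(5)
  disp <- colMeans(coordMatrix(drift, 20)[ligRows, ]) -
    colMeans(base[ligRows, ])
  expect_equal(disp[3], 10, tolerance = 3 * 0.05 / sqrt(5) * 5 + 0.2)
  expect_lt(abs(disp[1]), 0.5)
})

test_that("snapshot selection uses the half-open window at fixed spacing", {
  cx <- makeSyntheticComplex(2, 4, 2)
  traj <- perturbEnsemble(cx, 800, 0, 0, 1, interval = 10)  # 10..8000 ps
  last2ns <- selectSnapshots(traj, c(6000, 8000), 10)
  expect_equal(nSnapshots(last2ns), 200L)
  expect_equal(min(snapshotTimes(last2ns)), 6010)
  expect_equal(max(snapshotTimes(last2ns)), 8000)
  expect_true(all(snapshotTimes(last2ns) %in% snapshotTimes(traj)))
  expect_false(is.unsorted(snapshotTimes(last2ns)))
  ten <- selectSnapshots(perturbEnsemble(cx, 10, 0, 0, 1), c(0, 100), 10)
  expect_equal(nSnapshots(ten), 10L)
  expect_error(selectSnapshots(traj, c(7000, 9000), 10), "beyond")
})

test_that("superposition to the first frame removes rigid motion", {
  cx <- makeSyntheticComplex(4, 10, 4)
  base <- rbind(coordMatrix(receptor(cx)), coordMatrix(ligand(cx)))
  roster <- perturbEnsemble(cx, 1, 0, 0, 1)@roster
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)  # 90 deg about z
  coords <- list(base,
                 sweep(base, 2, c(5, -3, 2), "+"),
                 base %*% t(R))
  traj <- new("TrajectoryEnsemble", roster = roster, coords = coords,
              times = c(10, 20, 30))
  fit <- superposeToFirst(traj, "CA")
  expect_equal(coordMatrix(fit, 1), base)
  for (k in 2:3)
    expect_lt(max(abs(coordMatrix(fit, k) - base)), 1e-8)
  # noisy case: fitting never increases the selection RMSD
  noisy <- perturbEnsemble(cx, 6, 0.4, 0.2, 9)
  pre <- rmsdSeries(noisy, "CA")$rmsd
  post <- rmsdSeries(superposeToFirst(noisy, "CA"), "CA")$rmsd
  expect_true(all(post <= pre + 1e-9))
  expect_error(superposeToFirst(traj, "ZZ"), "degenerate")
})

test_that("RMSD series measures per-snapshot displacement from frame 1", {
  cx <- makeSyntheticComplex(4, 6, 2)
  still <- perturbEnsemble(cx, 3, 0, 0, 1)
  expect_equal(rmsdSeries(still, "CA")$rmsd, c(0, 0, 0))
  # single selected atom displaced by (3,4,0): RMSD 5 by Pythagoras
  moved <- still
  i <- which(moved@roster$name == "L1")
  moved@coords[[2]][i, ] <- moved@coords[[2]][i, ] + c(3, 4, 0)
  expect_equal(rmsdSeries(moved, "L1")$rmsd[2], 5)
  expect_error(rmsdSeries(still, "QQ"), "empty selection")
  # gaussian noise against a clean reference frame: E[RMSD] ~ sigma * sqrt(3)
  set.seed(1)
  big <- makeSyntheticComplex(1, 500, 4)
  base <- rbind(coordMatrix(receptor(big)), coordMatrix(ligand(big)))
  roster <- perturbEnsemble(big, 1, 0, 0, 1)@roster
  noisy <- new("TrajectoryEnsemble", roster = roster,
               coords = list(base, base + matrix(rnorm(length(base), 0, 0.7),
                                                 ncol = 3)),
               times = c(10, 20))
  expect_equal(rmsdSeries(noisy, "CA")$rmsd[2], 0.7 * sqrt(3),
               tolerance = 0.1)
})
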