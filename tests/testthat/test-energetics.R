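test_that("parameter files load, validate, and round-trip", {
  tmp <- tempfile(fileext = ".json")
  writeLines('{
    "types": {
      "CX": {"charge": 0.1, "eps": 0.09, "rmin2": 1.9, "mass": 12.011,
              "element": "C"},
      "OX": {"charge": -0.4, "eps": 0.21, "rmin2": 1.66, "mass": 15.999,
              "element": "O"}
    }
  }', tmp)
  ff <- loadForcefield(tmp)
  expect_setequal(names(ff@types), c("CX", "OX"))
  # GB radii filled from the element table
  expect_equal(ff@types$CX$gb_radius, 1.70)
  expect_equal(ff@types$OX$gb_radius, 1.50)
  expect_equal(ff@globals$eps_out, 78.5)
  # schema errors name the offender
  writeLines('{"types": {"CX": {"charge": 0.1, "eps": 0.1, "mass": 12}}}', tmp)
  expect_error(loadForcefield(tmp), "CX.*rmin2")
  writeLines('{"types": {"CX": {"charge": 0.1, "eps": 0.1, "rmin2": -2,
    "mass": 12, "element": "C"}}}', tmp)
  expect_error(loadForcefield(tmp), "non-positive radius")
  # the synthetic generator's emitted block reloads and parameterizes
  cx <- makeSyntheticComplex(19, 6, 3)
  writeForcefield(syntheticForcefield(cx), tmp)
  ff2 <- loadForcefield(tmp)
  sys <- parameterizeSystem(cx, ff2)
  expect_equal(nrow(sys@atoms), 15L)
  expect_true(all(is.finite(sys@atoms$charge)))
})

test_that("MM terms hit their closed-form landmarks", {
  t <- tinySystem()
  # bonds at their generated rest lengths contribute zero
  expect_equal(unname(mmEnergy(t$sys, t$x)["bond"]), 0, tolerance = 1e-12)
  expect_equal(unname(mmEnergy(t$sys, t$x)["angle"]), 0, tolerance = 1e-12)
  # two unit charges at 3.320636 A with eps_in = 1: E = 332.0636 / 3.320636
  ff <- new("ForceFieldSpec",
            types = list(QX = list(charge = 1, eps = 0, rmin2 = 1.9,
                                   mass = 12, gb_radius = 1.7,
                                   gb_screen = 0.72, lcpo = c(1, 0, 0, 0),
                                   lcpo_radius = 1.7)),
            globals = offtargetr:::.defaultGlobals(),
            atomTypes = c(CA = "QX", L1 = "QX"),
            topology = list(bonds = matrix(numeric(0), 0, 4),
                            angles = matrix(numeric(0), 0, 5),
                            torsions = matrix(numeric(0), 0, 7)))
  rec <- structureFromRows(atomRow(1L, "CA", "C", "A", 1L, "ALA", "protein",
                                   0, 0, 0))
  lig <- structureFromRows(atomRow(2L, "L1", "C", "L", 1L, "LIG", "hetero",
                                   3.320636, 0, 0))
  sys2 <- parameterizeSystem(new("ComplexModel", receptor = rec,
                                 ligand = lig), ff)
  e <- mmEnergy(sys2, rbind(c(0, 0, 0), c(3.320636, 0, 0)))
  expect_equal(unname(e["elec"]), 100.0, tolerance = 1e-9)
  # LJ minimum at r = rmin is -eps
  ff@types$QX$charge <- 0; ff@types$QX$eps <- 0.3
  sys3 <- parameterizeSystem(new("ComplexModel", receptor = rec,
                                 ligand = lig), ff)
  e3 <- mmEnergy(sys3, rbind(c(0, 0, 0), c(2 * 1.9, 0, 0)))
  expect_equal(unname(e3["vdw"]), -0.3, tolerance = 1e-12)
  expect_error(mmEnergy(t$sys, t$x[-1, ]), "mismatch")
})

test_that("the analytic gradient matches central finite differences", {
  t <- tinySystem(seed = 23, nres = 6, nlig = 3)
  set.seed(4)
  x <- t$x + matrix(rnorm(length(t$x), 0, 0.08), ncol = 3)
  g <- mmGradient(t$sys, x)
  h <- 1e-6
  for (pick in list(c(1, 1), c(5, 2), c(9, 3), c(13, 1), c(15, 3))) {
    xp <- x; xp[pick[1], pick[2]] <- xp[pick[1], pick[2]] + h
    xm <- x; xm[pick[1], pick[2]] <- xm[pick[1], pick[2]] - h
    num <- (sum(mmEnergy(t$sys, xp)) - sum(mmEnergy(t$sys, xm))) / (2 * h)
    expect_equal(g[pick[1], pick[2]], num, tolerance = 1e-5)
  }
})

test_that("all energy terms are invariant under rigid motion", {
  t <- tinySystem(seed = 29, nres = 6, nlig = 3)
  set.seed(5)
  R <- randomRotation()
  x2 <- sweep(t$x %*% t(R), 2, c(14, -3, 8), "+")
  expect_equal(sum(mmEnergy(t$sys, t$x)), sum(mmEnergy(t$sys, x2)),
               tolerance = 1e-6)
  expect_equal(gbPolarEnergy(t$sys, t$x), gbPolarEnergy(t$sys, x2),
               tolerance = 1e-6)
  expect_equal(sasaLCPO(t$sys, t$x)$total, sasaLCPO(t$sys, x2)$total,
               tolerance = 1e-6)
})

test_that("generalized Born reduces to the Born ion and its far-field sum", {
  t <- tinySystem(seed = 3, nres = 4, nlig = 1)
  ion <- subsetSystem(t$sys, nrow(t$sys@atoms))
  ion@atoms$charge <- 1
  # forced effective radius 2.0 A: the Born closed form
  born <- -(332.0636 / 2) * (1 - 1 / 78.5) / 2.0
  expect_equal(gbPolarEnergy(ion, matrix(0, 1, 3), effectiveRadii = 2.0),
               born, tolerance = 1e-6 * abs(born))
  # isolated-atom limit of the OBC radii: alpha = rho - offset
  expect_equal(effectiveBornRadii(ion, matrix(0, 1, 3)),
               ion@atoms$gb_radius - 0.09, tolerance = 1e-12)
  # zero charges give zero polar energy
  neutral <- ion; neutral@atoms$charge <- 0
  expect_equal(gbPolarEnergy(neutral, matrix(0, 1, 3)), 0)
  # far-field limit: at 400 A the pair decouples into isolated Born ions to
  # within 1%; at 100 A the residual equals the analytic screened-Coulomb
  # cross term -(1 - 1/eps_out) k q1 q2 / r
  two <- subsetSystem(t$sys, nrow(t$sys@atoms) - c(1, 0))
  two@atoms$charge <- c(1, 1)
  isolated <- sum(vapply(1:2, function(i)
    gbPolarEnergy(subsetSystem(two, i), matrix(0, 1, 3)), numeric(1)))
  far <- gbPolarEnergy(two, rbind(c(0, 0, 0), c(400, 0, 0)))
  expect_lt(abs(far - isolated), 0.01 * abs(isolated))
  mid <- gbPolarEnergy(two, rbind(c(0, 0, 0), c(100, 0, 0)))
  cross <- -(1 - 1 / 78.5) * 332.0636 / 100
  expect_equal(mid - isolated, cross, tolerance = 1e-4)
  # single-charge systems always solvate favourably
  expect_lt(gbPolarEnergy(ion, matrix(0, 1, 3)), 0)
})

test_that("LCPO surface area is exact for isolated atoms and near MC otherwise", {
  t <- tinySystem(seed = 3, nres = 4, nlig = 1)
  one <- subsetSystem(t$sys, nrow(t$sys@atoms))
  one@atoms$p1 <- 1; one@atoms$p2 <- 0; one@atoms$p3 <- 0; one@atoms$p4 <- 0
  R <- one@atoms$lcpo_radius + 1.4
  s <- sasaLCPO(one, matrix(0, 1, 3))
  expect_equal(s$total, 4 * pi * R^2, tolerance = 1e-10)
  expect_equal(s$g_sa, 0.0072 * s$total, tolerance = 1e-12)
  # a caged atom clamps at zero rather than going negative
  cage <- rbind(c(0, 0, 0), 2.0 * rbind(diag(3), -diag(3)))
  sysCage <- do.call(rbind, rep(list(one@atoms), 7))
  cageSys <- one
  cageSys@atoms <- sysCage
  cageSys@excl <- rep(list(integer(0)), 7)
  buried <- sasaLCPO(cageSys, cage)
  expect_gte(min(buried$per_atom), 0)
  # randomized clusters against the Monte-Carlo oracle (subset; the full
  # 100-cluster sweep runs in the acceptance suite)
  set.seed(6)
  relErr <- replicate(15, {
    centers <- randomSphereCluster(sample(2:20, 1))
    sys <- sphereClusterSystem(centers)
    lcpo <- sasaLCPO(sys, centers)$total
    mc <- mcSASA(centers, rep(1.7 + 1.4, nrow(centers)), nPoints = 4000L)
    abs(lcpo - mc) / mc
  })
  expect_lt(max(relErr), 0.05)
})

test_that("staged minimization descends and respects restraint fixtures", {
  # an exact minimum stays put
  t <- tinySystem(seed = 31, nres = 5, nlig = 2)
  # strip nonbonded terms so the generated geometry is an exact minimum
  sysH <- t$sys
  sysH@atoms$eps <- 0; sysH@atoms$charge <- 0
  sysH@torsions <- sysH@torsions[0, , drop = FALSE]
  xm <- stagedMinimization(sysH, t$x, tol = 1e-6)
  expect_lt(max(abs(xm - t$x)), 1e-6)
  # energy after the final stage never exceeds the first executed stage
  for (k in 1:5) {
    tt <- tinySystem(seed = 200 + k, nres = 5, nlig = 2)
    set.seed(k)
    x0 <- tt$x + matrix(rnorm(length(tt$x), 0, 0.05), ncol = 3)
    xk <- stagedMinimization(tt$sys, x0, maxit = 150L)
    es <- attr(xk, "stage_energies")
    expect_lte(es[length(es)], es[1] + 1e-9)
  }
  # a displaced restrained atom in a flat potential stays at its reference
  flat <- t$sys
  flat@atoms$eps <- 0; flat@atoms$charge <- 0
  flat@bonds <- flat@bonds[0, , drop = FALSE]
  flat@angles <- flat@angles[0, , drop = FALSE]
  flat@torsions <- flat@torsions[0, , drop = FALSE]
  xf <- stagedMinimization(flat, t$x)
  expect_lt(max(abs(xf - t$x)), 1e-6)
})

test_that("vibrational entropy matches the closed-form oscillator", {
  # one particle in an isotropic harmonic well k|x|^2: three modes at
  # omega = sqrt(2k/m)
  t <- tinySystem(seed = 3, nres = 4, nlig = 1)
  one <- subsetSystem(t$sys, nrow(t$sys@atoms))
  one@atoms$eps <- 0; one@atoms$charge <- 0
  k <- 25; m <- one@atoms$mass
  ts <- normalModeEntropy(one, matrix(0, 1, 3), restraintK = k,
                          restraintRef = matrix(0, 1, 3))
  conv <- 4184 / 6.02214076e23 * 1e20 / 1.66053906660e-27
  omega <- sqrt(2 * k / m * conv)
  hbar <- 6.62607015e-34 / (2 * pi); kB <- 1.380649e-23
  u <- hbar * omega / (kB * 298)
  sPerMode <- 1.987204259e-3 * (u / expm1(u) - log(-expm1(-u)))
  expect_equal(unname(ts["ts_vib"]), 298 * 3 * sPerMode,
               tolerance = 1e-6 * abs(298 * 3 * sPerMode))
  # translational entropy grows with temperature
  t1 <- normalModeEntropy(one, matrix(0, 1, 3), temperature = 298,
                          restraintK = k, restraintRef = matrix(0, 1, 3))
  t2 <- normalModeEntropy(one, matrix(0, 1, 3), temperature = 596,
                          restraintK = k, restraintRef = matrix(0, 1, 3))
  expect_gt(t2["ts_trans"] / 596, t1["ts_trans"] / 298)
  # rigid translation leaves all terms unchanged
  tt <- tinySystem(seed = 37, nres = 4, nlig = 2)
  sysH <- tt$sys
  sysH@atoms$eps <- 0; sysH@atoms$charge <- 0
  sysH@torsions <- sysH@torsions[0, , drop = FALSE]
  a <- normalModeEntropy(sysH, tt$x, gradTol = 1e-4)
  b <- normalModeEntropy(sysH, sweep(tt$x, 2, c(30, -20, 10), "+"),
                         gradTol = 1e-4)
  expect_equal(a, b, tolerance = 1e-8)
  # unminimized coordinates are refused
  set.seed(8)
  bent <- tt$x + matrix(rnorm(length(tt$x), 0, 0.3), ncol = 3)
  expect_error(normalModeEntropy(sysH, bent, gradTol = 1e-4),
               "not at a minimum")
})

test_that("single-snapshot MM/GBSA slices subsystems consistently", {
  t <- tinySystem(seed = 41, nres = 6, nlig = 3)
  b <- snapshotMMGBSA(t$sys, t$x)
  # entropy skipped: G_total is exactly E_MM + G_GB + G_SA and flagged
  expect_false(b$complex@entropyComputed)
  expect_equal(gTotal(b$complex), eMM(b$complex) + b$complex@gb + b$complex@sa)
  # single-trajectory slicing: receptor-internal gas-phase terms agree
  recIdx <- subsystemIndices(t$sys, "receptor")
  recSys <- subsetSystem(t$sys, recIdx)
  eRecOnly <- mmEnergy(recSys, t$x[recIdx, ])
  expect_equal(unname(eRecOnly["bond"]), b$receptor@bond)
  expect_equal(unname(eRecOnly["angle"]), b$receptor@angle)
  expect_equal(unname(eRecOnly["torsion"]), b$receptor@torsion)
  # an all-receptor system has no ligand to bind
  expect_error(snapshotMMGBSA(subsetSystem(t$sys, recIdx), t$x[recIdx, ]),
               "ligand mask")
})

test_that("ensemble averaging is exact arithmetic over snapshots", {
  t <- tinySystem(seed = 43, nres = 6, nlig = 3)
  same <- perturbEnsemble(t$cx, 4, 0, 0, 1)
  bfe <- ensembleBindingFreeEnergy(t$sys, same)
  one <- snapshotMMGBSA(t$sys, t$x)
  d <- function(f) f(one$complex) - f(one$receptor) - f(one$ligand)
  s <- bindingSummary(bfe)
  expect_equal(s$dH, d(eMM) + d(function(z) z@gb) + d(function(z) z@sa),
               tolerance = 1e-9)
  expect_equal(s$se_dG, 0)
  expect_equal(s$dG, s$dH - s$dTS, tolerance = 1e-12)
  # two distinct snapshots: dH is their arithmetic mean
  two <- perturbEnsemble(t$cx, 2, 0.1, 0, 7)
  b2 <- ensembleBindingFreeEnergy(t$sys, two)
  per <- perSnapshotEnergies(b2)
  expect_equal(bindingSummary(b2)$dH, mean(per$dH), tolerance = 1e-12)
  expect_error(ensembleBindingFreeEnergy(t$sys,
                                         perturbEnsemble(tinySystem(1, 5, 2)$cx,
                                                         2, 0, 0, 1)),
               "does not match")
})

test_that("free-energy bookkeeping reproduces published-style rows", {
  expect_equal(assembleDeltaG(-34.73, -14.16), -20.57, tolerance = 1e-12)
  expect_equal(assembleDeltaG(-52.68, -10.10), -42.58, tolerance = 1e-12)
  expect_equal(assembleDeltaG(-41.50, -26.70), -14.80, tolerance = 1e-12)
  expect_equal(assembleDeltaG(0, 0), 0)
  expect_error(assembleDeltaG(NA_real_, 0))
})

test_that("the consistency checker isolates the inconsistent table rows", {
  tab <- readEnergyTable()
  expect_equal(nrow(tab), 20L)
  chk <- checkTableConsistency(tab)
  flagged <- chk[!chk$consistent, ]
  expect_equal(sort(unique(flagged$target)), "AKT2")
  expect_equal(nrow(flagged), 2L)
  # two-decimal rounding drift is tolerated on the remaining rows
  ok <- chk[chk$consistent, ]
  expect_lte(max(abs(ok$residual)), 0.01)
})

test_that("stability diagnostics flag pocket exit but pass quiet ensembles", {
  cx <- makeSyntheticComplex(51, 12, 5)
  quiet <- superposeToFirst(perturbEnsemble(cx, 10, 0, 0, 1), "CA")
  sQuiet <- stabilityCheck(quiet, "CA")
  expect_equal(sQuiet$receptor_flag, "PASS")
  expect_equal(sQuiet$ligand_flag, "OK")
  drift <- superposeToFirst(perturbEnsemble(cx, 20, 0.05, 0.5, 2), "CA")
  sDrift <- stabilityCheck(drift, "CA")
  expect_equal(sDrift$ligand_flag, "POCKET_EXIT")
  for (sd in 1:5) {
    noisy <- superposeToFirst(perturbEnsemble(cx, 10, 0.5, 0, 10 + sd), "CA")
    sn <- stabilityCheck(noisy, "CA")
    expect_equal(sn$receptor_flag, "PASS")
    expect_lt(sn$max_backbone_rmsd, 3)
  }
  # an ensemble with un-fitted rigid motion is rejected
  raw <- perturbEnsemble(cx, 3, 0.05, 0, 3)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  raw@coords[[3]] <- sweep(raw@coords[[3]] %*% t(R), 2, c(6, 0, 0), "+")
  expect_error(stabilityCheck(raw, "CA"), "not aligned")
})
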