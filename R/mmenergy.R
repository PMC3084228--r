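# Gas-phase molecular-mechanics energy and analytic gradient (vectorized).
#
# Harmonic bonds/angles, cosine torsions, LJ 12-6 and Coulomb (eps = eps_in)
# over non-excluded pairs with no distance cutoff; 1-4 pairs scaled by the
# configurable factors (defaults 0.5 vdW, 1/1.2 electrostatics).

.nbPairs <- function(sys) {
  n <- nrow(sys@atoms)
  if (n < 2L) return(list(full = matrix(numeric(0), 0, 2), p14 = sys@pairs14))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  exKey <- unlist(lapply(seq_len(n), function(i) {
    ex <- sys@excl[[i]]; ex <- ex[ex > i]
    if (length(ex)) (i - 1) * n + ex else numeric(0)
  }))
  k14 <- if (nrow(sys@pairs14))
    (pmin(sys@pairs14[, 1], sys@pairs14[, 2]) - 1) * n +
    pmax(sys@pairs14[, 1], sys@pairs14[, 2]) else numeric(0)
  key <- (idx[, 1] - 1) * n + idx[, 2]
  keep <- !(key %in% c(exKey, k14))
  list(full = idx[keep, , drop = FALSE], p14 = sys@pairs14)
}

.sysNB <- function(sys) {
  key <- paste("nb", nrow(sys@atoms),
               paste(vapply(seq_along(sys@excl), function(i)
                 paste0(i, ":", paste(sys@excl[[i]], collapse = ",")),
                 character(1)), collapse = ";"),
               paste(sys@pairs14, collapse = ","), sep = "|")
  cached <- .pkgCache[[key]]
  if (!is.null(cached)) return(cached)
  nb <- .nbPairs(sys)
  .pkgCache[[key]] <- nb
  nb
}

.rowcross <- function(a, b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])

.torsionPhi <- function(x, t) {
  b1 <- x[t[, 2], , drop = FALSE] - x[t[, 1], , drop = FALSE]
  b2 <- x[t[, 3], , drop = FALSE] - x[t[, 2], , drop = FALSE]
  b3 <- x[t[, 4], , drop = FALSE] - x[t[, 3], , drop = FALSE]
  m <- .rowcross(b1, b2)
  nn <- .rowcross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  phi <- atan2(rowSums(.rowcross(m, nn) * b2) / nb2, rowSums(m * nn))
  list(b1 = b1, b2 = b2, b3 = b3, m = m, n = nn, nb2 = nb2, phi = phi)
}

.angleTheta <- function(x, t) {
  u <- x[t[, 1], , drop = FALSE] - x[t[, 2], , drop = FALSE]
  v <- x[t[, 3], , drop = FALSE] - x[t[, 2], , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  ct <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  list(u = u, v = v, nu = nu, nv = nv, ct = ct, theta = acos(ct))
}

.pairEnergies <- function(sys, x, pairs, scaleV = 1, scaleE = 1) {
  if (!nrow(pairs)) return(c(vdw = 0, elec = 0))
  a <- sys@atoms
  d <- sqrt(rowSums((x[pairs[, 1], , drop = FALSE] -
                       x[pairs[, 2], , drop = FALSE])^2))
  rmin <- a$rmin2[pairs[, 1]] + a$rmin2[pairs[, 2]]
  epsij <- sqrt(a$eps[pairs[, 1]] * a$eps[pairs[, 2]])
  sr6 <- (rmin / d)^6
  c(vdw = scaleV * sum(epsij * (sr6^2 - 2 * sr6)),
    elec = scaleE * sum(sys@globals$coulomb * a$charge[pairs[, 1]] *
                          a$charge[pairs[, 2]] / (sys@globals$eps_in * d)))
}

#' Gas-phase MM energy terms
#'
#' @param sys ParameterizedSystem.
#' @param coords n x 3 coordinate matrix matching the topology.
#' @return named numeric: bond, angle, torsion, vdw, elec (kcal/mol).
#' @export
mmEnergy <- function(sys, coords) {
  x <- as.matrix(coords)
  if (nrow(x) != nrow(sys@atoms) || ncol(x) != 3L)
    stop("coordinate/topology mismatch: expected ", nrow(sys@atoms), " x 3")
  eb <- 0
  if (nrow(sys@bonds)) {
    d <- sqrt(rowSums((x[sys@bonds[, 1], , drop = FALSE] -
                         x[sys@bonds[, 2], , drop = FALSE])^2))
    eb <- sum(sys@bonds[, 3] * (d - sys@bonds[, 4])^2)
  }
  ea <- 0
  if (nrow(sys@angles)) {
    ag <- .angleTheta(x, sys@angles)
    ea <- sum(sys@angles[, 4] * (ag$theta - sys@angles[, 5])^2)
  }
  et <- 0
  if (nrow(sys@torsions)) {
    tg <- .torsionPhi(x, sys@torsions)
    et <- sum(sys@torsions[, 5] *
                (1 + cos(sys@torsions[, 6] * tg$phi - sys@torsions[, 7])))
  }
  nb <- .sysNB(sys)
  e1 <- .pairEnergies(sys, x, nb$full)
  e4 <- .pairEnergies(sys, x, nb$p14, sys@globals$scale14_vdw,
                      sys@globals$scale14_elec)
  c(bond = eb, angle = ea, torsion = et,
    vdw = unname(e1["vdw"] + e4["vdw"]),
    elec = unname(e1["elec"] + e4["elec"]))
}

.accumulate <- function(g, idx, contrib) {
  acc <- rowsum(contrib, idx)
  rows <- as.integer(rownames(acc))
  g[rows, ] <- g[rows, , drop = FALSE] + acc
  g
}

.pairGradient <- function(sys, x, g, pairs, scaleV = 1, scaleE = 1) {
  if (!nrow(pairs)) return(g)
  a <- sys@atoms
  dx <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  rmin <- a$rmin2[pairs[, 1]] + a$rmin2[pairs[, 2]]
  epsij <- sqrt(a$eps[pairs[, 1]] * a$eps[pairs[, 2]])
  sr6 <- (rmin / d)^6
  dEdr <- scaleV * epsij * 12 * (sr6 - sr6^2) / d -
    scaleE * sys@globals$coulomb * a$charge[pairs[, 1]] *
    a$charge[pairs[, 2]] / (sys@globals$eps_in * d^2)
  f <- dx * (dEdr / d)
  .accumulate(g, c(pairs[, 1], pairs[, 2]), rbind(f, -f))
}

#' Analytic gradient of the gas-phase MM energy
#'
#' @param sys ParameterizedSystem.
#' @param coords n x 3 matrix.
#' @return n x 3 gradient matrix, kcal/mol/Angstrom.
#' @export
mmGradient <- function(sys, coords) {
  x <- as.matrix(coords)
  n <- nrow(x)
  g <- matrix(0, n, 3)
  if (nrow(sys@bonds)) {
    t <- sys@bonds
    dx <- x[t[, 1], , drop = FALSE] - x[t[, 2], , drop = FALSE]
    d <- sqrt(rowSums(dx^2))
    f <- dx * (2 * t[, 3] * (d - t[, 4]) / d)
    g <- .accumulate(g, c(t[, 1], t[, 2]), rbind(f, -f))
  }
  if (nrow(sys@angles)) {
    t <- sys@angles
    ag <- .angleTheta(x, t)
    st <- sqrt(pmax(1 - ag$ct^2, 1e-12))
    dEdth <- 2 * t[, 4] * (ag$theta - t[, 5])
    dthdu <- -(ag$v / (ag$nu * ag$nv) - ag$ct * ag$u / ag$nu^2) / st
    dthdv <- -(ag$u / (ag$nu * ag$nv) - ag$ct * ag$v / ag$nv^2) / st
    g <- .accumulate(g, c(t[, 1], t[, 3], t[, 2]),
                     rbind(dEdth * dthdu, dEdth * dthdv,
                           -dEdth * (dthdu + dthdv)))
  }
  if (nrow(sys@torsions)) {
    t <- sys@torsions
    tg <- .torsionPhi(x, t)
    dEdphi <- -t[, 5] * t[, 6] * sin(t[, 6] * tg$phi - t[, 7])
    m2 <- pmax(rowSums(tg$m^2), 1e-12)
    n2 <- pmax(rowSums(tg$n^2), 1e-12)
    dphi_i <- -tg$m * (tg$nb2 / m2)
    dphi_l <- tg$n * (tg$nb2 / n2)
    s1 <- rowSums(tg$b1 * tg$b2) / tg$nb2^2
    s2 <- rowSums(tg$b3 * tg$b2) / tg$nb2^2
    dphi_j <- -(1 + s1) * dphi_i + s2 * dphi_l
    dphi_k <- s1 * dphi_i - (1 + s2) * dphi_l
    g <- .accumulate(g, c(t[, 1], t[, 2], t[, 3], t[, 4]),
                     rbind(dEdphi * dphi_i, dEdphi * dphi_j,
                           dEdphi * dphi_k, dEdphi * dphi_l))
  }
  nb <- .sysNB(sys)
  g <- .pairGradient(sys, x, g, nb$full)
  .pairGradient(sys, x, g, nb$p14, sys@globals$scale14_vdw,
                sys@globals$scale14_elec)
}
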