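# Normal-mode entropy: translational (Sackur-Tetrode), rigid-rotor
# rotational, and quantum-harmonic-oscillator vibrational terms from a
# mass-weighted finite-difference Hessian of the gas-phase MM gradient.

.KB <- 1.380649e-23       # J/K
.H_PLANCK <- 6.62607015e-34
.AMU <- 1.66053906660e-27 # kg
.R_KCAL <- 1.987204259e-3 # kcal/mol/K
.PRESSURE <- 101325       # Pa (1 atm standard state)
# kcal/mol/A^2/amu -> s^-2
.FREQ_CONV <- 4184 / 6.02214076e23 * 1e20 / .AMU

.numHessian <- function(gradFn, x, step = 1e-4) {
  n3 <- length(x)
  H <- matrix(0, n3, n3)
  xv <- as.vector(x)
  for (k in seq_len(n3)) {
    xp <- xv; xp[k] <- xp[k] + step
    xm <- xv; xm[k] <- xm[k] - step
    H[, k] <- (gradFn(xp) - gradFn(xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

.externalModes <- function(coords, mass) {
  n <- nrow(coords)
  sm <- sqrt(mass)
  V <- list()
  for (d in 1:3) {
    v <- matrix(0, n, 3); v[, d] <- sm
    V[[length(V) + 1L]] <- as.vector(t(v))
  }
  com <- colSums(coords * mass) / sum(mass)
  xc <- sweep(coords, 2, com)
  for (d in 1:3) {
    axis <- numeric(3); axis[d] <- 1
    rot <- t(vapply(seq_len(n), function(i)
      sm[i] * c(axis[2] * xc[i, 3] - axis[3] * xc[i, 2],
                axis[3] * xc[i, 1] - axis[1] * xc[i, 3],
                axis[1] * xc[i, 2] - axis[2] * xc[i, 1]), numeric(3)))
    V[[length(V) + 1L]] <- as.vector(t(rot))
  }
  M <- do.call(cbind, V)
  qrM <- qr(M)
  qr.Q(qrM)[, seq_len(qrM$rank), drop = FALSE]
}

.qhoEntropy <- function(omega, temp) {
  # omega rad/s -> molar entropy, kcal/mol/K
  theta <- .H_PLANCK / (2 * pi) * omega / .KB
  u <- theta / temp
  .R_KCAL * sum(u / expm1(u) - log(-expm1(-u)))
}

#' Normal-mode entropy of a minimized state
#'
#' Builds the mass-weighted Hessian by central finite differences of the
#' gas-phase MM gradient (step 1e-4 Angstrom), projects out the external
#' translation/rotation modes, and evaluates the quantum harmonic-oscillator
#' vibrational entropy per mode; translational entropy comes from
#' Sackur-Tetrode at 1 atm and rotational entropy from the rigid rotor via
#' the inertia tensor. Residual negative eigenvalues beyond the external
#' modes are dropped with a warning.
#'
#' @param sys ParameterizedSystem.
#' @param coords n x 3 coordinates at a local minimum (RMS gradient component
#'   no larger than \code{gradTol}); run \code{\link{stagedMinimization}}
#'   first.
#' @param temperature Kelvin; defaults to the force-field global (298).
#' @param gradTol not-minimized tolerance, kcal/mol/A (default 0.1).
#' @param step finite-difference step, Angstrom.
#' @param restraintK,restraintRef optional isotropic harmonic restraint added
#'   to the potential (used e.g. for single-well oscillator checks); with a
#'   restraint no external modes are projected out.
#' @return named numeric: \code{ts_trans, ts_rot, ts_vib} as T*S in kcal/mol.
#' @export
normalModeEntropy <- function(sys, coords, temperature = NULL, gradTol = 0.1,
                              step = 1e-4, restraintK = NULL,
                              restraintRef = NULL) {
  x <- as.matrix(coords)
  n <- nrow(x)
  temp <- temperature %||% sys@globals$temperature
  mass <- sys@atoms$mass
  gradFn <- function(xv) {
    xm <- matrix(xv, ncol = 3, byrow = TRUE)
    g <- mmGradient(sys, xm)
    if (!is.null(restraintK))
      g <- g + 2 * restraintK * (xm - restraintRef)
    as.vector(t(g))
  }
  g0 <- gradFn(as.vector(t(x)))
  if (sqrt(mean(g0^2)) > gradTol)
    stop(sprintf("coordinates are not at a minimum (RMS gradient %.4f > %.4f)",
                 sqrt(mean(g0^2)), gradTol))
  H <- .numHessian(gradFn, as.vector(t(x)), step)
  sm <- rep(sqrt(mass), each = 3L)
  Hmw <- H / outer(sm, sm)
  nExternal <- 0L
  if (is.null(restraintK) && n > 1L) {
    P <- .externalModes(x, mass)
    nExternal <- ncol(P)
    Hmw <- Hmw - P %*% crossprod(P, Hmw)
    Hmw <- Hmw - (Hmw %*% P) %*% t(P)
    Hmw <- (Hmw + t(Hmw)) / 2
  } else if (is.null(restraintK) && n == 1L) {
    # a single free atom has no internal modes
    sTrans <- .sackurTetrode(sum(mass), temp)
    return(c(ts_trans = temp * sTrans, ts_rot = 0, ts_vib = 0))
  }
  ev <- eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values
  ord <- order(abs(ev))
  internal <- sort(ev[ord[seq.int(nExternal + 1L, length(ev))]],
                   decreasing = TRUE)
  neg <- internal < -1e-6
  if (any(neg)) {
    warning(sprintf("dropping %d negative eigenvalue(s) beyond the external modes",
                    sum(neg)))
    internal <- internal[!neg]
  }
  # eigenvalues below ~1e-6 kcal/mol/A^2/amu (~0.2 cm^-1) are residual
  # external or free-rotor modes; the harmonic-oscillator entropy diverges
  # there, so they are excluded rather than propagated
  internal <- internal[internal > 1e-6]
  omega <- sqrt(internal * .FREQ_CONV)
  tsVib <- temp * .qhoEntropy(omega, temp)
  tsTrans <- temp * .sackurTetrode(sum(mass), temp)
  tsRot <- temp * .rigidRotorEntropy(x, mass, temp)
  c(ts_trans = tsTrans, ts_rot = tsRot, ts_vib = tsVib)
}

.sackurTetrode <- function(totalMassAmu, temp) {
  m <- totalMassAmu * .AMU
  lam <- (2 * pi * m * .KB * temp / .H_PLANCK^2)^1.5
  .R_KCAL * (log(lam * .KB * temp / .PRESSURE) + 2.5)
}

.rigidRotorEntropy <- function(coords, mass, temp, sigma = 1) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  com <- colSums(coords * mass) / sum(mass)
  xc <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    r <- xc[i, ]
    I <- I + mass[i] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  mom <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values) *
    .AMU * 1e-20  # amu A^2 -> kg m^2
  pref <- 8 * pi^2 * .KB * temp / .H_PLANCK^2
  if (mom[1] < 1e-50 * max(mom[3], 1e-40)) {
    # linear rotor
    if (mom[3] <= 0) return(0)
    .R_KCAL * (log(pref * mom[3] / sigma) + 1)
  } else {
    .R_KCAL * (log(sqrt(pi) / sigma * pref^1.5 * sqrt(prod(mom))) + 1.5)
  }
}
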