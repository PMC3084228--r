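# Five-stage restrained conjugate-gradient minimization.

.objectiveFactory <- function(sys, baseCoords, freeIdx, restraintIdx,
                              restraintK, restraintRef) {
  n <- nrow(baseCoords)
  frozenMask <- rep(TRUE, n); frozenMask[freeIdx] <- FALSE
  assemble <- function(par) {
    x <- baseCoords
    x[freeIdx, ] <- matrix(par, ncol = 3)
    x
  }
  fn <- function(par) {
    x <- assemble(par)
    e <- sum(mmEnergy(sys, x))
    if (length(restraintIdx))
      e <- e + restraintK * sum((x[restraintIdx, , drop = FALSE] -
                                   restraintRef[restraintIdx, , drop = FALSE])^2)
    e
  }
  gr <- function(par) {
    x <- assemble(par)
    g <- mmGradient(sys, x)
    if (length(restraintIdx))
      g[restraintIdx, ] <- g[restraintIdx, ] +
        2 * restraintK * (x[restraintIdx, , drop = FALSE] -
                            restraintRef[restraintIdx, , drop = FALSE])
    as.vector(g[freeIdx, , drop = FALSE])
  }
  list(fn = fn, gr = gr, assemble = assemble)
}

#' Five-stage restrained minimization
#'
#' Conjugate-gradient minimization with progressively released position
#' restraints: (1) hydrogens only free, (2) plus waters (skipped when there
#' are none), (3) plus side chains, (4) all atoms free with harmonic
#' restraints of \code{restraintK} on protein backbone and ligand atoms,
#' (5) fully unrestrained. Stages whose free set adds nothing are skipped.
#' Errors out if a stage ends with a higher objective than it started
#' (divergence).
#'
#' @param sys ParameterizedSystem.
#' @param coords n x 3 starting coordinates.
#' @param restraintK restraint force constant, kcal/mol/A^2 (default 4.0).
#' @param tol gradient-norm (RMS per component) convergence tolerance,
#'   kcal/mol/A (default 0.1); also the divergence tolerance.
#' @param maxit CG iteration cap per stage.
#' @return minimized n x 3 coordinates with attribute \code{stage_energies}
#'   (total MM energy after each executed stage).
#' @export
stagedMinimization <- function(sys, coords, restraintK = 4.0, tol = 0.1,
                               maxit = 500L) {
  x <- as.matrix(coords)
  a <- sys@atoms
  isWater <- a$resname %in% c("HOH", "WAT")
  hIdx <- which(a$is_h)
  scIdx <- which(a$role == "sidechain" & !a$is_h & !isWater)
  bbLig <- which(a$role %in% c("backbone", "ligand") & !a$is_h)
  allIdx <- seq_len(nrow(a))
  stages <- list(
    list(free = hIdx, restr = integer(0)),
    list(free = sort(c(hIdx, which(isWater))), restr = integer(0)),
    list(free = sort(c(hIdx, which(isWater), scIdx)), restr = integer(0)),
    list(free = allIdx, restr = bbLig),
    list(free = allIdx, restr = integer(0)))
  e0 <- sum(mmEnergy(sys, x))
  if (!is.finite(e0)) stop("non-finite starting energy")
  stageE <- numeric(0)
  prevFree <- integer(0)
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    if (!length(st$free) ||
        (s < 4L && length(st$free) == length(prevFree))) next
    prevFree <- st$free
    obj <- .objectiveFactory(sys, x, st$free, st$restr, restraintK, x)
    par0 <- as.vector(x[st$free, , drop = FALSE])
    f0 <- obj$fn(par0)
    fit <- stats::optim(par0, obj$fn, obj$gr, method = "CG",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (fit$value > f0 + tol)
      stop(sprintf("minimization diverged in stage %d (%.3f -> %.3f)",
                   s, f0, fit$value))
    if (fit$value <= f0) x <- obj$assemble(fit$par)
    stageE <- c(stageE, sum(mmEnergy(sys, x)))
  }
  attr(x, "stage_energies") <- stageE
  x
}
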