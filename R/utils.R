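# shared numeric helpers

.pairdist <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m Euclidean distances
  n <- nrow(a); m <- nrow(b)
  d2 <- outer(rowSums(a^2), rep(1, m)) + outer(rep(1, n), rowSums(b^2)) -
    2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping point set \code{Q} onto
#' \code{P}, minimizing the RMSD over corresponding rows.
#'
#' @param P,Q n x 3 matrices of corresponding points (n >= 3, not all
#'   collinear).
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3; the map is \code{Q \%*\% t(R) + t}) and the minimized
#'   \code{rmsd}.
#' @export
superposePoints <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be matching n x 3 matrices")
  if (nrow(P) < 3L) stop("degenerate fit: at least 3 point pairs required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity check on both sets
  if (min(svd(Pc)$d[2], svd(Qc)$d[2]) < 1e-8 * max(1, max(abs(Pc)), max(abs(Qc))))
    stop("degenerate fit: points are collinear")
  H <- crossprod(Qc, Pc)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cp - as.vector(R %*% cq)
  Qfit <- tcrossprod(Qc, R)
  rmsd <- .rmsd(Pc, Qfit)
  list(rotation = R, translation = t, rmsd = rmsd)
}

.applyTransform <- function(X, rotation, translation)
  sweep(tcrossprod(as.matrix(X), rotation), 2, translation, "+")

.heavyIdx <- function(atoms) which(toupper(atoms$element) != "H")

.writeTSV <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.readTSV <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
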