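# Sequence-order-independent binding-site alignment and extreme-value
# significance.
#
# Alignment is posed on a correspondence graph: vertices are residue pairs
# (i in A, j in B) whose chemical/GP similarity clears w_min; edges join
# geometrically consistent vertices (|d_A(i,i') - d_B(j,j')| <= eps). The
# best alignment is the maximum-weight clique — exact branch-and-bound for
# small graphs, greedy seed-and-extend with best-of-k restarts otherwise.

.pkgCache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkgCache$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$blosum <- e$BLOSUM62
  }
  .pkgCache$blosum
}

.AA31 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")

.aa1 <- function(res3) {
  one <- .AA31[toupper(res3)]
  if (anyNA(one))
    stop("unknown residue code(s): ",
         paste(unique(res3[is.na(one)]), collapse = ", "))
  one
}

#' Default alignment parameters
#'
#' @param wMin minimum pair weight for a correspondence vertex.
#' @param eps geometric consistency tolerance, Angstrom.
#' @param exactLimit maximum correspondence-graph size for the exact solver.
#' @param restarts greedy restarts (best-of-k) above the exact limit.
#' @param lambda weight of the GP term relative to the substitution term.
#' @export
alignParams <- function(wMin = 0.4, eps = 1.5, exactLimit = 30L,
                        restarts = 32L, lambda = 1.0)
  list(wMin = wMin, eps = eps, exactLimit = as.integer(exactLimit),
       restarts = as.integer(restarts), lambda = lambda)

#' Similarity weight between two site residues
#'
#' \code{weight = S(aa_a, aa_b) / S_max + lambda * (1 - |GP_a - GP_b| / 100)}
#' with S a symmetric amino-acid substitution table (BLOSUM62) and S_max its
#' largest diagonal entry.
#'
#' @param resA,resB 3-letter residue codes.
#' @param gpA,gpB geometric potential scores in [0, 100].
#' @param params see \code{\link{alignParams}}.
#' @return numeric weight (vectorized over inputs).
#' @export
residuePairSimilarity <- function(resA, resB, gpA, gpB,
                                  params = alignParams()) {
  stopifnot(all(gpA >= -1e-9 & gpA <= 100 + 1e-9),
            all(gpB >= -1e-9 & gpB <= 100 + 1e-9))
  S <- .blosum62()
  smax <- max(diag(S[.AA31, .AA31]))
  S[cbind(.aa1(resA), .aa1(resB))] / smax +
    params$lambda * (1 - abs(gpA - gpB) / 100)
}

.vertexTable <- function(A, B, params) {
  ra <- A@residues; rb <- B@residues
  S <- .blosum62(); aa <- .AA31
  smax <- max(diag(S[aa, aa]))
  sub <- S[.aa1(ra$resname), .aa1(rb$resname), drop = FALSE] / smax
  gpterm <- params$lambda * (1 - abs(outer(ra$gp, rb$gp, "-")) / 100)
  W <- sub + gpterm
  idx <- which(W >= params$wMin, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  v <- data.frame(i = idx[, 1], j = idx[, 2], w = W[idx])
  v[order(v$i, v$j), , drop = FALSE]
}

.compatMatrix <- function(v, dA, dB, eps) {
  M <- abs(dA[v$i, v$i, drop = FALSE] - dB[v$j, v$j, drop = FALSE]) <= eps
  M[outer(v$i, v$i, "==") | outer(v$j, v$j, "==")] <- FALSE
  diag(M) <- FALSE
  M
}

.pairKey <- function(v, set) {
  s <- set[order(v$i[set], v$j[set])]
  paste(v$i[s], v$j[s], collapse = ";")
}

.lexLess <- function(v, a, b) {
  # TRUE when clique a's ordered pair list precedes b's lexicographically
  sa <- a[order(v$i[a], v$j[a])]; sb <- b[order(v$i[b], v$j[b])]
  la <- rbind(v$i[sa], v$j[sa]); lb <- rbind(v$i[sb], v$j[sb])
  n <- min(ncol(la), ncol(lb))
  for (k in seq_len(n)) {
    if (la[1, k] != lb[1, k]) return(la[1, k] < lb[1, k])
    if (la[2, k] != lb[2, k]) return(la[2, k] < lb[2, k])
  }
  ncol(la) < ncol(lb)
}

.maxCliqueExact <- function(v, M) {
  n <- nrow(v)
  best <- list(score = 0, set = integer(0))
  w <- v$w
  expand <- function(set, cands, score) {
    if (score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 && length(set) &&
         (!length(best$set) || .lexLess(v, set, best$set))))
      best <<- list(score = score, set = set)
    if (!length(cands)) return()
    if (score + sum(w[cands]) < best$score - 1e-12) return()
    for (k in seq_along(cands)) {
      p <- cands[k]
      rest <- cands[-seq_len(k)]
      expand(c(set, p), rest[M[p, rest]], score + w[p])
    }
  }
  expand(integer(0), seq_len(n), 0)
  best
}

.maxCliqueGreedy <- function(v, M, restarts) {
  n <- nrow(v)
  seeds <- order(-v$w, v$i, v$j)[seq_len(min(restarts, n))]
  best <- list(score = 0, set = integer(0))
  for (s in seeds) {
    set <- s
    cands <- which(M[s, ])
    score <- v$w[s]
    while (length(cands)) {
      k <- cands[order(-v$w[cands], v$i[cands], v$j[cands])[1]]
      set <- c(set, k); score <- score + v$w[k]
      cands <- cands[M[k, cands] & cands != k]
    }
    if (score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 && length(set) &&
         length(best$set) && .lexLess(v, set, best$set)))
      best <- list(score = score, set = set)
  }
  best
}

#' Align two binding sites (sequence-order independent)
#'
#' @param A,B BindingSite objects with >= 3 residues each.
#' @param params see \code{\link{alignParams}}.
#' @return AlignmentResult; empty (score 0, no transform) when no residue
#'   pair clears \code{wMin}.
#' @export
alignSites <- function(A, B, params = alignParams()) {
  if (nrow(A@residues) < 3L || nrow(B@residues) < 3L)
    stop("alignable sites need at least 3 residues")
  v <- .vertexTable(A, B, params)
  emptyRes <- new("AlignmentResult",
                  pairs = data.frame(idxA = integer(0), idxB = integer(0)),
                  score = 0, rotation = diag(3), translation = numeric(3),
                  rmsd = NA_real_, hasTransform = FALSE)
  if (is.null(v)) return(emptyRes)
  dA <- .pairdist(A@caCoords, A@caCoords)
  dB <- .pairdist(B@caCoords, B@caCoords)
  M <- .compatMatrix(v, dA, dB, params$eps)
  best <- if (nrow(v) <= params$exactLimit) .maxCliqueExact(v, M)
  else .maxCliqueGreedy(v, M, params$restarts)
  if (!length(best$set)) return(emptyRes)
  s <- best$set[order(v$i[best$set], v$j[best$set])]
  pairs <- data.frame(idxA = v$i[s], idxB = v$j[s])
  res <- new("AlignmentResult", pairs = pairs, score = best$score,
             rotation = diag(3), translation = numeric(3),
             rmsd = NA_real_, hasTransform = FALSE)
  if (nrow(pairs) >= 3L) {
    fit <- tryCatch(superposePoints(A@caCoords[pairs$idxA, , drop = FALSE],
                                    B@caCoords[pairs$idxB, , drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(fit))
      res <- new("AlignmentResult", pairs = pairs, score = best$score,
                 rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, hasTransform = TRUE)
  }
  res
}

#' Fit a Gumbel model to background alignment scores
#'
#' Maximum-likelihood fit of the type-I extreme value (Gumbel) distribution,
#' started from method-of-moments (\code{beta = s * sqrt(6) / pi},
#' \code{mu = mean - 0.5772 * beta}).
#'
#' @param scores numeric, >= 50 non-constant background scores.
#' @return EVDModel.
#' @export
fitEVD <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 50L) stop("EVD fit requires >= 50 scores")
  s <- stats::sd(scores)
  if (s < 1e-12) stop("EVD fit requires non-constant scores")
  beta0 <- s * sqrt(6) / pi
  mu0 <- mean(scores) - 0.57721566 * beta0
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (scores - mu) / beta
    length(scores) * log(beta) + sum(z) + sum(exp(-z))
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "BFGS")
  new("EVDModel", mu = fit$par[1], beta = exp(fit$par[2]))
}

#' Gumbel tail p-value of an alignment score
#'
#' \code{p = 1 - exp(-exp(-(score - mu) / beta))}, clamped to (1e-300, 1];
#' strictly decreasing in the score.
#'
#' @param score numeric (vectorized).
#' @param model EVDModel.
#' @export
evdPValue <- function(score, model) {
  z <- (score - model@mu) / model@beta
  p <- -expm1(-exp(-z))
  pmin(pmax(p, 1e-300), 1)
}

.shuffleDecoy <- function(site) {
  r <- site@residues
  perm <- sample.int(nrow(r))
  r$resname <- r$resname[perm]  # GP and geometry preserved, chemistry shuffled
  new("BindingSite", parentId = paste0(site@parentId, "_decoy"),
      residues = r, caCoords = site@caCoords, centroid = site@centroid)
}

#' Screen a query site against a site library
#'
#' Aligns the query to every library site, fits a Gumbel background (supplied
#' scores, or scores of the query against GP-preserving residue-label
#' shuffles of library sites) and assigns p-values and significance tiers.
#'
#' @param query BindingSite.
#' @param library named list of BindingSite objects.
#' @param background numeric background scores, or NULL to generate decoys.
#' @param alpha significance threshold on the p-value (default 1e-3).
#' @param alphaStringent stringent threshold (default 1e-4).
#' @param nDecoys decoys generated when \code{background} is NULL.
#' @param seed RNG seed for decoy generation.
#' @param params see \code{\link{alignParams}}.
#' @return data.frame sorted by ascending p-value: \code{target_id, score,
#'   p_value, tier}; the fitted model and background scores are attached as
#'   attributes \code{evd} and \code{background} for audit.
#' @export
screenSites <- function(query, library, background = NULL, alpha = 1e-3,
                        alphaStringent = 1e-4, nDecoys = 200L, seed = 1L,
                        params = alignParams()) {
  if (!length(library)) stop("empty site library")
  if (is.null(names(library)))
    names(library) <- paste0("target", seq_along(library))
  # sites below the 3-residue alignability floor score 0 rather than erroring
  scores <- vapply(library, function(s)
    if (nrow(siteResidues(s)) < 3L) 0 else
      alignmentScore(alignSites(query, s, params)), numeric(1))
  if (is.null(background)) {
    srcPool <- Filter(function(s) nrow(siteResidues(s)) >= 3L, library)
    if (!length(srcPool))
      stop("background generation failed: no alignable library sites")
    background <- .withSeed(seed, {
      vapply(seq_len(nDecoys), function(k) {
        src <- srcPool[[((k - 1L) %% length(srcPool)) + 1L]]
        alignmentScore(alignSites(query, .shuffleDecoy(src), params))
      }, numeric(1))
    })
    if (stats::sd(background) < 1e-12)
      stop("background generation failed: constant decoy scores")
  }
  model <- fitEVD(background)
  p <- evdPValue(scores, model)
  tier <- ifelse(p < alphaStringent, "stringent",
                 ifelse(p < alpha, "significant", "none"))
  out <- data.frame(target_id = names(library), score = scores, p_value = p,
                    tier = tier, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$score, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evd") <- model
  attr(out, "background") <- background
  out
}
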