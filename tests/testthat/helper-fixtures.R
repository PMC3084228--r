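# Shared fixtures and independent oracles for the test suite.

# a tiny parameterized synthetic system
tinySystem <- function(seed = 3L, nres = 8L, nlig = 4L) {
  cx <- makeSyntheticComplex(seed, nres, nlig)
  ff <- syntheticForcefield(cx)
  sys <- parameterizeSystem(cx, ff)
  x <- rbind(coordMatrix(receptor(cx)), coordMatrix(ligand(cx)))
  list(cx = cx, ff = ff, sys = sys, x = x)
}

# minimal hand-built Structure
atomRow <- function(serial, name, element, chain, resno, resname, record,
                    x, y, z)
  data.frame(serial = serial, name = name, element = element, chain = chain,
             resno = resno, resname = resname, record = record,
             x = x, y = y, z = z, stringsAsFactors = FALSE)

structureFromRows <- function(...) new("Structure", atoms = rbind(...))

# random rotation (proper) for invariance tests
randomRotation <- function() {
  M <- matrix(rnorm(9), 3)
  qrd <- qr(M)
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random small binding site with GP scores
randomSite <- function(nres, id = "S", spread = 8) {
  xyz <- matrix(runif(3 * nres, -spread, spread), ncol = 3)
  new("BindingSite", parentId = id,
      residues = data.frame(chain = "A", resno = seq_len(nres),
                            resname = sample(names(offtargetr:::.AA31), nres,
                                             replace = TRUE),
                            gp = runif(nres, 0, 100),
                            stringsAsFactors = FALSE),
      caCoords = xyz, centroid = colMeans(xyz))
}

# exhaustive oracle for the order-independent site alignment:
# enumerate every injective, pairwise geometrically consistent mapping whose
# pairs all clear wMin, and return the maximum total weight.
bruteForceAlignScore <- function(A, B, params = alignParams()) {
  ra <- siteResidues(A); rb <- siteResidues(B)
  W <- outer(seq_len(nrow(ra)), seq_len(nrow(rb)), Vectorize(function(i, j)
    residuePairSimilarity(ra$resname[i], rb$resname[j], ra$gp[i], rb$gp[j],
                          params)))
  dA <- as.matrix(dist(siteCoords(A)))
  dB <- as.matrix(dist(siteCoords(B)))
  best <- 0
  nA <- nrow(ra); nB <- nrow(rb)
  recurse <- function(i, usedB, pairs, score) {
    if (score > best) best <<- score
    if (i > nA) return()
    recurse(i + 1L, usedB, pairs, score)   # skip residue i
    for (j in seq_len(nB)) {
      if (usedB[j] || W[i, j] < params$wMin) next
      ok <- TRUE
      if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
        if (abs(dA[pairs[r, 1], i] - dB[pairs[r, 2], j]) > params$eps) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      usedB[j] <- TRUE
      recurse(i + 1L, usedB, rbind(pairs, c(i, j)), score + W[i, j])
      usedB[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nB), matrix(0L, 0, 2), 0)
  best
}

# Monte-Carlo SASA oracle: sphere sampling with neighbour occlusion
mcSASA <- function(centers, radii, nPoints = 2000L) {
  total <- 0
  n <- nrow(centers)
  for (i in seq_len(n)) {
    z <- matrix(rnorm(3 * nPoints), ncol = 3)
    z <- z / sqrt(rowSums(z^2))
    pts <- sweep(z * radii[i], 2, centers[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, centers[j, ])^2)
      free <- free & d2 > radii[j]^2
    }
    total <- total + 4 * pi * radii[i]^2 * mean(free)
  }
  total
}

# independent sign-propagation oracle: enumerate all simple paths from each
# inhibited node with igraph and aggregate sign products
pathOracle <- function(net, inhibited) {
  nodes <- networkNodes(net); edges <- networkEdges(net)
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     vertices = nodes$id, directed = TRUE)
  dir <- setNames(rep("unchanged", nrow(nodes)), nodes$id)
  signOf <- function(from, to)
    edges$sign[edges$source == from & edges$target == to][1]
  seen <- list()
  for (s in inhibited) {
    for (v in nodes$id) {
      if (v == s) next
      paths <- igraph::all_simple_paths(g, from = s, to = v, mode = "out")
      for (p in paths) {
        ids <- names(p)
        val <- "down"
        for (k in seq_len(length(ids) - 1L)) {
          sg <- signOf(ids[k], ids[k + 1L])
          if (sg == "dual" || val == "mixed") val <- "mixed"
          else if (sg == "inhibition")
            val <- if (val == "down") "up" else "down"
        }
        seen[[v]] <- union(seen[[v]], val)
      }
    }
    seen[[s]] <- union(seen[[s]], "down")
  }
  for (v in names(seen)) {
    vals <- seen[[v]]
    dir[v] <- if ("mixed" %in% vals || length(setdiff(vals, "mixed")) > 1L)
      "mixed" else vals
  }
  dir
}

# random signed DAG over the closed kind set
randomSignedDAG <- function(nNodes, pEdge = 0.3) {
  ids <- paste0("n", seq_len(nNodes))
  kinds <- c("off_target",
             sample(c("intermediate", "pathway", "effect"), nNodes - 1L,
                    replace = TRUE))
  edges <- NULL
  for (i in seq_len(nNodes - 1L)) for (j in seq.int(i + 1L, nNodes)) {
    if (runif(1) < pEdge)
      edges <- rbind(edges, data.frame(
        source = ids[i], target = ids[j],
        sign = sample(c("activation", "activation", "inhibition", "dual"), 1L),
        stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(source = ids[1], target = ids[2],
                        sign = "activation", stringsAsFactors = FALSE)
  signedNetwork(data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE),
                edges)
}

# randomly grown sphere cluster (sequential attachment, min spacing 2.6 A)
randomSphereCluster <- function(n, step = 2.2, minDist = 2.6) {
  centers <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    repeat {
      cand <- centers[sample(i - 1L, 1), ] + rnorm(3, 0, step)
      if (min(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                 2, cand)^2))) > minDist) break
    }
    centers[i, ] <- cand
  }
  centers
}
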