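test_that("residue pair weights follow the substitution + GP formula", {
  # identical residue and GP: S(x,x)/S_max + lambda
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  expect_equal(residuePairSimilarity("TRP", "TRP", 30, 30),
               e$BLOSUM62["W", "W"] / 11 + 1)
  expect_equal(residuePairSimilarity("ALA", "ALA", 10, 10),
               e$BLOSUM62["A", "A"] / 11 + 1)
  # maximal GP difference kills the profile term
  expect_equal(residuePairSimilarity("ALA", "ALA", 0, 100),
               e$BLOSUM62["A", "A"] / 11)
  expect_error(residuePairSimilarity("XXX", "ALA", 10, 10), "unknown residue")
  # symmetry over random pairs
  set.seed(1)
  aa <- names(offtargetr:::.AA31)
  for (k in 1:100) {
    a <- sample(aa, 1); b <- sample(aa, 1)
    ga <- runif(1, 0, 100); gb <- runif(1, 0, 100)
    expect_equal(residuePairSimilarity(a, b, ga, gb),
                 residuePairSimilarity(b, a, gb, ga))
  }
})

test_that("self-alignment recovers the identity pairing at zero RMSD", {
  set.seed(7)
  A <- randomSite(6)
  res <- alignSites(A, A)
  expect_equal(alignedPairs(res)$idxA, alignedPairs(res)$idxB)
  expect_equal(nrow(alignedPairs(res)), 6L)
  r <- siteResidues(A)
  expect_equal(alignmentScore(res),
               sum(residuePairSimilarity(r$resname, r$resname, r$gp, r$gp)))
  expect_lt(alignmentRmsd(res), 1e-9)
})

test_that("alignment is invariant under rigid motion of one site", {
  set.seed(8)
  A <- randomSite(6)
  R <- randomRotation()
  B <- new("BindingSite", parentId = "S",
           residues = siteResidues(A),
           caCoords = sweep(siteCoords(A) %*% t(R), 2, c(4, 5, -6), "+"),
           centroid = numeric(3))
  self <- alignSites(A, A)
  res <- alignSites(A, B)
  expect_equal(alignedPairs(res), alignedPairs(self))
  expect_equal(alignmentScore(res), alignmentScore(self))
  expect_lt(alignmentRmsd(res), 1e-6)
  tr <- alignmentTransform(res)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
})

test_that("the exact solver matches exhaustive search on small sites", {
  set.seed(21)
  for (k in 1:40) {
    A <- randomSite(sample(3:6, 1), spread = 6)
    B <- randomSite(sample(3:6, 1), spread = 6)
    got <- alignmentScore(alignSites(A, B))
    want <- bruteForceAlignScore(A, B)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("case %d solver score", k))
    # symmetry of the exact score
    expect_equal(got, alignmentScore(alignSites(B, A)), tolerance = 1e-9)
  }
})

test_that("point superposition is exact for congruent sets", {
  set.seed(3)
  P <- matrix(rnorm(30), ncol = 3)
  expect_lt(superposePoints(P, P)$rmsd, 1e-12)
  tr <- superposePoints(P, sweep(P, 2, c(3, -2, 9), "+"))
  expect_lt(tr$rmsd, 1e-12)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  R <- randomRotation()
  both <- superposePoints(P, sweep(P %*% t(R), 2, c(1, 2, 3), "+"))
  expect_lt(both$rmsd, 1e-8)
  expect_equal(det(both$rotation), 1, tolerance = 1e-9)
  expect_error(superposePoints(P[1:2, ], P[1:2, ]), "3 point")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superposePoints(line, line), "collinear")
  # noisy copy: rmsd concentrates near sigma * sqrt(3)
  sig <- 0.1
  rms <- replicate(100, {
    Q <- P + matrix(rnorm(30, 0, sig), ncol = 3)
    superposePoints(P, Q)$rmsd
  })
  expect_true(all(rms > 0.5 * sig * sqrt(3) & rms < 1.5 * sig * sqrt(3)))
})

test_that("Gumbel fitting recovers location and scale", {
  set.seed(99)
  u <- runif(1e4)
  x <- 5 - 2 * log(-log(u))  # Gumbel(mu = 5, beta = 2)
  m <- fitEVD(x)
  expect_equal(evdLocation(m), 5, tolerance = 0.02 * 5)
  expect_equal(evdScale(m), 2, tolerance = 0.02 * 2)
  # location family: shifting scores shifts mu only
  m2 <- fitEVD(x + 7)
  expect_equal(evdLocation(m2), evdLocation(m) + 7, tolerance = 1e-4)
  expect_equal(evdScale(m2), evdScale(m), tolerance = 1e-4)
  # scale family
  m3 <- fitEVD(3 * x)
  expect_equal(evdLocation(m3), 3 * evdLocation(m), tolerance = 1e-3)
  expect_equal(evdScale(m3), 3 * evdScale(m), tolerance = 1e-3)
  expect_error(fitEVD(rep(1, 100)), "non-constant")
  expect_error(fitEVD(x[1:10]), ">= 50")
})

test_that("EVD p-values follow the closed form and are monotone", {
  m <- new("EVDModel", mu = 3, beta = 1.5)
  expect_equal(evdPValue(3, m), 1 - exp(-1), tolerance = 1e-12)
  med <- 3 - 1.5 * log(log(2))
  expect_equal(evdPValue(med, m), 0.5, tolerance = 1e-9)
  s <- seq(0, 40, length.out = 200)  # below ~mu - 2.4 beta, p saturates at 1
  p <- evdPValue(s, m)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  expect_equal(evdPValue(1e6, m), 1e-300)  # clamped, never exactly 0
})

test_that("screening ranks a planted similar site first with sane tiers", {
  set.seed(5)
  query <- randomSite(8, id = "query")
  # planted: rigid copy with one residue mutated
  R <- randomRotation()
  res <- siteResidues(query)
  res$resname[3] <- setdiff(names(offtargetr:::.AA31), res$resname[3])[1]
  planted <- new("BindingSite", parentId = "planted", residues = res,
                 caCoords = sweep(siteCoords(query) %*% t(R), 2, c(8, 1, -3),
                                  "+"),
                 centroid = numeric(3))
  lib <- list(planted = planted)
  for (k in 1:25) lib[[paste0("decoy", k)]] <- randomSite(8, id = "d")
  hits <- screenSites(query, lib, nDecoys = 80, seed = 10)
  expect_equal(hits$target_id[1], "planted")
  expect_true(all(hits$tier %in% c("none", "significant", "stringent")))
  expect_true(all((hits$p_value < 1e-4) == (hits$tier == "stringent")))
  # the query itself is always rank 1 when present
  hits2 <- screenSites(query, c(list(self = query), lib["decoy1"]),
                       nDecoys = 60, seed = 2)
  expect_equal(hits2$target_id[1], "self")
  # an all-decoy library yields no significant hit
  decoysOnly <- lib[names(lib) != "planted"]
  hits3 <- screenSites(query, decoysOnly, nDecoys = 80, seed = 3)
  expect_true(all(hits3$p_value >= 1e-3))
})
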