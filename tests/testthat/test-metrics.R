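test_that("every score equals 1 on self-comparison", {
  cells <- makeTissue(tissueSpec(frameSize = 200, K = 3, density = 0.01),
                      seed = 71)
  img <- stripeImage(1, S = 32)
  expect_equal(structureScore(img, img)$score, 1, tolerance = 1e-9)
  expect_equal(densityScore(cells, cells, k = 10)$score, 1, tolerance = 1e-9)
  expect_equal(compositionScore(cells, cells)$score, 1, tolerance = 1e-9)
  lab <- matrix(sample(c("a", "b", NA), 32 * 32, TRUE), 32)
  expect_equal(featureAlignmentScore(img, img, lab, lab, dMax = 1)$score, 1)
  expect_equal(neighborhoodScore(cells, cells, k = 10, C = 4,
                                 seed = 1)$score, 1, tolerance = 1e-9)
})

test_that("composition score matches the hand-computed penalized-KL oracle", {
  r <- compositionScore(c(0.5, 0.5), c(1, 0), beta = 1, eps = 1e-8)
  klOracle <- 0.5 * log(0.5 / 1) + 0.5 * log(0.5 / 1e-8) + 0.5
  expect_equal(r$klPenalized, klOracle, tolerance = 1e-6)
  expect_equal(r$score, 1 / (1 + klOracle^2), tolerance = 1e-6)
  expect_equal(r$score, 0.01215, tolerance = 1e-3)
  # identical distributions: zero divergence, score one
  expect_equal(compositionScore(c(0.3, 0.7), c(0.3, 0.7))$score, 1)
})

test_that("density score follows the per-type KL construction and penalizes missing types", {
  cellsT <- makeTissue(tissueSpec(frameSize = 150, K = 2, density = 0.02,
                                  mixWidth = 0), seed = 72)
  cellsG <- makeTissue(tissueSpec(frameSize = 150, K = 2, density = 0.02,
                                  mixWidth = 0), seed = 73)
  r <- densityScore(cellsT, cellsG, k = 8, bins = 16)
  # recompute one per-type KL with an independent histogram/KL oracle
  kd <- function(cells) {
    D <- as.matrix(dist(cellCoords(cells)))
    diag(D) <- Inf
    apply(D, 1, function(r) mean(sort(r)[1:8]))
  }
  dT <- kd(cellsT); dG <- kd(cellsG)
  edges <- seq(0, max(dT, dG) * (1 + 1e-9), length.out = 17)
  h <- function(x) {
    hh <- tabulate(pmin(findInterval(x, edges), 16L), nbins = 16L)
    hh / sum(hh)
  }
  selT <- cellTypes(cellsT) == "type1"; selG <- cellTypes(cellsG) == "type1"
  expect_equal(r$St[["type1"]],
               1 / (1 + bruteKL(h(dT[selT]), h(dG[selG]))), tolerance = 1e-9)
  expect_equal(r$score, 0.5 * mean(r$St) + 0.5 * r$Sglobal, tolerance = 1e-12)

  # a type missing from the generated map scores 1 / (1 + lambda)
  gOne <- cellsG[cellTypes(cellsG) == "type1"]
  r2 <- densityScore(cellsT, gOne, k = 8, lambda = 1)
  expect_equal(r2$St[["type2"]], 0.5)
  expect_error(densityScore(cellsT, cellsG[1:5], k = 8), "below the cell count")
})

test_that("feature alignment equals hand-computed centroid distances", {
  # three types with hand-placed channel centroids
  d1 <- array(0, c(4, 4, 3)); d2 <- array(0, c(4, 4, 3))
  lab <- matrix(NA_character_, 4, 4)
  lab[1, 1:2] <- "a"; lab[2, 1] <- "b"; lab[3, 3] <- "c"
  cols1 <- list(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  cols2 <- list(a = c(0.8, 0, 0), b = c(0, 0.5, 0), c = c(0, 0, 1))
  for (tt in names(cols1)) for (ch in 1:3) {
    p1 <- d1[, , ch]; p1[!is.na(lab) & lab == tt] <- cols1[[tt]][ch]
    d1[, , ch] <- p1
    p2 <- d2[, , ch]; p2[!is.na(lab) & lab == tt] <- cols2[[tt]][ch]
    d2[, , ch] <- p2
  }
  r <- featureAlignmentScore(d1, d2, lab, lab, dMin = 0, dMax = 1)
  expect_equal(unname(r$dt), c(0.2, 0.5, 0), tolerance = 1e-12)
  expect_equal(r$dbar, mean(c(0.2, 0.5, 0)), tolerance = 1e-12)
  expect_equal(r$score, 1 - r$dbar, tolerance = 1e-12)
  # missing type gets the fixed penalty lambda = 2.5
  lab2 <- lab; lab2[!is.na(lab2) & lab2 == "c"] <- NA
  r2 <- featureAlignmentScore(d1, d2, lab, lab2, lambda = 2.5, dMax = 5)
  expect_equal(unname(r2$dt[["c"]]), 2.5)
  expect_error(featureAlignmentScore(d1, d2, lab, lab, dMax = 0), "exceed")
})

test_that("Hungarian niche matching equals exhaustive permutation search", {
  set.seed(74)
  for (C in c(3, 5, 6)) {
    zT <- matrix(runif(C * 4), C)
    zG <- matrix(runif(C * 4), C)
    cost <- as.matrix(dist(rbind(zT, zG)))[1:C, C + 1:C]
    best <- Inf
    perms <- if (C <= 6) combinat_perms(C) else NULL
    for (pp in perms) best <- min(best, sum(cost[cbind(1:C, pp)]))
    lsap <- as.integer(clue::solve_LSAP(cost))
    expect_equal(sum(cost[cbind(1:C, lsap)]), best, tolerance = 1e-12)
  }
})

test_that("neighborhood score detects scrambled niches", {
  cells <- makeTissue(tissueSpec(frameSize = 200, K = 3, density = 0.015,
                                 mixWidth = 0), seed = 75)
  self <- neighborhoodScore(cells, cells, k = 10, C = 4, seed = 2)$score
  shuf <- corruptCells(cells, "type_shuffle", 1, seed = 3)
  sc <- neighborhoodScore(cells, shuf, k = 10, C = 4, seed = 2)$score
  expect_lt(sc, self)
  expect_equal(self, 1, tolerance = 1e-9)
})

test_that("structure score drops under pixel permutation and decreases with noise", {
  img <- stripeImage(3, S = 32)
  d <- imageData(img)
  set.seed(76)
  perm <- sample(32 * 32)
  dp <- d
  for (ch in 1:3) dp[, , ch] <- matrix(d[, , ch][perm], 32)
  sPerm <- structureScore(d, dp)$score
  expect_lt(sPerm, structureScore(d, d)$score)

  sev <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  sc <- vapply(sev, function(sv) {
    set.seed(100 + round(100 * sv))
    dn <- pmin(pmax(d + array(rnorm(length(d), 0, sv), dim(d)), 0), 1)
    structureScore(d, dn)$score
  }, numeric(1))
  expect_lte(cor(sev, sc, method = "spearman"), 0)
})

test_that("the aggregate report records scores and hyperparameters", {
  cells <- makeTissue(tissueSpec(frameSize = 150, K = 2, density = 0.02),
                      seed = 77)
  img <- stripeImage(4, S = 32)
  rep <- evaluateGeneration(cells, cells, img, img, k = 8, C = 3, seed = 1)
  expect_s4_class(rep, "MetricReport")
  s <- metricScores(rep)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(s[c("density", "composition", "neighborhood")]),
               c(1, 1, 1), tolerance = 1e-9)
  expect_equal(rep@params$k, 8L)
  expect_equal(rep@params$structureBackend, "randconv")
})
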