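test_that("cluster regularizer matches the double-loop oracle and its analytic zeros", {
  set.seed(13)
  z <- matrix(rnorm(20 * 3), 20)
  lab <- sample(1:3, 20, TRUE)
  p <- abs(matrix(rnorm(20 * 4), 20)); p <- p / rowSums(p)
  expect_equal(clusterLoss(z, lab, p, 0.1, 0.1, 1),
               bruteClusterLoss(z, lab, p, 0.1, 0.1, 1), tolerance = 1e-12)
  expect_equal(clusterLoss(z, lab, p, 0.7, 0.3, 2.5),
               bruteClusterLoss(z, lab, p, 0.7, 0.3, 2.5), tolerance = 1e-12)

  # all pairs same class with identical embeddings: zero loss
  zz <- matrix(1, 6, 3)
  expect_identical(clusterLoss(zz, rep(1, 6), matrix(1 / 4, 6, 4)), 0)
  # all cross pairs at squared distance >= m: repulsion hinge inactive
  zfar <- rbind(matrix(0, 3, 3), matrix(10, 3, 3))
  expect_identical(clusterLoss(zfar, rep(1:2, each = 3),
                               matrix(1 / 4, 6, 4), lambdaIntra = 0), 0)
  expect_error(clusterLoss(z, lab, p, lambdaIntra = -1), "invalid")
})

test_that("autoencoder round trip preserves argmax labels on separable input", {
  set.seed(14)
  K <- 3; n <- 600
  lab <- factor(sample(paste0("t", 1:K), n, TRUE))
  logits <- 4 * diag(K)[as.integer(lab), ] + matrix(rnorm(n * K, 0, 0.3), n)
  p <- exp(logits) / rowSums(exp(logits))
  ae <- trainTypeAutoencoder(p, lab, epochs = 40, hidden = c(32, 64, 16),
                             seed = 0)
  expect_gte(ae$recoveryAccuracy, 0.95)

  emb <- encodeCells(p, ae)
  # identical cells get identical embeddings (deterministic encoder)
  p2 <- p[c(1, 1, 2), ]
  e2 <- encodeCells(p2, ae)$normalized
  expect_equal(e2[1, ], e2[2, ])
  # display form
  expect_equal(encodeCells(p, ae)$display, round(255 * emb$normalized))
  expect_true(all(emb$normalized >= 0 & emb$normalized <= 1))

  # normalization is invertible to within display precision
  back <- CellCanvas:::.ae_denormalize(ae, emb$normalized)
  renorm <- CellCanvas:::.ae_normalize(ae, back)
  expect_lt(max(abs(renorm - emb$normalized)), 1 / 255)

  # rows not summing to one are renormalized with a warning
  expect_warning(trainTypeAutoencoder(2 * p[1:50, ], lab[1:50], epochs = 1,
                                      hidden = c(8, 16, 8)), "renormaliz")
})

test_that("embedding geometry reflects probability-profile similarity", {
  set.seed(15)
  K <- 4; n <- 800
  lab <- sample(1:K, n, TRUE)
  centers <- rbind(c(8, 0, 0, 0), c(0, 8, 0, 0), c(0, 0, 8, 0),
                   c(0, 0, 5.2, 5))          # types 3 and 4 share mass
  logits <- centers[lab, ] + matrix(rnorm(n * K, 0, 0.4), n)
  p <- exp(logits) / rowSums(exp(logits))
  ae <- trainTypeAutoencoder(p, factor(lab), epochs = 50,
                             hidden = c(32, 64, 16), seed = 1)
  z <- encodeCells(p, ae)$normalized
  # mean embedding distance between type pairs vs cosine similarity of mean
  # probability profiles: Spearman correlation must be negative
  mu <- t(vapply(1:K, function(k) colMeans(p[lab == k, ]), numeric(K)))
  zc <- t(vapply(1:K, function(k) colMeans(z[lab == k, ]), numeric(3)))
  pairs <- t(combn(K, 2))
  cs <- apply(pairs, 1, function(ij)
    sum(mu[ij[1], ] * mu[ij[2], ]) /
      (sqrt(sum(mu[ij[1], ]^2)) * sqrt(sum(mu[ij[2], ]^2))))
  dd <- apply(pairs, 1, function(ij) sqrt(sum((zc[ij[1], ] - zc[ij[2], ])^2)))
  expect_lt(cor(cs, dd, method = "spearman"), 0)
})

test_that("painting and reading tissue images round-trips labels and is local", {
  set.seed(16)
  K <- 3; n <- 150
  lab <- factor(sample(paste0("t", 1:K), n, TRUE))
  logits <- 5 * diag(K)[as.integer(lab), ] + matrix(rnorm(n * K, 0, 0.2), n)
  p <- exp(logits) / rowSums(exp(logits))
  ae <- trainTypeAutoencoder(p, lab, epochs = 40, hidden = c(16, 32, 8),
                             seed = 2)
  cells <- randomCells(n, frame = 100, seed = 17)
  grid <- rasterizeCells(cells, 100, 32)
  emb <- encodeCells(p, ae)
  img <- paintImage(grid, emb)

  # empty pixels carry the background; occupied pixels carry embeddings
  expect_equal(sum(occupancyMask(img)), sum(gridPixels(grid) > 0L))
  expect_true(all(imageData(img)[, , 1][!occupancyMask(img)] == 0))

  # paint -> read reproduces decode_cells labels on the retained cells
  back <- readImage(img, ae)
  retained <- gridPixels(grid)[gridPixels(grid) > 0L]
  dec <- decodeCells(emb, ae)
  expect_equal(nCells(back), length(retained))
  occ <- which(gridPixels(grid) > 0L)
  expect_equal(as.character(cellTypes(back)),
               dec$types[gridPixels(grid)[occ]])

  # all-empty grid paints a background-only image
  g0 <- new("PixelGrid", pixels = matrix(0L, 8, 8), dOrig = 100, dNew = 8,
            dropped = integer(0))
  img0 <- paintImage(g0, emb)
  expect_true(all(imageData(img0) == 0))
  expect_equal(nCells(readImage(img0, ae)), 0L)

  # perturbing one pixel by +0.01 per channel changes at most that cell
  d <- imageData(img)
  pix <- which(occupancyMask(img))[1]
  for (ch in 1:3) {
    pl <- d[, , ch]; pl[pix] <- min(1, pl[pix] + 0.01); d[, , ch] <- pl
  }
  img2 <- new("TissueImage", data = d, occupancy = occupancyMask(img),
              background = c(0, 0, 0))
  b2 <- readImage(img2, ae)
  expect_equal(nCells(b2), nCells(back))
  changed <- as.character(cellTypes(b2)) != as.character(cellTypes(back))
  expect_lte(sum(changed), 1L)
})

test_that("decoding clamps out-of-range latents with a warning", {
  set.seed(18)
  lab <- factor(rep(c("a", "b"), 30))
  p <- cbind(runif(60, 0.6, 0.9)); p <- cbind(p, 1 - p)
  ae <- trainTypeAutoencoder(p, lab, epochs = 5, hidden = c(8, 16, 8),
                             seed = 3)
  expect_warning(decodeCells(matrix(c(1.2, 0.5, -0.1), 1), ae), "clamped")
})
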