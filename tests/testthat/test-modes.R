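# Mechanics of the four inference modes: contracts that hold regardless of
# training state, exercised with a small assembled cascade (trained codec,
# freshly initialized UNets, T = 5).

test_that("inpainting preserves observed pixels bit-exactly and is seed-deterministic", {
  m <- tinyCascade()
  img <- stripeImage(5, S = 32)
  msk <- rectMask(32, 32, c(0.25, 0.25, 0.75, 0.75))
  r1 <- inpaint(img, msk, m, seed = 4)
  out <- imageData(r1@image); inp <- imageData(img)
  mm <- msk@mask
  for (ch in 1:3)
    expect_identical(out[, , ch][mm == 0L], inp[, , ch][mm == 0L])
  r2 <- inpaint(img, msk, m, seed = 4)
  expect_identical(imageData(r1@image), imageData(r2@image))
  r3 <- inpaint(img, msk, m, seed = 5)
  expect_false(identical(imageData(r1@image), imageData(r3@image)))

  # empty mask returns the input unchanged with a warning
  expect_warning(r0 <- inpaint(img, maskSpec(matrix(0L, 32, 32)), m), "empty")
  expect_identical(imageData(r0@image), inp)

  # arbitrary (non-rectangular) masks are supported
  set.seed(30)
  mArb <- maskSpec(matrix(rbinom(32 * 32, 1, 0.2), 32))
  rA <- inpaint(img, mArb, m, seed = 6)
  for (ch in 1:3)
    expect_identical(imageData(rA@image)[, , ch][mArb@mask == 0L],
                     inp[, , ch][mArb@mask == 0L])
})

test_that("outpainting accounts width exactly and never touches the original block", {
  m <- tinyCascade()
  img <- stripeImage(6, S = 32)
  # strip = 1 latent column at frac 0.25 of a 4-column latent
  r <- outpaint(img, "right", nIter = 3, model = m, fracPerIter = 0.25,
                seed = 1)
  expect_equal(dim(imageData(r@image)), c(32, 32 + 3 * 8, 3))
  expect_identical(imageData(r@image)[, 1:32, ], imageData(img))
  expect_equal(r@log$width, c(40, 48, 56))

  for (dir in c("left", "up", "down")) {
    rd <- outpaint(img, dir, nIter = 2, model = m, fracPerIter = 0.25,
                   seed = 2)
    d <- imageData(rd@image)
    expect_equal(sort(dim(d)[1:2]), c(32, 48))
    orig <- switch(dir,
                   left = d[, 17:48, ],
                   up = d[17:48, , ],
                   down = d[1:32, , ])
    expect_identical(orig, imageData(img))
  }
  expect_error(outpaint(img, "right", nIter = 0, model = m), "positive")
  expect_error(outpaint(img, "right", nIter = 1, model = m,
                        fracPerIter = 0.5), "0.25")
})

test_that("2D imputation fills the gap on schedule and preserves both sides", {
  m <- tinyCascade()
  left <- stripeImage(7, S = 32)
  right <- stripeImage(8, S = 32)
  # gap of 0 returns the concatenation unchanged
  r0 <- impute2d(left, right, gapCols = 0, model = m)
  expect_identical(imageData(r0@image)[, 1:32, ], imageData(left))
  expect_identical(imageData(r0@image)[, 33:64, ], imageData(right))

  r <- impute2d(left, right, gapCols = 2, model = m, seed = 9)
  d <- imageData(r@image)
  expect_equal(dim(d), c(32, 32 + 16 + 32, 3))
  expect_identical(d[, 1:32, ], imageData(left))
  expect_identical(d[, 49:80, ], imageData(right))
  # gap filled: generated block has signal
  expect_gt(sum(abs(d[, 33:48, ])), 0)
})

test_that("2D imputation closes a 6-column gap at one column per side per iteration in 3 iterations", {
  imgs <- lapply(1:2, stripeImage, S = 64)
  m <- memo("tinyCascade64", function()
    trainCascade(imgs, T = 3, stepsCodec = 20, stepsLatent = 0,
                 stepsPixel = 0, baseLatent = 8, basePixel = 8, featDim = 8,
                 seed = 0))
  r <- impute2d(imgs[[1]], imgs[[2]], gapCols = 6, model = m, patchCols = 1,
                seed = 1)
  fillIters <- r@log[r@log$phase == "fill", ]
  expect_equal(nrow(fillIters), 3L)
  expect_equal(fillIters$remaining, c(4L, 2L, 0L))
})

test_that("blend weights are normalized, reflective and exact on the worked cases", {
  expect_equal(blendWeights(0, 200, 100), c(wPrev = 0.5, wNext = 0.5))
  expect_equal(blendWeights(0, 200, 50), c(wPrev = 0.75, wNext = 0.25))
  set.seed(31)
  for (i in 1:20) {
    zi <- runif(1, 0, 10); zj <- zi + runif(1, 0.1, 10)
    zt <- runif(1, zi + 1e-6, zj - 1e-6)
    w <- blendWeights(zi, zj, zt)
    expect_equal(sum(w), 1)
    wr <- blendWeights(zi, zj, zi + zj - zt)
    expect_equal(unname(w), unname(rev(wr)), tolerance = 1e-12)
  }
  expect_error(blendWeights(0, 100, 150), "outside")
})

test_that("3D imputation blends endpoint prompts and is order-invariant", {
  m <- tinyCascade()
  a <- stripeImage(10, S = 32, boundary = 8)
  b <- stripeImage(11, S = 32, boundary = 24)
  ser <- SliceSeries(c(0, 200), list(a, b))

  # identical endpoints: all intermediate prompts identical
  full <- rectMask(32, 32, c(0, 0, 1, 1))
  Pa <- buildSpatialPrompt(imageData(a), full, m$prompt)
  wHalf <- blendWeights(0, 200, 100)
  Pblend <- wHalf[1] * Pa + wHalf[2] * Pa
  expect_equal(Pblend, Pa)
  # endpoint-coincident target uses that endpoint's prompt (w = 1 limit)
  serSame <- SliceSeries(c(0, 200), list(a, a))
  g1 <- impute3d(serSame, 100, m, seed = 3)
  g2 <- impute3d(serSame, 100, m, seed = 3)
  expect_identical(imageData(g1@slices[[2]]), imageData(g2@slices[[2]]))

  # permuting target order does not change any generated slice
  r12 <- impute3d(ser, c(50, 150), m, seed = 7)
  r21 <- impute3d(ser, c(150, 50), m, seed = 7)
  expect_equal(r12@positions, c(0, 50, 150, 200))
  expect_identical(imageData(r12@slices[[2]]), imageData(r21@slices[[2]]))
  expect_identical(imageData(r12@slices[[3]]), imageData(r21@slices[[3]]))

  expect_error(impute3d(ser, 500, m, seed = 1), "outside")
})

test_that("generated cells carry generated provenance while observed cells are kept", {
  m <- tinyCascade()
  set.seed(32)
  K <- 2; n <- 120
  lab <- factor(sample(c("a", "b"), n, TRUE))
  logits <- 5 * diag(K)[as.integer(lab), ] + matrix(rnorm(n * K, 0, 0.2), n)
  p <- exp(logits) / rowSums(exp(logits))
  ae <- trainTypeAutoencoder(p, lab, epochs = 20, hidden = c(8, 16, 8),
                             seed = 4)
  cells <- randomCells(n, frame = 100, seed = 33)
  grid <- rasterizeCells(cells, 100, 32)
  img <- paintImage(grid, encodeCells(p, ae))
  msk <- rectMask(32, 32, c(0.25, 0.25, 0.75, 0.75))
  r <- inpaint(img, msk, m, seed = 8, embedding = ae)
  prov <- cellProvenance(r@cells)
  expect_true(any(prov == "observed"))
  xy <- cellCoords(r@cells)
  inMask <- msk@mask[cbind(ceiling(xy[, 2]), ceiling(xy[, 1]))] == 1L
  expect_true(all(prov[inMask] == "generated"))
  expect_true(all(prov[!inMask] == "observed"))
})
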