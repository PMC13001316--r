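test_that("frame standardization pads without moving cells and crops densest window", {
  set.seed(3)
  cells <- CellMap(coords = cbind(runif(200, 0, 7000), runif(200, 0, 7000)),
                   cellType = factor(rep("a", 200)))
  pad <- standardizeFrame(cells, 9000, "pad")
  # padding only adds empty space: relative positions unchanged
  expect_equal(cellCoords(pad), sweep(cellCoords(cells), 2,
                                      apply(cellCoords(cells), 2, min)))
  expect_true(all(cellCoords(pad) < 9000))

  # dense 9000-window inside a 12000 span must be found by the crop search
  set.seed(4)
  sparse <- cbind(runif(100, 0, 12000), runif(100, 0, 12000))
  dense <- cbind(runif(400, 1500, 10000), runif(400, 1500, 10000))
  big <- CellMap(coords = rbind(sparse, dense),
                 cellType = factor(rep("a", 500)))
  crop <- standardizeFrame(big, 9000, "crop")
  expect_gte(nCells(crop), 400)
  expect_true(all(cellCoords(crop) >= 0 & cellCoords(crop) < 9000))

  # crop count matches an exhaustive coarse window scan
  set.seed(5)
  unif <- CellMap(coords = cbind(runif(500, 0, 10000), runif(500, 0, 10000)),
                  cellType = factor(rep("a", 500)))
  crop2 <- standardizeFrame(unif, 9000, "crop")
  xy <- sweep(cellCoords(unif), 2, apply(cellCoords(unif), 2, min))
  M <- 9000; stride <- 900
  best <- 0
  for (ox in unique(c(seq(0, max(xy[, 1]) - M, stride), max(xy[, 1]) - M)))
    for (oy in unique(c(seq(0, max(xy[, 2]) - M, stride), max(xy[, 2]) - M)))
      best <- max(best, sum(xy[, 1] >= ox & xy[, 1] < ox + M &
                            xy[, 2] >= oy & xy[, 2] < oy + M))
  expect_equal(nCells(crop2), best)

  expect_error(standardizeFrame(unif[0], 9000, "pad"), "empty")
  small <- CellMap(coords = cbind(runif(10, 0, 100), runif(10, 0, 100)),
                   cellType = factor(rep("a", 10)))
  expect_warning(standardizeFrame(small, 9000, "crop"), "no-op")
})

test_that("linear-scaling rasterization assigns pixels and resolves conflicts by center distance", {
  # exact scaling arithmetic: x0 = 4500, 9000 -> 1024 gives column 512
  c1 <- CellMap(coords = cbind(4500, 4500), cellType = factor("a"))
  g1 <- rasterizeCells(c1, 9000, 1024)
  expect_equal(which(gridPixels(g1) > 0L),
               512 * 1024 + 512 + 1)   # 0-based (512, 512), column-major

  # of two conflicting cells at scaled 512.10 and 512.45, the one nearer
  # the pixel center 512.5 is retained
  xs <- c(512.10, 512.45) * 9000 / 1024
  c2 <- CellMap(coords = cbind(xs, xs), cellType = factor(c("a", "b")))
  g2 <- rasterizeCells(c2, 9000, 1024)
  expect_equal(droppedCells(g2), 1L)
  expect_equal(gridPixels(g2)[gridPixels(g2) > 0L], 2L)

  # random table: retained set equals the brute-force per-pixel argmin
  cells <- randomCells(1000, frame = 100, seed = 11)
  g <- rasterizeCells(cells, 100, 24)
  retained <- sort(gridPixels(g)[gridPixels(g) > 0L])
  expect_equal(retained, bruteRaster(cells, 100, 24))

  expect_error(rasterizeCells(cells, 100, 200), "exceed")
  bad <- CellMap(coords = cbind(150, 10), cellType = factor("a"), cellId = 77L)
  expect_error(rasterizeCells(bad, 100, 24), "77")
})

test_that("nearest-neighbor downsampling reassigns collisions to nearby empty pixels", {
  # <= 1 cell per 2x2 block: zero drops, every cell mapped
  px <- matrix(0L, 16, 16)
  px[cbind(seq(1, 16, 2), seq(1, 16, 2))] <- seq_len(8)
  g <- new("PixelGrid", pixels = px, dOrig = 16, dNew = 16,
           dropped = integer(0))
  g2 <- downsampleGrid(g, 8)
  expect_equal(length(droppedCells(g2)), 0L)
  expect_equal(sum(gridPixels(g2) > 0L), 8L)

  # two cells colliding at one target pixel, adjacent pixel free: one moves
  px <- matrix(0L, 4, 4)
  px[1, 1] <- 1L; px[2, 2] <- 2L          # both map to target (1,1) at 2x2
  g <- new("PixelGrid", pixels = px, dOrig = 4, dNew = 4, dropped = integer(0))
  g2 <- downsampleGrid(g, 2)
  expect_equal(sum(gridPixels(g2) > 0L), 2L)
  expect_equal(gridPixels(g2)[1, 1], 1L)  # first claimant in row-major scan
  expect_equal(length(droppedCells(g2)), 0L)

  # dense random grid: result equals a replay of the same greedy scan
  set.seed(9)
  px <- matrix(0L, 32, 32)
  occ <- sample(32 * 32, 500)
  px[occ] <- seq_along(occ)
  g <- new("PixelGrid", pixels = px, dOrig = 32, dNew = 32,
           dropped = integer(0))
  g2 <- downsampleGrid(g, 16)
  expect_identical(gridPixels(downsampleGrid(g, 16)), gridPixels(g2))
  # conservation at this stage
  expect_equal(sum(gridPixels(g2) > 0L) + length(droppedCells(g2)), 500L)
  # one-pixel-per-cell invariant
  vals <- gridPixels(g2)[gridPixels(g2) > 0L]
  expect_false(anyDuplicated(vals) > 0)
})

test_that("grid_to_cells inverts rasterization up to conflict drops", {
  cells <- randomCells(300, frame = 200, seed = 21)
  g <- rasterizeCells(cells, 200, 64)
  back <- gridToCells(g, cells)
  expect_equal(sort(cellIds(back)),
               sort(setdiff(seq_len(300), droppedCells(g))))
  # conflict-free case is a bijection
  sparse <- CellMap(coords = cbind(seq(5, 195, 10), seq(5, 195, 10)),
                    cellType = factor(rep("a", 20)))
  gs <- rasterizeCells(sparse, 200, 64)
  expect_equal(nCells(gridToCells(gs, sparse)), 20L)
  # empty grid gives an empty table
  ge <- new("PixelGrid", pixels = matrix(0L, 8, 8), dOrig = 200, dNew = 8,
            dropped = integer(0))
  expect_equal(nCells(gridToCells(ge, cells)), 0L)
  # dangling index errors
  gbad <- new("PixelGrid", pixels = matrix(c(999L, rep(0L, 63)), 8),
              dOrig = 200, dNew = 8, dropped = integer(0))
  expect_error(gridToCells(gbad, sparse), "outside")
})

test_that("rasterization is deterministic and conserves cells at every stage", {
  cells <- randomCells(2000, frame = 150, seed = 31)
  g1a <- rasterizeCells(cells, 150, 48)
  g1b <- rasterizeCells(cells, 150, 48)
  expect_identical(gridPixels(g1a), gridPixels(g1b))
  expect_equal(sum(gridPixels(g1a) > 0L) + length(droppedCells(g1a)), 2000L)
  g2 <- downsampleGrid(g1a, 24)
  expect_equal(sum(gridPixels(g2) > 0L) + length(droppedCells(g2)),
               sum(gridPixels(g1a) > 0L))
})

test_that("retention is total when inter-cell spacing exceeds the pixel pitch", {
  # lattice spacing > 2 * (dOrig / dNew)
  s <- seq(0.5, 99, by = 5)                   # spacing 5 > 2 * (100/64)
  cells <- CellMap(coords = as.matrix(expand.grid(s, s)),
                   cellType = factor(rep("a", length(s)^2)))
  g <- rasterizeCells(cells, 100, 64)
  expect_equal(length(droppedCells(g)), 0L)
  g2 <- downsampleGrid(g, 32)                  # pitch doubles, spacing still >
  expect_equal(length(droppedCells(g2)), 0L)
})
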