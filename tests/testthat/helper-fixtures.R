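# Shared fixtures and memoized heavy objects. Everything is generated in
# code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# small random cell table with uniform coordinates
randomCells <- function(n, frame = 100, K = 3, seed = 1) {
  set.seed(seed)
  CellMap(coords = cbind(runif(n, 0, frame), runif(n, 0, frame)),
          cellType = factor(sample(paste0("t", seq_len(K)), n, TRUE)),
          markers = matrix(rnorm(n * 2), n))
}

# brute-force rasterization oracle: per-pixel argmin of center distance,
# ties to the lowest cell id
bruteRaster <- function(cells, dOrig, dNew) {
  xy <- cellCoords(cells)
  sx <- xy[, 1] * dNew / dOrig
  sy <- xy[, 2] * dNew / dOrig
  cx <- floor(sx); cy <- floor(sy)
  keep <- integer(0)
  for (pix in unique(cy * dNew + cx)) {
    in_pix <- which(cy * dNew + cx == pix)
    d2 <- (sx[in_pix] - (cx[in_pix] + 0.5))^2 +
      (sy[in_pix] - (cy[in_pix] + 0.5))^2
    best <- in_pix[order(d2, cellIds(cells)[in_pix])][1]
    keep <- c(keep, best)
  }
  sort(keep)
}

# brute-force kNN oracle (Euclidean, ties by index order)
bruteKnn <- function(coords, k) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  t(vapply(seq_len(n), function(i) order(D[i, ])[seq_len(k)], integer(k)))
}

# double-loop oracle for the cluster regularizer (unordered pairs)
bruteClusterLoss <- function(z, labels, p, lambdaIntra, alpha, m) {
  n <- nrow(z)
  labels <- as.integer(as.factor(labels))
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d2 <- sum((z[i, ] - z[j, ])^2)
    if (labels[i] == labels[j]) tot <- tot + lambdaIntra * d2
    else {
      s <- sum(p[i, ] * p[j, ]) / (sqrt(sum(p[i, ]^2)) * sqrt(sum(p[j, ]^2)))
      tot <- tot + (1 - alpha * s) * max(m - d2, 0)
    }
  }
  tot
}

# all permutations of 1..n (for the factorial assignment oracle)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1L)) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(sub, n, after = pos)
  out
}

# high-precision KL oracle over histograms with eps smoothing
bruteKL <- function(p, q, eps = 1e-8) {
  p <- p + eps; q <- q + eps
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

# random tissue image painted from per-type reference colors
stripeImage <- function(seed, S = 32, boundary = NULL, colA = c(0.85, 0.2, 0.2),
                        colB = c(0.2, 0.3, 0.9), occupancy = 0.5) {
  set.seed(seed)
  if (is.null(boundary)) boundary <- sample(seq(S %/% 4, 3 * S %/% 4), 1)
  occ <- matrix(runif(S * S) < occupancy, S)
  d <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    pl <- matrix(0, S, S)
    pl[seq_len(boundary), ] <- colA[ch]
    pl[(boundary + 1):S, ] <- colB[ch]
    pl <- pmin(pmax(pl + matrix(rnorm(S * S, 0, 0.02), S), 0), 1)
    pl[!occ] <- 0
    d[, , ch] <- pl
  }
  new("TissueImage", data = d, occupancy = occ, background = c(0, 0, 0))
}

# tiny assembled (untrained) cascade at 32 px for mechanics tests
tinyCascade <- function() memo("tinyCascade", function() {
  imgs <- lapply(1:4, stripeImage)
  trainCascade(imgs, T = 5L, stepsCodec = 30L, stepsLatent = 0L,
               stepsPixel = 0L, baseLatent = 8L, basePixel = 8L,
               featDim = 8L, seed = 0L)
})

# separable 5-type fixture spec: types 4 and 5 deliberately close in marker
# space so their probability profiles are the most cosine-similar pair
separableSpec <- function(frameSize = 700, density = 0.0102) {
  mu <- rbind(c(7, 0, 0), c(0, 7, 0), c(0, 0, 7),
              c(4.5, 4.5, 0), c(4.8, 4.1, 0))
  tissueSpec(frameSize = frameSize, K = 5, density = density, nMarkers = 3,
             markerMeans = mu, markerSd = 1, mixWidth = 4)
}

# Desk-scale generative study: a two-type tissue family (stripes with
# varying layer proportions, crypt-like discs with varying radius) at
# near-saturated raster occupancy, embedded through the GCN + autoencoder
# pipeline, used to train the toy cascade (64 px maps, T = 50) and exercise
# inpainting, 2D imputation and 3D slice imputation end to end.
toyStudy <- function() memo("toyStudy", function() {
  baseStripe <- function(propA)
    tissueSpec(frameSize = 512, K = 2, density = 0.05, nMarkers = 3,
               markerSep = 4, mixWidth = 6, proportions = c(propA, 1 - propA))
  baseDisc <- function(r)
    tissueSpec(frameSize = 512, K = 2, layout = "disc", density = 0.05,
               nMarkers = 3, markerSep = 4, mixWidth = 6, discRadius = r)
  cellsRef <- makeTissue(baseStripe(0.5), seed = 500)
  gRef <- buildKnnGraph(cellsRef, k = 10)
  gcn <- trainGCN(gRef, cellTypes(cellsRef), hidden = 32, epochs = 60,
                  seed = 0)
  ae <- trainTypeAutoencoder(gcnForward(gRef, gcn)$probs, cellTypes(cellsRef),
                             epochs = 25, seed = 0)
  imgOf <- function(cells)
    suppressWarnings(cellsToImage(cells, gcn, ae, dOrig = 512, size = 64,
                                  k = 10)$image)
  set.seed(42)
  imgs <- lapply(1:200, function(i) {
    if (i %% 5 < 3) imgOf(makeTissue(baseStripe(runif(1, 0.25, 0.75)),
                                     seed = 1000 + i))
    else imgOf(makeTissue(baseDisc(runif(1, 50, 160)), seed = 1000 + i))
  })
  model <- trainCascade(imgs, T = 50, stepsCodec = 250, stepsLatent = 400,
                        stepsPixel = 400, seed = 0)
  untrained <- trainCascade(imgs[1:2], T = 50, codec = model$codec,
                            stepsLatent = 0, stepsPixel = 0, seed = 0)

  # (a) inpainting a held-out hole, trained vs untrained, identical seeds.
  # Composition is scored on the generated cells against the held-out truth
  # inside the hole; density is scored on the completed map against the
  # full truth map, because kNN distances restricted to the hole suffer
  # boundary truncation.
  held <- imgOf(makeTissue(baseStripe(0.65), seed = 9999))
  msk <- rectMask(64, 64, c(0.3, 0.3, 0.7, 0.7))
  truthAll <- suppressWarnings(readImage(held, ae))
  inMask <- function(cm) {
    xy <- cellCoords(cm)
    msk@mask[cbind(ceiling(xy[, 2]), ceiling(xy[, 1]))] == 1L
  }
  truthIn <- truthAll[inMask(truthAll)]
  scoreOf <- function(mod) {
    r <- inpaint(held, msk, mod, seed = 77, embedding = ae)
    gen <- r@cells[cellProvenance(r@cells) == "generated"]
    c(comp = compositionScore(truthIn, gen)$score,
      dens = densityScore(truthAll, r@cells, k = 20)$score)
  }
  sT <- scoreOf(model)
  sU <- scoreOf(untrained)

  # (b) 2D imputation between an 80/20 and a 20/80 mixture
  imgL <- imgOf(makeTissue(baseStripe(0.8), seed = 7001))
  imgR <- imgOf(makeTissue(baseStripe(0.2), seed = 7002))
  r2 <- impute2d(imgL, imgR, gapCols = 4, model = model, seed = 11,
                 embedding = ae)
  band <- floor((cellCoords(r2@cells)[, 1] - 1e-9) / 8) + 1
  bands <- 7:14                     # flanking observed + the 4 gap columns
  props <- vapply(bands, function(b) {
    sel <- band == b
    if (sum(sel) < 3) return(NA_real_)
    mean(cellTypes(r2@cells)[sel] == "type2")
  }, numeric(1))
  trendRho <- suppressWarnings(cor(bands, props, method = "spearman",
                                   use = "complete.obs"))

  # (c) 3D imputation of a disc growing from radius 60 to 150
  discA <- imgOf(makeTissue(baseDisc(60), seed = 8001))
  discB <- imgOf(makeTissue(baseDisc(150), seed = 8002))
  ser <- SliceSeries(c(0, 200), list(discA, discB))
  r3 <- impute3d(ser, c(50, 100, 150), model, seed = 13)
  genIdx <- which(r3@positions %in% c(50, 100, 150))
  areas <- vapply(genIdx, function(i)
    sum(cellTypes(suppressWarnings(
      readImage(r3@slices[[i]], ae))) == "type2"), numeric(1))
  discRho <- suppressWarnings(cor(r3@positions[genIdx], areas,
                                  method = "spearman"))

  list(model = model, untrained = untrained, ae = ae,
       inpaintTrained = sT, inpaintUntrained = sU,
       trendSpearman = trendRho, discAreas = areas, discSpearman = discRho)
})

# the full soft-typing + embedding pipeline on the 5-type separable fixture,
# shared by the embedding and acceptance tests
separablePipeline <- function() memo("separablePipeline", function() {
  spec <- separableSpec()
  cells <- makeTissue(spec, seed = 101)
  graph <- buildKnnGraph(cells, k = 20)
  gcn <- trainGCN(graph, cellTypes(cells), hidden = 64, epochs = 120,
                  seed = 0)
  probs <- gcnForward(graph, gcn)$probs
  ae <- trainTypeAutoencoder(probs, cellTypes(cells), epochs = 35, seed = 0)
  list(spec = spec, cells = cells, graph = graph, gcn = gcn, probs = probs,
       ae = ae)
})
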