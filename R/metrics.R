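## Generation-fidelity metrics. All five scores lie in [0, 1] and equal 1
## when the generated map is a copy of the truth (matched seeds). Natural
## logarithms throughout; zero-mass histogram bins are smoothed with
## eps = 1e-8 before any KL divergence.

.kl <- function(p, q, eps = 1e-8) {
  p <- p + eps; q <- q + eps
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

# mean distance to the k nearest neighbors, per cell (exact search)
.mean_knn_dist <- function(coords, k) {
  nn <- BiocNeighbors::findKNN(coords, k = k,
                               BNPARAM = BiocNeighbors::KmknnParam(),
                               warn.ties = FALSE)
  rowMeans(nn$distance)
}

#' Structural similarity score
#'
#' \code{S = 1 - d_perc} where \code{d_perc} is a perceptual feature
#' distance between the two images. The perceptual network is a pluggable
#' backend; the built-in \code{"randconv"} backend uses multi-scale
#' fixed-seed random convolutional features compared by cosine distance, so
#' scoring never requires downloads. A pretrained-feature backend can be
#' supplied as a function \code{(arrayTrue, arrayGen) -> distance in [0,1]}.
#'
#' @param imgTrue,imgGen \linkS4class{TissueImage}s (or (H, W, 3) arrays) of
#'   equal shape.
#' @param backend \code{"randconv"} or a distance function.
#' @param nFilters,scales randconv backend settings.
#' @param seed seed fixing the random filter bank.
#' @return list with \code{score} and \code{backend}.
#' @export
structureScore <- function(imgTrue, imgGen, backend = "randconv",
                           nFilters = 24L, scales = c(1L, 2L, 4L),
                           seed = 7L) {
  a <- if (is(imgTrue, "TissueImage")) imageData(imgTrue) else imgTrue
  b <- if (is(imgGen, "TissueImage")) imageData(imgGen) else imgGen
  if (!all(dim(a) == dim(b))) stop("image shape mismatch")
  if (is.function(backend))
    return(list(score = 1 - backend(a, b), backend = "custom"))
  set.seed(seed)
  Wb <- matrix(rnorm(nFilters * 3 * 9), nFilters)   # fixed 3x3 filter bank
  featDist <- function(x, y, sc) {
    if (sc > 1L) { x <- .block_mean(x, sc); y <- .block_mean(y, sc) }
    fx <- .randconv_feats(x, Wb); fy <- .randconv_feats(y, Wb)
    num <- rowSums(fx * fy)
    den <- sqrt(rowSums(fx^2)) * sqrt(rowSums(fy^2))
    cs <- ifelse(den > 0, num / den, 1)
    mean((1 - cs) / 2)
  }
  d <- mean(vapply(scales, function(sc) featDist(a, b, sc), numeric(1)))
  list(score = 1 - min(max(d, 0), 1), backend = "randconv")
}

.block_mean <- function(x, f) {
  H <- dim(x)[1] %/% f; W <- dim(x)[2] %/% f
  out <- array(0, c(H, W, dim(x)[3]))
  for (ch in seq_len(dim(x)[3])) {
    m <- x[seq_len(H * f), seq_len(W * f), ch]
    m <- rowsum(m, rep(seq_len(H), each = f))
    m <- t(rowsum(t(m), rep(seq_len(W), each = f))) / f^2
    out[, , ch] <- m
  }
  out
}

.randconv_feats <- function(x, Wb) {
  ad_tape_start()
  h <- ad_relu(ad_conv2d(ad_leaf(x), ad_leaf(Wb),
                         ad_leaf(numeric(nrow(Wb))), 3L))
  v <- ad_value(h)
  matrix(v, dim(v)[1] * dim(v)[2], dim(v)[3])
}

#' Cell-density consistency score
#'
#' For each cell type, the per-cell mean distance to its k nearest
#' neighbors is histogrammed (shared bin edges across the two maps) and the
#' true and generated histograms are compared by KL divergence;
#' \code{S_t = 1/(1 + KL)}. A type present in truth but missing from the
#' generated map scores \code{1/(1 + lambda)}. The final score combines the
#' per-type mean with the type-agnostic global analogue:
#' \code{S = alpha * mean_t(S_t) + (1 - alpha) * S_global}.
#'
#' @param cellsTrue,cellsGen \linkS4class{CellMap}s.
#' @param k neighbor count (default 20; must be below both cell counts).
#' @param lambda missing-type penalty (default 1).
#' @param alpha per-type vs global balance in [0,1] (default 0.5).
#' @param bins shared histogram bin count (default 32).
#' @return list with \code{score}, per-type scores \code{St},
#'   \code{Sglobal} and the parameters used.
#' @export
densityScore <- function(cellsTrue, cellsGen, k = 20L, lambda = 1,
                         alpha = 0.5, bins = 32L) {
  if (k >= min(nCells(cellsTrue), nCells(cellsGen)))
    stop("k must be below the cell count of both maps")
  dT <- .mean_knn_dist(cellCoords(cellsTrue), k)
  dG <- .mean_knn_dist(cellCoords(cellsGen), k)
  edges <- seq(0, max(dT, dG) * (1 + 1e-9), length.out = bins + 1L)
  hist01 <- function(x) {
    h <- tabulate(pmin(findInterval(x, edges, left.open = FALSE), bins),
                  nbins = bins)
    h / sum(h)
  }
  types <- levels(droplevels(cellTypes(cellsTrue)))
  St <- setNames(numeric(length(types)), types)
  for (tt in types) {
    selT <- cellTypes(cellsTrue) == tt
    selG <- cellTypes(cellsGen) == tt
    St[tt] <- if (!any(selG)) 1 / (1 + lambda) else
      1 / (1 + .kl(hist01(dT[selT]), hist01(dG[selG])))
  }
  Sg <- 1 / (1 + .kl(hist01(dT), hist01(dG)))
  list(score = alpha * mean(St) + (1 - alpha) * Sg, St = St, Sglobal = Sg,
       params = list(k = k, lambda = lambda, alpha = alpha, bins = bins))
}

#' Cell-type composition similarity score
#'
#' Penalized KL divergence between the normalized type proportions p (true)
#' and q (generated):
#' \code{KL_pen = sum_t p_t log(p_t / (q_t + eps)) + beta * sum_{t: q_t <=
#' eps} p_t}, and \code{S = 1 / (1 + KL_pen^2)}.
#'
#' @param cellsTrue,cellsGen \linkS4class{CellMap}s (or named proportion
#'   vectors over a shared type set).
#' @param beta missing-type penalty weight (default 1).
#' @param eps numerical floor (default 1e-8).
#' @return list with \code{score}, \code{klPenalized} and the parameters.
#' @export
compositionScore <- function(cellsTrue, cellsGen, beta = 1, eps = 1e-8) {
  as_prop <- function(x, lev) {
    if (is(x, "CellMap")) {
      tab <- table(factor(as.character(cellTypes(x)), levels = lev))
      as.numeric(tab) / max(1, sum(tab))
    } else as.numeric(x) / sum(x)
  }
  lev <- if (is(cellsTrue, "CellMap"))
    union(levels(droplevels(cellTypes(cellsTrue))),
          levels(droplevels(cellTypes(cellsGen)))) else
    seq_along(cellsTrue)
  p <- as_prop(cellsTrue, lev)
  q <- as_prop(cellsGen, lev)
  pos <- p > 0
  klp <- sum(p[pos] * log(p[pos] / (q[pos] + eps))) + beta * sum(p[q <= eps])
  list(score = 1 / (1 + klp^2), klPenalized = klp,
       params = list(beta = beta, eps = eps))
}

#' Feature-alignment score
#'
#' Compares per-type channel centroids between the true and generated
#' images: \code{d_t = ||c_t^true - c_t^gen||}, with a fixed penalty
#' \code{lambda} for a type absent from either image, mapped linearly to
#' \code{S = 1 - (dbar - dMin) / (dMax - dMin)}, clamped to [0, 1].
#' Centroids are computed on the working channel scale of the supplied
#' images, which is recorded in the output.
#'
#' @param imgTrue,imgGen \linkS4class{TissueImage}s (or arrays).
#' @param labelsTrue,labelsGen H x W matrices (or vectors aligned with the
#'   occupied pixels) of per-pixel type labels; NA = no cell.
#' @param lambda missing-type penalty distance (default 2.5, on the 0..255/100
#'   display scale of the original formulation; set to the working scale).
#' @param dMin,dMax linear mapping bounds; \code{dMax = NULL} uses the
#'   diameter of the pooled centroid cloud.
#' @return list with \code{score}, per-type distances \code{dt},
#'   \code{dbar}, and the parameters (including the channel scale in use).
#' @export
featureAlignmentScore <- function(imgTrue, imgGen, labelsTrue, labelsGen,
                                  lambda = 2.5, dMin = 0, dMax = NULL) {
  a <- if (is(imgTrue, "TissueImage")) imageData(imgTrue) else imgTrue
  b <- if (is(imgGen, "TissueImage")) imageData(imgGen) else imgGen
  lev <- sort(unique(c(as.character(labelsTrue[!is.na(labelsTrue)]),
                       as.character(labelsGen[!is.na(labelsGen)]))))
  centroid <- function(d, lab, tt) {
    sel <- !is.na(lab) & lab == tt
    if (!any(sel)) return(NULL)
    c(mean(d[, , 1][sel]), mean(d[, , 2][sel]), mean(d[, , 3][sel]))
  }
  dt <- setNames(numeric(length(lev)), lev)
  cloud <- NULL
  for (tt in lev) {
    cT <- centroid(a, labelsTrue, tt)
    cG <- centroid(b, labelsGen, tt)
    cloud <- rbind(cloud, cT, cG)
    dt[tt] <- if (is.null(cT) || is.null(cG)) lambda else
      sqrt(sum((cT - cG)^2))
  }
  if (is.null(dMax)) dMax <- max(dist(cloud), lambda)
  if (dMax <= dMin) stop("dMax must exceed dMin")
  dbar <- mean(dt)
  s <- min(max(1 - (dbar - dMin) / (dMax - dMin), 0), 1)
  list(score = s, dt = dt, dbar = dbar,
       params = list(lambda = lambda, dMin = dMin, dMax = dMax,
                     channelScale = "[0,1] normalized embedding"))
}

# per-cell neighbor-type composition over the k nearest neighbors
.niche_histograms <- function(cells, k) {
  nn <- BiocNeighbors::findKNN(cellCoords(cells), k = k,
                               BNPARAM = BiocNeighbors::KmknnParam(),
                               warn.ties = FALSE)
  typ <- as.integer(cellTypes(cells))
  K <- nlevels(cellTypes(cells))
  H <- matrix(0, nCells(cells), K)
  for (j in seq_len(k)) {
    tj <- typ[nn$index[, j]]
    H[cbind(seq_len(nrow(H)), tj)] <- H[cbind(seq_len(nrow(H)), tj)] + 1
  }
  H / k
}

#' Neighborhood (niche) similarity score
#'
#' Each cell's local neighborhood composition (type histogram over its k
#' nearest neighbors) is clustered into C niche centroids per map
#' (full-batch k-means, fixed seed); the two centroid sets are matched by
#' solving the linear sum assignment problem minimizing the total Euclidean
#' centroid distance, and \code{S = 1 / (1 + D_total)}.
#'
#' @param cellsTrue,cellsGen \linkS4class{CellMap}s sharing a type set.
#' @param k neighbors per composition histogram (default 20).
#' @param C niche cluster count (default 10; reduced with a warning when a
#'   map has fewer distinct compositions).
#' @param seed k-means seed.
#' @return list with \code{score}, \code{Dtotal}, matched per-cluster
#'   distances \code{matchedDist}, the permutation \code{pi}, and the
#'   parameters.
#' @export
neighborhoodScore <- function(cellsTrue, cellsGen, k = 20L, C = 10L,
                              seed = 0L) {
  if (min(nCells(cellsTrue), nCells(cellsGen)) < C)
    stop("both maps need at least C cells")
  hT <- .niche_histograms(cellsTrue, k)
  hG <- .niche_histograms(cellsGen, k)
  Cuse <- min(C, nrow(unique(hT)), nrow(unique(hG)))
  if (Cuse < C) warning("fewer distinct compositions than C; using C = ", Cuse)
  km <- function(H) {
    set.seed(seed)
    kmeans(H, centers = Cuse, nstart = 1L, iter.max = 100L)$centers
  }
  zT <- km(hT); zG <- km(hG)
  cost <- as.matrix(dist(rbind(zT, zG)))[seq_len(Cuse),
                                         Cuse + seq_len(Cuse), drop = FALSE]
  pi <- as.integer(clue::solve_LSAP(cost))
  md <- cost[cbind(seq_len(Cuse), pi)]
  list(score = 1 / (1 + sum(md)), Dtotal = sum(md), matchedDist = md,
       pi = pi, params = list(k = k, C = Cuse, seed = seed))
}

#' Score a generated map against the truth with all five metrics
#'
#' @param cellsTrue,cellsGen \linkS4class{CellMap}s.
#' @param imgTrue,imgGen \linkS4class{TissueImage}s.
#' @param labelsTrue,labelsGen per-pixel label matrices for the
#'   feature-alignment score (NA = empty); when NULL they are derived from
#'   the cell maps if pixel-aligned, otherwise the feature score is skipped.
#' @param k,lambdaDensity,alphaDensity,bins,betaComposition,eps,lambdaRGB,C,seed
#'   metric hyperparameters (see the individual scores).
#' @return A \linkS4class{MetricReport}.
#' @export
evaluateGeneration <- function(cellsTrue, cellsGen, imgTrue, imgGen,
                               labelsTrue = NULL, labelsGen = NULL,
                               k = 20L, lambdaDensity = 1, alphaDensity = 0.5,
                               bins = 32L, betaComposition = 1, eps = 1e-8,
                               lambdaRGB = 2.5, C = 10L, seed = 0L) {
  st <- structureScore(imgTrue, imgGen)
  de <- densityScore(cellsTrue, cellsGen, k = k, lambda = lambdaDensity,
                     alpha = alphaDensity, bins = bins)
  co <- compositionScore(cellsTrue, cellsGen, beta = betaComposition,
                         eps = eps)
  fa <- if (!is.null(labelsTrue) && !is.null(labelsGen))
    featureAlignmentScore(imgTrue, imgGen, labelsTrue, labelsGen,
                          lambda = lambdaRGB) else NULL
  ne <- neighborhoodScore(cellsTrue, cellsGen, k = k, C = C, seed = seed)
  scores <- c(structure = st$score, density = de$score,
              composition = co$score,
              featureAlignment = if (is.null(fa)) NA_real_ else fa$score,
              neighborhood = ne$score)
  new("MetricReport",
      scores = scores[!is.na(scores)],
      perType = list(density = de$St,
                     featureAlignment = if (is.null(fa)) NULL else fa$dt,
                     matchedClusterDist = ne$matchedDist),
      params = list(k = k, lambdaDensity = lambdaDensity,
                    alphaDensity = alphaDensity, bins = bins,
                    betaComposition = betaComposition, eps = eps,
                    lambdaRGB = lambdaRGB, C = ne$params$C, seed = seed,
                    structureBackend = st$backend))
}
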