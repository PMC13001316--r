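#' Build a k-nearest-neighbor spatial graph
#'
#' Nodes are cells, edges connect each cell to its k nearest neighbors by
#' Euclidean distance on planar coordinates (exact, exhaustive search). The
#' directed kNN edge set is symmetrized by union; self-loops are not stored
#' (they are added analytically as A + I during message passing).
#'
#' @param cells a \linkS4class{CellMap}.
#' @param k neighbor count (default 20).
#' @return A \code{SpatialGraph} list: \code{n}, \code{k}, \code{knn}
#'   (N x k neighbor-index matrix, directed), \code{adj} (symmetrized sparse
#'   adjacency without self-loops), and \code{features} (raw marker matrix).
#' @export
buildKnnGraph <- function(cells, k = 20L) {
  n <- nCells(cells)
  if (n <= k) stop("need more cells than neighbors (N > k)")
  nn <- BiocNeighbors::findKNN(cellCoords(cells), k = k,
                               BNPARAM = BiocNeighbors::KmknnParam(),
                               warn.ties = FALSE)
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn$index)
  keep <- ii != jj                      # self cannot be its own neighbor
  adj <- Matrix::sparseMatrix(i = c(ii[keep], jj[keep]),
                              j = c(jj[keep], ii[keep]), x = 1,
                              dims = c(n, n))
  adj@x[] <- 1                          # union semantics (duplicates summed)
  structure(list(n = n, k = as.integer(k), knn = nn$index, adj = adj,
                 features = markerMatrix(cells)),
            class = "SpatialGraph")
}

# Symmetrically normalized adjacency with self-loops:
# Ahat = Dtilde^{-1/2} (A + I) Dtilde^{-1/2}, degrees on A + I.
.norm_adj <- function(adj) {
  at <- adj + Matrix::Diagonal(nrow(adj))
  d <- Matrix::rowSums(at)
  di <- Matrix::Diagonal(x = 1 / sqrt(d))
  di %*% at %*% di
}

.relu <- function(x) pmax(x, 0)

.softmax_rows <- function(o) {
  o <- o - apply(o, 1, max)
  e <- exp(o)
  e / rowSums(e)
}

# Architecture: fully connected input layer, two graph-convolution layers,
# linear classifier to K logits; ReLU activations, dropout on hidden layers.
.gcn_init <- function(nIn, hidden, K, seed) {
  set.seed(seed)
  g <- function(a, b) matrix(rnorm(a * b, 0, sqrt(2 / a)), a, b)
  list(W1 = g(nIn, hidden), b1 = numeric(hidden),
       W2 = g(hidden, hidden), W3 = g(hidden, hidden),
       W4 = g(hidden, K), b4 = numeric(K))
}

#' Forward pass of the soft cell-typing GCN
#'
#' Implements per-layer message passing
#' \code{h^(l+1) = relu(sum_u 1/sqrt(dv du) W h_u)} over neighbors plus
#' self-loop (degrees on A + I), i.e. the symmetrically normalized
#' propagation \code{Ahat H W}, followed by a linear classifier and row-wise
#' softmax.
#'
#' @param graph a \code{SpatialGraph} from \code{\link{buildKnnGraph}}.
#' @param model a trained GCN model from \code{\link{trainGCN}}.
#' @param features optional feature override (defaults to z-scored graph
#'   features using the model's stored training statistics).
#' @return A \code{SoftTypeProbs} list: \code{probs} (N x K row-stochastic
#'   matrix) and \code{labels} (the model's class labels).
#' @export
gcnForward <- function(graph, model, features = NULL) {
  X <- if (is.null(features)) scale(graph$features, center = model$featMean,
                                    scale = model$featSd) else features
  if (ncol(X) != nrow(model$params$W1)) stop("feature width mismatch")
  Ah <- .norm_adj(graph$adj)
  p <- model$params
  H1 <- .relu(X %*% p$W1 + rep(p$b1, each = nrow(X)))
  H2 <- .relu(as.matrix(Ah %*% (H1 %*% p$W2)))
  H3 <- .relu(as.matrix(Ah %*% (H2 %*% p$W3)))
  logits <- H3 %*% p$W4 + rep(p$b4, each = nrow(X))
  list(probs = .softmax_rows(logits), labels = model$labels)
}

#' Train the soft cell-typing GCN
#'
#' Four-layer network (fully connected input layer, two graph-convolution
#' layers, linear classifier) trained with cross-entropy
#' \code{L = -sum_i y_i log yhat_i} under Adam, full batch, on a seeded
#' random train/validation/test split. Marker features are z-scored with
#' training-split statistics, which are stored with the model.
#'
#' @param graph a \code{SpatialGraph}.
#' @param labels factor of per-cell type labels.
#' @param hidden hidden width (default 1024; use less for desk-scale runs).
#' @param epochs training epochs (default 150).
#' @param lr Adam learning rate.
#' @param dropout dropout rate on hidden layers during training.
#' @param split train/val/test fractions (default 80/10/10).
#' @param seed integer seed controlling init, split and dropout.
#' @return A \code{gcnModel} list with \code{params}, \code{labels} (class
#'   levels), stored feature statistics, the split indices, and
#'   \code{accuracy} (train/val/test).
#' @export
trainGCN <- function(graph, labels, hidden = 1024L, epochs = 150L,
                     lr = 5e-3, dropout = 0.1, split = c(0.8, 0.1, 0.1),
                     seed = 0L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    warning("labels contain a single class; task is degenerate")
  n <- graph$n
  K <- nlevels(labels)
  set.seed(seed)
  perm <- sample.int(n)
  nTr <- floor(split[1] * n); nVa <- floor(split[2] * n)
  idxTr <- perm[seq_len(nTr)]
  idxVa <- perm[nTr + seq_len(nVa)]
  idxTe <- perm[(nTr + nVa + 1L):n]

  mu <- colMeans(graph$features[idxTr, , drop = FALSE])
  sdv <- apply(graph$features[idxTr, , drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  X <- scale(graph$features, center = mu, scale = sdv)
  Y <- diag(K)[as.integer(labels), , drop = FALSE]
  Ah <- .norm_adj(graph$adj)

  p <- .gcn_init(ncol(X), hidden, K, seed)
  mAdam <- lapply(p, function(w) w * 0)
  vAdam <- mAdam
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  onTr <- numeric(n); onTr[idxTr] <- 1 / length(idxTr)

  for (ep in seq_len(epochs)) {
    d1 <- if (dropout > 0) matrix(rbinom(n * hidden, 1, 1 - dropout), n) /
      (1 - dropout) else 1
    d2 <- if (dropout > 0) matrix(rbinom(n * hidden, 1, 1 - dropout), n) /
      (1 - dropout) else 1
    M1 <- X %*% p$W1 + rep(p$b1, each = n); H1 <- .relu(M1) * d1
    M2 <- as.matrix(Ah %*% (H1 %*% p$W2)); H2 <- .relu(M2) * d2
    M3 <- as.matrix(Ah %*% (H2 %*% p$W3)); H3 <- .relu(M3)
    logits <- H3 %*% p$W4 + rep(p$b4, each = n)
    P <- .softmax_rows(logits)

    dO <- (P - Y) * onTr
    g <- list()
    g$W4 <- crossprod(H3, dO); g$b4 <- colSums(dO)
    dH3 <- tcrossprod(dO, p$W4) * (M3 > 0)
    AdH3 <- as.matrix(Ah %*% dH3)
    g$W3 <- crossprod(H2, AdH3)
    dH2 <- tcrossprod(AdH3, p$W3) * d2 * (M2 > 0)
    AdH2 <- as.matrix(Ah %*% dH2)
    g$W2 <- crossprod(H1, AdH2)
    dH1 <- tcrossprod(AdH2, p$W2) * d1 * (M1 > 0)
    g$W1 <- crossprod(X, dH1); g$b1 <- colSums(dH1)

    for (nm in names(p)) {
      mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g[[nm]]
      vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g[[nm]]^2
      mh <- mAdam[[nm]] / (1 - b1^ep)
      vh <- vAdam[[nm]] / (1 - b2^ep)
      p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + epsA)
    }
  }

  model <- structure(list(params = p, labels = levels(labels), featMean = mu,
                          featSd = sdv, hidden = hidden, seed = seed,
                          split = list(train = idxTr, val = idxVa, test = idxTe)),
                     class = "gcnModel")
  probs <- gcnForward(graph, model)$probs
  pred <- max.col(probs, ties.method = "first")
  truth <- as.integer(labels)
  model$accuracy <- c(train = mean(pred[idxTr] == truth[idxTr]),
                      val = mean(pred[idxVa] == truth[idxVa]),
                      test = mean(pred[idxTe] == truth[idxTe]))
  model
}

#' @export
print.gcnModel <- function(x, ...) {
  cat(sprintf("GCN soft cell-typer: %d -> %d -> %d classes\n",
              nrow(x$params$W1), x$hidden, length(x$labels)))
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy: train %.3f / val %.3f / test %.3f\n",
                x$accuracy[1], x$accuracy[2], x$accuracy[3]))
  invisible(x)
}

#' Mean cross-entropy of predicted class probabilities
#'
#' \code{L = -sum_i y_i log yhat_i}, averaged over cells; the training
#' criterion of the soft cell-typer.
#'
#' @param probs N x K row-stochastic predictions.
#' @param labels true labels (factor or integer indices into the columns).
#' @return scalar mean cross-entropy (natural log).
#' @export
crossEntropyLoss <- function(probs, labels) {
  idx <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), idx)], 1e-12)))
}

#' One graph-convolution layer (sparse)
#'
#' The message-passing primitive used inside the GCN:
#' \code{relu(Ahat H W)} with \code{Ahat} the symmetrically normalized
#' adjacency with self-loops (degrees on A + I).
#'
#' @param adj sparse adjacency without self-loops.
#' @param H node feature matrix.
#' @param W weight matrix.
#' @param activation apply ReLU (default TRUE).
#' @return Propagated node features.
#' @export
graphConvolve <- function(adj, H, W, activation = TRUE) {
  out <- as.matrix(.norm_adj(adj) %*% (H %*% W))
  if (activation) .relu(out) else out
}

#' Dense reference for normalized graph propagation
#'
#' Computes \code{Dtilde^(-1/2) (A + I) Dtilde^(-1/2) H W} with dense
#' matrices; intended as an independent cross-check of the sparse message
#' passing on small graphs.
#'
#' @param adj dense or sparse adjacency (no self-loops).
#' @param H node features.
#' @param W weight matrix.
#' @return Dense propagated features (pre-activation).
#' @export
densePropagate <- function(adj, H, W) {
  A <- as.matrix(adj) + diag(nrow(H))
  d <- rowSums(A)
  Ah <- diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  Ah %*% (H %*% W)
}
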