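#' Cluster regularizer for the 3-D type embedding
#'
#' Sum over unordered cell pairs of an intra-class cohesion term and a
#' biologically weighted inter-class repulsion:
#' \deqn{\lambda \sum_{y_i=y_j} \|z_i-z_j\|^2 +
#'       \sum_{y_i \ne y_j} (1-\alpha s_{ij}) [m - \|z_i-z_j\|^2]_+}
#' where \eqn{s_{ij}} is the cosine similarity of the cells' soft type
#' probability profiles, so that biologically similar types are allowed to
#' sit closer in the latent manifold.
#'
#' @param z N x 3 latent embeddings.
#' @param labels per-cell type labels (factor or integer).
#' @param p N x K soft type probabilities (for the cosine weights).
#' @param lambdaIntra intra-class cohesion weight (>= 0, default 0.1).
#' @param alpha similarity relaxation in [0, 1] (default 0.1).
#' @param m repulsion margin on squared distances (> 0, default 1).
#' @return scalar loss.
#' @export
clusterLoss <- function(z, labels, p, lambdaIntra = 0.1, alpha = 0.1, m = 1) {
  if (lambdaIntra < 0 || alpha < 0 || alpha > 1 || m <= 0)
    stop("invalid hyperparameters: need lambdaIntra >= 0, alpha in [0,1], m > 0")
  .cluster_loss_grad(z, labels, p, lambdaIntra, alpha, m, scale = 1,
                     wantGrad = FALSE)$value
}

# loss and gradient over unordered pairs i<j; scale multiplies both
.cluster_loss_grad <- function(z, labels, p, lambdaIntra, alpha, m, scale = 1,
                               wantGrad = TRUE) {
  n <- nrow(z)
  labels <- as.integer(as.factor(labels))
  G <- tcrossprod(z)
  sq <- diag(G)
  D <- outer(sq, sq, `+`) - 2 * G               # squared distances
  pn <- p / pmax(sqrt(rowSums(p^2)), 1e-12)
  S <- tcrossprod(pn)                           # cosine similarities
  hinge <- pmax(m - D, 0)
  Wrep <- (1 - alpha * S) * (D < m)
  up <- upper.tri(D)
  sm <- outer(labels, labels, `==`)
  val <- lambdaIntra * sum(D[up][sm[up]]) +
    sum(((1 - alpha * S) * hinge)[up][!sm[up]])
  out <- list(value = scale * val)
  if (wantGrad) {
    W <- matrix(0, n, n)
    W[sm] <- lambdaIntra
    W[!sm] <- -Wrep[!sm]
    diag(W) <- 0
    out$grad <- 2 * scale * (rowSums(W) * z - W %*% z)
  }
  out
}

# fused tape node for the cluster regularizer
ad_cluster <- function(z, labels, p, lambdaIntra, alpha, m, scale) {
  res <- .cluster_loss_grad(z$value, labels, p, lambdaIntra, alpha, m, scale)
  .ad_node(res$value, list(z), function(g) list(g * res$grad))
}

## ---- encoder/decoder MLPs (expansion-compression, LN + ReLU) ----

.ae_mlp_params <- function(widths, prefix) {
  p <- list()
  for (i in seq_len(length(widths) - 1L)) {
    p[[sprintf("%s%d.W", prefix, i)]] <- .he_lin(widths[i], widths[i + 1L])
    p[[sprintf("%s%d.b", prefix, i)]] <- numeric(widths[i + 1L])
    if (i < length(widths) - 1L) {
      p[[sprintf("%s%d.g", prefix, i)]] <- rep(1, widths[i + 1L])
      p[[sprintf("%s%d.bb", prefix, i)]] <- numeric(widths[i + 1L])
    }
  }
  p
}

.ae_mlp_forward <- function(p, prefix, x, nLayers) {
  h <- x
  for (i in seq_len(nLayers)) {
    h <- ad_bias_rows(ad_matmul(h, p[[sprintf("%s%d.W", prefix, i)]]),
                      p[[sprintf("%s%d.b", prefix, i)]])
    if (i < nLayers)
      h <- ad_relu(ad_layernorm(h, p[[sprintf("%s%d.g", prefix, i)]],
                                p[[sprintf("%s%d.bb", prefix, i)]]))
  }
  h
}

#' Train the categorical-to-RGB autoencoder
#'
#' Compresses K-dimensional soft type probabilities to a 3-D latent through
#' a four-layer fully connected encoder (widths expanding to 512 before
#' contracting to the 3-D bottleneck, layer norm + ReLU) and a mirrored
#' decoder with a softmax output. The objective is the Kullback-Leibler
#' reconstruction divergence KL(p || phat) plus \code{beta} times the
#' \code{\link{clusterLoss}} regularizer evaluated over within-minibatch
#' pairs (scaled by the pair count). Latent min/max per channel are recorded
#' for [0, 1] normalization, and a per-type codebook of mean normalized
#' embeddings is stored for image decoding.
#'
#' @param probs N x K row-stochastic matrix of soft type probabilities.
#' @param labels per-cell true type labels (factor).
#' @param beta weight of the cluster regularizer (default 1).
#' @param lambdaIntra,alpha,m cluster-loss hyperparameters (defaults 0.1,
#'   0.1, 1).
#' @param hidden encoder hidden widths between input and bottleneck
#'   (default c(128, 512, 64)).
#' @param epochs,batch,lr optimizer settings.
#' @param seed integer seed.
#' @return A \code{typeEmbedding} model: encoder/decoder parameters, latent
#'   normalization bounds, class labels, per-type codebook, recovery
#'   accuracy (fraction of cells whose argmax type survives a round trip),
#'   and the configuration.
#' @export
trainTypeAutoencoder <- function(probs, labels, beta = 1, lambdaIntra = 0.1,
                                 alpha = 0.1, m = 1,
                                 hidden = c(128L, 512L, 64L), epochs = 60L,
                                 batch = 256L, lr = 1e-3, seed = 0L) {
  probs <- as.matrix(probs)
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("probability rows do not sum to 1; renormalizing")
    probs <- probs / rs
  }
  labels <- as.factor(labels)
  K <- ncol(probs)
  set.seed(seed)
  p <- c(.ae_mlp_params(c(K, hidden, 3L), "enc"),
         .ae_mlp_params(c(3L, rev(hidden), K), "dec"))
  st <- adam_init(p)
  n <- nrow(probs)
  nL <- length(hidden) + 1L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch)) {
      sel <- ord[b0:min(b0 + batch - 1L, n)]
      if (length(sel) < 2L) next
      ad_tape_start()
      pn <- ad_params(p)
      x <- ad_leaf(probs[sel, , drop = FALSE])
      z <- .ae_mlp_forward(pn, "enc", x, nL)
      logits <- .ae_mlp_forward(pn, "dec", z, nL)
      loss <- ad_kl_softmax(logits, probs[sel, , drop = FALSE])
      npair <- length(sel) * (length(sel) - 1) / 2
      cl <- ad_cluster(z, labels[sel], probs[sel, , drop = FALSE],
                       lambdaIntra, alpha, m, scale = beta / npair)
      total <- ad_add_scalar(loss, cl)
      ad_backward(total)
      upd <- adam_step(p, ad_collect_grads(pn), st, lr)
      p <- upd$params; st <- upd$state
    }
  }
  model <- structure(list(params = p, labels = levels(labels), K = K,
                          nLayers = nL,
                          config = list(beta = beta, lambdaIntra = lambdaIntra,
                                        alpha = alpha, m = m, hidden = hidden,
                                        epochs = epochs, batch = batch,
                                        lr = lr, seed = seed)),
                     class = "typeEmbedding")
  zAll <- .ae_encode_raw(model, probs)
  model$boundsMin <- apply(zAll, 2, min)
  model$boundsMax <- apply(zAll, 2, max)
  rngFix <- model$boundsMax - model$boundsMin
  model$boundsMax[rngFix == 0] <- model$boundsMin[rngFix == 0] + 1
  zn <- .ae_normalize(model, zAll)
  cb <- matrix(0, nlevels(labels), 3)
  for (k in seq_len(nlevels(labels)))
    cb[k, ] <- colMeans(zn[labels == levels(labels)[k], , drop = FALSE])
  model$codebook <- cb
  dec <- decodeCells(zn, model)
  model$recoveryAccuracy <-
    mean(dec$types == levels(labels)[max.col(probs, ties.method = "first")])
  model
}

#' @export
print.typeEmbedding <- function(x, ...) {
  cat(sprintf("typeEmbedding: %d types -> 3-D latent (recovery %.3f)\n",
              x$K, x$recoveryAccuracy))
  invisible(x)
}

# plain (no-tape) MLP evaluation
.ae_eval <- function(model, prefix, x) {
  p <- model$params
  h <- x
  for (i in seq_len(model$nLayers)) {
    n <- nrow(h)
    h <- h %*% p[[sprintf("%s%d.W", prefix, i)]]
    h <- h + rep(p[[sprintf("%s%d.b", prefix, i)]], each = n)
    if (i < model$nLayers) {
      hc <- h - rowMeans(h)
      h <- hc / sqrt(rowMeans(hc^2) + 1e-5)
      h <- h * rep(p[[sprintf("%s%d.g", prefix, i)]], each = n) +
        rep(p[[sprintf("%s%d.bb", prefix, i)]], each = n)
      h[h < 0] <- 0
    }
  }
  h
}

.ae_encode_raw <- function(model, probs) .ae_eval(model, "enc", probs)

.ae_normalize <- function(model, z) {
  zn <- sweep(sweep(z, 2, model$boundsMin), 2,
              model$boundsMax - model$boundsMin, "/")
  pmin(pmax(zn, 0), 1)
}

.ae_denormalize <- function(model, zn) {
  sweep(sweep(zn, 2, model$boundsMax - model$boundsMin, "*"), 2,
        model$boundsMin, "+")
}

#' Encode soft type probabilities to the 3-D RGB-like latent
#'
#' @param probs N x K soft type probabilities.
#' @param model a trained \code{typeEmbedding}.
#' @return An \code{Embedding3} list: \code{normalized} (N x 3 in [0,1],
#'   clamped to the stored training bounds with a warning if any value fell
#'   outside), \code{display} (N x 3 integers in 0..255,
#'   \code{round(255 * normalized)}), and \code{raw} (pre-normalization
#'   latents).
#' @export
encodeCells <- function(probs, model) {
  raw <- .ae_encode_raw(model, as.matrix(probs))
  lo <- sweep(raw, 2, model$boundsMin, `<`)
  hi <- sweep(raw, 2, model$boundsMax, `>`)
  if (any(lo) || any(hi))
    warning(sum(lo | hi), " latent value(s) outside stored bounds; clamped")
  zn <- .ae_normalize(model, raw)
  structure(list(normalized = zn, display = round(255 * zn), raw = raw),
            class = "Embedding3")
}

#' Decode 3-D latents back to soft type probabilities and labels
#'
#' @param z N x 3 matrix of normalized latents in [0,1] (or an
#'   \code{Embedding3}).
#' @param model a trained \code{typeEmbedding}.
#' @return list with \code{probs} (N x K, row-stochastic) and \code{types}
#'   (character labels; argmax with ties broken to the lowest class index).
#' @export
decodeCells <- function(z, model) {
  if (inherits(z, "Embedding3")) z <- z$normalized
  z <- as.matrix(z)
  if (any(z < -1e-9) || any(z > 1 + 1e-9)) {
    warning("normalized latents outside [0,1]; clamped")
    z <- pmin(pmax(z, 0), 1)
  }
  logits <- .ae_eval(model, "dec", .ae_denormalize(model, z))
  probs <- .softmax_rows(logits)
  list(probs = probs,
       types = model$labels[max.col(probs, ties.method = "first")])
}
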