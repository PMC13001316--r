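#' DDPM noise schedule
#'
#' Linear beta schedule with cumulative signal coefficients
#' \code{alphabar_t = prod(1 - beta_1..t)}. The beta endpoints scale
#' inversely with the step count so that the diffusion always terminates in
#' (near-)pure noise: \code{alphabar_0 = 1} and \code{alphabar_T} is near 0
#' for every T. At the reference T = 1000 the defaults are exactly the
#' conventional 1e-4 and 2e-2; shorter schedules (e.g. the desk-scale
#' T = 50) use proportionally larger betas, preserving the total noise
#' budget so that sampling from N(0, 1) matches the training distribution.
#'
#' @param T step count (default 1000; toy configurations use 50).
#' @param betaStart,betaEnd linear beta endpoints (defaults 0.1/T, 20/T).
#' @return A \code{noiseSchedule} list with \code{T}, \code{beta},
#'   \code{alpha} and \code{alphabar} (indexed 1..T).
#' @export
noiseSchedule <- function(T = 1000L, betaStart = 0.1 / T,
                          betaEnd = min(20 / T, 0.5)) {
  if (betaStart <= 0 || betaEnd >= 1) stop("betas must lie in (0, 1)")
  beta <- seq(betaStart, betaEnd, length.out = T)
  alpha <- 1 - beta
  structure(list(T = as.integer(T), beta = beta, alpha = alpha,
                 alphabar = cumprod(alpha)), class = "noiseSchedule")
}

.abar <- function(sched, t) if (t <= 0L) 1 else sched$alphabar[t]

#' Masked forward noising of a latent
#'
#' Applies Gaussian forward diffusion only inside the latent mask:
#' \code{z_t = (1-M) z0 + M (sqrt(abar_t) z0 + sqrt(1-abar_t) eps)}.
#' Unmasked entries are bit-identical to the input for every t.
#'
#' @param z0 latent array (Hz, Wz, C).
#' @param M latent mask (Hz x Wz in {0,1}); recycled over channels.
#' @param t timestep in 0..T.
#' @param sched a \code{\link{noiseSchedule}}.
#' @param eps noise array of the latent's shape (drawn if NULL).
#' @return The noised latent z_t.
#' @export
forwardNoiseLatent <- function(z0, M, t, sched, eps = NULL) {
  if (t < 0L || t > sched$T) stop("t out of range")
  if (is.null(eps)) eps <- array(rnorm(length(z0)), dim(z0))
  ab <- .abar(sched, t)
  Ma <- array(M, dim(z0))
  (1 - Ma) * z0 + Ma * (sqrt(ab) * z0 + sqrt(1 - ab) * eps)
}

#' Unmasked forward noising (pixel stage)
#'
#' \code{x_t = sqrt(abar_t) x0 + sqrt(1-abar_t) eps}.
#'
#' @inheritParams forwardNoiseLatent
#' @param x0 clean image array.
#' @return The noised image x_t.
#' @export
forwardNoisePixel <- function(x0, t, sched, eps = NULL) {
  if (is.null(eps)) eps <- array(rnorm(length(x0)), dim(x0))
  ab <- .abar(sched, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' One reverse DDPM step with clean-sample parameterization
#'
#' Posterior-mean ancestral step given a predicted clean sample:
#' \code{mu = sqrt(abar_{t-1}) beta_t / (1-abar_t) x0hat +
#'        sqrt(alpha_t) (1-abar_{t-1}) / (1-abar_t) x_t}, variance
#' \code{(1-abar_{t-1})/(1-abar_t) beta_t}; no noise is added at t = 1.
#'
#' @param xt current sample at step t.
#' @param t timestep in 1..T.
#' @param x0hat network prediction of the clean sample.
#' @param sched a \code{\link{noiseSchedule}}.
#' @param noise optional standard-normal array (drawn if NULL and t > 1).
#' @return The sample at step t - 1.
#' @export
ddpmStep <- function(xt, t, x0hat, sched, noise = NULL) {
  ab <- sched$alphabar[t]
  abPrev <- .abar(sched, t - 1L)
  bt <- sched$beta[t]
  at <- sched$alpha[t]
  mu <- (sqrt(abPrev) * bt / (1 - ab)) * x0hat +
    (sqrt(at) * (1 - abPrev) / (1 - ab)) * xt
  if (t <= 1L) return(mu)
  if (is.null(noise)) noise <- array(rnorm(length(xt)), dim(xt))
  v <- (1 - abPrev) / (1 - ab) * bt
  mu + sqrt(v) * noise
}
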