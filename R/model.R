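## Generative model and mean-field variational family.
##
## Latent variables and their unconstrained parameterizations:
##   U (N x K, > 0)      log U      ~ N(mu_u, sigma_u^2)        TF activity
##   A (M x K, (0,1))    logit A    ~ N(prior logits, sigma_a^2) edge prob.
##   B (M x K, real)     B          ~ N(0, sigma_b^2)            edge strength
##   d (N, (0,1))        logit d    ~ N(0, 9)                    seq. depth
##   sigma_obs (> 0)     log sigma  ~ N(0, 1)                    obs. noise
## Likelihood: W_nm ~ N(d_n * (U (A*B)^T)_nm, sigma_obs^2).
##
## All log-densities below are densities over the CONSTRAINED variables
## (change-of-variable Jacobians included in both prior and variational
## log-pdfs), so prior and variational values are directly comparable and
## the Jacobians cancel in ELBO/importance-weight differences.

logit <- function(p) log(p) - log1p(-p)
logistic <- function(x) plogis(x)

#' Clip a prior entry into the open unit interval
#'
#' `max(min(value, a_max), a_min)`: maps the binary prior-knowledge entries
#' {0, 1} to interior values so their logit is finite.
#'
#' @param value numeric vector/matrix of prior entries.
#' @param a_min,a_max clipping bounds, `0 < a_min < a_max < 1`.
#' @return clipped values, same shape as `value`.
#' @export
clip_prior <- function(value, a_min = 0.005, a_max = 0.995) {
  if (!(a_min > 0 && a_min < a_max && a_max < 1))
    stop("configuration error: need 0 < a_min < a_max < 1")
  pmax(pmin(value, a_max), a_min)
}

#' Prior logit means for the interaction-probability matrix
#'
#' Elementwise `logit(clip(prior, a_min, a_max))`. A prior entry of 1 maps
#' to `logit(a_max)` and 0 to `logit(a_min)`; with the default symmetric
#' bounds the two are negatives of each other.
#'
#' @param prior genes x TFs binary prior-knowledge matrix.
#' @inheritParams clip_prior
#' @return M x K numeric matrix of prior means in logit space.
#' @export
build_prior_logit_means <- function(prior, a_min = 0.005, a_max = 0.995) {
  prior <- as_network(prior)
  out <- logit(clip_prior(unclass(prior), a_min, a_max))
  dimnames(out) <- dimnames(prior)
  out
}

#' Effective regulatory coefficient matrix
#'
#' `V = A * B` elementwise: interaction probability times signed strength.
#'
#' @param A,B M x K numeric matrices.
#' @return M x K matrix `V`.
#' @export
interaction_matrix <- function(A, B) {
  if (!identical(dim(A), dim(B)))
    stop("A and B must have identical dimensions")
  A * B
}

## ---- latent samples --------------------------------------------------

new_latent_sample <- function(U, A, B, d, sigma_obs) {
  structure(list(U = U, A = A, B = B, d = d, sigma_obs = sigma_obs),
            class = "pmfgrn_sample")
}

check_sample <- function(sample) {
  stopifnot(is.list(sample))
  if (any(!is.finite(sample$U)) || any(sample$U <= 0))
    stop("latent sample outside support: U must be strictly positive")
  if (any(sample$A <= 0) || any(sample$A >= 1))
    stop("latent sample outside support: A must lie in (0, 1)")
  if (any(!is.finite(sample$B)))
    stop("latent sample outside support: B must be finite")
  if (any(sample$d <= 0) || any(sample$d >= 1))
    stop("latent sample outside support: d must lie in (0, 1)")
  if (!is.finite(sample$sigma_obs) || sample$sigma_obs <= 0)
    stop("latent sample outside support: sigma_obs must be > 0")
  invisible(sample)
}

## ---- variational state -----------------------------------------------

#' Initialize the mean-field variational state at the prior
#'
#' The variational family mirrors the prior factor by factor: Gaussians on
#' log U, logit d, logit A, B and log sigma_obs. Initialization sets every
#' factor equal to its prior (edge means at the prior logits), so the
#' early optimization is driven by the likelihood.
#'
#' @param prior genes x TFs binary prior-knowledge matrix.
#' @param n_cells number of cells N.
#' @param config a [pmfgrn_config()].
#' @return list of class `"pmfgrn_state"` with mean/scale arrays for each
#'   factor (`U_mean`, `U_scale`, `d_mean`, `d_scale`, `A_mean`, `A_scale`,
#'   `B_mean`, `B_scale`, `o_mean`, `o_scale`).
#' @export
init_variational_state <- function(prior, n_cells, config = pmfgrn_config()) {
  prior <- as_network(prior)
  M <- nrow(prior); K <- ncol(prior); N <- as.integer(n_cells)
  pl <- build_prior_logit_means(prior, config$a_min, config$a_max)
  dn <- dimnames(prior)
  state <- list(
    U_mean = matrix(config$mu_u, N, K), U_scale = matrix(config$sigma_u, N, K),
    d_mean = rep(0, N), d_scale = rep(config$d_prior_sd, N),
    A_mean = pl, A_scale = matrix(config$sigma_a, M, K, dimnames = dn),
    B_mean = matrix(0, M, K, dimnames = dn),
    B_scale = matrix(config$sigma_b, M, K, dimnames = dn),
    o_mean = config$o_prior_mean, o_scale = config$o_prior_sd)
  class(state) <- "pmfgrn_state"
  check_state(state)
  state
}

check_state <- function(state) {
  sc <- c("U_scale", "d_scale", "A_scale", "B_scale", "o_scale")
  for (nm in sc)
    if (any(state[[nm]] <= 0)) stop("variational scale ", nm,
                                    " must be strictly positive")
  if (!identical(dim(state$U_mean), dim(state$U_scale)) ||
      !identical(dim(state$A_mean), dim(state$A_scale)) ||
      !identical(dim(state$B_mean), dim(state$B_scale)) ||
      !identical(dim(state$A_mean), dim(state$B_mean)) ||
      length(state$d_mean) != length(state$d_scale) ||
      length(state$d_mean) != nrow(state$U_mean) ||
      ncol(state$U_mean) != ncol(state$A_mean))
    stop("variational state shapes are inconsistent")
  invisible(state)
}

state_dims <- function(state) {
  c(N = nrow(state$U_mean), M = nrow(state$A_mean), K = ncol(state$A_mean))
}

## Draw the unconstrained Gaussian variates for every factor using the
## current RNG stream. Fixed draw order: U, d, A, B, o.
draw_unconstrained <- function(state) {
  dm <- state_dims(state)
  N <- dm["N"]; M <- dm["M"]; K <- dm["K"]
  list(
    u = state$U_mean + state$U_scale * matrix(stats::rnorm(N * K), N, K),
    delta = state$d_mean + state$d_scale * stats::rnorm(N),
    a = state$A_mean + state$A_scale * matrix(stats::rnorm(M * K), M, K),
    b = state$B_mean + state$B_scale * matrix(stats::rnorm(M * K), M, K),
    o = state$o_mean + state$o_scale * stats::rnorm(1))
}

unconstrained_to_sample <- function(z) {
  new_latent_sample(U = exp(z$u), A = logistic(z$a), B = z$b,
                    d = logistic(z$delta), sigma_obs = exp(z$o))
}

#' Draw a reparameterized sample from the variational posterior
#'
#' Draws standard-normal variates in the unconstrained space, shifts and
#' scales them by the variational parameters, and maps through `exp`
#' (U, sigma_obs) or the logistic function (A, d); B stays unconstrained.
#' The transforms guarantee the range invariants of every latent exactly.
#'
#' @param state a `pmfgrn_state`.
#' @param seed optional integer; when given, seeds the RNG for a
#'   reproducible draw.
#' @return list of class `"pmfgrn_sample"` with elements `U`, `A`, `B`,
#'   `d`, `sigma_obs`.
#' @export
variational_sample <- function(state, seed = NULL) {
  check_state(state)
  if (!is.null(seed)) set.seed(as.integer(seed))
  unconstrained_to_sample(draw_unconstrained(state))
}

## ---- log densities ---------------------------------------------------

#' Gaussian observation log-likelihood
#'
#' Sum over all cells and genes of the Normal log-density of the observed
#' count at mean `d_n * (U V^T)_nm` with shared noise SD `sigma_obs`,
#' where `V = A * B`.
#'
#' @param W cells x genes expression matrix (or plain numeric matrix).
#' @param sample a latent sample (list with `U`, `A`, `B`, `d`,
#'   `sigma_obs`).
#' @return scalar log-likelihood.
#' @export
likelihood_logpdf <- function(W, sample) {
  W <- unclass(as_expression(W))
  check_sample(sample)
  mu <- sample$d * (sample$U %*% t(interaction_matrix(sample$A, sample$B)))
  if (!identical(dim(W), dim(mu)))
    stop("W dimensions do not match the latent sample")
  sum(stats::dnorm(W, mean = mu, sd = sample$sigma_obs, log = TRUE))
}

#' Log-density of the prior over all latent variables
#'
#' Evaluates the joint prior at a constrained-space sample: lognormal on U,
#' logistic-normal on A (centred on the prior logits) and on d, Gaussian on
#' B, lognormal-type prior on sigma_obs. All change-of-variable Jacobians
#' are included, so the value is a density over the constrained variables
#' and directly comparable with [variational_logpdf()].
#'
#' @param sample a latent sample.
#' @param prior_logits M x K matrix from [build_prior_logit_means()].
#' @param config a [pmfgrn_config()] supplying the prior scales.
#' @return scalar log-density.
#' @export
prior_logpdf <- function(sample, prior_logits, config = pmfgrn_config()) {
  check_sample(sample)
  lu <- log(sample$U)
  la <- logit(sample$A)
  ld <- logit(sample$d)
  lo <- log(sample$sigma_obs)
  sum(stats::dnorm(lu, config$mu_u, config$sigma_u, log = TRUE)) - sum(lu) +
    sum(stats::dnorm(la, prior_logits, config$sigma_a, log = TRUE)) -
    sum(log(sample$A) + log1p(-sample$A)) +
    sum(stats::dnorm(sample$B, 0, config$sigma_b, log = TRUE)) +
    sum(stats::dnorm(ld, 0, config$d_prior_sd, log = TRUE)) -
    sum(log(sample$d) + log1p(-sample$d)) +
    stats::dnorm(lo, config$o_prior_mean, config$o_prior_sd, log = TRUE) - lo
}

#' Log-density of the variational posterior
#'
#' Product of the mean-field factors evaluated at a constrained-space
#' sample, with the same Jacobian convention as [prior_logpdf()].
#'
#' @param sample a latent sample.
#' @param state a `pmfgrn_state`.
#' @return scalar log-density.
#' @export
variational_logpdf <- function(sample, state) {
  check_sample(sample)
  check_state(state)
  lu <- log(sample$U)
  la <- logit(sample$A)
  ld <- logit(sample$d)
  lo <- log(sample$sigma_obs)
  sum(stats::dnorm(lu, state$U_mean, state$U_scale, log = TRUE)) - sum(lu) +
    sum(stats::dnorm(la, state$A_mean, state$A_scale, log = TRUE)) -
    sum(log(sample$A) + log1p(-sample$A)) +
    sum(stats::dnorm(sample$B, state$B_mean, state$B_scale, log = TRUE)) +
    sum(stats::dnorm(ld, state$d_mean, state$d_scale, log = TRUE)) -
    sum(log(sample$d) + log1p(-sample$d)) +
    stats::dnorm(lo, state$o_mean, state$o_scale, log = TRUE) - lo
}
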