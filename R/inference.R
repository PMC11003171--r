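## Stochastic variational inference for the matrix-factorization model.
##
## The objective is the beta-weighted ELBO
##   E_q[ log p(W|z) + beta * (log p(z) - log q(z)) ],  beta >= 1,
## estimated by reparameterized Monte Carlo. Because every variational
## factor is Gaussian in the unconstrained space, the gradients of the
## one-sample estimator are available in closed form and are computed
## analytically (no autodiff): with z = m + s*eps,
##   d/dm [log p]   = analytic chain rule through exp/logistic,
##   d/ds [log p]   = (d/dz log p) * eps,
##   d/dm [-log q]  = 0,   d/ds [-log q] = 1/s.
## Minibatching over cells scales the likelihood and the local (per-cell)
## prior/entropy terms by N/|batch|; global terms (A, B, sigma_obs) are
## unscaled, so the minibatch objective is an unbiased estimator of the
## full objective.

softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
softplus_inv <- function(y) y + log1p(-exp(-y))

# numerical clamps on the unconstrained parameterization
MEAN_CLAMP <- 15
SCALE_MIN <- 1e-4
SCALE_MAX <- 10

align_prior_logits <- function(prior, config) {
  if (inherits(prior, "prior_network") ||
      (is.matrix(prior) && all(prior %in% c(0, 1))))
    build_prior_logit_means(prior, config$a_min, config$a_max)
  else as.matrix(prior)
}

## One-sample objective at an unconstrained draw `z` (full-size), with the
## likelihood restricted to `idx` cells and the stated minibatch scaling.
## Jacobian terms are omitted identically from prior and variational parts
## (they cancel exactly in the difference). `beta` is passed explicitly so
## the importance-weight computation can force beta = 1.
objective_at_z <- function(W, z, state, config, prior_logits, idx, beta) {
  N <- nrow(W)
  nb <- length(idx)
  s <- N / nb
  u <- z$u[idx, , drop = FALSE]
  delta <- z$delta[idx]
  U <- exp(u)
  A <- logistic(z$a)
  d <- logistic(delta)
  sig <- exp(z$o)
  V <- A * z$b
  mu <- d * (U %*% t(V))
  lik <- sum(stats::dnorm(W[idx, , drop = FALSE], mu, sig, log = TRUE))
  pl <- sum(stats::dnorm(u, config$mu_u, config$sigma_u, log = TRUE)) +
    sum(stats::dnorm(delta, 0, config$d_prior_sd, log = TRUE))
  ql <- sum(stats::dnorm(u, state$U_mean[idx, , drop = FALSE],
                         state$U_scale[idx, , drop = FALSE], log = TRUE)) +
    sum(stats::dnorm(delta, state$d_mean[idx], state$d_scale[idx],
                     log = TRUE))
  pg <- sum(stats::dnorm(z$a, prior_logits, config$sigma_a, log = TRUE)) +
    sum(stats::dnorm(z$b, 0, config$sigma_b, log = TRUE)) +
    stats::dnorm(z$o, config$o_prior_mean, config$o_prior_sd, log = TRUE)
  qg <- sum(stats::dnorm(z$a, state$A_mean, state$A_scale, log = TRUE)) +
    sum(stats::dnorm(z$b, state$B_mean, state$B_scale, log = TRUE)) +
    stats::dnorm(z$o, state$o_mean, state$o_scale, log = TRUE)
  s * lik + beta * (s * (pl - ql) + (pg - qg))
}

#' Monte Carlo estimate of the beta-weighted ELBO
#'
#' Draws `n_samples` reparameterized samples from the variational state
#' and averages the one-sample objective. When `cell_indices` is a proper
#' subset of the cells, the likelihood and the local (per-cell) prior and
#' entropy terms are scaled by `N / length(cell_indices)`; global terms
#' are unscaled, making the minibatch estimate unbiased for the full one.
#'
#' @param W cells x genes expression matrix.
#' @param prior genes x TFs binary prior network (or a precomputed matrix
#'   of prior logit means).
#' @param state a `pmfgrn_state`.
#' @param config a [pmfgrn_config()] (supplies `beta` and prior scales).
#' @param cell_indices integer subset of cells; `NULL` means all cells.
#' @param n_samples Monte Carlo samples to average.
#' @param seed optional integer seed for reproducible draws.
#' @return scalar ELBO estimate.
#' @export
elbo_estimate <- function(W, prior, state, config = pmfgrn_config(),
                          cell_indices = NULL, n_samples = 1, seed = NULL) {
  W <- unclass(as_expression(W))
  check_state(state)
  prior_logits <- align_prior_logits(prior, config)
  if (is.null(cell_indices)) cell_indices <- seq_len(nrow(W))
  cell_indices <- as.integer(cell_indices)
  if (length(cell_indices) == 0) stop("cell_indices must be non-empty")
  if (!is.null(seed)) set.seed(as.integer(seed))
  vals <- vapply(seq_len(n_samples), function(s) {
    z <- draw_unconstrained(state)
    objective_at_z(W, z, state, config, prior_logits, cell_indices,
                   beta = config$beta)
  }, numeric(1))
  mean(vals)
}

#' Importance-weighted estimate of the marginal log-likelihood
#'
#' `log( (1/S) * sum_s exp(log p(W, z_s) - log q(z_s)) )` with samples
#' from the variational posterior, computed through log-sum-exp. The
#' unweighted (`beta = 1`) joint is always used, regardless of the
#' `beta` in `config`. Tighter than the ELBO; used as the early-stopping
#' criterion for final fits.
#'
#' @inheritParams elbo_estimate
#' @param S number of importance samples (>= 1).
#' @return scalar estimate of `log p(W)`.
#' @export
iw_log_marginal <- function(W, prior, state, config = pmfgrn_config(),
                            S = config$iw_samples, seed = NULL) {
  W <- unclass(as_expression(W))
  check_state(state)
  if (S < 1) stop("S must be >= 1")
  prior_logits <- align_prior_logits(prior, config)
  idx <- seq_len(nrow(W))
  if (!is.null(seed)) set.seed(as.integer(seed))
  lw <- vapply(seq_len(S), function(s) {
    z <- draw_unconstrained(state)
    objective_at_z(W, z, state, config, prior_logits, idx, beta = 1)
  }, numeric(1))
  m <- max(lw)
  m + log(mean(exp(lw - m)))
}

## ---- optimizer internals ---------------------------------------------

## raw (unconstrained) parameter list: means as-is, scales via softplus
state_to_raw <- function(state) {
  list(U_mean = state$U_mean, U_raw = softplus_inv(state$U_scale),
       d_mean = state$d_mean, d_raw = softplus_inv(state$d_scale),
       A_mean = state$A_mean, A_raw = softplus_inv(state$A_scale),
       B_mean = state$B_mean, B_raw = softplus_inv(state$B_scale),
       o_mean = state$o_mean, o_raw = softplus_inv(state$o_scale))
}

raw_to_state <- function(raw, template) {
  st <- list(U_mean = raw$U_mean, U_scale = softplus(raw$U_raw),
             d_mean = raw$d_mean, d_scale = softplus(raw$d_raw),
             A_mean = raw$A_mean, A_scale = softplus(raw$A_raw),
             B_mean = raw$B_mean, B_scale = softplus(raw$B_raw),
             o_mean = raw$o_mean, o_scale = softplus(raw$o_raw))
  dimnames(st$A_mean) <- dimnames(template$A_mean)
  dimnames(st$A_scale) <- dimnames(template$A_mean)
  dimnames(st$B_mean) <- dimnames(template$A_mean)
  dimnames(st$B_scale) <- dimnames(template$A_mean)
  class(st) <- "pmfgrn_state"
  st
}

zero_like <- function(raw) lapply(raw, function(p) p * 0)

## One-sample analytic gradient of the minibatch objective w.r.t. the raw
## parameters. Returns list(value, grad). `pl` = prior logit means.
grad_step <- function(W, raw, config, pl, idx) {
  N <- nrow(W); M <- nrow(pl); K <- ncol(pl)
  nb <- length(idx); s <- N / nb
  beta <- config$beta
  Us_b <- softplus(raw$U_raw[idx, , drop = FALSE])
  ds_b <- softplus(raw$d_raw[idx])
  As <- softplus(raw$A_raw); Bs <- softplus(raw$B_raw)
  os <- softplus(raw$o_raw)
  Um_b <- raw$U_mean[idx, , drop = FALSE]
  dm_b <- raw$d_mean[idx]

  eps_u <- matrix(stats::rnorm(nb * K), nb, K)
  eps_d <- stats::rnorm(nb)
  eps_a <- matrix(stats::rnorm(M * K), M, K)
  eps_b <- matrix(stats::rnorm(M * K), M, K)
  eps_o <- stats::rnorm(1)

  u <- Um_b + Us_b * eps_u
  delta <- dm_b + ds_b * eps_d
  a <- raw$A_mean + As * eps_a
  b <- raw$B_mean + Bs * eps_b
  o <- raw$o_mean + os * eps_o

  U <- exp(u); A <- logistic(a); d <- logistic(delta)
  sig <- exp(o); tau <- exp(-2 * o)
  V <- A * b
  M0 <- U %*% t(V)          # nb x M, pre-depth mean
  MU <- d * M0
  Wb <- W[idx, , drop = FALSE]
  R <- Wb - MU

  # objective value (for the trace)
  lik <- -0.5 * tau * sum(R * R) - nb * M * (o + 0.5 * log(2 * pi))
  pl_loc <- sum(stats::dnorm(u, config$mu_u, config$sigma_u, log = TRUE)) +
    sum(stats::dnorm(delta, 0, config$d_prior_sd, log = TRUE))
  ql_loc <- sum(stats::dnorm(u, Um_b, Us_b, log = TRUE)) +
    sum(stats::dnorm(delta, dm_b, ds_b, log = TRUE))
  pg <- sum(stats::dnorm(a, pl, config$sigma_a, log = TRUE)) +
    sum(stats::dnorm(b, 0, config$sigma_b, log = TRUE)) +
    stats::dnorm(o, config$o_prior_mean, config$o_prior_sd, log = TRUE)
  qg <- sum(stats::dnorm(a, raw$A_mean, As, log = TRUE)) +
    sum(stats::dnorm(b, raw$B_mean, Bs, log = TRUE)) +
    stats::dnorm(o, raw$o_mean, os, log = TRUE)
  value <- s * lik + beta * (s * (pl_loc - ql_loc) + (pg - qg))

  # likelihood gradients in the unconstrained space
  P <- tau * (R * d)                        # row-scaled by depth
  GU <- (P %*% V) * U                       # d lik / d u
  GV <- crossprod(P, U)                     # d lik / d V (M x K)
  Ga <- GV * b * A * (1 - A)
  Gb <- GV * A
  Gdelta <- (tau * rowSums(R * M0)) * d * (1 - d)
  Go <- tau * sum(R * R) - nb * M

  # prior gradients d log p / dz = -(z - mu_p)/sigma_p^2
  pu <- -(u - config$mu_u) / config$sigma_u^2
  pd <- -delta / config$d_prior_sd^2
  pa <- -(a - pl) / config$sigma_a^2
  pb <- -b / config$sigma_b^2
  po <- -(o - config$o_prior_mean) / config$o_prior_sd^2

  gz_u <- s * GU + beta * s * pu
  gz_d <- s * Gdelta + beta * s * pd
  gz_a <- s * Ga + beta * pa
  gz_b <- s * Gb + beta * pb
  gz_o <- s * Go + beta * po

  grad <- zero_like(raw)
  grad$U_mean[idx, ] <- gz_u
  grad$U_raw[idx, ] <- (gz_u * eps_u + beta * s / Us_b) *
    logistic(raw$U_raw[idx, , drop = FALSE])
  grad$d_mean[idx] <- gz_d
  grad$d_raw[idx] <- (gz_d * eps_d + beta * s / ds_b) *
    logistic(raw$d_raw[idx])
  grad$A_mean <- gz_a
  grad$A_raw <- (gz_a * eps_a + beta / As) * logistic(raw$A_raw)
  grad$B_mean <- gz_b
  grad$B_raw <- (gz_b * eps_b + beta / Bs) * logistic(raw$B_raw)
  grad$o_mean <- gz_o
  grad$o_raw <- (gz_o * eps_o + beta / os) * logistic(raw$o_raw)

  list(value = value, grad = grad)
}

clip_global_norm <- function(grad, max_norm) {
  sq <- sum(vapply(grad, function(g) sum(g * g), numeric(1)))
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > max_norm)
    grad <- lapply(grad, function(g) g * (max_norm / nrm))
  attr(grad, "norm") <- min(nrm, max_norm)
  grad
}

project_raw <- function(raw) {
  lo <- softplus_inv(SCALE_MIN); hi <- softplus_inv(SCALE_MAX)
  for (nm in c("U_mean", "d_mean", "A_mean", "B_mean", "o_mean"))
    raw[[nm]] <- pmin(pmax(raw[[nm]], -MEAN_CLAMP), MEAN_CLAMP)
  for (nm in c("U_raw", "d_raw", "A_raw", "B_raw", "o_raw"))
    raw[[nm]] <- pmin(pmax(raw[[nm]], lo), hi)
  raw
}

## ---- the fitting front-end -------------------------------------------

#' Fit the probabilistic matrix factorization GRN model
#'
#' Decomposes a cells x genes count matrix into latent TF activity and a
#' TF-target interaction matrix anchored on a binary prior network, by
#' maximizing the beta-weighted ELBO with Adam. The stopping metric is
#' evaluated every `config$eval_interval` steps; training stops when it
#' has not improved for `config$patience` evaluations or at
#' `config$max_steps`, and the returned state is the checkpoint with the
#' best metric (ties keep the earliest).
#'
#' @param expression cells x genes count matrix (labels required). Genes
#'   are reconciled with the prior: the model runs on the lexicographically
#'   sorted intersection.
#' @param prior genes x TFs binary prior-knowledge network.
#' @param config a [pmfgrn_config()].
#' @param stopping early-stopping metric: `"iw_log_marginal"` (default;
#'   importance-weighted marginal likelihood on the training data) or
#'   `"validation_auprc"` (AUPRC of held-out prior rows, used during
#'   hyperparameter search).
#' @param holdout optional [holdout_prior()] split. Required context for
#'   `stopping = "validation_auprc"`; built automatically (with
#'   `config$holdout_fraction` and `config$seed`) when absent. The model
#'   is then fitted on the masked prior and scored against the full one.
#' @param verbose print progress at each evaluation.
#' @return an object of class `"pmfgrn"`: a list with the fitted
#'   variational `state`, the training `trace` (data frame of step, ELBO
#'   estimate and stopping metric), `stopped_at`, `stop_reason`,
#'   `best_metric`, `best_step`, the reconciled `expression` and `prior`,
#'   the `config`, and the label `reconciliation`.
#' @seealso [summary.pmfgrn()], [pmfgrn_search()], [final_fit()]
#' @export
pmf_grn <- function(expression, prior, config = pmfgrn_config(),
                    stopping = c("iw_log_marginal", "validation_auprc"),
                    holdout = NULL, verbose = FALSE) {
  stopping <- match.arg(stopping)
  W_full <- as_expression(expression)
  prior <- as_network(prior)
  rec <- reconcile_labels(W_full, prior)
  W <- unclass(W_full)[, rec$shared_genes, drop = FALSE]
  prior <- prior_network(unclass(prior)[rec$shared_genes, , drop = FALSE])
  N <- nrow(W)

  set.seed(config$seed)
  if (stopping == "validation_auprc") {
    if (is.null(holdout))
      holdout <- holdout_prior(prior, config$holdout_fraction, config$seed)
    if (!identical(rownames(holdout$full_prior), rownames(prior)))
      stop("holdout split gene labels do not match the reconciled prior")
    fit_prior <- holdout$modified_prior
    held_idx <- match(holdout$held_out_genes, rownames(prior))
  } else {
    fit_prior <- prior
    held_idx <- integer(0)
  }
  pl <- build_prior_logit_means(fit_prior, config$a_min, config$a_max)

  state0 <- init_variational_state(fit_prior, N, config)
  raw <- state_to_raw(state0)
  if (config$max_steps == 0L) {
    trace <- data.frame(step = integer(0), elbo = numeric(0),
                        metric = numeric(0))
    return(new_pmfgrn(state0, trace, 0L, "max_steps", NA_real_, NA_integer_,
                      W, prior, config, stopping, holdout, rec))
  }

  mom_m <- zero_like(raw); mom_v <- zero_like(raw)
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  lr <- config$learning_rate
  batch <- min(config$batch_size, N)
  elbo_vec <- numeric(config$max_steps)
  eval_steps <- integer(0); eval_vals <- numeric(0)
  best_metric <- -Inf; best_raw <- NULL; best_step <- NA_integer_
  since_best <- 0L
  stop_reason <- "max_steps"; stopped_at <- config$max_steps
  max_grad_norm <- 0

  evaluate_metric <- function(raw) {
    st <- raw_to_state(raw, state0)
    if (stopping == "iw_log_marginal") {
      iw_log_marginal(W, pl, st, config, S = config$iw_samples)
    } else {
      sm <- summarize_A_rows(st, held_idx, config$summary_mc_samples)
      validation_auprc_matrix(sm$mean,
                              holdout$full_prior[held_idx, , drop = FALSE])
    }
  }

  for (step in seq_len(config$max_steps)) {
    idx <- if (batch < N) sample.int(N, batch) else seq_len(N)
    acc <- NULL; val <- 0
    for (ms in seq_len(config$elbo_mc_samples)) {
      gs <- grad_step(W, raw, config, pl, idx)
      val <- val + gs$value
      acc <- if (is.null(acc)) gs$grad
             else mapply(`+`, acc, gs$grad, SIMPLIFY = FALSE)
    }
    if (config$elbo_mc_samples > 1) {
      acc <- lapply(acc, `/`, config$elbo_mc_samples)
      val <- val / config$elbo_mc_samples
    }
    elbo_vec[step] <- val
    acc <- clip_global_norm(acc, config$grad_clip_norm)
    max_grad_norm <- max(max_grad_norm, attr(acc, "norm"))
    t_ <- step
    cm <- 1 - b1^t_; cv <- 1 - b2^t_
    for (nm in names(raw)) {
      mom_m[[nm]] <- b1 * mom_m[[nm]] + (1 - b1) * acc[[nm]]
      mom_v[[nm]] <- b2 * mom_v[[nm]] + (1 - b2) * acc[[nm]]^2
      raw[[nm]] <- raw[[nm]] +
        lr * (mom_m[[nm]] / cm) / (sqrt(mom_v[[nm]] / cv) + 1e-8)
    }
    raw <- project_raw(raw)

    if (step %% config$eval_interval == 0L) {
      metric <- evaluate_metric(raw)
      eval_steps <- c(eval_steps, step)
      eval_vals <- c(eval_vals, metric)
      if (verbose)
        message(sprintf("step %6d  elbo %12.2f  %s %.6g", step, val,
                        stopping, metric))
      if (metric > best_metric) {
        best_metric <- metric; best_raw <- raw; best_step <- step
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) {
          stop_reason <- "patience_exhausted"; stopped_at <- step
          break
        }
      }
    }
  }
  if (stop_reason == "max_steps") stopped_at <- config$max_steps

  final_raw <- if (!is.null(best_raw)) best_raw else raw
  state <- raw_to_state(final_raw, state0)
  trace <- data.frame(step = seq_len(stopped_at),
                      elbo = elbo_vec[seq_len(stopped_at)],
                      metric = NA_real_)
  trace$metric[match(eval_steps, trace$step)] <- eval_vals
  new_pmfgrn(state, trace, stopped_at, stop_reason,
             if (is.finite(best_metric)) best_metric else NA_real_,
             best_step, W, prior, config, stopping, holdout, rec,
             max_grad_norm = max_grad_norm)
}

new_pmfgrn <- function(state, trace, stopped_at, stop_reason, best_metric,
                       best_step, W, prior, config, stopping, holdout, rec,
                       max_grad_norm = NA_real_) {
  structure(list(state = state, trace = trace, stopped_at = stopped_at,
                 stop_reason = stop_reason, best_metric = best_metric,
                 best_step = best_step, expression = W, prior = prior,
                 config = config, stopping = stopping, holdout = holdout,
                 reconciliation = rec, max_grad_norm = max_grad_norm),
            class = "pmfgrn")
}
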