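# Stochastic variational inference: ELBO estimator, minibatch scaling,
# the optimizer contract, and the importance-weighted marginal likelihood.

make_toy <- function(N = 8, M = 6, K = 2, seed = 3) {
  set.seed(seed)
  pr <- prior_network(rand_binary_prior(M, K))
  W <- expression_matrix(matrix(rpois(N * M, 3), N, M,
                                dimnames = list(sprintf("c%02d", 1:N),
                                                rownames(pr))))
  list(W = W, prior = pr)
}

test_that("full-batch ELBO equals the all-cells batch estimate", {
  toy <- make_toy()
  cfg <- pmfgrn_config(beta = 2)
  st <- init_variational_state(toy$prior, nrow(toy$W), cfg)
  full <- elbo_estimate(toy$W, toy$prior, st, cfg, seed = 4)
  batch <- elbo_estimate(toy$W, toy$prior, st, cfg,
                         cell_indices = seq_len(nrow(toy$W)), seed = 4)
  expect_identical(full, batch)
  expect_error(elbo_estimate(toy$W, toy$prior, st, cfg,
                             cell_indices = integer(0)), "non-empty")
})

test_that("one-sample beta=1 ELBO equals log p(W, z) - log q(z)", {
  toy <- make_toy()
  cfg <- pmfgrn_config(beta = 1)
  st <- init_variational_state(toy$prior, nrow(toy$W), cfg)
  el <- elbo_estimate(toy$W, toy$prior, st, cfg, n_samples = 1, seed = 77)
  z <- variational_sample(st, seed = 77)
  pl <- build_prior_logit_means(toy$prior)
  by_hand <- likelihood_logpdf(toy$W, z) + prior_logpdf(z, pl, cfg) -
    variational_logpdf(z, st)
  expect_equal(el, by_hand, tolerance = 1e-8)
})

test_that("minibatch ELBO is unbiased over a disjoint equal partition", {
  toy <- make_toy(N = 12)
  cfg <- pmfgrn_config(beta = 3)
  st <- rand_state(12, 6, 2)
  dimnames(st$A_mean) <- dimnames(unclass(toy$prior))
  full <- elbo_estimate(toy$W, toy$prior, st, cfg, seed = 5)
  batches <- split(seq_len(12), rep(1:4, each = 3))
  # the same seed redraws the same full latent sample in every call
  parts <- vapply(batches, function(b)
    elbo_estimate(toy$W, toy$prior, st, cfg, cell_indices = b, seed = 5),
    numeric(1))
  expect_equal(mean(parts), full, tolerance = 1e-8)
})

test_that("ELBO estimate matches tensor quadrature on a 1x1x1 toy", {
  # one cell, one gene, one TF: five scalar latents; the exact ELBO is a
  # 5-dimensional Gaussian expectation computed by tensor Gauss-Hermite
  W <- expression_matrix(matrix(2, 1, 1, dimnames = list("c1", "g1")))
  pr <- prior_network(matrix(1, 1, 1, dimnames = list("g1", "t1")))
  cfg <- pmfgrn_config(beta = 2, sigma_a = 0.8, sigma_u = 1.2)
  st <- init_variational_state(pr, 1, cfg)
  # move q off the prior so the KL part is non-trivial
  st$U_mean[] <- 0.4; st$U_scale[] <- 0.7
  st$A_mean[] <- 1.0; st$A_scale[] <- 0.6
  st$B_mean[] <- 0.5; st$B_scale[] <- 0.8
  st$d_mean[] <- 0.2; st$d_scale[] <- 0.9
  st$o_mean <- -0.1; st$o_scale <- 0.5
  pl <- build_prior_logit_means(pr)

  gh <- pracma::gaussHermite(11)
  nodes <- expand.grid(u = gh$x, d = gh$x, a = gh$x, b = gh$x, o = gh$x)
  wts <- expand.grid(u = gh$w, d = gh$w, a = gh$w, b = gh$w, o = gh$w)
  wprod <- wts$u * wts$d * wts$a * wts$b * wts$o / pi^(5 / 2)
  zu <- st$U_mean[1] + sqrt(2) * st$U_scale[1] * nodes$u
  zd <- st$d_mean[1] + sqrt(2) * st$d_scale[1] * nodes$d
  za <- st$A_mean[1] + sqrt(2) * st$A_scale[1] * nodes$a
  zb <- st$B_mean[1] + sqrt(2) * st$B_scale[1] * nodes$b
  zo <- st$o_mean + sqrt(2) * st$o_scale * nodes$o
  lik <- dnorm(2, plogis(zd) * exp(zu) * plogis(za) * zb, exp(zo),
               log = TRUE)
  logp <- dnorm(zu, cfg$mu_u, cfg$sigma_u, log = TRUE) +
    dnorm(zd, 0, cfg$d_prior_sd, log = TRUE) +
    dnorm(za, pl[1], cfg$sigma_a, log = TRUE) +
    dnorm(zb, 0, cfg$sigma_b, log = TRUE) +
    dnorm(zo, 0, 1, log = TRUE)
  logq <- dnorm(zu, st$U_mean[1], st$U_scale[1], log = TRUE) +
    dnorm(zd, st$d_mean[1], st$d_scale[1], log = TRUE) +
    dnorm(za, st$A_mean[1], st$A_scale[1], log = TRUE) +
    dnorm(zb, st$B_mean[1], st$B_scale[1], log = TRUE) +
    dnorm(zo, st$o_mean, st$o_scale, log = TRUE)
  exact <- sum(wprod * (lik + cfg$beta * (logp - logq)))

  set.seed(31)
  reps <- vapply(1:200, function(i)
    elbo_estimate(W, pr, st, cfg, n_samples = 100), numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - exact), 3 * se)

  # for beta = 1 the exact ELBO lower-bounds log p(W): compare with the
  # marginal likelihood integrated over the PRIOR by the same quadrature
  cfg1 <- cfg; cfg1$beta <- 1
  exact1 <- sum(wprod * (lik + logp - logq))
  pu <- cfg$mu_u + sqrt(2) * cfg$sigma_u * nodes$u
  pd <- 0 + sqrt(2) * cfg$d_prior_sd * nodes$d
  pa <- pl[1] + sqrt(2) * cfg$sigma_a * nodes$a
  pb <- 0 + sqrt(2) * cfg$sigma_b * nodes$b
  po <- 0 + sqrt(2) * 1 * nodes$o
  lik_p <- dnorm(2, plogis(pd) * exp(pu) * plogis(pa) * pb, exp(po))
  log_marginal <- log(sum(wprod * lik_p))
  expect_lte(exact1, log_marginal)
})

test_that("importance-weighted estimate: S=1 identity, stability, growth in S", {
  toy <- make_toy(N = 1, M = 1, K = 1, seed = 9)
  cfg <- pmfgrn_config(beta = 1, iw_samples = 1)
  st <- init_variational_state(toy$prior, 1, cfg)
  st$U_mean[] <- 0.3  # off the prior so weights vary
  iw1 <- iw_log_marginal(toy$W, toy$prior, st, cfg, S = 1, seed = 123)
  el1 <- elbo_estimate(toy$W, toy$prior, st, cfg, n_samples = 1,
                       seed = 123)
  expect_identical(iw1, el1)

  # log-sum-exp stability: a state far from the data gives very negative
  # log-weights but a finite estimate
  Wbig <- expression_matrix(matrix(1000, 1, 1,
                                   dimnames = list("c1", "g1")))
  far <- iw_log_marginal(Wbig, toy$prior, st, cfg, S = 3, seed = 1)
  expect_true(is.finite(far))
  expect_lt(far, -1e4)

  # IWAE monotonicity: more importance samples tighten the bound
  set.seed(55)
  m1 <- mean(vapply(1:50, function(i)
    iw_log_marginal(toy$W, toy$prior, st, cfg, S = 1), numeric(1)))
  m100 <- mean(vapply(1:50, function(i)
    iw_log_marginal(toy$W, toy$prior, st, cfg, S = 100), numeric(1)))
  expect_gte(m100, m1)
  expect_error(iw_log_marginal(toy$W, toy$prior, st, cfg, S = 0), "S")
})

test_that("fit with max_steps = 0 returns the initialized state unchanged", {
  toy <- make_toy()
  cfg <- pmfgrn_config(max_steps = 0)
  fit <- pmf_grn(toy$W, toy$prior, cfg)
  st0 <- init_variational_state(toy$prior, nrow(toy$W), cfg)
  expect_equal(fit$state$A_mean, st0$A_mean)
  expect_equal(fit$state$U_scale, st0$U_scale)
  expect_identical(nrow(fit$trace), 0L)
  expect_identical(fit$stop_reason, "max_steps")
})

test_that("fitting is deterministic and honors the trace contract", {
  toy <- make_toy(N = 30, M = 20, K = 2, seed = 13)
  cfg <- fast_config(seed = 21)
  f1 <- pmf_grn(toy$W, toy$prior, cfg)
  f2 <- pmf_grn(toy$W, toy$prior, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$state, f2$state)
  expect_true(all(diff(f1$trace$step) == 1))
  expect_lte(f1$stopped_at, cfg$max_steps)
  expect_true(f1$stop_reason %in% c("max_steps", "patience_exhausted"))
  # returned metric is the best over all evaluated checkpoints
  evald <- f1$trace$metric[!is.na(f1$trace$metric)]
  expect_equal(f1$best_metric, max(evald))
  # instrumented gradient-clipping assertion
  expect_lte(f1$max_grad_norm, cfg$grad_clip_norm + 1e-12)
})

test_that("minibatch and multi-sample fitting run deterministically", {
  toy <- make_toy(N = 40, M = 15, K = 2, seed = 23)
  cfg <- pmfgrn_config(max_steps = 60, eval_interval = 30, patience = 2,
                       batch_size = 16L, summary_mc_samples = 200,
                       seed = 8)
  f1 <- pmf_grn(toy$W, toy$prior, cfg)
  f2 <- pmf_grn(toy$W, toy$prior, cfg)
  expect_identical(f1$state, f2$state)
  expect_identical(nrow(f1$trace), f1$stopped_at)
  cfg2 <- pmfgrn_config(max_steps = 30, eval_interval = 15, patience = 2,
                        elbo_mc_samples = 3L, summary_mc_samples = 200,
                        seed = 8)
  f3 <- pmf_grn(toy$W, toy$prior, cfg2)
  expect_identical(nrow(f3$trace), f3$stopped_at)
  expect_true(all(is.finite(f3$trace$elbo)))
})

test_that("optimization increases the ELBO on simulated data", {
  sim <- small_sim()
  cfg <- pmfgrn_config(max_steps = 1200, eval_interval = 50,
                       patience = 24, seed = 5,
                       summary_mc_samples = 500)
  fit <- pmf_grn(sim$W, sim$prior, cfg, stopping = "iw_log_marginal")
  ev <- fit$trace$elbo[!is.na(fit$trace$metric)]
  expect_gte(length(ev), 20)
  expect_gt(mean(utils::tail(ev, 10)), mean(utils::head(ev, 10)))
})

test_that("fit requires overlapping genes between expression and prior", {
  toy <- make_toy()
  W2 <- unclass(toy$W)
  colnames(W2) <- paste0("other_", seq_len(ncol(W2)))
  expect_error(pmf_grn(expression_matrix(W2), toy$prior), "shared")
})
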