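# Independent oracles used to check the package's computations. These are
# deliberately naive (scalar loops, explicit threshold sweeps, quadrature)
# and share no code with the implementation under test.

logit_ <- function(p) log(p / (1 - p))

# Brute-force average precision: sweep every unique score as a threshold
# (descending), compute precision/recall at each, accumulate step-wise AP.
oracle_ap <- function(scores, labels) {
  labels <- as.numeric(labels != 0)
  stopifnot(sum(labels) > 0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    called <- scores >= t
    precision <- sum(labels[called]) / sum(called)
    recall <- sum(labels[called]) / sum(labels)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Scalar-by-scalar log-density of the prior at a constrained sample.
# Uses base R's dlnorm for the lognormal factors as an independent route.
oracle_prior_logpdf <- function(sample, prior_logits, cfg) {
  total <- 0
  for (x in as.vector(sample$U))
    total <- total + dlnorm(x, cfg$mu_u, cfg$sigma_u, log = TRUE)
  A <- sample$A
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    total <- total +
      dnorm(logit_(A[i, j]), prior_logits[i, j], cfg$sigma_a, log = TRUE) -
      log(A[i, j] * (1 - A[i, j]))
  for (x in as.vector(sample$B))
    total <- total + dnorm(x, 0, cfg$sigma_b, log = TRUE)
  for (x in sample$d)
    total <- total + dnorm(logit_(x), 0, cfg$d_prior_sd, log = TRUE) -
      log(x * (1 - x))
  total + dlnorm(sample$sigma_obs, cfg$o_prior_mean, cfg$o_prior_sd,
                 log = TRUE)
}

oracle_variational_logpdf <- function(sample, state) {
  total <- 0
  U <- sample$U
  for (i in seq_len(nrow(U))) for (j in seq_len(ncol(U)))
    total <- total + dlnorm(U[i, j], state$U_mean[i, j],
                            state$U_scale[i, j], log = TRUE)
  A <- sample$A
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    total <- total +
      dnorm(logit_(A[i, j]), state$A_mean[i, j], state$A_scale[i, j],
            log = TRUE) - log(A[i, j] * (1 - A[i, j]))
  B <- sample$B
  for (i in seq_len(nrow(B))) for (j in seq_len(ncol(B)))
    total <- total + dnorm(B[i, j], state$B_mean[i, j],
                           state$B_scale[i, j], log = TRUE)
  for (i in seq_along(sample$d))
    total <- total +
      dnorm(logit_(sample$d[i]), state$d_mean[i], state$d_scale[i],
            log = TRUE) - log(sample$d[i] * (1 - sample$d[i]))
  total + dlnorm(sample$sigma_obs, state$o_mean, state$o_scale, log = TRUE)
}

oracle_likelihood_logpdf <- function(W, sample) {
  V <- sample$A * sample$B
  total <- 0
  for (n in seq_len(nrow(W))) for (m in seq_len(ncol(W))) {
    mu <- sample$d[n] * sum(sample$U[n, ] * V[m, ])
    total <- total + dnorm(W[n, m], mu, sample$sigma_obs, log = TRUE)
  }
  total
}

# Gauss-Hermite moments of logistic(N(mu, sigma^2)).
gh_logistic_moments <- function(mu, sigma, n = 200) {
  gh <- pracma::gaussHermite(n)
  f <- plogis(mu + sqrt(2) * sigma * gh$x)
  m <- sum(gh$w * f) / sqrt(pi)
  v <- sum(gh$w * (f - m)^2) / sqrt(pi)
  c(mean = m, var = v)
}

# Random small variational state and a constrained sample drawn from it.
rand_state <- function(N, M, K) {
  st <- list(
    U_mean = matrix(rnorm(N * K), N, K),
    U_scale = matrix(runif(N * K, 0.2, 1.5), N, K),
    d_mean = rnorm(N), d_scale = runif(N, 0.2, 1.5),
    A_mean = matrix(rnorm(M * K), M, K),
    A_scale = matrix(runif(M * K, 0.2, 1.5), M, K),
    B_mean = matrix(rnorm(M * K), M, K),
    B_scale = matrix(runif(M * K, 0.2, 1.5), M, K),
    o_mean = rnorm(1), o_scale = runif(1, 0.2, 1.5))
  class(st) <- "pmfgrn_state"
  st
}

rand_binary_prior <- function(M, K, density = 0.3) {
  m <- matrix(as.numeric(runif(M * K) < density), M, K,
              dimnames = list(sprintf("g%02d", 1:M), sprintf("t%02d", 1:K)))
  m
}
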