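# The generative model's densities, transforms and prior construction.

test_that("prior clipping maps binary entries to the published bounds", {
  expect_equal(clip_prior(1, 0.005, 0.995), 0.995)
  expect_equal(clip_prior(0, 0.005, 0.995), 0.005)
  expect_equal(clip_prior(0.5, 0.005, 0.995), 0.5)
  expect_equal(clip_prior(c(0, 0.3, 1)), c(0.005, 0.3, 0.995))
  expect_error(clip_prior(0.5, 0.9, 0.1), "a_min")
})

test_that("prior logit means are antisymmetric in the binary prior", {
  pr <- prior_network(matrix(c(1, 0, 0, 1), 2, 2,
                             dimnames = list(c("g1", "g2"), c("t1", "t2"))))
  pl <- build_prior_logit_means(pr)
  expect_equal(pl["g1", "t1"], log(0.995 / 0.005), tolerance = 1e-12)
  expect_equal(pl["g1", "t1"], 5.2933, tolerance = 1e-4)
  expect_equal(pl["g2", "t1"], -log(0.995 / 0.005), tolerance = 1e-12)
  expect_equal(pl["g1", "t1"] + pl["g2", "t1"], 0)
  # antisymmetry under complementing the prior
  pl2 <- build_prior_logit_means(prior_network(1 - unclass(pr)))
  expect_equal(unclass(pl2), -unclass(pl), ignore_attr = TRUE)
  expect_error(build_prior_logit_means(matrix(0.5, 2, 2)), "binary")
})

test_that("interaction matrix is the elementwise product", {
  A <- matrix(c(0, 1, 0.5, 1), 2, 2)
  B <- matrix(c(3, -1, -2, 7), 2, 2)
  expect_equal(interaction_matrix(A, B), A * B)
  expect_equal(interaction_matrix(matrix(1, 2, 2), B), B)
  expect_equal(interaction_matrix(A, B)[1, 1], 0)
  expect_equal(interaction_matrix(A, B)[1, 2], -1)
  expect_error(interaction_matrix(A, matrix(0, 3, 2)), "dimensions")
})

test_that("likelihood log-density matches hand values and the scalar oracle", {
  s1 <- list(U = matrix(2, 1, 1), A = matrix(0.5, 1, 1),
             B = matrix(3, 1, 1), d = 0.5, sigma_obs = 1)
  w_exact <- 0.5 * 2 * 0.5 * 3
  expect_equal(likelihood_logpdf(matrix(w_exact, 1, 1,
                                        dimnames = list("c", "g")), s1),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(likelihood_logpdf(matrix(w_exact + 1, 1, 1,
                                        dimnames = list("c", "g")), s1),
               -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
  set.seed(11)
  st <- rand_state(3, 4, 2)
  z <- variational_sample(st, seed = 2)
  W <- matrix(abs(rnorm(12)), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  expect_equal(likelihood_logpdf(W, z), oracle_likelihood_logpdf(W, z),
               tolerance = 1e-10)
})

test_that("prior and variational log-densities match the brute-force oracle", {
  # a standard logistic-normal factor evaluated at 0.5: change of
  # variables gives -log(2*pi)/2 - log(0.25) ~ 0.4674
  expect_equal(dnorm(0, 0, 1, log = TRUE) - log(0.5 * 0.5), 0.4674,
               tolerance = 1e-4)

  set.seed(42)
  for (rep in 1:25) {
    N <- sample(1:4, 1); M <- sample(1:4, 1); K <- sample(1:4, 1)
    cfg <- pmfgrn_config(sigma_a = runif(1, 0.3, 2),
                         sigma_u = runif(1, 0.3, 2),
                         sigma_b = runif(1, 0.3, 2),
                         mu_u = rnorm(1))
    st <- rand_state(N, M, K)
    z <- variational_sample(st)
    pl <- matrix(rnorm(M * K), M, K)
    expect_equal(prior_logpdf(z, pl, cfg),
                 oracle_prior_logpdf(z, pl, cfg), tolerance = 1e-8)
    expect_equal(variational_logpdf(z, st),
                 oracle_variational_logpdf(z, st), tolerance = 1e-8)
  }
})

test_that("lognormal prior contribution at exp(mu_u) is the closed form", {
  cfg <- pmfgrn_config(mu_u = 0.7, sigma_u = 1, sigma_a = 1)
  z <- list(U = matrix(exp(0.7), 1, 1), A = matrix(0.5, 1, 1),
            B = matrix(0, 1, 1), d = 0.5, sigma_obs = 1)
  pl <- matrix(0, 1, 1)
  # subtract every other factor's known contribution to isolate U's
  full <- prior_logpdf(z, pl, cfg)
  others <- (-0.5 * log(2 * pi) - log(0.25)) +      # A at its prior mean
    (-0.5 * log(2 * pi)) +                          # B at 0
    (dnorm(0, 0, 3, log = TRUE) - log(0.25)) +      # d at 0.5
    (-0.5 * log(2 * pi))                            # sigma_obs at 1
  expect_equal(full - others, -0.5 * log(2 * pi) - 0.7, tolerance = 1e-10)
})

test_that("variational samples respect support and determinism", {
  set.seed(5)
  st <- rand_state(6, 5, 3)
  draws <- replicate(50, variational_sample(st), simplify = FALSE)
  for (z in draws) {
    expect_true(all(z$U > 0))
    expect_true(all(z$A > 0 & z$A < 1))
    expect_true(all(z$d > 0 & z$d < 1))
    expect_gt(z$sigma_obs, 0)
  }
  expect_identical(variational_sample(st, seed = 9),
                   variational_sample(st, seed = 9))
  # degenerate-scale limit: sample collapses to transformed means
  st0 <- st
  for (nm in c("U_scale", "d_scale", "A_scale", "B_scale", "o_scale"))
    st0[[nm]][] <- 1e-12
  z0 <- variational_sample(st0, seed = 3)
  expect_equal(z0$U, exp(st$U_mean), tolerance = 1e-9)
  expect_equal(z0$A, plogis(st$A_mean), tolerance = 1e-9)
  expect_equal(z0$B, st$B_mean, tolerance = 1e-9)
})

test_that("variational equals prior log-density when q is the prior", {
  cfg <- pmfgrn_config(sigma_a = 0.8, sigma_u = 1.3, mu_u = 0.2)
  pr <- prior_network(rand_binary_prior(4, 3))
  st <- init_variational_state(pr, 5, cfg)
  pl <- build_prior_logit_means(pr)
  for (seed in 1:5) {
    z <- variational_sample(st, seed = seed)
    expect_equal(variational_logpdf(z, st), prior_logpdf(z, pl, cfg),
                 tolerance = 1e-10)
  }
})

test_that("support violations raise errors rather than -Inf", {
  st <- rand_state(2, 2, 2)
  z <- variational_sample(st, seed = 1)
  z$U[1, 1] <- -1
  expect_error(variational_logpdf(z, st), "support")
  z2 <- variational_sample(st, seed = 1)
  z2$A[1, 1] <- 1.2
  expect_error(prior_logpdf(z2, matrix(0, 2, 2), pmfgrn_config()),
               "support")
})
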