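#' Model and optimizer configuration
#'
#' Collects every fixed and searchable constant of the model and of the
#' stochastic variational inference run. Defaults follow the published
#' settings of the method: Adam with learning rate 0.1 and moment decays
#' (0.9, 0.99), gradient norms clipped at 1e-4, prior clipping bounds
#' `a_min = 0.005`, `a_max = 0.995`, `sigma_b = 1`, `mu_u = 0`, a N(0, 9)
#' prior on the logit sequencing depth and a N(0, 1) prior on the log
#' observation noise. `sigma_a`, `sigma_u` and `beta` are the
#' hyperparameters intended to be searched over.
#'
#' @param sigma_a prior scale of logit A (strength of the prior network
#'   anchor; smaller = stronger anchor).
#' @param sigma_u prior scale of log U (TF activity spread).
#' @param beta ELBO weighting constant (>= 1); up-weights the prior and
#'   entropy terms relative to the likelihood to fight factor
#'   non-identifiability.
#' @param a_min,a_max clipping bounds applied to the binary prior before
#'   the logit transform, both in (0, 1) with `a_min < a_max`.
#' @param sigma_b prior scale of the interaction strength B.
#' @param mu_u prior mean of log U.
#' @param d_prior_sd prior SD of logit depth (fixed at 3, i.e. variance 9).
#' @param o_prior_mean,o_prior_sd prior for log observation noise (N(0,1)).
#' @param learning_rate,adam_beta1,adam_beta2 Adam settings.
#' @param grad_clip_norm global gradient-norm clip value.
#' @param batch_size cells per minibatch; full-batch when `>= N`.
#' @param elbo_mc_samples Monte Carlo samples per ELBO gradient estimate.
#' @param summary_mc_samples Monte Carlo samples for posterior summaries.
#' @param iw_samples importance samples for the marginal-likelihood
#'   early-stopping estimate.
#' @param holdout_fraction fraction of genes whose prior rows are masked
#'   for validation AUPRC (hyperparameter search).
#' @param max_steps,patience,eval_interval optimization schedule: cap on
#'   gradient steps, evaluations without improvement before stopping, and
#'   steps between stopping-metric evaluations.
#' @param seed integer seed controlling every random draw of a fit.
#' @return a list of class `"pmfgrn_config"`.
#' @export
pmfgrn_config <- function(sigma_a = 1, sigma_u = 1, beta = 1,
                          a_min = 0.005, a_max = 0.995,
                          sigma_b = 1, mu_u = 0,
                          d_prior_sd = 3,
                          o_prior_mean = 0, o_prior_sd = 1,
                          learning_rate = 0.1,
                          adam_beta1 = 0.9, adam_beta2 = 0.99,
                          grad_clip_norm = 1e-4,
                          batch_size = 1024L,
                          elbo_mc_samples = 1L,
                          summary_mc_samples = 2000L,
                          iw_samples = 10L,
                          holdout_fraction = 0.2,
                          max_steps = 20000L, patience = 20L,
                          eval_interval = 100L,
                          seed = 1L) {
  cfg <- list(sigma_a = sigma_a, sigma_u = sigma_u, beta = beta,
              a_min = a_min, a_max = a_max, sigma_b = sigma_b, mu_u = mu_u,
              d_prior_sd = d_prior_sd,
              o_prior_mean = o_prior_mean, o_prior_sd = o_prior_sd,
              learning_rate = learning_rate,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              grad_clip_norm = grad_clip_norm,
              batch_size = as.integer(batch_size),
              elbo_mc_samples = as.integer(elbo_mc_samples),
              summary_mc_samples = as.integer(summary_mc_samples),
              iw_samples = as.integer(iw_samples),
              holdout_fraction = holdout_fraction,
              max_steps = as.integer(max_steps),
              patience = as.integer(patience),
              eval_interval = as.integer(eval_interval),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pmfgrn_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("sigma_a", "sigma_u", "sigma_b", "d_prior_sd", "o_prior_sd",
           "learning_rate", "grad_clip_norm")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("configuration error: ", nm, " must be > 0")
  if (cfg$beta < 1) stop("configuration error: beta must be >= 1")
  if (!(cfg$a_min > 0 && cfg$a_min < cfg$a_max && cfg$a_max < 1))
    stop("configuration error: need 0 < a_min < a_max < 1")
  if (cfg$holdout_fraction <= 0 || cfg$holdout_fraction >= 1)
    stop("configuration error: holdout_fraction must be in (0, 1)")
  ints <- c("batch_size", "elbo_mc_samples", "summary_mc_samples",
            "iw_samples")
  for (nm in ints)
    if (cfg[[nm]] < 1) stop("configuration error: ", nm, " must be >= 1")
  if (cfg$max_steps < 0) stop("configuration error: max_steps must be >= 0")
  invisible(cfg)
}

#' @method print pmfgrn_config
#' @export
print.pmfgrn_config <- function(x, ...) {
  cat("pmfgrn configuration\n")
  cat(sprintf("  priors:    sigma_a=%g sigma_u=%g sigma_b=%g mu_u=%g beta=%g\n",
              x$sigma_a, x$sigma_u, x$sigma_b, x$mu_u, x$beta))
  cat(sprintf("  clipping:  a_min=%g a_max=%g\n", x$a_min, x$a_max))
  cat(sprintf("  optimizer: Adam lr=%g betas=(%g, %g) grad_clip=%g\n",
              x$learning_rate, x$adam_beta1, x$adam_beta2, x$grad_clip_norm))
  cat(sprintf("  schedule:  max_steps=%d eval_interval=%d patience=%d batch=%d\n",
              x$max_steps, x$eval_interval, x$patience, x$batch_size))
  cat(sprintf("  sampling:  elbo=%d summary=%d iw=%d seed=%d\n",
              x$elbo_mc_samples, x$summary_mc_samples, x$iw_samples, x$seed))
  invisible(x)
}

# Read a config from a YAML file of field = value pairs; unknown fields error.
#' Read a configuration from YAML
#'
#' @param path YAML file whose keys are [pmfgrn_config()] argument names.
#' @return a `pmfgrn_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pmfgrn_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration fields: ",
                        paste(bad, collapse = ", "))
  do.call(pmfgrn_config, vals)
}
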