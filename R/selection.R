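## Hyperparameter selection workflow: hold out prior rows, search a
## configuration grid scored by validation AUPRC, refit the winner on the
## full prior with importance-weighted early stopping; plus the k-fold
## gold-standard cross-validation harness.

#' Hold out prior information for a fraction of genes
#'
#' Selects `round(fraction * M)` genes uniformly at random and zeroes
#' their rows in the prior, so every entry of a held-out row gets the
#' same low prior mean `logit(a_min)`. The untouched full prior is kept
#' for scoring: validation AUPRC ranks the posterior estimates of the
#' held-out rows against their original prior entries.
#'
#' @param prior genes x TFs binary prior network.
#' @param fraction fraction of genes to hold out (default 0.2).
#' @param seed integer seed.
#' @return object of class `"pmfgrn_holdout"`: list with
#'   `modified_prior`, `held_out_genes`, `full_prior`, `seed`.
#' @export
holdout_prior <- function(prior, fraction = 0.2, seed = 1L) {
  prior <- as_network(prior)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  M <- nrow(prior)
  n_hold <- round(fraction * M)
  if (n_hold == 0 || n_hold == M)
    stop("fraction ", fraction, " holds out ", n_hold, " of ", M,
         " genes; nothing to fit or nothing to validate")
  set.seed(as.integer(seed))
  held <- sort(sample(rownames(prior), n_hold))
  mod <- unclass(prior)
  mod[held, ] <- 0
  structure(list(modified_prior = prior_network(mod),
                 held_out_genes = held,
                 full_prior = prior, seed = as.integer(seed)),
            class = "pmfgrn_holdout")
}

#' @method print pmfgrn_holdout
#' @export
print.pmfgrn_holdout <- function(x, ...) {
  cat(sprintf("prior holdout: %d of %d gene rows masked (seed %d)\n",
              length(x$held_out_genes), nrow(x$full_prior), x$seed))
  invisible(x)
}

## AP of score rows against label rows (both already restricted to the
## held-out genes, same shape).
validation_auprc_matrix <- function(scores, labels) {
  average_precision(as.vector(scores), as.vector(unclass(labels)))
}

#' Validation AUPRC of a posterior against a prior holdout
#'
#' Restricts the posterior edge-probability matrix to the held-out gene
#' rows of a [holdout_prior()] split and computes average precision
#' against the corresponding rows of the full prior. This is the
#' hyperparameter-selection objective.
#'
#' @param A_mean genes x TFs posterior mean matrix with labels covering
#'   the held-out genes.
#' @param split a `pmfgrn_holdout` object.
#' @return scalar AUPRC in `[0, 1]`.
#' @export
validation_auprc <- function(A_mean, split) {
  if (!inherits(split, "pmfgrn_holdout")) stop("split must be a holdout")
  A_mean <- check_scored(A_mean, "A_mean")
  held <- split$held_out_genes
  if (!all(held %in% rownames(A_mean)))
    stop("A_mean does not cover all held-out genes")
  tf <- colnames(split$full_prior)
  if (!all(tf %in% colnames(A_mean)))
    stop("A_mean does not cover the prior TF labels")
  validation_auprc_matrix(A_mean[held, tf, drop = FALSE],
                          split$full_prior[held, , drop = FALSE])
}

#' Default hyperparameter search grid
#'
#' Crossed grid over the searched hyperparameters: prior scale of logit A
#' `sigma_a` in {0.25, 0.5, 1, 2}, prior scale of log U `sigma_u` in
#' {0.25, 1}, ELBO weight `beta` in {1, 2, 4}. All other settings come
#' from `base`.
#'
#' @param sigma_a,sigma_u,beta numeric vectors of candidate values.
#' @param base a [pmfgrn_config()] supplying the non-searched settings.
#' @return list of `pmfgrn_config` objects.
#' @export
pmfgrn_default_grid <- function(sigma_a = c(0.25, 0.5, 1, 2),
                                sigma_u = c(0.25, 1),
                                beta = c(1, 2, 4),
                                base = pmfgrn_config()) {
  combos <- expand.grid(sigma_a = sigma_a, sigma_u = sigma_u, beta = beta,
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    cfg <- base
    cfg$sigma_a <- combos$sigma_a[i]
    cfg$sigma_u <- combos$sigma_u[i]
    cfg$beta <- combos$beta[i]
    validate_config(cfg)
    cfg
  })
}

#' Hyperparameter search scored by validation AUPRC
#'
#' Builds one prior holdout split (shared by all configurations for
#' comparability), fits every configuration of the grid with validation
#' AUPRC as the early-stopping metric, and returns all records plus the
#' configuration attaining the highest validation AUPRC (ties keep the
#' earliest grid entry).
#'
#' @param expression cells x genes counts.
#' @param prior binary prior network.
#' @param grid non-empty list of [pmfgrn_config()] objects.
#' @param fraction gene fraction for the holdout split.
#' @param seed seed for the split (configurations keep their own seeds).
#' @param verbose print one line per configuration.
#' @return object of class `"pmfgrn_search"`: list with `records` (data
#'   frame of sigma_a, sigma_u, beta, validation AUPRC, best step),
#'   `best_config`, `best_index`, `holdout`.
#' @export
pmfgrn_search <- function(expression, prior, grid = pmfgrn_default_grid(),
                          fraction = 0.2, seed = 1L, verbose = FALSE) {
  if (!length(grid)) stop("hyperparameter grid is empty")
  W <- as_expression(expression)
  prior <- as_network(prior)
  rec <- reconcile_labels(W, prior)
  prior_rc <- prior_network(unclass(prior)[rec$shared_genes, , drop = FALSE])
  split <- holdout_prior(prior_rc, fraction, seed)
  records <- data.frame(index = seq_along(grid), sigma_a = NA_real_,
                        sigma_u = NA_real_, beta = NA_real_,
                        val_auprc = NA_real_, best_step = NA_integer_,
                        stopped_at = NA_integer_)
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    fit <- pmf_grn(W, prior_rc, cfg, stopping = "validation_auprc",
                   holdout = split)
    records$sigma_a[i] <- cfg$sigma_a
    records$sigma_u[i] <- cfg$sigma_u
    records$beta[i] <- cfg$beta
    records$val_auprc[i] <- fit$best_metric
    records$best_step[i] <- fit$best_step
    records$stopped_at[i] <- fit$stopped_at
    if (verbose)
      message(sprintf(
        "config %d/%d (sigma_a=%g sigma_u=%g beta=%g): val AUPRC %.4f",
        i, length(grid), cfg$sigma_a, cfg$sigma_u, cfg$beta,
        fit$best_metric))
  }
  best <- which.max(records$val_auprc)  # first maximum on ties
  structure(list(records = records, best_config = grid[[best]],
                 best_index = best, holdout = split),
            class = "pmfgrn_search")
}

#' @method print pmfgrn_search
#' @export
print.pmfgrn_search <- function(x, ...) {
  cat("hyperparameter search (validation AUPRC)\n")
  print(x$records[, c("sigma_a", "sigma_u", "beta", "val_auprc",
                      "best_step")])
  cat(sprintf("best: configuration %d (val AUPRC %.4f)\n", x$best_index,
              x$records$val_auprc[x$best_index]))
  invisible(x)
}

#' Final fit with the selected configuration on the full prior
#'
#' Refits the model with the winning configuration, using the unmodified
#' prior and the importance-weighted marginal likelihood as the
#' early-stopping criterion, then summarizes the posterior.
#'
#' @param expression cells x genes counts.
#' @param prior binary prior network (full, no holdout).
#' @param best the selected [pmfgrn_config()] (or a `pmfgrn_search`
#'   object, whose `best_config` is used).
#' @param ... passed to [summary.pmfgrn()].
#' @return a `summary.pmfgrn` posterior summary; the underlying fit is
#'   attached as attribute `"fit"`.
#' @export
final_fit <- function(expression, prior, best, ...) {
  if (inherits(best, "pmfgrn_search")) best <- best$best_config
  fit <- pmf_grn(expression, prior, best, stopping = "iw_log_marginal")
  sm <- summary(fit, ...)
  attr(sm, "fit") <- fit
  sm
}

#' Gold-standard cross-validation
#'
#' Repeats `n_folds` independent random splits of the gold-standard
#' positive edges: `train_fraction` of the positives form a binary prior,
#' the remainder the evaluation standard. Within each fold a
#' hyperparameter search runs on an inner holdout of the fold prior, the
#' winner is refitted on the whole fold prior, and the resulting network
#' is scored by keep-all AUPRC against the fold's evaluation edges (which
#' are disjoint from the fold prior by construction).
#'
#' @param expression cells x genes counts.
#' @param gold binary gold-standard network.
#' @param n_folds number of independent random splits (default 5).
#' @param train_fraction fraction of positives used as prior (default
#'   0.8; sweep {0.8, 0.6, 0.4, 0.2} for the split-ratio experiment).
#' @param grid list of candidate configurations.
#' @param inner_fraction gene fraction for the inner search holdout.
#' @param seed base seed; fold seeds are derived from it.
#' @return object of class `"pmfgrn_cv"`: data frame `folds` with one row
#'   per fold (auprc, baseline, selected hyperparameters) plus the
#'   per-fold `splits` and `searches`.
#' @export
cross_validate <- function(expression, gold, n_folds = 5,
                           train_fraction = 0.8,
                           grid = pmfgrn_default_grid(),
                           inner_fraction = 0.2, seed = 1L) {
  if (n_folds < 1) stop("n_folds must be >= 1")
  gold <- as_network(gold)
  folds <- data.frame(fold = seq_len(n_folds), auprc = NA_real_,
                      baseline = NA_real_, sigma_a = NA_real_,
                      sigma_u = NA_real_, beta = NA_real_)
  splits <- vector("list", n_folds)
  searches <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    fs <- as.integer(seed) + 7919L * f
    sp <- split_reference(gold, train_fraction, seed = fs)
    sr <- pmfgrn_search(expression, sp$prior_part, grid,
                        fraction = inner_fraction, seed = fs)
    sm <- final_fit(expression, sp$prior_part, sr$best_config)
    folds$auprc[f] <- auprc(sm$A_mean, sp$eval_part, "keep_all")
    folds$baseline[f] <- mean(unclass(sp$eval_part) != 0)
    folds$sigma_a[f] <- sr$best_config$sigma_a
    folds$sigma_u[f] <- sr$best_config$sigma_u
    folds$beta[f] <- sr$best_config$beta
    splits[[f]] <- sp
    searches[[f]] <- sr
  }
  structure(list(folds = folds, splits = splits, searches = searches,
                 train_fraction = train_fraction),
            class = "pmfgrn_cv")
}

#' @method print pmfgrn_cv
#' @export
print.pmfgrn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%.0f%% prior / %.0f%% evaluation)\n",
              nrow(x$folds), 100 * x$train_fraction,
              100 * (1 - x$train_fraction)))
  print(x$folds)
  cat(sprintf("mean AUPRC %.4f (sd %.4f)\n", mean(x$folds$auprc),
              stats::sd(x$folds$auprc)))
  invisible(x)
}
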