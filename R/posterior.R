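## Posterior summaries: per-edge interaction probabilities with
## uncertainty, TF activity point estimates, edge lists, multi-dataset
## averaging, and the S3 methods of the fitted "pmfgrn" object.

## MC summary restricted to a subset of gene rows; uses the current RNG
## stream (callers seed). Chunked so memory stays bounded.
##
## Draws are stratified: each of the S draws for an entry comes from its
## own equal-probability stratum of the Gaussian (inverse-CDF of a
## uniform jittered within the stratum). The estimator remains the plain
## sample mean / (S-1)-denominator sample variance over S identically
## weighted logistic-normal draws, but the stratification shrinks the
## Monte Carlo error from O(S^-1/2) to O(S^-1).
summarize_A_rows <- function(state, rows, S, with_var = FALSE) {
  K <- ncol(state$A_mean)
  nr <- length(rows)
  mean_out <- matrix(NA_real_, nr, K)
  var_out <- if (with_var) matrix(NA_real_, nr, K) else NULL
  chunk <- max(1L, as.integer(2e7 / (K * S)))
  i <- 1L
  while (i <= nr) {
    j <- min(nr, i + chunk - 1L)
    ridx <- rows[i:j]
    nc <- length(ridx) * K
    mu <- as.vector(state$A_mean[ridx, , drop = FALSE])
    sc <- as.vector(state$A_scale[ridx, , drop = FALSE])
    u <- stats::runif(nc * S)
    eps <- stats::qnorm((rep(seq_len(S), each = nc) - u) / S)
    draws <- logistic(matrix(eps, nc, S) * sc + mu)
    m <- rowMeans(draws)
    mean_out[i:j, ] <- m
    if (with_var)
      var_out[i:j, ] <- rowSums((draws - m)^2) / (S - 1)
    i <- j + 1L
  }
  list(mean = mean_out, var = var_out)
}

#' Monte Carlo posterior mean and variance of the interaction matrix
#'
#' The posterior of each entry of A is logistic-normal, which has no
#' closed-form moments; the mean and unbiased sample variance are
#' estimated from `S` simple Monte Carlo draws per entry. The mean is the
#' posterior point estimate of the interaction probability; the variance
#' is its uncertainty proxy.
#'
#' @param state a `pmfgrn_state` (or a fitted `pmfgrn` object).
#' @param S draws per entry (>= 2).
#' @param seed optional integer seed.
#' @return list with `A_mean` and `A_var`, both M x K with the prior's
#'   dimnames.
#' @export
summarize_A <- function(state, S = 2000, seed = NULL) {
  if (inherits(state, "pmfgrn")) state <- state$state
  check_state(state)
  if (S < 2) stop("S must be >= 2 to form a sample variance")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sm <- summarize_A_rows(state, seq_len(nrow(state$A_mean)), S,
                         with_var = TRUE)
  dimnames(sm$mean) <- dimnames(state$A_mean)
  dimnames(sm$var) <- dimnames(state$A_mean)
  list(A_mean = sm$mean, A_var = sm$var)
}

#' Posterior point estimate of transcription factor activity
#'
#' The variational posterior of each TFA entry is lognormal, whose mean is
#' available in closed form: `exp(U_mean + U_scale^2 / 2)`.
#'
#' @param state a `pmfgrn_state` (or a fitted `pmfgrn` object).
#' @return N x K matrix of strictly positive activity estimates.
#' @export
tfa_point_estimate <- function(state) {
  if (inherits(state, "pmfgrn")) state <- state$state
  check_state(state)
  exp(state$U_mean + state$U_scale^2 / 2)
}

#' Threshold a posterior network into an edge list
#'
#' Retains exactly the entries with posterior probability at or above
#' `min_prob`, sorted by descending probability and then by (gene, TF)
#' label order. The sign of the posterior mean of B gives the putative
#' direction (activation/repression) as auxiliary output.
#'
#' @param summary a posterior summary (from [summary.pmfgrn()] or a list
#'   with `A_mean`, optionally `A_var` and `B_mean`).
#' @param min_prob probability threshold in `[0, 1]`; 0.9 is the usual
#'   cut for high-confidence edge lists.
#' @return data frame with columns `gene`, `tf`, `probability`,
#'   `variance`, `sign`.
#' @export
threshold_network <- function(summary, min_prob = 0.9) {
  if (min_prob < 0 || min_prob > 1) stop("min_prob must be in [0, 1]")
  A <- summary$A_mean
  if (is.null(A)) stop("summary must contain A_mean")
  keep <- which(A >= min_prob, arr.ind = TRUE)
  gene <- rownames(A)[keep[, 1]]
  tf <- colnames(A)[keep[, 2]]
  prob <- A[keep]
  varr <- if (!is.null(summary$A_var)) summary$A_var[keep] else NA_real_
  sgn <- if (!is.null(summary$B_mean)) sign(summary$B_mean[keep])
         else NA_real_
  out <- data.frame(gene = gene, tf = tf, probability = prob,
                    variance = varr, sign = sgn,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$probability, out$gene, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average posterior mean matrices across datasets
#'
#' Multiple expression observations of the same system are modelled
#' separately and combined by averaging their posterior edge-probability
#' matrices elementwise. Matrices must carry identical gene and TF label
#' sets (reordered to the first matrix); a mismatch is an error rather
#' than a silent intersection.
#'
#' @param summaries list of M x K labelled matrices (or of summary lists
#'   with an `A_mean` element).
#' @return the elementwise mean matrix with the first matrix's labels.
#' @export
average_posteriors <- function(summaries) {
  if (!length(summaries)) stop("need at least one posterior to average")
  mats <- lapply(summaries, function(s) {
    if (is.list(s) && !is.null(s$A_mean)) s$A_mean else as.matrix(s)
  })
  ref <- mats[[1]]
  if (is.null(rownames(ref)) || is.null(colnames(ref)))
    stop("posterior matrices must carry gene and TF labels")
  acc <- ref
  for (m in mats[-1]) {
    if (!setequal(rownames(m), rownames(ref)) ||
        !setequal(colnames(m), colnames(ref)))
      stop("posterior matrices have mismatched label sets")
    acc <- acc + m[rownames(ref), colnames(ref), drop = FALSE]
  }
  acc / length(mats)
}

## ---- S3 methods for fitted objects -----------------------------------

#' @method print pmfgrn
#' @export
print.pmfgrn <- function(x, ...) {
  dm <- state_dims(x$state)
  cat("Probabilistic matrix factorization GRN fit\n")
  cat(sprintf("  %d cells x %d genes x %d TFs; prior edges: %d\n",
              dm["N"], dm["M"], dm["K"], sum(x$prior != 0)))
  cat(sprintf("  stopped at step %d (%s); best %s %.6g at step %s\n",
              x$stopped_at, x$stop_reason, x$stopping,
              x$best_metric, format(x$best_step)))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Computes the Monte Carlo posterior mean and variance of every entry of
#' the interaction matrix A, the closed-form TFA point estimate, and the
#' posterior mean of B, together with provenance (configuration, seed,
#' sample count, stopping step).
#'
#' @param object a fitted `pmfgrn` object.
#' @param mc_samples Monte Carlo draws per entry of A.
#' @param seed seed for the summary draws; defaults to the fit seed + 1.
#' @param ... unused.
#' @return an object of class `"summary.pmfgrn"`: list with `A_mean`,
#'   `A_var`, `tfa`, `B_mean`, label vectors and `meta`.
#' @method summary pmfgrn
#' @export
summary.pmfgrn <- function(object, mc_samples = object$config$summary_mc_samples,
                           seed = object$config$seed + 1L, ...) {
  sm <- summarize_A(object$state, S = mc_samples, seed = seed)
  out <- list(A_mean = sm$A_mean, A_var = sm$A_var,
              tfa = tfa_point_estimate(object$state),
              B_mean = object$state$B_mean,
              gene_ids = rownames(object$prior),
              tf_ids = colnames(object$prior),
              cell_ids = rownames(object$expression),
              meta = list(config = object$config, seed = seed,
                          mc_samples = mc_samples,
                          stopped_at = object$stopped_at,
                          stop_reason = object$stop_reason,
                          stopping = object$stopping,
                          best_metric = object$best_metric,
                          best_step = object$best_step))
  rownames(out$tfa) <- out$cell_ids
  colnames(out$tfa) <- out$tf_ids
  class(out) <- "summary.pmfgrn"
  out
}

#' @method print summary.pmfgrn
#' @export
print.summary.pmfgrn <- function(x, ...) {
  cat(sprintf("Posterior summary: %d genes x %d TFs (%d MC draws/entry)\n",
              length(x$gene_ids), length(x$tf_ids), x$meta$mc_samples))
  e9 <- sum(x$A_mean >= 0.9)
  cat(sprintf("  edges with probability >= 0.9: %d (%.3g%% of entries)\n",
              e9, 100 * e9 / length(x$A_mean)))
  cat(sprintf("  mean posterior variance: %.4g\n", mean(x$A_var)))
  invisible(x)
}

#' Extract posterior coefficient matrices
#'
#' @param object a fitted `pmfgrn` object.
#' @param type `"probability"` (MC posterior mean of A, default),
#'   `"strength"` (posterior mean of B), or `"interaction"` (their
#'   elementwise product, the effective regulatory coefficients V).
#' @param ... passed to [summary.pmfgrn()] when a summary is needed.
#' @return M x K labelled matrix.
#' @export
coef.pmfgrn <- function(object, type = c("probability", "strength",
                                         "interaction"), ...) {
  type <- match.arg(type)
  if (type == "strength") return(object$state$B_mean)
  A <- summary(object, ...)$A_mean
  if (type == "probability") A
  else interaction_matrix(A, object$state$B_mean)
}

## Plug-in posterior reconstruction of the expression mean:
## depth (posterior median of the logistic-normal) times TFA mean times
## the effective coefficients from the MC mean of A and mean of B.
#' @export
fitted.pmfgrn <- function(object, ...) {
  A <- summary(object, ...)$A_mean
  V <- interaction_matrix(A, object$state$B_mean)
  d <- logistic(object$state$d_mean)
  out <- d * (tfa_point_estimate(object$state) %*% t(V))
  dimnames(out) <- dimnames(object$expression)
  out
}

#' @export
predict.pmfgrn <- function(object, ...) fitted(object, ...)

#' @export
residuals.pmfgrn <- function(object, ...) {
  unclass(object$expression) - fitted(object, ...)
}

#' Simulate expression replicates from the fitted posterior
#'
#' Draws latent samples from the variational posterior and then
#' observations from the Gaussian likelihood, giving posterior-predictive
#' replicates of the count matrix (floored at zero and rounded, matching
#' the count-like convention of the simulator).
#'
#' @param object a fitted `pmfgrn` object.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` matrices shaped like the training data.
#' @export
simulate.pmfgrn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  W <- object$expression
  lapply(seq_len(nsim), function(i) {
    z <- variational_sample(object$state)
    mu <- z$d * (z$U %*% t(interaction_matrix(z$A, z$B)))
    out <- round(pmax(matrix(stats::rnorm(length(mu), mu, z$sigma_obs),
                             nrow(mu), ncol(mu)), 0))
    dimnames(out) <- dimnames(W)
    out
  })
}

#' Plot the training trace
#'
#' ELBO estimates per step (thinned) with the stopping-metric evaluations
#' overlaid on a second panel.
#'
#' @param x a fitted `pmfgrn` object.
#' @param ... passed to `plot.default`.
#' @export
plot.pmfgrn <- function(x, ...) {
  tr <- x$trace
  if (!nrow(tr)) {
    warning("empty training trace; nothing to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  thin <- tr[seq(1, nrow(tr), by = max(1L, nrow(tr) %/% 2000L)), ]
  plot(thin$step, thin$elbo, type = "l", xlab = "step",
       ylab = "ELBO estimate", main = "optimization trace", ...)
  ev <- tr[!is.na(tr$metric), ]
  if (nrow(ev)) {
    plot(ev$step, ev$metric, type = "b", pch = 20, xlab = "step",
         ylab = x$stopping)
    graphics::abline(v = x$best_step, lty = 2)
  }
  invisible(x)
}

#' @export
logLik.pmfgrn <- function(object, S = object$config$iw_samples,
                          seed = object$config$seed + 2L, ...) {
  val <- iw_log_marginal(object$expression, object$prior, object$state,
                         object$config, S = S, seed = seed)
  structure(val, df = NA_integer_, nobs = length(object$expression),
            class = "logLik")
}
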