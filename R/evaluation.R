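## Evaluation metrics and robustness protocols.
##
## AUPRC here is step-wise average precision: thresholds sweep the unique
## score values in descending order, tied scores form a single threshold
## group, and AP = sum_k (R_k - R_{k-1}) * P_k. No interpolation. A
## constant predictor therefore scores exactly the positive rate.

## scores: numeric (may contain -Inf); labels: 0/1. Scalar AP.
average_precision <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pos <- sum(labels != 0)
  if (pos == 0) stop("AUPRC undefined: no positives among evaluated pairs")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- as.numeric(labels[ord] != 0)
  ends <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[ends]
  prec <- tp / ends
  rec <- tp / pos
  sum(diff(c(0, rec)) * prec)
}

#' Area under the precision-recall curve for a scored network
#'
#' Scores a predicted network against a binary gold standard. Two
#' conventions handle the imperfect overlap between predicted and gold
#' label sets: `"keep_all"` evaluates every pair of the gold standard,
#' ranking gold pairs absent from the prediction last (score `-Inf`);
#' `"overlap"` evaluates only pairs present in both matrices.
#'
#' @param pred genes x TFs numeric score matrix with labels (e.g.
#'   posterior `A_mean`).
#' @param gold genes x TFs binary gold-standard matrix with labels.
#' @param mode `"keep_all"` or `"overlap"`.
#' @return scalar average precision in `[0, 1]`.
#' @export
auprc <- function(pred, gold, mode = c("keep_all", "overlap")) {
  mode <- match.arg(mode)
  pred <- check_scored(pred, "pred")
  gold <- as_network(gold)
  if (mode == "keep_all") {
    scores <- matrix(-Inf, nrow(gold), ncol(gold), dimnames = dimnames(gold))
    gi <- intersect(rownames(gold), rownames(pred))
    ti <- intersect(colnames(gold), colnames(pred))
    scores[gi, ti] <- pred[gi, ti]
    average_precision(as.vector(scores), as.vector(unclass(gold)))
  } else {
    gi <- intersect(rownames(gold), rownames(pred))
    ti <- intersect(colnames(gold), colnames(pred))
    if (!length(gi) || !length(ti))
      stop("no overlapping labels between prediction and gold standard")
    average_precision(as.vector(pred[gi, ti, drop = FALSE]),
                      as.vector(unclass(gold)[gi, ti, drop = FALSE]))
  }
}

#' Random-baseline AUPRC ratio
#'
#' Convenience wrapper: [auprc()] divided by the positive rate of the
#' evaluated pair set (the expected AP of a random ranking).
#'
#' @inheritParams auprc
#' @return list with `auprc`, `baseline` (positive rate) and `ratio`.
#' @export
auprc_ratio <- function(pred, gold, mode = c("keep_all", "overlap")) {
  mode <- match.arg(mode)
  ap <- auprc(pred, gold, mode)
  gold <- as_network(gold)
  pred <- check_scored(pred, "pred")
  if (mode == "keep_all") {
    base <- mean(unclass(gold) != 0)
  } else {
    gi <- intersect(rownames(gold), rownames(pred))
    ti <- intersect(colnames(gold), colnames(pred))
    base <- mean(unclass(gold)[gi, ti] != 0)
  }
  list(auprc = ap, baseline = base, ratio = ap / base)
}

#' Cumulative-variance calibration curve
#'
#' Sorts posterior entries by ascending posterior variance (stable
#' tie-break by gene then TF label) and forms `n_bins` cumulative bins:
#' the lowest 1/n, 2/n, ... fractions. Each bin is scored with overlap
#' AUPRC against the gold standard, so bins are not penalized for pairs
#' absent from the gold standard. For a calibrated posterior the AUPRC
#' should decline as higher-variance entries are admitted.
#'
#' @param summary a posterior summary with `A_mean` and `A_var`.
#' @param gold binary gold-standard network.
#' @param n_bins number of cumulative bins (default 10: deciles).
#' @return object of class `"pmfgrn_calibration"`: list with
#'   `bin_fractions`, `bin_auprc` (NA where the bin holds no gold
#'   positives), `bin_sizes`, `bin_defined`.
#' @export
calibration_curve <- function(summary, gold, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  A <- summary$A_mean; V <- summary$A_var
  if (is.null(A) || is.null(V)) stop("summary must contain A_mean and A_var")
  gold <- as_network(gold)
  n <- length(A)
  genes <- rownames(A)[row(A)]
  tfs <- colnames(A)[col(A)]
  ord <- order(as.vector(V), genes, tfs)
  gv <- genes[ord]; tv <- tfs[ord]; sv <- as.vector(A)[ord]
  in_gold <- gv %in% rownames(gold) & tv %in% colnames(gold)
  lab <- rep(NA_real_, n)
  lab[in_gold] <- unclass(gold)[cbind(gv[in_gold], tv[in_gold])]
  fractions <- seq_len(n_bins) / n_bins
  sizes <- ceiling(fractions * n)
  ap <- rep(NA_real_, n_bins)
  defined <- logical(n_bins)
  for (j in seq_len(n_bins)) {
    sel <- seq_len(sizes[j])
    sel <- sel[in_gold[sel]]
    if (length(sel) && any(lab[sel] != 0)) {
      ap[j] <- average_precision(sv[sel], lab[sel])
      defined[j] <- TRUE
    }
  }
  structure(list(bin_fractions = fractions, bin_auprc = ap,
                 bin_sizes = sizes, bin_defined = defined),
            class = "pmfgrn_calibration")
}

#' @method print pmfgrn_calibration
#' @export
print.pmfgrn_calibration <- function(x, ...) {
  cat("cumulative variance calibration curve\n")
  print(data.frame(fraction = x$bin_fractions, size = x$bin_sizes,
                   auprc = round(x$bin_auprc, 4)))
  invisible(x)
}

#' Intersection-over-union of two networks' top edges
#'
#' Ranks each network's entries by score (ties broken by gene then TF
#' label), keeps the top `round(top_fraction * M * K)` pairs from each,
#' and returns |intersection| / |union| of the two edge sets. Used to
#' quantify agreement between networks inferred from different datasets.
#'
#' @param a,b genes x TFs score matrices over identical label sets.
#' @param top_fraction fraction of all entries retained (default 0.25).
#' @return scalar IoU in `[0, 1]`.
#' @export
iou_top_edges <- function(a, b, top_fraction = 0.25) {
  a <- check_scored(a, "a"); b <- check_scored(b, "b")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (!setequal(rownames(a), rownames(b)) ||
      !setequal(colnames(a), colnames(b)))
    stop("networks have mismatched label sets")
  b <- b[rownames(a), colnames(a), drop = FALSE]
  n_top <- round(top_fraction * length(a))
  if (n_top < 1) stop("top_fraction selects no edges")
  top_set <- function(m) {
    genes <- rownames(m)[row(m)]
    tfs <- colnames(m)[col(m)]
    ord <- order(-as.vector(m), genes, tfs)
    paste(genes[ord[seq_len(n_top)]], tfs[ord[seq_len(n_top)]], sep = "\r")
  }
  ea <- top_set(a); eb <- top_set(b)
  length(intersect(ea, eb)) / length(union(ea, eb))
}

#' Shuffled-prior negative control
#'
#' Randomly permutes the rows of the prior while leaving the gene labels
#' attached to the row positions, so each gene receives another gene's
#' prior hyperparameters. Inference with a shuffled prior should perform
#' near chance; the gap to the true prior measures the prior's utility.
#'
#' @param prior genes x TFs binary network.
#' @param seed integer seed for the permutation.
#' @return a `prior_network` with misassigned rows.
#' @export
shuffle_prior <- function(prior, seed = 1L) {
  prior <- as_network(prior)
  if (nrow(prior) < 2) stop("need at least two genes to shuffle")
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(prior))
  out <- unclass(prior)[perm, , drop = FALSE]
  rownames(out) <- rownames(prior)
  prior_network(out)
}

#' Empty-prior (no prior) negative control
#'
#' All entries set to zero, labels preserved; every edge prior mean
#' becomes `logit(a_min)`.
#'
#' @param prior genes x TFs binary network.
#' @return an all-zero `prior_network` of the same shape.
#' @export
empty_prior <- function(prior) {
  prior <- as_network(prior)
  out <- unclass(prior) * 0
  prior_network(out)
}

#' Inject false-positive noise into a prior network
#'
#' Adds `round(noise_level * P)` new edges (P = current positive count)
#' at uniformly sampled zero entries, without replacement; original edges
#' are untouched. Starting from 1% density, levels 1.0 / 2.5 / 5.0 yield
#' 2% / 3.5% / 6% density.
#'
#' @param prior genes x TFs binary network.
#' @param noise_level non-negative multiple of the original edge count.
#' @param seed integer seed.
#' @return a noisier `prior_network`.
#' @export
inject_noise <- function(prior, noise_level, seed = 1L) {
  prior <- as_network(prior)
  if (noise_level < 0) stop("noise_level must be >= 0")
  n_new <- round(noise_level * sum(prior != 0))
  if (n_new == 0) return(prior)
  zeros <- which(unclass(prior) == 0)
  if (length(zeros) < n_new)
    stop("not enough zero entries to host ", n_new, " noise edges")
  set.seed(as.integer(seed))
  out <- unclass(prior)
  out[sample(zeros, n_new)] <- 1
  prior_network(out)
}

#' Downsample cells of an expression matrix
#'
#' Uniform sampling without replacement of `round(fraction * N)` cells;
#' the gene axis is untouched.
#'
#' @param W cells x genes expression matrix.
#' @param fraction fraction of cells retained, in (0, 1].
#' @param seed integer seed.
#' @return an `expression_matrix` with fewer rows.
#' @export
downsample_cells <- function(W, fraction, seed = 1L) {
  W <- as_expression(W)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- round(fraction * nrow(W))
  if (n < 1) stop("fraction selects zero cells")
  set.seed(as.integer(seed))
  keep <- sort(sample.int(nrow(W), n))
  expression_matrix(unclass(W)[keep, , drop = FALSE])
}

#' Split a reference network into prior and evaluation halves
#'
#' Partitions the positive edges uniformly at random:
#' `round(prior_fraction * P)` go to the prior part, the rest to the
#' evaluation part; the two are disjoint and their union is the input.
#' With `prior_fraction = 0.5` this is the reference-GRN split used for
#' synthetic benchmarks; 0.8 reproduces the cross-validation split.
#'
#' @param gold genes x TFs binary reference network.
#' @param prior_fraction fraction of positives assigned to the prior.
#' @param seed integer seed.
#' @return list with `prior_part` and `eval_part` (`prior_network`s).
#' @export
split_reference <- function(gold, prior_fraction = 0.5, seed = 1L) {
  gold <- as_network(gold)
  if (prior_fraction <= 0 || prior_fraction >= 1)
    stop("prior_fraction must be in (0, 1)")
  pos <- which(unclass(gold) != 0)
  if (length(pos) < 2) stop("need at least two positive edges to split")
  n_prior <- round(prior_fraction * length(pos))
  if (n_prior == 0 || n_prior == length(pos))
    stop("prior_fraction leaves one side empty")
  set.seed(as.integer(seed))
  take <- sample(pos, n_prior)
  pp <- unclass(gold) * 0; pp[take] <- 1
  ep <- unclass(gold); ep[take] <- 0
  list(prior_part = prior_network(pp), eval_part = prior_network(ep))
}

## ---- experiment drivers ----------------------------------------------

#' Prior noise-robustness sweep
#'
#' For each noise level and repetition, injects false edges into the
#' prior with a distinct seed, refits the model (importance-weighted
#' early stopping) and scores the posterior against the gold standard
#' with keep-all AUPRC.
#'
#' @param expression cells x genes counts.
#' @param prior binary prior network.
#' @param gold binary gold standard.
#' @param levels noise levels (multiples of the prior edge count).
#' @param config a [pmfgrn_config()].
#' @param n_reps repetitions per level.
#' @param seed base seed; level/repetition seeds are derived from it.
#' @return data frame with columns `level`, `rep`, `density`, `auprc`.
#' @export
noise_sweep <- function(expression, prior, gold,
                        levels = c(0, 1, 2.5, 5), config = pmfgrn_config(),
                        n_reps = 5, seed = 1L) {
  rows <- list()
  for (li in seq_along(levels)) {
    for (r in seq_len(n_reps)) {
      s <- as.integer(seed) + 1000L * li + r
      pr <- inject_noise(prior, levels[li], seed = s)
      cfg <- config; cfg$seed <- s
      fit <- pmf_grn(expression, pr, cfg, stopping = "iw_log_marginal")
      sm <- summary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        level = levels[li], rep = r, density = mean(unclass(pr) != 0),
        auprc = auprc(sm$A_mean, gold, "keep_all"))
    }
  }
  do.call(rbind, rows)
}

#' Expression downsampling sweep
#'
#' For each retained-cell fraction and repetition, downsamples the cells
#' with a distinct seed, runs hyperparameter search on an 80/20 prior
#' holdout, refits with the selected configuration and scores against the
#' gold standard with keep-all AUPRC.
#'
#' @inheritParams noise_sweep
#' @param fractions cell fractions to retain.
#' @param grid list of [pmfgrn_config()] objects to search over.
#' @return data frame with columns `fraction`, `rep`, `n_cells`, `auprc`.
#' @export
downsample_sweep <- function(expression, prior, gold,
                             fractions = c(0.8, 0.6, 0.4, 0.2),
                             grid = pmfgrn_default_grid(),
                             n_reps = 5, seed = 1L) {
  rows <- list()
  for (fi in seq_along(fractions)) {
    for (r in seq_len(n_reps)) {
      s <- as.integer(seed) + 1000L * fi + r
      Wd <- downsample_cells(expression, fractions[fi], seed = s)
      sr <- pmfgrn_search(Wd, prior, grid, fraction = 0.2, seed = s)
      sm <- final_fit(Wd, prior, sr$best_config)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fractions[fi], rep = r, n_cells = nrow(Wd),
        auprc = auprc(sm$A_mean, gold, "keep_all"))
    }
  }
  do.call(rbind, rows)
}
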