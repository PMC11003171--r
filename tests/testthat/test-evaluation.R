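# Metrics and perturbation protocols: average precision against a
# brute-force sweep, calibration bins, IoU, prior controls, noise
# injection, downsampling and reference splitting.

scored <- function(m, genes = NULL, tfs = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(tfs)) tfs <- sprintf("t%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, tfs)
  m
}

test_that("average precision matches the brute-force threshold sweep", {
  # worked example: scores [0.9, 0.4, 0.35, 0.1], labels [1, 0, 1, 0]
  pred <- scored(matrix(c(0.9, 0.4, 0.35, 0.1), 4, 1))
  gold <- scored(matrix(c(1, 0, 1, 0), 4, 1))
  expect_equal(auprc(pred, gold, "overlap"), 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-12)
  expect_equal(auprc(pred, gold, "overlap"), 0.8333, tolerance = 1e-4)

  # perfect ranking
  expect_equal(auprc(scored(matrix(c(4, 3, 2, 1), 4, 1)),
                     scored(matrix(c(1, 1, 0, 0), 4, 1)), "overlap"), 1)

  # 200 random instances with heavy ties, exact agreement with oracle
  set.seed(17)
  for (i in 1:200) {
    n <- sample(2:25, 1)
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    y <- as.numeric(runif(n) < 0.4)
    if (sum(y) == 0) y[sample.int(n, 1)] <- 1
    pred <- scored(matrix(s, n, 1))
    gold <- scored(matrix(y, n, 1))
    expect_equal(auprc(pred, gold, "overlap"), oracle_ap(s, y),
                 tolerance = 1e-12)
  }

  # constant scores collapse to one tie group: AP = positive rate
  s <- rep(0.5, 20); y <- c(rep(1, 6), rep(0, 14))
  expect_equal(auprc(scored(matrix(s, 20, 1)), scored(matrix(y, 20, 1)),
                     "overlap"), 0.3, tolerance = 1e-12)
  expect_error(auprc(scored(matrix(1, 2, 1)), scored(matrix(0, 2, 1))),
               "no positives")
})

test_that("keep-all AUPRC ranks unpredicted gold pairs last", {
  gold <- scored(matrix(c(1, 1, 0, 0), 4, 1))
  # prediction covers only the first three genes
  pred <- scored(matrix(c(0.1, 0.9, 0.5), 3, 1),
                 genes = rownames(gold)[1:3])
  ka <- auprc(pred, gold, "keep_all")
  # equivalent explicit construction: missing gene g04 scored -Inf
  expect_equal(ka, oracle_ap(c(0.1, 0.9, 0.5, -Inf), c(1, 1, 0, 0)),
               tolerance = 1e-12)
  ov <- auprc(pred, gold, "overlap")
  expect_equal(ov, oracle_ap(c(0.1, 0.9, 0.5), c(1, 1, 0)),
               tolerance = 1e-12)
  rr <- auprc_ratio(pred, gold, "keep_all")
  expect_equal(rr$baseline, 0.5)
  expect_equal(rr$ratio, ka / 0.5)
})

test_that("calibration bins are cumulative deciles with exact sizes", {
  set.seed(23)
  M <- 30; K <- 4
  A <- scored(matrix(runif(M * K), M, K))
  V <- scored(matrix(runif(M * K), M, K))
  gold <- scored(matrix(as.numeric(runif(M * K) < 0.2), M, K))
  sm <- list(A_mean = A, A_var = V)
  cal <- calibration_curve(sm, gold, n_bins = 10)
  expect_equal(cal$bin_fractions, seq(0.1, 1, by = 0.1))
  expect_equal(cal$bin_sizes, ceiling(seq_len(10) * M * K / 10))
  # last bin contains everything: equals overall overlap AUPRC
  expect_equal(cal$bin_auprc[10], auprc(A, gold, "overlap"),
               tolerance = 1e-12)

  # constructed fixture: low-variance edges perfectly ranked, the rest
  # random -> first bin is perfect
  A2 <- A; V2 <- V
  ord <- order(as.vector(V2))
  low <- ord[1:12]
  g2 <- unclass(gold)
  g2[low] <- 0; g2[low[1:4]] <- 1
  A2[low] <- 0.1; A2[low[1:4]] <- 0.9
  cal2 <- calibration_curve(list(A_mean = A2, A_var = V2),
                            scored(g2, rownames(gold), colnames(gold)),
                            n_bins = 10)
  expect_equal(cal2$bin_auprc[1], 1.0)
})

test_that("IoU of top edges handles identity, disjointness and overlap", {
  a <- scored(matrix(c(4, 3, 2, 1), 2, 2))
  expect_equal(iou_top_edges(a, a, 0.5), 1.0)
  b <- scored(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(iou_top_edges(a, b, 0.5), 0.0)
  # top-2 sets {e1,e2} vs {e2,e3}: intersection 1, union 3
  c_ <- scored(matrix(c(1, 4, 3, 2), 2, 2))
  expect_equal(iou_top_edges(a, c_, 0.5), 1 / 3)
  # symmetry
  set.seed(9)
  x <- scored(matrix(rnorm(40), 10, 4))
  y <- scored(matrix(rnorm(40), 10, 4))
  expect_equal(iou_top_edges(x, y, 0.25), iou_top_edges(y, x, 0.25))
  colnames(y) <- paste0("z", 1:4)
  expect_error(iou_top_edges(x, y), "mismatch")
})

test_that("prior controls: shuffling preserves content, emptying removes it", {
  set.seed(31)
  pr <- prior_network(rand_binary_prior(12, 3, 0.3))
  sh <- shuffle_prior(pr, seed = 4)
  expect_identical(rownames(sh), rownames(pr))
  expect_equal(sum(sh), sum(pr))
  expect_equal(unname(sort(rowSums(unclass(sh)))),
               unname(sort(rowSums(unclass(pr)))))
  expect_identical(unclass(shuffle_prior(pr, seed = 4)),
                   unclass(sh))
  ep <- empty_prior(pr)
  expect_equal(sum(ep), 0)
  expect_identical(dimnames(ep), dimnames(pr))
  expect_identical(unclass(empty_prior(ep)), unclass(ep))
})

test_that("noise injection adds exactly the requested edge multiples", {
  set.seed(41)
  pr <- prior_network(rand_binary_prior(100, 20, 0.02))
  p0 <- sum(pr)
  for (lv in c(0, 0.5, 1, 2.5)) {
    out <- inject_noise(pr, lv, seed = 6)
    expect_equal(sum(out), p0 + round(lv * p0))
    expect_true(all(unclass(out)[unclass(pr) == 1] == 1))
  }
  expect_error(inject_noise(pr, 1e6, seed = 1), "not enough zero")
})

test_that("cell downsampling keeps genes and samples without replacement", {
  set.seed(51)
  W <- expression_matrix(matrix(rpois(1000 * 5, 2), 1000, 5))
  Wd <- downsample_cells(W, 0.2, seed = 3)
  expect_identical(nrow(Wd), 200L)
  expect_identical(colnames(Wd), colnames(W))
  expect_false(anyDuplicated(rownames(Wd)) > 0)
  expect_identical(rownames(downsample_cells(W, 0.2, seed = 3)),
                   rownames(Wd))
  expect_error(downsample_cells(W, 0), "in \\(0, 1]")
})

test_that("robustness sweep drivers loop the protocols with distinct seeds", {
  sim <- simulate_grn_data(simulation_config(
    n_cells = 50, n_genes = 40, n_tfs = 3, edge_density = 0.2, seed = 12))
  cfg <- pmfgrn_config(max_steps = 60, eval_interval = 30, patience = 1,
                       summary_mc_samples = 200, seed = 1)
  ns <- noise_sweep(sim$W, sim$prior, sim$true_A, levels = c(0, 1),
                    config = cfg, n_reps = 2, seed = 3)
  expect_identical(nrow(ns), 4L)
  expect_true(all(is.finite(ns$auprc)))
  # density doubles at level 1 and differs across replicates only by seed
  expect_equal(ns$density[ns$level == 1][1],
               2 * mean(unclass(sim$prior) != 0), tolerance = 1e-12)
  ds <- downsample_sweep(sim$W, sim$prior, sim$true_A, fractions = 0.5,
                         grid = list(cfg), n_reps = 2, seed = 3)
  expect_identical(nrow(ds), 2L)
  expect_identical(ds$n_cells, c(25L, 25L))
  expect_true(all(is.finite(ds$auprc)))
})

test_that("reference splitting partitions positives disjointly", {
  set.seed(61)
  gold <- prior_network(rand_binary_prior(40, 5, 0.2))
  P <- sum(gold)
  sp <- split_reference(gold, 0.5, seed = 2)
  expect_equal(sum(sp$prior_part), round(0.5 * P))
  expect_equal(sum(unclass(sp$prior_part) * unclass(sp$eval_part)), 0)
  expect_equal(unclass(sp$prior_part) + unclass(sp$eval_part),
               unclass(gold), ignore_attr = TRUE)
  sp8 <- split_reference(gold, 0.8, seed = 2)
  expect_equal(sum(sp8$prior_part), round(0.8 * P))
})
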