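# pmfgrn

Gene regulatory network (GRN) inference from single-cell RNA-seq by
probabilistic matrix factorization with stochastic variational
inference.

A GRN maps transcription factors (TFs) to the target genes they
regulate. Direct measurement is impractical at scale, so `pmfgrn` treats
an observed cells × genes count matrix *W* as a noisy product of latent
factors and infers their posteriors:

$$W_n \sim \mathcal{N}\!\left(d_n\,U_n V^\top,\ \sigma_{obs}^2\right),
\qquad V = A \odot B,$$

* **U** (cells × TFs, positive): latent transcription-factor activity;
* **A** (genes × TFs, in (0,1)): probability that an interaction exists,
  anchored on a binary prior-knowledge network via a logistic-normal
  prior — the prior fixes which latent factor corresponds to which named
  TF;
* **B** (genes × TFs, real): signed interaction strength;
* **d** (per cell, in (0,1)): sequencing-depth factor; raw UMI counts go
  in unnormalized;
* **σ<sub>obs</sub>**: shared observation noise.

Inference maximizes a β-weighted evidence lower bound with Adam
(mean-field Gaussian posteriors on the unconstrained scales,
reparameterized gradients computed analytically). Hyperparameters
(σ<sub>a</sub>, σ<sub>u</sub>, β) are selected by masking the prior rows
of 20% of the genes and scoring the *validation AUPRC* of their
posterior edge probabilities against the unmasked prior; the winning
configuration is refitted on the full prior with an importance-weighted
marginal-likelihood early-stopping criterion. The posterior mean of each
entry of A is the edge probability, and its posterior variance is a
per-edge uncertainty estimate.

The package is intended for computational biologists who have a
single-cell count matrix plus a binary prior network (from databases or
ATAC-seq + motif analysis) and want a probability-ranked edge list with
calibrated uncertainty, along with the standard evaluation toolbox:
keep-all/overlap AUPRC, cumulative-variance calibration bins, top-edge
intersection-over-union, shuffled/empty-prior negative controls, prior
noise injection, cell downsampling, and gold-standard cross-validation.
A generative simulator produces fully synthetic benchmarks so every
workflow runs without external data.

## Worked example

```r
library(pmfgrn)

# synthetic benchmark: 120 cells, 60 genes, 4 TFs, corrupted prior
sim <- simulate_grn_data(simulation_config(n_cells = 120, n_genes = 60,
                                           n_tfs = 4, edge_density = 0.12,
                                           seed = 7))
fit <- pmf_grn(sim$W, sim$prior, pmfgrn_config(seed = 7))
print(fit)
#> Probabilistic matrix factorization GRN fit
#>   120 cells x 60 genes x 4 TFs; prior edges: 28
#>   stopped at step 4200 (patience_exhausted); best iw_log_marginal -4877.73 at step 2200

sm <- summary(fit)
print(sm)
#> Posterior summary: 60 genes x 4 TFs (2000 MC draws/entry)
#>   edges with probability >= 0.9: 28 (11.7% of entries)
#>   mean posterior variance: 5.914e-05

auprc_ratio(sm$A_mean, sim$true_A, "overlap")
#> overlap AUPRC vs truth: 0.863 (random baseline 0.121, ratio 7.1)

head(threshold_network(sm, 0.9), 3)
#>       gene    tf probability     variance sign
#> 1 gene_031 tf_04   0.9962575 1.713183e-05   -1
#> 2 gene_028 tf_03   0.9961420 7.604633e-06    1
#> 3 gene_040 tf_04   0.9959923 1.064466e-05    1
```

The fit stops when the importance-weighted marginal likelihood stops
improving and returns the best checkpoint. The summary's `A_mean` ranks
all gene–TF pairs; against the known simulated truth it achieves an
overlap AUPRC of 0.86 versus a 0.12 random baseline. `threshold_network`
extracts the high-confidence edge list (probability ≥ 0.9), with the
sign of the posterior mean of B as the putative direction.

The full selection workflow is `pmfgrn_search()` (grid search scored by
validation AUPRC) followed by `final_fit()`; `cross_validate()` runs the
80/20 gold-standard cross-validation harness. A command-line front end
with `simulate | infer | search | cv | evaluate` subcommands lives at
`inst/cli/pmfgrn.R`.

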