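---
title: "Simulating and mitigating ancestry-related performance disparities in clinico-genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and mitigating ancestry-related performance disparities in clinico-genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most genome-wide association data come from European-ancestry (EUR) cohorts.
Prediction models trained on such data transfer poorly to data-disadvantaged
populations (DDPs) — ancestry groups with far fewer samples — both because of
the smaller sample sizes and because the genotype–phenotype relationship
shifts across ancestries (allele frequencies and effect sizes differ).
`equigen` provides a controlled laboratory for this problem: a synthetic
multi-ancestry cohort generator with tunable data inequality and distribution
shift, the standard genotype QC stack, two predictor families (penalized
logistic regression and a small neural network), four multi-ancestral
learning schemes (mixture, independent, naive transfer, transfer learning),
and the disparity statistics used to compare them.

## The generative model

**Genotypes.** Each population has a minor-allele-frequency profile on
`[0.05, 0.95]`. The EUR profile is uniform; each DDP profile is a
Balding–Nichols-style perturbation: conditional on the EUR frequency $f$,
the DDP frequency is $\mathrm{Beta}$-distributed with mean $f$ and variance
$c\,f(1-f)$, clipped to the bounds. The divergence scalar $c$ is calibrated
by Monte-Carlo root-finding so that the expected genetic distance
$d = \sum_j |F^{EUR}_j - F^{DDP}_j|$ matches a target; the package defaults
target the distances 42.7 (AMR), 46.1 (SAS), 80.6 (EAS) and 94.1 (AFR) per
500 SNPs, scaled proportionally for other SNP counts. Genotype dosages are
independent Binomial(2, $F_j$) draws. Linkage disequilibrium, admixture and
recombination maps are deliberately out of scope: the generator reproduces
the frequency-divergence and effect-shift structure of real multi-ancestry
panels, not their correlation structure, so results on these data speak to
distribution shift and data inequality, not to LD-dependent phenomena.

**Effect sizes and shift.** The EUR effect vector $W$ is drawn from a
standard normal truncated to $[-1, 1]$ (the bounded support keeps single-SNP
effects small; the overall scale is irrelevant because the genetic score is
standardized). Each DDP uses
$W' = \rho W + \sqrt{1-\rho^2}\,\zeta'$ with $\zeta'$ drawn the same way, so
$\mathrm{cor}(W, W') \approx \rho$. The correlation follows the distance
schedule $\rho_k = \rho_0 (d_0/d_k)^r$ with $\rho_0 = 0.8$ at the reference
(AMR) distance; $r = 0.5$ gives the milder shifts
(0.80/0.77/0.58/0.54), $r = 1$ the stronger ones (0.80/0.74/0.42/0.36).

**Phenotypes.** A liability-threshold model: the weighted genetic score is
standardized per population, multiplied by $\sqrt{h^2}$, and added to
independent noise scaled to variance $1-h^2$ — so $\mathrm{Var}(g)\approx 1$
and $h^2$ is exactly the fraction of liability variance explained by
genotype. The noise is a truncated standard normal rescaled to unit variance
by the normalization scalar $a = 1/\mathrm{sd}$ of the truncated draw; a
`truncate = FALSE` flag gives a plain Gaussian reading instead (the two are
indistinguishable downstream because both are standardized). Case status is
liability above the empirical quantile of the population at the control
fraction, so a 1:1 or 1:4 case:control ratio is realized exactly up to
rounding; ties at the threshold fall to the control side. Thresholds are per
population, computed independently for EUR and the DDP.

**Defaults.** 500 SNPs, 10,000 EUR + 2,000 DDP individuals, $h^2 \in
\{0.5, 0.25\}$, ratios 1:1 (`SD` compendium) and 1:4 (`SD*`), 80/10/10
train/validation/test split stratified jointly by ancestry and label. One
master seed expands deterministically into per-stage streams, so a dataset
is byte-reproducible from its configuration.

## Quality control

`qc_filter()` drops SNPs with missing rate > 0.20, minor allele frequency
< 0.05, or Hardy–Weinberg p below a threshold ($10^{-5}$ default; $10^{-4}$
is the stricter rule appropriate for simulated-source panels). The HWE test
is a Wigginton-style exact test (chi-square fallback available), computed on
all samples by default with a controls-only option. `sample_filter()`
removes individuals with > 20% missing dosages. `ld_prune()` implements
greedy windowed pruning (window 50, step 5, $r^2$ cut-off 0.2), retaining
the lower-p member of a correlated pair when association p-values are
supplied and the earlier-ordered member otherwise; pair scanning within a
window restarts after each removal, which makes the procedure deterministic.
`rank_and_select()` ranks features by two-group ANOVA F on the training
split only, never touching validation or test labels. The PLINK-style
association step and the F-based selection step of common pipelines are
collapsed into this single ranking; the same per-SNP p-values feed the LD
tie rule.

## Predictors

**Logistic regression.** `train_lr()` minimizes
$-\log L(\beta) + \tfrac{\lambda}{2}\lVert\beta\rVert^2$ (intercept
unpenalized), i.e. ridge logistic regression with $C = 1/\lambda$ in the
scikit-learn parameterization; the default is $\lambda = 1$. The fit is
delegated to glmnet on a short decreasing ridge path with a tight
convergence threshold; a brute-force objective minimization in the test
suite confirms agreement with the penalized-likelihood optimum.

**Neural network.** `train_dnn()` fits the pyramid architecture: input
layer of K features, one dense layer of 100 ReLU units, dropout 0.5, and a
logistic output unit. The loss is mean binary cross-entropy plus
$\lambda_1 \sum |W| + \lambda_2 \sum W^2$ over the weight matrices
($\lambda_1 = \lambda_2 = 0.001$; the L2 term uses the squared norm, the
convention of standard deep-learning regularizers). Optimization is
mini-batch SGD (batch 32) with Nesterov momentum 0.9, initial learning rate
0.25 decayed per update as $\eta_t = \eta_0/(1 + 0.003\,t)$, at most 200
epochs, and early stopping on validation accuracy with patience 200 and
best-epoch weight restoration (with patience equal to the epoch cap,
stopping rarely triggers but the best-epoch weights are always the ones
kept). Weights are Glorot-uniform initialized from a seeded stream; batch
order and dropout masks come from the same stream, so training is
bit-reproducible. Two engineering choices stabilize this schedule on
genotype matrices: features are z-scored with training-split statistics
(stored in the model and re-applied at prediction time), and gradients are
globally norm-clipped at 1.0 — without them the 0.25 learning rate diverges
on inputs of several hundred features, while with them the training loss
decreases smoothly to a plateau. The L1 subgradient at 0 is taken as 0.

## Transfer learning

**Fine-tuning (DL).** `fine_tune_dnn()` continues SGD from the pretrained
EUR weights on the DDP training split, all layers trainable, same
hyperparameters, early stopping on the DDP validation split. The update
counter carries over from pretraining, so fine-tuning proceeds at the
already-decayed learning rate — the behavior of refitting the same model
object in the deep-learning frameworks this schedule comes from. Restarting
the decay schedule instead would make the first fine-tuning epochs erase the
source representation (we observed exactly this: a restarted schedule drove
the transferred model to independent-learning quality, discarding the
pretraining). The pretrained model object is never modified; EUR-facing
predictions are bit-identical whether or not transfer runs happen in the
same session — the Pareto property at the artifact level.

**Linear transfer (LR).** The target model keeps the source decomposition
$\beta_j = \beta_j^{pre} + \tau_j$ (and $\gamma_k = \gamma_k^{pre} +
\delta_k$ for clinical covariates). The printed form of this model is a
continuous-response regression with Gaussian noise; because the outcome here
is binary, `fit_linear_transfer()` estimates the adjustments on the logit
scale: an L2-penalized logistic regression with the pretrained linear
predictor as a fixed offset. The penalty shrinks the target model toward
the source model (infinite penalty recovers naive transfer up to intercept
recalibration; zero penalty a free target refit) and is selected on the
target validation split over the fixed grid $10^{-1}, \dots, 10^4$, ties
toward the stronger penalty.

## Experiments and statistics

Seven experiments per dataset (Mix0/Mix1/Mix2 share one model trained on
pooled data and differ only in the evaluated test subset; Ind1 and Ind2
train within one population; NT applies the EUR model to the DDP; TL
pretrains on EUR and adapts on the DDP). Data splits are frozen across the
replicate runs; run-to-run variation comes from model initialization, batch
order and dropout only, which makes cross-run comparisons paired. The
logistic fits are deterministic given the data, so their replicate runs
coincide — their run-level comparisons rely on the paired signed-rank test
across datasets rather than the rank-sum test across runs. Metrics: AUROC
(primary), AUPR, Tjur's R², and sensitivity/specificity/PPV/NPV at the
Youden-optimal threshold, chosen by default on the validation split and
applied to the test split (a `threshold_on = "test"` mode exists for
exact-replication exercises). Prevalence-adjusted PPV/NPV recompute the
predictive values at an external disease prevalence. Disparity statistics:
the gap $G$ (mean EUR AUROC − mean DDP AUROC), improvements $I$ of TL over
the Mix2/Ind2/NT baselines, and the DL−LR transfer difference $D$, each with
a one-sided Wilcoxon test — exact by enumeration when both groups have ≤ 12
observations without ties, the tie-corrected normal approximation with
continuity correction otherwise.

## Problem sizes and what the tests show

The packaged test-suite and acceptance script exercise the generator at the
full study size (10,000 individuals, 500 SNPs) for the statistical-recovery
checks, and the learning-scheme experiments on scaled-down analogues of the
first compendium block (500 SNPs, 3 replicate runs) at two scalings, each
preserving the study property its contrast depends on: the
independent-learning disparity gap is assessed at 4,000 EUR + 1,000 DDP
individuals, which keeps the ~4:1 training-data inequality that produces
the gap, while the transfer-learning contrasts are assessed at 4,000 EUR +
2,000 DDP individuals, which keeps the full-size target cohort that
fine-tuning and its validation-driven early stopping depend on (shrinking
the DDP to a few hundred individuals makes its 10% validation and test
splits too small to resolve the transfer effect). The complete 16-dataset ×
20-run compendium at 10,000 + 2,000 individuals is a multi-hour computation
run via `run_compendium(sd_compendium())`.

Because the synthetic liability is exactly linear in dosages and SNPs are
independent, penalized logistic regression is the correctly specified model
here, and the validation-tuned linear transfer is a strong baseline: the
neural network's advantage in transfer (the $D$ statistic) is therefore
smaller on these data than on real LD-structured cohorts, and at easy
operating points (high $\rho$, large target cohorts) the two transfer
routes can tie. The qualitative contrasts — disparity gaps under mixture
and independent learning, and fine-tuning rescuing the DDP from the naive
transfer penalty — are robust in this world; the precise margins between
the two transfer families are not a property the generator is designed to
pin down.

## Known limitations

No LD, admixture, or site ascertainment; clinical covariates are optional
and synthetic (one Gaussian, one Bernoulli); the logistic fits have no
stochastic run-to-run variation (a deliberate consequence of frozen splits
and a deterministic solver); and the neural-network trainer is single
threaded by design for reproducibility.
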