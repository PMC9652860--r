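---
title: "Kinase-substrate edge biomarkers: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase-substrate edge biomarkers: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeqnet)
```

## The problem

Single-molecule ("node") biomarkers often generalize poorly for drug-response
prediction in heterogeneous tumor cohorts: a drug acts on signaling, and
signaling lives on interactions. `edgeqnet` instead builds features on
*edges* of the kinase-substrate network: each feature quantifies, for one
sample, the joint deviation of a kinase's protein abundance and one of its
substrate phosphosites from their state-specific cohort means. Per-drug
penalized linear models over these edge features predict tumor cell growth
inhibition (TCGI, in percent), the response measured in miniPDX-style drug
assays.

## The edge-strength transformation

Samples carry a state label $k \in \{1, 2\}$ (1 = primary tumor,
2 = metastatic tumor). For kinase $u$ (protein layer) and substrate
phosphosite $v$ (phosphosite layer), the strength of edge
$\langle u\!-\!v\rangle$ in sample $j$ of state $k$ is the product of
within-state z-scores,

$$ s_{uv,j} \;=\; \frac{x_{u,jk}-\mu_{u,k}}{\sigma_{u,k}}\cdot
                  \frac{x_{v,jk}-\mu_{v,k}}{\sigma_{v,k}}, $$

where $\mu_{\cdot,k}$ and $\sigma_{\cdot,k}$ are the mean and *sample*
standard deviation (denominator $n_k-1$) over the state-$k$ samples of the
reference cohort. Two consequences are used as correctness oracles
throughout the test suite:

* **Correlation identity.** Within a state,
  $\sum_{j \in k} s_{uv,j} = (n_k - 1)\, r_{uv,k}$, the within-state Pearson
  correlation of the two molecules. This ties the feature to the
  differential-correlation view of edge biomarkers and is checked to
  $10^{-10}$ on random cohorts.
* **Affine invariance.** Strengths are invariant to positive affine
  rescaling of any molecule within a state, and flip sign exactly under
  negative scaling — so per-layer normalization conventions cannot leak
  into the features.

The sample SD (ddof = 1) is a deliberate choice: the identity above holds
exactly for it, and it matches conventional implementations of
edge-biomarker feature construction.

New patients are standardized against the **frozen** reference-cohort
statistics of their declared state; the reference is *not* re-estimated
with the new sample. This makes predictions deterministic per patient and
independent of upload order. A `pooled = TRUE` option in
`transform_new_sample()` provides the re-pooled alternative for users who
want the reference updated.

## Screening differentially correlated pairs

`dcp_screen()` flags kinase-substrate pairs whose within-state Pearson
correlations differ between primary and metastatic samples. The test is the
Fisher z comparison: $z_k = \operatorname{atanh} r_k$,
$\mathrm{SE} = \sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-sided normal p-value. A
pair is selected iff $|r_1 - r_2| \ge$ `min_abs_delta` (default 0.5) *and*
$p \le$ `alpha_level` (default 0.05). The thresholds are a concretization —
the screening step itself names no cut-off in the sources the package
follows — and both are exposed as parameters. No multiplicity correction is
applied across candidate pairs; the screen is a feature filter, not an
inference procedure. Pairs with $|r| = 1$ produce an infinite z and hence
$p = 0$; zero-variance columns are reported unselected with `NA` statistics.

## Edge-biomarker selection

`select_edge_biomarkers()` implements a repeated-resampling elastic-net
search. For each of `n_splits` random train/test partitions (default 100,
stratified on state so no test set is single-state; test fraction 0.3) and
each mixing value $\alpha$ on a fixed-step grid (default 0, 0.1, ..., 1),
the penalty $\lambda$ is chosen by 5-fold cross-validation on the training
part over a 100-point log-spaced path from $\lambda_{\max}$ down to
$10^{-3}\lambda_{\max}$, the training fit is scored on the held-out part,
and the single (split, $\alpha$, $\lambda$) fit with the globally smallest
test MSE defines the selected edges — those with nonzero coefficients. The
objective is the canonical elastic net

$$ \min_{\beta_0,\beta}\; \frac{1}{2n}\sum_j (y_j - \beta_0 - x_j^\top\beta)^2
   + \lambda\Big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\Big). $$

Design points that were genuinely open, and how they were settled:

* **Split proportion, CV folds, alpha step.** Not fixed by the procedure's
  description; defaults (0.3, 5, 0.1) follow standard penalized-regression
  practice and are configurable in `selection_config()`.
* **"Smallest MSE" rule.** Read as the *global* minimum across all
  (split, alpha) fits, which the text's phrasing implies; a more
  conservative median-MSE-per-alpha rule is available via `rule = "median"`
  but is not the default.
* **Engine.** The cross-validated path search runs on glmnet (the standard
  tool for exactly this loop); the final refit uses the package's own
  coordinate-descent solver (below). Features are standardized within each
  training fit; reported coefficients are on the original edge-strength
  scale.
* **Determinism.** The entire procedure is a function of `seed`: split
  draws and CV fold assignments come from one seeded stream, and identical
  seeds give bit-identical `edge_selection` objects.
* **Pre-filter.** An optional response-correlation screen keeps edges with
  $|r(\text{strength}, \text{TCGI})|$ above a threshold or the top-$m$ by
  $|r|$, with a deterministic tie-break ($|r|$ descending, then edge id
  ascending). Both rules are off by default.

## The final drug model

`fit_drug_model()` refits the elastic net at the winning
$(\alpha, \lambda)$ on *all* cohort samples, restricted to the selected
edges — the full-cohort refit reading of model construction. The fit is the
package's own cyclic coordinate descent, iterated until the subgradient
(KKT) residual of the objective above falls below $10^{-8}$, so every
returned model certifies its own optimality (`training_meta$kkt`); glmnet
serves as an independent cross-check of this solver in the tests, never as
its implementation. Feature scaling constants are stored in the model, and
coefficients are reported on the original strength scale, so a persisted
model predicts self-contained. Predictions are
$\hat y = \beta_0 + x^\top \beta$ and are *not* clipped to $[0, 100]$:
shrinkage already concentrates predictions on a narrower scale than
observations, and clipping would hide that.

Evaluation reports $R^2$ as the squared Pearson correlation between
predicted and observed TCGI with the two-sided t-based p-value
($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df). Squared correlation is sign-blind
and insensitive to calibration, so the coefficient of determination
$1 - \mathrm{SS}_{\mathrm{res}}/\mathrm{SS}_{\mathrm{tot}}$ is reported
alongside (`r_squared_cod`); the two differ for biased predictions.

## The synthetic cohort generator

`generate_cohort()` emulates the study setting: a small two-state cohort
(default 31 samples, 16 primary / 15 metastatic), a protein layer of
kinases, a phosphosite layer of substrate sites, a relation catalogue
(default 53 relations over 20 kinases), and one drug response. Kinase
columns are standard normal within each state. An informative substrate is
$\rho\, z_u + \sqrt{1-\rho^2}\,\varepsilon$ (default $\rho = 0.9$), so its
true within-state correlation with its kinase is exactly $\rho$ when the
idiosyncratic noise SD is at its default 1. The response is

$$ \mathrm{TCGI}_j = 50 + \textstyle\sum_e c_e\, s_{e,j} +
   \mathcal N(0, \sigma_{\mathrm{resp}}^2), $$

with planted coefficients $c = (3, -2, 1.5)$ over three informative edges
and $s_{e,j}$ the *cohort-standardized* edge strength — i.e. the response
is linear in the pipeline's own model class, so the noiseless optimum is
achievable and end-to-end tests have a well-defined target. Two generator
design choices deserve emphasis:

* **Planted edges sit on distinct kinases.** If two informative substrates
  shared a kinase, their edge features would be strongly correlated
  (for $\rho = 0.9$, $\operatorname{cor} \approx 0.93$ by Isserlis'
  theorem), making exact support recovery ill-posed regardless of noise —
  a collinearity artifact, not a property of the method. Decoy edges may
  still share kinases with planted ones; their features remain
  uncorrelated with the planted features.
* **Held-out samples** from `generate_holdout()` define their true TCGI
  through edge strengths standardized against the *frozen reference
  cohort* statistics — exactly the semantics a deployed model applies to a
  new patient.

What the generator does **not** emulate: proteome-scale dimensions, batch
effects, missing values (the input contract forbids them), heavy-tailed or
skewed expression, and catalogue errors (false kinase-substrate
relations). Passing the synthetic-recovery tests therefore demonstrates
correctness of the machinery on its model class, not performance on real
cohorts.

## Numerical choices and test scales

* The coordinate-descent solver converges on coefficient updates at
  relative $10^{-12}$ and then verifies a KKT residual below $10^{-8}$;
  ridge ($\alpha = 0$) paths cap $\lambda_{\max}$ via the standard
  $\alpha \to 10^{-3}$ device.
* Constant molecules (zero within-state SD) are flagged at statistics time
  and raise a typed error if an edge requires them; constant features in
  the final fit keep coefficient zero.
* Model JSON is written with 17 significant digits so save/load round
  trips reproduce predictions bit-for-bit.
* Simulation studies in the acceptance tests use scaled problem sizes
  chosen up front: the planted-recovery study runs the generator exactly at
  its stated conditions (n = 40, 3 planted edges among 50 decoys) with a
  10-resample, alpha-step-0.25 search; recovery-rate monotonicity across
  response noise levels is asserted with a two-seed binomial margin, since
  rates near 1 differ only by simulation error. The permutation check of
  the Pearson p-value uses instances of size 300: the permutation null
  conditions on the data and deviates from the unconditional t null by an
  Edgeworth-order term of roughly $0.13/n$, so smaller instances would
  fail a 3-Monte-Carlo-SE comparison at 200,000 permutations no matter how
  correct the implementation; at $n = 300$ the band genuinely covers the
  approximation gap. The noiseless end-to-end check trains on 200 samples
  and evaluates 200 held-out samples.

## Limitations

* The kinase layer is protein abundance; kinase *activity* (e.g. activating
  phosphosites on the kinase itself) is not modeled.
* Catalogue relations are treated uniformly: no confidence weighting, no
  merging logic across sources beyond triple-level deduplication.
* The repeated-split minimum-MSE rule is optimistically biased as an error
  estimate (selection over many test sets); it is used only to *choose* a
  fit, and no unbiased nested-CV error is reported.
* With both prefilter rules off and many more edges than samples, selection
  stability depends on the penalty; users wanting stability guarantees
  should aggregate selections across seeds.

## A minimal session

```{r example, eval = FALSE}
co <- generate_cohort(synth_config(seed = 1))
res <- run_pipeline(co$protein, co$phosphosite, co$relations,
                    co$responses, drug = "drug1",
                    selection = selection_config(seed = 1))
print(res)
score_recovery(res$selection, co$truth)

patient <- patient_profile(co$protein$values[1, ],
                           co$phosphosite$values[1, ], "new-patient", state = 1)
v <- transform_new_sample(patient, res$stats,
                          restrict_edges(res$edges, res$model$features))
predict(res$model, v)
```
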