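---
title: "Models, parameters and design choices in glycodrug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in glycodrug}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`glycodrug` nominates drugs for metastatic castration-resistant prostate
cancer (mCRPC) with high glycolysis/OXPHOS activity and discovers expression
biomarkers for them. This vignette is the package's own account of the
science: the models and their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. No empirical claim is made here that the test
suite does not itself compute.

## 1. Single-sample signature scoring

For gene $i$ with expression $x_{ij}$ across samples $j = 1..n$, the
kernel-CDF statistic is
$\hat z_{ij} = \frac{1}{n}\sum_k \Phi\!\big((x_{ij}-x_{ik})/h_i\big)$ with
bandwidth $h_i = \mathrm{sd}_i/4$. Because $h_i$ scales with the per-gene
standard deviation, $\hat z$ — and hence every downstream score — is
invariant to positive affine transforms of any gene row (tested to 1e-8).
Per sample, genes are ranked by $\hat z$ (ties broken by lexicographic gene
id for reproducibility), ranks are symmetrized as $r = |p/2 - \mathrm{rank}|$,
and a weighted KS random walk (weight exponent $\tau = 1$) steps up by
$r^\tau$ (normalized within the set) at set genes and down by $1/(p-m)$
elsewhere. The score is the largest positive deviation minus the magnitude
of the largest negative deviation, so it lies in $(-1, 1)$.

Assumptions: at least 2 samples; every scored set overlaps the matrix in at
least 2 genes after zero-variance genes are dropped (single-gene "sets" are
rejected — the walk is degenerate and the upstream contract requires ≥ 2).
Raw scores are min–max rescaled to 0–100 **within each cohort**: the
analysis scores each cohort's tumors on its own scale and no cross-cohort
calibration is defined; this means the 0–100 values are not comparable
across cohorts, only the per-cohort orderings are (a deliberate, recorded
choice).

AR activity is the per-sample sum of z-scored AR-signature gene expression,
min–max scaled to $[0,1]$. The AR(low)Gly(high) stratum uses **strict**
inequalities on both medians; samples exactly at a median fall into "other",
so the stratum can hold at most $\lfloor n/2 \rfloor$ samples.

## 2. Response imputation

*Harmonization.* Training (cell-line) and target (tumor) matrices are
restricted to common genes and adjusted by the standard two-batch parametric
empirical-Bayes location–scale procedure: per-gene standardization against
the pooled model, batch-wise mean/variance estimates shrunk toward normal /
inverse-gamma priors via the usual iterative solution, then back-transform.
Genes with zero variance in either batch are excluded with a warning.
Note the shrinkage floor: with a homogeneous planted shift the adjusted
per-gene batch means differ by roughly $(1-w)$ times the per-gene sampling
noise (~0.05 sd at n = 100/batch), which no empirical-Bayes variant can
remove; the acceptance check therefore bounds the mean absolute per-gene
difference (< 0.1) plus a 0.3 cap on the maximum.

*Response transform.* Measured AUCs are shifted strictly positive
(`shift = max(0, eps - min)`) and Box–Cox transformed with the exponent
chosen by profile-likelihood over the grid $-2..2$ step 0.1. Exponent 1 is
identity-up-to-shift; constant vectors pass through with a warning.
Predictions stay on the transformed scale: downstream use is only
linear/rank association with scores, which the drug-wise monotone transform
preserves.

*Ridge.* Per drug, coefficients minimize
$\|y - X\beta - \beta_0\|^2 + \lambda\|\beta\|^2$ on column-standardized
predictors with an unpenalized intercept, solved exactly through an
eigen-decomposition of the smaller Gram matrix (so the $\lambda \to 0$ limit
reproduces OLS and the coefficient-norm path is monotone). $\lambda$ is
picked by 10-fold CV over a 25-point grid $10^{-3}..10^{4}$; fold membership
is a function of the *sorted sample ids* and the seed, which makes the whole
fit-then-predict pipeline invariant to gene-row and sample-column order.
Fold decompositions are cached and shared across drugs whose training sets
coincide (the common complete-data case), which keeps 60–200 drug models in
the seconds range. Drugs with fewer than 10 measured lines are skipped with
a logged reason; missing AUC entries give per-drug complete-case training.
Whether the original tool standardizes predictors is not restated anywhere;
standardization is this package's recorded choice.

## 3. Association, nomination and the filter cascade

Per drug and cohort, OLS of score on predicted response (Eq. 1); for OXPHOS
an age-at-procurement covariate is added **when the cohort provides ≥ 3
non-missing ages** (the source analysis made the adjustment conditional on
availability; this package makes it data-driven). Constant predictors yield
$p = 1$ with a warning rather than an error, so a shrunk-to-intercept model
cannot crash a 200-drug screen. BH-FDR is applied per
(cohort × training source × score type) family across drugs — the family
structure is not stated anywhere upstream; per-dataset families are this
package's choice, and both α and the family structure are configurable.

Drug_HG/Drug_OX require β1 < 0 with FDR < α (default 0.05); Drug_DE is their
intersection; cross-cohort sets intersect over cohorts within a training
source. Primary mechanisms of action: within each cohort the candidates are
ranked by β1 p-value, the top 50% kept, the cross-cohort overlap summarized
by MOA, and MOAs appearing ≥ 2 times flagged.

The four filters: (1) status ∈ {approved, clinical}; (2) drop drugs with any
β1 > 0 at FDR < α in another dataset — "significantly opposing" is
operationalized by reusing the nomination threshold, a recorded choice, and
the trail stores the offending record; (3) on cell lines, both the
glycolysis and OXPHOS scores must have negative OLS slopes against measured
AUC — sign only, no significance requirement (slopes and p-values are
recorded for transparency); (4) one-sided Welch test for a score *increase*
post-treatment at α = 0.05 on replicate-level scores; drugs lacking
perturbation data pass with reason "no data". Survivor sets are nested by
construction and the cascade is idempotent on its survivors.

## 4. Network biomarkers

Candidate genes: |Spearman ρ| ≥ 0.4 between expression and the drug's
imputed response (the correlation flavor is not fixed upstream; Spearman
matches the module's other correlation uses). The PPI subnetwork is the
induced subgraph on exactly these genes (maximum interactors = 0) with edge
confidence ≥ 700 on the STRING 0–1000 scale; isolated candidates remain as
nodes; duplicate undirected pairs collapse keeping the maximum confidence.

The 12 centralities follow the cytoHubba-style definitions, with these
numerical decisions:

* **Closeness** uses the harmonic form (sum of reciprocal distances) so
  disconnected subnetworks — common after confidence filtering — are
  well-defined.
* **Bottleneck** needs a canonical shortest-path tree: BFS visiting
  neighbors in sorted node-id order. Consequently Bottleneck (alone among
  the deterministic methods) is not invariant under node relabeling when
  multiple shortest-path trees exist; the other deterministic methods are
  isomorphism-invariant and tested as such.
* **MNC/DMNC** tie rule: among largest neighbourhood components, prefer more
  edges, then the smallest lexicographic node id. DMNC's exponent is 1.7 per
  the method's original description.
* **MCC** sums $(|C|-1)!$ over maximal cliques of size ≥ 2 containing the
  node; an edgeless neighbourhood therefore yields exactly the degree, and
  isolated nodes score 0.
* **EPC** retains each edge independently with probability confidence/1000
  (0.5 if unweighted) over R = 1000 seeded replicates and averages the
  node's component size; with all-certain edges it equals the component size
  exactly for any R. The percolation model is an explicit reconstruction —
  the original plugin does not publish its scheme.

Per method the top k = 50 genes (ties lexicographic) are listed; consensus
counts how many methods list a gene, and the selected tier keeps genes with
≥ `min_methods` (6 of 12 by default, 8 for a stricter tier). Consensus
selection is monotone in `min_methods`. Candidate biomarkers then require a
significantly negative Spearman correlation (two-sided p < 0.05, ρ < 0)
between expression and *measured* cell-line AUC, so higher expression means
higher measured sensitivity.

## 5. Survival

Kaplan–Meier product-limit curves with events processed before censorings at
tied times; the two-group log-rank statistic uses the hypergeometric
variance with $(O-E)^2/V \sim \chi^2_1$. Median splits label expression
strictly above the median "high"; values at the median go to "low" (recorded
convention). All-equal expression is an error — the split is undefined.

## 6. The synthetic world

All inputs derive from one latent program: per sample, bivariate standard
normal (glycolysis, OXPHOS) latents with correlation `prog_corr` (default
0.5 — the joint distribution in real tumors is uncharacterized, so this is a
free parameter, not an estimate) plus an independent AR latent. Signature
genes load on their program (loadings U(0.6, 1.4)); every gene adds Gaussian
noise with per-gene sd U(0.5, 1.5) around a N(6, 1.5²) baseline, giving
log2(x+1)-like values. Cohorts add a constant batch shift (default 2 log
units; the "WC" cohort gets 1.5×, emulating a different unit convention).
Planted Drug_HG AUCs have a standardized slope `effect_size_gamma = -0.5` on
latent glycolysis; Drug_DE additionally on OXPHOS; null drugs have slope 0.
The AUC residual sd defaults to 0.15 = 0.3·|γ| (the stated recovery noise).
Survival is exponential proportional hazards with log-hazard
`survival_beta = 0.8` per sd of one dedicated marker gene's expression,
baseline median 36 months, independent censoring at rate 0.2, ages uniform
45–85 (optionally OXPHOS-dependent to exercise the age adjustment). The PPI
table wires each planted hub to 30 signature-gene partners at confidence
750–980 over a sparse mixed-confidence background. Perturbation profiles are
r = 5 replicates per arm; the default design plants one glycolysis-activating
drug (+1, to be caught by filter 4) and one suppressing drug (−1).

What the generator does **not** emulate: RNA-seq count noise, off-signature
co-expression modules, copy-number/mutation structure, dose-level viability
curves, non-proportional hazards. A green end-to-end test therefore
establishes that the pipeline recovers planted structure under idealized
block-structured expression — not that it is calibrated or powerful on real
transcriptomes.

## 7. Known limitations

**Imputed-response associations are conditionally anti-conservative.** A
ridge model trained on a drug with *no* metabolic dependence still acquires
random weights along the dominant co-expression directions of the training
matrix; with a 200-gene OXPHOS block among ~1000 selected genes, the
prediction's component along the latent program has random sign but
magnitude comparable to its total variation (scale ≈ $m\,l\sqrt{\rho/p}$ for
block size $m$, loading $l$, within-block correlation $\rho$, $p$ selected
genes). The Eq. (1) t-test conditions on the imputed predictor, so these
associations are *real given the model* and replicate across cohorts (the
per-cohort models share the training screen). Consequences, measured by the
acceptance suite and deliberately left failing: pooled null p-values are far
from uniform, and null drugs enter the cross-cohort Drug_HG set well above
the nominal FDR. This is a property of the method class, not of this
implementation — it is exactly why the four-filter cascade (measured-data
trend, perturbation check, cross-dataset consistency) exists downstream of
the FDR screen, and users should read the nomination FDR as a ranking
device, not an error rate.

Other limitations: per-cohort 0–100 scales are not cross-cohort comparable;
Bottleneck depends on node labeling through its canonical tree; EPC is
Monte-Carlo (seeded, R configurable); the empirical-Bayes harmonization
leaves a shrinkage-floor residual; the biomarker stage analyzes the first
cohort by convention; no Cox models or confidence bands are provided.
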