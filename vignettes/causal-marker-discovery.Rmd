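---
title: "Causal marker discovery with snpdag: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal marker discovery with snpdag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide association scans in an autotetraploid crop return a long list
of statistically associated markers. Linkage disequilibrium, admixed
population structure and shared environments make most of those
associations indirect: a marker can light up because it is physically
linked to a causal variant, because it tracks ancestry that also tracks the
trait, or because it sits upstream of the true causal locus in a regulatory
cascade. `snpdag` implements a two-stage route from association to
structure:

1. **De-confounded screening.** Every dosage marker is scored with
   cross-fitted double machine learning (DML) on the partially linear model
   \[ Y = \theta D + g(X) + \zeta, \qquad D = m(X) + \nu, \]
   where \(Y\) is the trait, \(D\) a single marker's allele dosage
   (0–4), and \(X\) the leading genotype principal components standing in
   for population structure and correlated environment. Both nuisance
   functions are fit by cross-validated lasso on held-out folds;
   \(\hat\theta\) is the partialling-out ratio
   \(\sum \hat\nu \tilde y / \sum \hat\nu^2\) with a sandwich variance.
   Repeating the whole screen over re-randomised fold splits and keeping
   markers that stay below a strict per-repetition threshold
   (stability selection) guards against split luck.
2. **Structure learning.** Over the stable candidates plus the trait, a
   PC-stable constraint-based search with Fisher-Z conditional-independence
   tests builds a CPDAG; v-structures are oriented from separation sets and
   closed under Meek's rules; trait-outgoing edges are forbidden (a
   phenotype cannot rewrite germline genotypes); and the ancestral subgraph
   of the trait is extracted. Nodes with a directed edge into the trait are
   **direct parent SNPs (DPSs)** — with the trait childless, exactly its
   Markov blanket — while high out-degree non-parents are **upstream hub
   SNPs (UHSs)**, acting through mediators.

A validation stage quantifies what the role labels buy: out-of-fold
R² of the DPS panel versus a size-matched hub panel and size-matched random
panels.

## The simulator as the test bed

`sim_config()` fixes the cohort regime every test runs under: 500
individuals, 2,000 dosage markers, two admixed subpopulations
(Dirichlet(0.5) ancestry), LD blocks of 10 markers whose latent
frequencies are copied with probability 0.8 (jitter sd 0.02 on the
frequency scale, half the markers differentiated across subpopulations),
five direct-parent markers, two hubs with two mediators each, a unit
ancestry effect on the trait, unit residual noise, and 2% missing calls.
Dosages are Binomial(4, p) draws at the individual's ancestry-weighted
allele frequency.

Three choices deserve explanation:

* **Hub→mediator edges by latent-Gaussian rank-matching.** How one SNP
  "causes" another is not physically modelled; the simulator needs a
  directed dependence the constraint-based learner can detect without
  distorting dosage marginals. Each mediator is regenerated by
  rank-matching its original dosages to
  \(z = t\,\mathrm{std}(\text{hub}) + \sqrt{1-t^2}\,\varepsilon\), which
  preserves the mediator's dosage multiset exactly while planting a
  monotone dependence of strength \(t\). LD-copying provides a second,
  undirected dependence mechanism; only the hub mechanism contributes
  edges to the ground-truth DAG.
* **`hub_transfer = 0.7`.** The transfer strength trades off two powers:
  the hub's *marginal* association with the trait (which rises with
  \(t\) and determines whether the hub is screened in at all) against each
  mediator's association *conditional on its hub* (which falls with
  \(t\) and determines whether the mediator keeps its direct edge in the
  graph). At 0.7 both are comfortably detectable at \(n = 500\).
* **`beta_parent = 0.35` with planting restricted to MAF ≥ 0.2.** The
  per-allele effect is sized so a single screening repetition detects a
  parent with probability near 0.9 at the \(10^{-4}\) threshold:
  detection requires
  \(z = \beta\sigma_D\sqrt{n}/\sigma_{\text{resid}} \gtrsim
  z_{1-5\cdot10^{-5}} + z_{0.9} \approx 5.2\), and with
  \(\sigma_D \approx 0.85\) (common variants only — hence the MAF floor for
  planted loci) and \(\sigma_{\text{resid}} \approx 1.3\) (unit noise plus
  the eight sibling effects a single-marker model cannot absorb),
  \(\beta = 0.35\) lands at \(z \approx 5.1\). The mediators of one hub
  share a sign so they reinforce rather than cancel the hub's marginal
  signal. At these settings the trait's broad-sense heritability is
  roughly 0.4.

What the simulator does **not** emulate: tetrasomic meiosis and double
reduction, genotyping error, dominance and epistasis, multi-environment
trials, and LD decay profiles of real chromosomes. Passing tests therefore
demonstrate the statistical machinery under an idealised additive,
homoscedastic regime — not performance on any real panel.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_missing` | 0.10 | markers with a missing fraction *strictly above* this are dropped (exactly 10% is kept) |
| `min_maf` | 0.05 | markers with MAF *strictly below* this are dropped; MAF = min(p, 1−p), p = mean dosage / 4 |
| `n_pcs` | 10 | genotype PCs used as the confounding proxy \(X\) |
| `n_rep`, `n_folds` | 100, 5 | stability repetitions × cross-fitting folds |
| `p_thresh` | 1e-4 | per-repetition significance bar |
| `stability_pi` | 0.8 | selection frequency required across repetitions (1.0 gives the literal "significant in every split") |
| `alpha` | 0.05 | Fisher-Z level of the skeleton search |
| `max_cond` | 3 | largest conditioning set; bounds both runtime and test reliability at n = 500 |
| `uhs_min_out_degree` | 2 | out-degree bar for the hub label |

## Numerical and algorithmic choices

* **Nuisance lasso in Gram form.** The screen solves one small lasso per
  marker per fold per repetition. All markers share a design matrix, so
  the coordinate-descent updates are batched across markers on the
  cross-product matrices \(X^\top X/n\) and \(X^\top D/n\) — identical
  solutions to per-marker glmnet calls (the tests assert fixed-penalty
  agreement to 1e-6) at a small fraction of the cost. Penalties follow a
  20-point geometric path per response from each response's own
  \(\lambda_{\max}\), selected by internal 5-fold CV at the minimum-MSE
  point. Columns are standardised with population (1/n) variances so the
  Gram diagonal is exactly one.
* **Small-sample variance correction.** The sandwich variance of the
  partialling-out estimator carries the factor \(n/(n - 2(k+1))\), with
  \(k\) the number of adjustment covariates: the two nuisance regressions
  each consume \(k+1\) degrees of freedom, and without the correction the
  normal-approximation p-values are anti-conservative by \(O(k/n)\)
  (empirically, genomic inflation of ~1.05 on a null cohort at
  \(n = 500\), \(k = 10\); ~1.00 with the correction).
* **Reported per-marker effect.** Across stability repetitions the
  reported (θ, se, p) triple comes from the repetition whose p-value is
  the lower median — stable under reseeding and immune to the optimism of
  the minimum-p repetition.
* **Degenerate markers** (residual dosage variance below 1e-10, e.g. a
  constant column) are kept in the output with θ = 0, p = 1, flagged,
  and can never be selected.
* **PCA** is computed after QC on centred, unit-variance markers
  (preventing high-MAF markers from dominating the structure axes), with
  component signs fixed by the largest-loading convention so runs are
  bit-reproducible.
* **Skeleton search** is the PC-stable variant: adjacency sets are frozen
  per conditioning-set size, removing order dependence; nodes are
  processed in input order and subsets lexicographically, so the result is
  deterministic. A numerically singular conditioning submatrix is treated
  as independence (conservative: the edge is dropped).
* **Orientation conflicts** between overlapping v-structures are resolved
  first-writer-wins in deterministic order and logged on the graph object.
  Meek closure never creates a directed cycle (an explicit reachability
  guard refuses such orientations).
* **Graph inputs are PC-residualized** in the pipeline
  (`residualize_graph = TRUE`). With an ancestry confounder acting on both
  markers and trait, raw-dosage tests are miscalibrated with respect to the
  SNP→trait structure: a true parent's marginal association can be
  *masked* (cancelled) or a null marker's inflated, and constraint-based
  learning assumes causal sufficiency. Regressing the selected markers on
  the PCs before the search restores that premise; the trait (already a
  BLUP-scale quantity) is used as given. `learn_graph()` itself defaults
  to raw dosages so both behaviours are available.
* **Ancestral pruning and hub degrees under partial orientation.** A hub
  whose edges into its mediators are reversible within the Markov
  equivalence class appears with *undirected* edges in the CPDAG. Under a
  literal directed-path rule it would always be pruned, and its out-degree
  would always be 0 — upstream regulators would be structurally invisible
  no matter how strong the data. The pipeline therefore (i) traverses
  undirected edges during ancestral pruning
  (`ancestral_include_undirected = TRUE`; the strict variant remains the
  default of `ancestral_subgraph()` itself), and (ii) counts undirected
  incident edges — orientable outward within the class — towards a node's
  out-degree, always excluding edges that touch the trait.
* **Edge weights.** The CPDAG is extended to one member DAG
  (deterministic sink-elimination, logged), and each child is regressed on
  its DAG parents with all variables standardised; an edge's weight is the
  absolute standardised coefficient. Collinear parent sets fall back to a
  ridge solve (penalty 1e-6, logged).
* **Validation R².** Out-of-fold: OLS on training folds, predictions
  pooled over held-out folds, `1 − SS_res/SS_tot` with totals about the
  training-fold means — negative values are possible and meaningful
  (worse than predicting the mean). The random control averages 20 draws
  excluding the DPS and UHS panels; the hub panel is truncated or padded
  to the DPS panel's size via the out-degree ranking. The full
  stability-selected set can be scored as a fourth panel.
* **Spatial BLUPs.** Plot-level phenotypes are adjusted with the
  row-column mixed model `y ~ (1|genotype) + (1|row) + (1|column)`
  (REML via lme4) and the genotype predictions are returned on the trait
  scale. This is deliberately simpler than a full spatial-covariance
  analysis: no autoregressive residuals, no spline trends.
* **Seeds.** Every stochastic step derives from one seed with fixed
  offsets (genotypes: seed; trait: seed + 1; screen repetition r:
  seed + r; inner CV folds: seed + 7919·fold). Reruns are bit-identical.

## Problem sizes used by the shipped checks

The test-suite simulations are sized for exactness of the property being
checked, not for realism everywhere: the structured-null calibration runs
one full-scale cohort (500 × 2,000); the structure-recovery study runs ten
cohorts at full marker count with 10 stability repetitions; the
oracle-exactness check enumerates every labelled DAG on up to four nodes
and adds seeded random draws at five and six nodes (the 6-node space —
3.78 million DAGs — is far too large to enumerate, and the sampled check
covers it at the same exactness per instance); unit tests use
200 × 300 cohorts.

## Known limitations

* Linear, additive machinery throughout: dominance, epistasis and
  non-linear confounding are outside the model class (the screening
  nuisances are lasso fits, the CI tests are partial correlations).
* Causal sufficiency after PC adjustment is an approximation; unmeasured
  confounders not aligned with the leading PCs will still distort edges.
* SNP→SNP edges conflate physical linkage, co-ancestry and any true
  regulatory dependence; only edges into the trait carry the
  de-confounding guarantee of the screening stage.
* Markers are treated as quasi-continuous; at extreme allele frequencies
  the Gaussian CI test is only an approximation to the discrete reality.
* With n = 500 and α = 0.05 the learned graph is a point estimate; edges
  should be read as hypotheses, not verdicts.
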