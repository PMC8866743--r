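---
title: "Ant-colony short-form construction for hierarchical ordinal scales: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ant-colony short-form construction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`antshort` shortens a hierarchical ordinal instrument — items nested in
facets nested in domains, answered on a small number of ordered categories —
to a fixed two-items-per-facet form, and then evaluates the result with the
standard ordinal-CFA toolkit. This vignette explains the models, the search,
the numerical choices, and what the synthetic-data machinery does and does
not demonstrate.

## The measurement model

Responses are modelled through a latent-response formulation. Each item $i$
of facet $f$ in domain $d$ has a continuous latent response

$$y_i^\ast = \lambda_i\,\eta_f + \varepsilon_i,\qquad
  \eta_f = \gamma_f\,\xi_d + \zeta_f,\qquad
  \xi \sim N(0, \Phi),$$

with all latent variances standardized to 1, and the observed category is
determined by fixed increasing thresholds $\tau_{i1} < \dots < \tau_{i,K-1}$
on $y_i^\ast$ (probit / normal-ogive graded response). Under this model the
latent correlation between two items is obtained by path tracing:
$\rho_{ij} = \lambda_i\lambda_j\,\mathrm{corr}(\eta_{f(i)}, \eta_{f(j)})$
with $\mathrm{corr}(\eta_f,\eta_g) = \gamma_f\gamma_g\Phi_{d(f)d(g)}$ across
facets. These latent correlations are exactly what polychoric correlations
estimate, which is why estimation proceeds in two steps:

1. **Thresholds** are fixed at the probit of the cumulative category
   proportions; **polychoric correlations** are then estimated pair by pair
   by maximizing the bivariate-normal cell likelihood over the single
   correlation parameter (bounded one-dimensional search, estimates clamped
   to $\pm 0.999$).
2. **DWLS**: structural parameters minimize
   $F(\theta) = \sum_{j<k} (s_{jk} - \sigma_{jk}(\theta))^2 / w_{jk}$,
   where $s$ are the sample polychorics, $\sigma(\theta)$ the model-implied
   correlations, and $w$ estimates of the sampling variances of the $s_{jk}$.

Two model modes are supported. The *essential tau-equivalent* mode fixes all
unstandardized first- and second-order loadings to 1 — the selection model —
so the free parameters are the facet total variances and the domain
covariance matrix; implied correlations are piecewise constant (facet
variance within a facet, domain covariance across facets). The *congeneric*
mode frees standardized loadings at both levels with unit latent variances.
Both modes have closed-form gradients, which is what makes a search that
fits tens of thousands of candidate models affordable.

## Weights and the scaled chi-square

The weights $w_{jk}$ are estimated by a deterministic delete-one-group
jackknife over respondents (default 30 consecutive blocks): the polychoric
matrix is recomputed with each block deleted and the jackknife variance
taken entrywise. This is simple, testably correct (it halves when $n$
doubles), and automatically includes threshold-estimation noise.

The test statistic is $T = (n-1)F$. Because the $s_{jk}$ are correlated
across pairs, $T$ is *not* chi-square calibrated under a diagonal weight
matrix: on well-specified data we measure $E[T]/df \approx 0.7$. The
mean-scaled statistic divides by $c = \mathrm{tr}(U\hat\Gamma)/df$, where
$U$ is the residual projection under the fitting weights and $\hat\Gamma$
the full asymptotic covariance of the polychorics — estimated at no extra
cost from the same jackknife replicates, with the model Jacobian evaluated
analytically at the solution. A 200-replication simulation (the test suite)
confirms $E[T_s]/df \approx 1$. The scaling engages automatically whenever
the weights object carries replicates (`fit_cfa()` does this); the ant
search's inner fits compare candidates on one common data set and therefore
run unscaled, as does the invariance ladder, where only differences between
adjacent levels matter.

CFI uses a zero-correlation independence baseline (thresholds free), RMSEA
inverts the noncentral chi-square for its 90% interval, and SRMR is the
root mean squared correlation residual over the non-redundant entries.

## The search

Selections — one unordered item pair per facet — form a product space
(for the full 141-item pool, about $4.02\times10^{24}$ selections). The
searcher is a MAX–MIN ant system over per-item pheromone:

* each of 16 ants per iteration draws, per facet, a first item with
  probability proportional to pheromone and a second proportional to
  pheromone among the rest;
* each candidate is scored by fitting the tau-equivalent model on the
  relevant submatrix of the pool polychorics and mapping statistics through
  logistic transforms: objective A combines CFI, RMSEA, SRMR, and mean
  facet/domain omega; objective B combines CFI, RMSEA, mean omega, the
  minimum standardized loading, and the mean part-whole correlation between
  the two-item and full-pool facet scores. Non-converged or Heywood-flagged
  fits score 0: inadmissible solutions are excluded, not ranked;
* only the global-best ant deposits (its objective value, on each of its
  items); pheromone decays by the retention factor 0.95 and is clamped to
  $[\varphi_{\max}/(2m_f), \varphi_{\max}]$ with
  $\varphi_{\max} = \text{best}/(1-0.95)$ and $m_f$ the facet pool size;
* the run stops after 30 iterations without global-best improvement, or at
  300 iterations.

Two additions reflect how MAX–MIN ant systems are used in practice and were
adopted after observing a reproducible failure mode — facets whose two
selected items are *homogeneously weak* fit the equal-loading model well
(high CFI) but have low reliability, and escaping that trap requires
changing two facets at once, which pheromone sampling alone almost never
does within the stagnation window:

* pheromone is initialized proportional to the corrected item-rest
  correlation within each facet (per-facet mean 1), a cheap visibility
  prior that washes out as deposits accumulate;
* a new global best is refined by greedy local search: single-facet pair
  swaps to convergence, then one targeted joint swap over the two facets
  with the lowest facet omega (candidate pairs drawn from each facet's six
  best items by the same prior), repeating while anything improves. All
  evaluations are cached by item set, so revisits are free.

With these, the search attains the exhaustive-enumeration optimum in at
least 18 of 20 seeded runs on the enumerable 4-facet test instance (the
test suite's bar; dry runs reach 18-20), and recovers all 17 planted pairs
of the 141-item pool template.

The logistic midpoints and slopes (CFI: .95/100 increasing; RMSEA: .05/100
decreasing; SRMR: .06/100 decreasing; mean omega: .70/30; minimum loading:
.50/20; part-whole r: .80/30; unit weights) are package defaults, all
configurable: they place the transition of each transform at the
conventional acceptability threshold of its statistic. The minimum-loading
component uses *standardized* loadings: in the essential tau-equivalent
selection model every unstandardized loading is fixed at 1, so an
unstandardized minimum would be degenerate.

## The pipeline

`shorten_scale()` runs the full procedure: a stratified train/test split
(largest-remainder allocation per stratum; default test share 0.30), three
runs of each objective on the training half, evaluation of every run's best
selection on the test half (sorted by test CFI, then RMSEA, then SRMR),
consensus over the best three (a facet is resolved when the same pair
appears at least twice; otherwise its candidates are pooled), brute-force
enumeration of all candidate-pair combinations for unresolved facets, and a
final ranking on the test half that drops any candidate with a test-set
Heywood flag and orders the rest by test CFI, RMSEA, then mean omega. The
choice among closely ranked candidates on content/semantic grounds is
deliberately left to the user — the report says so rather than automating
it. All stage seeds derive from one master seed.

## The synthetic-data generator

The study's response data are not redistributable, so every downstream
stage is exercised on generated data whose population matches the model
above exactly. Defaults encode the published summary magnitudes of the
instrument this machinery was built around: 17 facets in 6 domains;
standardized loadings 0.8 at both levels; mean inter-domain correlation .32
(implemented as a constant off-diagonal — the published correlations range
widely around that mean, but the mean is the quantity the analysis
reproduces); four response categories with mildly right-skewed thresholds
$(-0.2, 0.6, 1.4)$, emulating the skew of maladaptive-trait items (a
symmetric option remains available). The pool template plants two
high-loading items ($\lambda = .8$) per facet among weaker distractors
($\lambda = .4$), so recovery of the planted pairs is a measurable target.
Group overrides shift thresholds, scale loadings, or shift domain means;
careless responders (constant or uniform-random rows) and MCAR missingness
can be injected.

Because generation and estimation share one distributional family, passing
recovery tests demonstrates *self-consistency*, not robustness: real data
bring non-normal latent distributions, cross-loadings, local dependence,
and non-ignorable missingness, none of which the generator produces.
Conclusions about those require real data.

Simulation sizes used by the test suite are the generator's natural working
points: $n = 2000$ for pipeline-scale runs (mirroring the construction
sample's training size), $n = 1500$ per group for invariance, $n = 500$ for
the calibration study, 20 seeded replications for stochastic search
properties.

## The invariance ladder

Four nested multi-group models are fitted to per-group thresholds and
polychorics jointly, with the discrepancy extended by threshold residuals
weighted by their binomial/delta variances:

1. *Configural*: thresholds free per group (they reproduce the margins),
   standardized congeneric structure free per group.
2. *Equal thresholds and intercepts*: thresholds shared; item intercepts
   fixed at zero with free latent domain means and free item scales in
   non-reference groups (the standard ordinal identification trade).
3. *+ equal loadings*: unstandardized first- and second-order loadings
   shared; domain covariances, facet disturbances, residual variances, and
   latent means free elsewhere.
4. *+ equal residual variances.*

Shared thresholds enter the discrepancy linearly given everything else and
are concentrated out in closed form. Levels are fitted constrained-first
and each warm-starts the next less constrained level, so the nesting
property (discrepancy non-increasing from level 4 down to level 1) holds by
construction; a level passes relative to its predecessor when the CFI drop
and SRMR rise are both below .01 and the RMSEA 90% intervals overlap. For
exactly duplicated groups the discrepancy is identical at all four levels;
CFI and RMSEA still move at the $10^{-3}$ scale because their
degrees-of-freedom corrections differ by level — arithmetic of the index
definitions, not misfit.

## Numerical choices and edge cases

* Zero-frequency categories are collapsed into the adjacent lower category
  (the first category collapses upward), loudly logged, so a pool item with
  an empty top category never halts a run.
* Pairwise deletion handles missing responses in the polychorics; facet
  scores require half of a facet's items observed (configurable).
* A non-PSD polychoric matrix is eigenvalue-clipped (floor $10^{-6}$) and
  rescaled to unit diagonal, logged.
* DWLS starts are fixed (loadings 0.7, variances 0.5, domain correlations
  0.2) so fits are reproducible; one fallback restart at 0.4 on
  non-convergence, plus a machine-precision polish when the discrepancy is
  near zero. Heywood detection flags negative disturbances or uniquenesses,
  standardized loadings above 1, and out-of-range latent correlations;
  flagged parameters are reported, never silently clipped.
* Ridge regularization ($10^{-6}\cdot\mathrm{tr}/p$) keeps the Mahalanobis
  screen stable when few categories make the item covariance near-singular.
* "Average longstring" is the mean maximal-run length of identical
  consecutive responses (runs broken by missingness); the even-odd screen
  splits facets by item position and applies the Spearman–Brown correction.
  Both indices are right/left-skewed even for clean simulated responders,
  so the two-sided 2.5-SD inclusion rule trims about 5% of a clean sample —
  a property of the rule itself, worth knowing before applying it.

## Known limitations

* Facet and domain scores are means of their parts (configurable nowhere:
  this keeps short and long forms on one scale); published raw-score tables
  that used sums differ by a constant factor.
* The engine fits correlation structures; latent means enter only through
  the invariance ladder's threshold model. Full-information ML and Bayesian
  re-estimation of inadmissible solutions are out of scope — Heywood cases
  are flagged and excluded, not re-estimated.
* The scaled chi-square uses a jackknife covariance estimate whose rank is
  bounded by the number of blocks; for models with more free parameters
  than blocks the scaling is conservative. Reported fits of 34-item models
  with 30 blocks sit below that bound for the tau-equivalent mode and
  slightly above for the congeneric mode, where the scaling factor is then
  a mild underestimate.
* Search guarantees are empirical (oracle equivalence on enumerable pools,
  planted-structure recovery), not worst-case.
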