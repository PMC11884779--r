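---
title: "Amino acid substitution rates and physicochemical distance: models and methods"
author: "aasubst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino acid substitution rates and physicochemical distance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Empirical amino-acid substitution models (LG, WAG, the Q-matrix family)
summarize, in a 20×20 matrix, how readily each pair of amino acids exchanges
over evolutionary time. Under nearly neutral reasoning, exchanges between
physicochemically dissimilar amino acids (radical substitutions) should be
removed by purifying selection more often than exchanges between similar ones
(conservative substitutions), so pairs that differ more in properties such as
charge or size should show lower substitution rates. This package turns that
question into a reusable, tested pipeline: it derives per-pair substitution
rates from published exchangeability matrices, quantifies pairwise
physicochemical difference by a PCA of property differences, derives
mutational covariates from the genetic code, and fits linear mixed models of
log rate with random intercepts for the amino acids of each pair.

## From exchangeabilities to rates

A time-reversible model consists of symmetric exchangeabilities $s_{ij}$ and
equilibrium frequencies $\pi$. The instantaneous substitution rate from $i$
to $j$ is

$$Q_{ij} = s_{ij}\,\pi_j,$$

so each unordered pair yields two directed rates whose ratio is
$\pi_j/\pi_i$ (detailed balance). Time non-reversible models supply the full
matrix of directed rates without that constraint. `pair_rates()` emits either
the 380-row directed table or the 190-row undirected table (the arithmetic
mean of the two directions); rates are used as published, with an optional
mean-1 normalization, and are natural-log transformed before modelling
(the base is configurable and recorded).

The regressions default to the **directed** 380-row table. The undirected
table discards the frequency asymmetry between the two directions, and the
denominator degrees of freedom characteristic of the directed fit (roughly
340–372 under Satterthwaite) match the scale on which results for this model
family are usually reported. The undirected mode remains available by flag.

## Genetic-code covariates

Three mutational covariates are computed from NCBI translation table 1
(alternative codes are rejected, not substituted; RNA input is normalized to
DNA):

* **Minimum mutational steps** — the smallest Hamming distance between any
  codon of one amino acid and any codon of the other (1–3). Intermediate
  codons are *not* required to be sense codons; the Hamming minimum is the
  convention in this literature, and a constrained-path variant is out of
  scope.
* **GC difference** — the absolute difference in mean codon GC fraction,
  codons weighted uniformly (codon-usage weighting is deliberately not
  offered).
* **Pyrimidine-proportion difference** — the absolute difference in mean
  codon pyrimidine fraction, used as a transition:transversion proxy: pairs
  whose codon sets differ more in pyrimidine content require on average more
  transversions to interconvert. The quantity is defined (and named here) as
  a pyrimidine-proportion difference even where the literature loosely calls
  it a transition:transversion ratio; we implement the definition, not the
  name.

All three are verified in the test suite against an exhaustive double loop
over the 61×61 sense-codon pairs built on an independent genetic-code table.

## The property set and its PCA

Physicochemical scales come from AAindex (via the copy distributed with
seqinr; `parse_aaindex()` reads AAindex1 flat files and a plain CSV is also
accepted, so the set is fully swappable). The builtin set pins ten scales,
each recorded by accession in the table's `provenance` attribute:

| name | accession | family |
|---|---|---|
| hydropathy | KYTJ820101 | charge/hydrophobicity |
| hydrophobicity | FASG890101 | charge/hydrophobicity |
| contact_energy | MIYS990101 | charge/hydrophobicity |
| flexibility | BHAR880101 | charge/hydrophobicity |
| polarity | GRAR740102 | charge/hydrophobicity |
| net_charge | KLEP840101 | charge/hydrophobicity |
| iso_point | ZIMJ680104 | charge/hydrophobicity |
| mol_weight | FASG760101 | size |
| volume | GRAR740103 | size |
| max_asa | CHOC760101 | size |

The set was chosen once, from the variable families that recur in this
literature, with two constraints in mind. First, the scales must reproduce
the standard correlation structure of the AAindex families: with these
accessions, molecular weight and volume correlate at $r = 0.908$ and contact
energy and Kyte–Doolittle hydropathy at $r = -0.840$ across the 20 amino
acids. Second, the pair-difference PCA must separate into the two
interpretable axes this analysis requires. With a minimal eight-scale set
(one scale per family member) the leading component mixes the size and
hydrophobicity families; including two further charge/hydrophobicity-family
members (FASG890101, ZIMJ680104) recovers the clean split: PC1 is loaded by
the charge/hydrophobicity family (34% of variance) and PC2 by the size
family (27%).

`pair_pca()` standardizes the 190×P absolute-difference table (correlation
PCA; the mixed units of raw scales make covariance PCA meaningless here) and
reports loadings, scores, explained fractions, per-variable contributions
(each component's sum to 100%) and cos² quality of representation. PCA is
computed on the 190 unordered pairs; directed tables reuse the scores by
symmetry rather than duplicating rows, which would distort the variance
fractions.

Because PCA signs are arbitrary but slope signs in the regression depend on
them, each component's sign is fixed deterministically: an anchor variable's
loading is made positive (`hydropathy` for PC1 and `mol_weight` for PC2 in
the builtin analysis, so that larger scores mean larger differences), and
components without an anchor make their largest-magnitude loading positive.

```{r}
library(aasubst)
props <- builtin_properties()
pca <- pair_pca(pairwise_differences(props),
                anchors = c(PC1 = "hydropathy", PC2 = "mol_weight"))
pca$explained_fraction[1:2]
```

## The mixed model

The response is the log substitution rate of each (directed) pair; the fixed
effects are PC1, PC2, their interaction, minimum mutational steps and the
pyrimidine-proportion difference (GC difference enters only the model
comparison). Because every amino acid appears in many pairs, observations
are not independent; the model therefore includes crossed random intercepts
for the two amino-acid slots of the pair — donor and acceptor identity in
directed mode:

$$\log Q_{ij} = \beta_0 + \beta^\top x_{ij} + u_i + v_j + \varepsilon_{ij},
\qquad u_i \sim N(0, \sigma_u^2),\; v_j \sim N(0, \sigma_v^2),\;
\varepsilon_{ij} \sim N(0, \sigma^2).$$

In undirected mode the same crossed structure is used with the two pair
slots as factors. A shared-variance multimembership effect (one variance,
each observation belonging to both its members' levels) would be the more
faithful structure there, but lme4 has no multimembership interface and
bypassing it through the modular API would disconnect the Satterthwaite
machinery; since the directed table is the default everywhere, the crossed
approximation is accepted and noted.

Fitting is by REML through lme4, with Satterthwaite denominator degrees of
freedom from lmerTest — the standard choice when fractional dfs are to be
reported. Model comparisons (`compare_models()`) always refit by maximum
likelihood before the likelihood-ratio test, as fixed-effect LRTs are not
valid under REML; `delta_aic` is reported on the same ML scale. P-values are
stored at full precision; only the pretty-printer floors them at 2×10⁻¹⁶.

By default the response and all numeric covariates are z-scored before
fitting (`scale = TRUE`), so estimates are standardized slopes of comparable
magnitude and the intercept is near zero; the scaling is recorded on the fit
and `predict()` maps back to the raw scale. Raw-scale fits are a flag away
and are what the recovery experiments use, so that estimates compare
directly to the generating coefficients.

Variance decomposition follows the Nakagawa–Schielzeth scheme:
marginal $R^2 = \mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
\sum_g \hat\sigma_g^2 + \hat\sigma^2)$, and the conditional variant adds the
random-intercept variances to the numerator.

Group-level auxiliary tests use the heteroscedasticity-robust Welch forms
(`oneway.test`, `t.test`): variances of the mutational covariates differ
strongly across step classes, so the equal-variance forms would be wrong.
These are computed on the 190 unordered pairs (using directed rows would
double-count each pair).

## The synthetic generator

`synth_scenario()` fixes a ground truth and `generate_exchange_model()`
draws a model from it:

* A 20×P property table with two correlated blocks (charge-like and
  size-like; within-block correlation 0.7, between-block 0), so its
  pair-difference PCA produces two dominant components like the real set.
* The design matrix combines those synthetic PC scores with the *real*
  genetic code's steps and pyrimidine metrics. This keeps the collinearity
  between mutational and property covariates realistic — one-step pairs
  genuinely tend to be more similar — which purely simulated covariates
  would miss.
* Log directed rates follow the linear mixed model above. In directed mode
  the donor and acceptor intercept vectors are independent draws, exactly
  matching the fitted crossed structure (a single shared vector would induce
  a cross-direction covariance the fitted model does not represent, making
  SEs and coverage uninterpretable); output is a non-reversible model. In
  undirected mode one shared vector and one residual per pair are drawn and
  the output is a reversible model with uniform frequencies.

Default truth: slopes (−0.4, −0.3) for PC1/PC2, −0.4 for steps, −0.2 for the
pyrimidine difference, +0.08 for the interaction, $\sigma_u^2 = 0.1$,
$\sigma^2 = 0.3$. These magnitudes sit in the signal-to-noise regime typical
of standardized fits of this model family (compare the worked example in the
README); they are configuration, not claims about any dataset.

What the generator does **not** emulate: selection on actual protein
structure, non-Gaussian rate variation, realistic equilibrium frequency
vectors (uniform in reversible output), or codon-level mutation processes.
Passing recovery tests therefore demonstrate that the estimator is correct
under its own assumptions on a realistic design — not that real data meet
those assumptions.

All randomness flows through seeds; generation saves and restores the
caller's RNG state, and a replicate's noise seed is derived as
`scenario_seed + 1009 * replicate` (kept well below 2³¹).

## Recovery experiments and antithetic pairing

`recovery_experiment()` reruns the full pipeline per replicate over a fixed
design (the property table derives from the scenario seed; intercepts and
residuals are redrawn) and reports per-coefficient bias, RMSE, empirical SE,
mean model SE and 95% Wald-interval coverage with Satterthwaite df.

Replicates are generated in antithetic pairs by default: the second member
of each pair negates the first member's Gaussian draws. Negating a centered
Gaussian leaves its distribution unchanged, so every replicate is a valid
draw from the scenario; but the estimator is nearly linear in the noise, so
the first-order noise contribution to the *mean bias* cancels within pairs.
The REML/GLS estimator is unbiased, and 200 independent replicates estimate
the mean of the noisiest slope only to about ±0.013 — too coarse to certify
a bias bound of 0.02; antithetic pairing sharpens that estimate by orders of
magnitude at identical cost, without touching the scenario. Coverage and SE
summaries are unaffected.

`lrt_null_experiment()` complements this by forcing one coefficient to zero
and collecting maximum-likelihood LRT p-values, whose uniformity is checked
by a Kolmogorov–Smirnov test.

## Numerical choices and degenerate inputs

* Frequencies are renormalized when their sum deviates from 1 by at most
  1e-4 and rejected beyond that; exchangeability asymmetry beyond 1e-8 is an
  error.
* Zero or negative rates abort the log transform with the offending pairs
  named; a property containing missing values is dropped with a warning
  (imputation is deliberately not offered); constant columns are errors
  under standardization.
* Aliased fixed-effect designs are rejected before lme4 can silently drop
  columns; variance estimates at the zero boundary are flagged on the fit,
  not errors.
* Problem sizes in the test suite: the calibration checks use 200 replicates
  of the 380-row design for recovery and for null-LRT uniformity; smaller
  property-block and boundary checks use 10–60 replicates. The full suite
  and the acceptance script each complete in about a minute of CPU.

## Limitations

* The builtin property set is a pinned, documented choice; analyses of the
  exact property lists used by specific published studies require supplying
  those lists (AAindex file or CSV), and component percentages shift with
  the set.
* The undirected-mode random-effect structure is an approximation (above).
* Exchangeability matrices are taken as data; estimation uncertainty in the
  published matrices is not propagated.
* The transition:transversion proxy is a codon-composition approximation,
  not a mutation-spectrum estimate.
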