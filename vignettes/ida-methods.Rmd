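---
title: "Outcome-blinded initial data analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-blinded initial data analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package does and why

Before a prespecified multivariable regression model is fitted, the
analysis team needs reliable knowledge of the *predictor side* of the
data: how much is missing and in what patterns, how each variable is
distributed, and how the predictors relate to each other. Acting on such
knowledge after peeking at predictor–outcome associations invites
post-hoc bias; not acting on it invites broken models (inestimable
categories, wild collinearity, imputation of the unimputable).

`idascreen` implements this screening phase as a deterministic,
reproducible pipeline that is *structurally incapable* of evaluating
predictor–outcome associations: the outcome enters only its own
univariate summary, and by default the outcome column is first detached
and permuted ("blinded") with a seeded permutation, so even an
accidental association query would return noise. Screening results feed
a rule engine whose thresholds are fixed in the plan *before* the data
are seen; triggered rules become recommended amendments to the
statistical analysis plan, with a full evidence trail, never automatic
changes.

## The screening pipeline

The pipeline is organized as a checklist with three computation domains;
every report section carries its checklist tag (PRE1–PRE4, M1–M4, ME1,
U1–U2, UE1, V1–V3, VE1–VE3) so coverage can be audited mechanically.

### Missing values (M1–M4, ME1)

* **Unit missingness (M1)** can only be passed through from enrollment
  counts; for registry exports it is reported as explicitly
  "not evaluable" rather than silently skipped.
* **Item missingness (M2)** is a count and proportion per variable,
  outcome and structural variables included.
* **Complete cases (M3)** are computed per candidate model set; an
  observation is complete for a set iff the outcome and every member are
  observed. Rows with a missing outcome are incomplete in every set.
* **Patterns (M4)** use the *discordance* between two variables'
  missingness indicators: `d(i,j)` is the exact fraction of rows where
  one is missing and the other is not. It is a genuine distance
  (`|p_i - p_j| <= d(i,j) <= min(1, p_i + p_j)`), and average-linkage
  agglomerative clustering on it yields the missingness dendrogram.
  Average linkage is the default because it keeps intermediate merge
  heights readable; complete and single linkage are selectable. Pairs of
  variables that are missing together sit near height zero.
* **Predictors of missingness (ME1)** contrast structural variables
  between complete and incomplete cases using standardized mean
  differences (continuous) or per-level proportion differences
  (categorical). No hypothesis tests: a p-value here would be inference
  smuggled into screening.

### Univariate descriptions (U1, U2, UE1)

Continuous summaries report extremes, the plan's quantile set
(5/10/25/50/75/90/95% by default, a 1–99% preset available), mean, SD,
IQR, Gini mean difference, number of distinct values, the five lowest
and highest values, and the mode with its frequency. Quantiles use the
linear-interpolation convention (R type 7) — a reporting choice with no
downstream effect on decisions. The *concentration ratio*
(modal frequency over average frequency per distinct value) and the
modal proportion drive spike detection: a variable whose mode holds at
least 40% of the observations (threshold `spike_mode_prop`, boundary
inclusive) is flagged; a spike at zero cannot be removed by any
monotone transformation, making such predictors discard candidates.

### Transformation selection

Right-skewed laboratory values distort scatterplots, clustering and
VIFs. Two candidate symmetrizing transforms are assessed per continuous
predictor:

* the **pseudo-log** `asinh(x / (2 sigma)) / log(b)` — defined at zero
  and for negatives, antisymmetric, and equal to `log_b(x)` up to
  `O((sigma/x)^2)` for large `x`; `sigma` (default 1, per-variable
  overrides in the plan) sets the scale below which it is linear;
* the **signed cube root** `sign(x) |x|^{1/3}`.

Success is measured by the *normal-scores correlation*: the correlation
of the sorted sample with standard-normal quantiles at Blom plotting
positions `(i - 3/8)/(n + 1/4)`. The statistic is location–scale
invariant, so the criterion is insensitive to the plotting-position
convention. A transform is adopted when it raises this correlation by
more than `normdev_gain = 0.2`; the pseudo-log wins ties of eligibility.
Chosen transforms are materialized as `t_`-prefixed columns and
propagate to scatter displays — *not* to the correlation screen itself,
since Spearman correlations are invariant under strictly monotone maps
(a property the test suite asserts to machine precision).

One calibration fact worth knowing: for lognormal data the gain crosses
0.2 right around `sigma_log = 1` at realistic sample sizes, and the raw
normal-scores correlation rises as `n` falls. Variables with
`sigma_log` near 1 are therefore genuine boundary cases that may land
on either side; the synthetic-data recovery tests assert selection only
from `sigma_log >= 1.2`.

### Multivariate descriptions (V1–V3, VE1–VE3)

* Correlation matrices are **pairwise-complete** Spearman (average
  ranks for ties) and Pearson; entries with fewer than `min_pairs = 30`
  complete pairs are flagged unreliable, and pairs with fewer than 2 are
  undefined. Binary variables enter as 0/1 numerics (Spearman on a
  binary variable is the rank-biserial correlation up to sign).
* Pairs whose Spearman and Pearson coefficients differ by more than 0.1
  are listed for scatterplot review — such divergence usually means
  influential points or nonlinearity.
* **Variable clustering** uses similarity `rho_S^2` (squared Spearman,
  so strong negative association clusters too) with distance
  `1 - rho_S^2` and average linkage; pairs with `rho_S > 0.8` are listed.
* **VIF** is computed on the complete cases of each candidate set,
  outcome excluded. Linear basis: the diagonal of the inverse
  correlation matrix. Additive basis: each continuous predictor is
  expanded in a restricted cubic spline (4 knots for key predictors, 3
  otherwise — more flexibility where more model complexity is planned —
  at equally spaced quantiles, 5–95% boundaries), and a generalized VIF
  per predictor comes from the determinant formula, reported raw and as
  `(GVIF^{1/(2 df)})^2` for cross-dimension comparability. A
  near-singular system (eigenvalue ratio beyond 1e12) yields explicit
  "infinite" markers per variable rather than noise or an exception —
  exactly what happens for a full set of compositional percentage
  variables that sum to 100.
* **Redundancy analysis** iteratively regresses each remaining
  predictor on all others with the additive basis and removes the
  best-predicted one while its R² exceeds 0.9. The fits are refused
  when the complete cases are fewer than three times the expanded
  design dimension: below that, every predictor looks "perfectly
  predictable" purely through overfitting (we observed exactly this on
  a 51-predictor set with ~100 complete cases, which is why the guard
  exists).

### Consequence rules

Eight deterministic rules translate screening results into findings
(details on `?apply_consequence_rules`). Two design points deserve
mention. First, findings are *recommendations*; published analyses mix
rule-triggered and expert-judgment exclusions, and an engine should not
pretend to automate judgment. Second, the part–whole rule emits a
concrete reparameterization: when a whole W and its dominant component
C (declared via `component_of` in the dictionary) are collinear, the
derived variable `W_NO<C> = W - C` retains all information while
removing the built-in correlation — e.g. replacing a total leukocyte
count with "leukocytes minus neutrophils" next to neutrophils.

The correlated-missingness block rule uses a within-block discordance
ceiling of 0.05: variables that are missing *together* cannot serve
each other in imputation models, which strengthens the case for
omitting those with high missingness. The 0.05 value is a design
choice (the qualitative criterion is "highly correlated missingness");
it is a plan threshold and overridable like all others.

### Blinding

The outcome column is permuted as a unit — a missing outcome cell
travels with its value — by a seeded uniform permutation. This
preserves the outcome's marginal distribution and item-missingness
proportion exactly, destroys every predictor–outcome association in
expectation, and leaves all predictor columns byte-identical. Because
no screening computation touches predictor–outcome associations,
screening output is *identical* with and without blinding (asserted by
the test suite); blinding is pure protection against accidental or
deliberate peeking, imitating blinded data review in clinical trials.
The permutation's seed and checksum are recorded for provenance.

## The synthetic study generator

`default_bacteremia_like_spec()` defines a 51-predictor study emulating
the structure of routine clinical laboratory data: lognormal
concentrations; a 5-component cell-count block whose total is the
component sum times small multiplicative noise ("approximately but not
exactly"); percentage forms of each component; zero-inflated components
at 87% and 48% zeros; block-correlated missingness (a shared missing
indicator per panel plus 1% individual noise, giving within-block
discordance ~0.02 against a 0.05 rule ceiling); two individually
missing panels above 20%; one planted Spearman-0.92 pair realized by a
Gaussian copula (latent correlation `2 sin(pi rho/6)`); and an 8%
binary outcome drawn independently of every predictor. Sample size
defaults to 2000. Every planted feature is returned in a ground-truth
record so tests can act as oracles.

Choices where the emulated study fixes no value: block missingness
probabilities (0.35 / 0.22 / 0.12) and the mid-band individual
proportions were set so that the *pattern* matches the emulated study —
about seven predictors above 20% missingness (three above one third),
ten between 10 and 20%, the key-predictor set ~94% complete. The
maximum planted missingness is ~36%; overall completeness across all 51
predictors is lower than in the real study it mimics because real
laboratory data have panel-wide correlated missingness beyond the
planted blocks. Marginal means/scales are loosely typical clinical
values; no attempt is made to match a real joint distribution.

What passing tests on this fixture do show: exact recovery of planted
missingness blocks, spikes, strong-skew transforms, high-correlation
pairs, composition-block VIF and the part–whole rule. What they cannot
show: behavior under real-world quirks such as digit preference,
detection limits (other than spikes at zero), rounded reporting
resolutions (which deflate distinct-value counts and hence inflate
concentration ratios relative to unrounded simulation), or
missingness mechanisms tied to unmeasured severity.

## Numerical conventions and degenerate inputs

* Gini mean difference via the sorted-prefix identity
  `2/(n(n-1)) * sum_i (2i - n - 1) x_(i)` (O(n log n)), equal to the
  all-pairs definition to 1e-12 relative tolerance; needs `n >= 2`, and
  is 0 for constant input.
* Mode ties are broken toward the smallest value, deterministically.
* Normal-scores correlation requires 3 distinct values; variables
  failing this are "not assessable", never an error mid-pipeline.
* Missingness dendrograms need two or more variables with missing
  values; otherwise the section reports that fact.
* Correlation entries from fewer than 2 complete pairs are undefined
  (`NA`); variables with undefined entries are excluded from clustering
  with notice.
* All randomness (blinding, synthesis) flows through one seeded
  routine that restores the caller's RNG state; identical inputs and
  seed give byte-identical machine-readable output (timestamps live
  only in the human-readable report).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline on the
default synthetic study at n = 2000 (the generator default) and on
reduced instances (n = 200–1200) for brute-force cross-checks, chosen
so each oracle comparison is exact or within stated Monte-Carlo bounds.

## Known limitations

* Unit missingness cannot be computed from a data table; it is
  pass-through only.
* Measures of association for pairs of *categorical* predictors are
  limited to the 0/1 coding of binary variables; polytomous nominal
  predictors appear in univariate and missingness screening but not in
  the correlation matrices.
* Redundancy analysis requires generous complete cases relative to the
  expanded spline design and will (correctly) refuse large candidate
  sets with few complete observations.
* The rule engine recommends; it never edits the model. Judgment calls
  — e.g. whether to drop further components of a collinear family —
  remain with the analysis team, as they should.
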