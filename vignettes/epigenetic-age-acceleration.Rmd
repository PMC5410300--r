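---
title: "Epigenetic age acceleration and prospective cancer incidence: methods"
author: "epiclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic age acceleration and prospective cancer incidence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclock)
```

## The scientific question

DNA methylation at a small number of CpG sites changes so reproducibly
with age that linear "epigenetic clocks" predict chronological age from
blood methylation with correlations above 0.9. A subject whose predicted
("DNAm") age runs ahead of their chronological age is epigenetically
*accelerated*, and accumulating evidence ties blood age acceleration to
later morbidity — including cancers diagnosed years after the blood
draw. `epiclock` implements the full analysis chain for asking that
question in a prospective case–control methylation cohort:

1. estimate DNAm age per subject under several clocks;
2. convert it into **control-anchored age acceleration**;
3. compare prospective cancer cases against age-matched, same-sex
   controls;
4. relate acceleration to cancer incidence with Kaplan–Meier curves and
   the log-rank test.

A synthetic-cohort generator with known ground truth makes every stage
testable without access to a real HM450 series.

## The clocks

A clock is a linear predictor on beta values (methylated fractions in
$[0,1]$): $\widehat{\mathrm{age}} = g\!\left(b_0 + \sum_i w_i \beta_i\right)$.
Three clocks with fully published coefficients are built in:

| clock   | CpGs | formula (years) |
|---------|------|-----------------|
| weidner | 3    | $38.0 - 26.4\,\beta_{\mathrm{cg02228185}} - 23.7\,\beta_{\mathrm{cg25809905}} + 164.7\,\beta_{\mathrm{cg17861230}}$ |
| elovl2  | 1    | $158.81\,\beta_{\mathrm{cg16867657}} - 42.35$ |
| fhl2    | 1    | $198.6\,\beta_{\mathrm{cg06639320}} - 30.12$ |

One printing of the three-CpG blood clock omits the operator before the
23.7 term. We use subtraction: it matches the original model's published
signs, and it is the only reading under which beta profiles in $[0,1]$
map onto plausible adult ages (addition would push outputs past 180
years for ordinary blood profiles). This choice is deliberate and
documented rather than silent.

Larger clocks (353-CpG multi-tissue, 71-CpG blood) are supported as
plug-ins via `load_clock_coefficients()`: a two-column
`probe_id,coefficient` file with one `(Intercept)` row, optionally
evaluated through the two-branch log-linear age calibration
(`horvath_inverse_transform()`, knot at `adult_age = 20` years,
configurable). Their published coefficient tables are not shipped; a
synthetic 353-row stand-in exercises the loader in the tests.

Missing betas fail loudly by default. Per-probe mean imputation — what
online calculators typically do — is available behind `impute = TRUE`,
and is a deliberate opt-in because silent imputation changes estimates.

## Control-anchored acceleration

"Acceleration" is only meaningful relative to a reference trajectory.
Following standard practice we fit, **on cancer-free controls only**,
the ordinary least squares model

$$\mathrm{DNAmAge} = \alpha + \gamma\,\mathrm{age} + \varepsilon
\qquad\text{(Age Accel)}$$

or, for the intrinsic variant (IEAA),

$$\mathrm{DNAmAge} = \alpha + \gamma\,\mathrm{age} +
\sum_{k=1}^{7}\delta_k\,c_k + \varepsilon$$

with $c_k$ the seven estimated blood cell abundances (naive CD8 T,
exhausted CD8 T, plasma B, CD4 T, NK, monocytes, granulocytes) supplied
as an input covariate table — cell deconvolution itself is out of scope.
Every subject's residual against the control fit is their acceleration
in years. OLS guarantees residuals of the fitting controls average
exactly zero and are orthogonal to age and to each covariate; the test
suite asserts both at $10^{-8}$.

Numerical choices worth knowing:

* **Fit scope.** By default each stratum's regression is anchored on its
  *own matched controls* (`fit_scope = "stratum"`), so residual
  centering holds inside every comparison; `fit_scope = "pool"` fits
  once on the full control pool instead. Whether the original analyses
  did one or the other is not documented; we chose the option that makes
  each stratum's test self-contained.
* **Degenerate covariates.** A zero-variance covariate column is
  unidentifiable next to the intercept and carries no information; it is
  dropped with a warning (residuals are provably unchanged). Any
  remaining collinearity — the classic case being cell *fractions* that
  sum to one, which are exactly collinear with the intercept — raises an
  error at a condition-number threshold of $10^8$ rather than being
  silently repaired.
* **Minimum controls**: 3 unadjusted, 10 adjusted, plus a hard
  requirement of more controls than coefficients.

## Matching and group comparison

Cases are analyzed per sex × tumor stratum (breast–female, CRC–male,
CRC–female; breast–male only if such cases exist; "other" cancers are
excluded everywhere). For each stratum an equal-sized control subgroup
with the same mean age is selected at random from the same-sex
cancer-free pool: among `n_draws = 1000` seeded random subsets, the one
maximizing the Wilcoxon p-value of age between groups is kept, subject
to a hard mean-age gap tolerance of `tol = 0.5` years. This "best of
many random draws" design directly mirrors the matching diagnostic such
studies report (a Wilcoxon p on age at recruitment); greedy nearest-age
matching was rejected because it destroys the randomness the design
describes. Inside the scoring loop a tie- and continuity-corrected
normal approximation ranks the candidate subsets; the reported
diagnostic for the selected subset uses the full test. When the pool
cannot out-size the case group — the CRC-male situation, 84 male
controls for 87 cases — the entire pool is used unmatched and the
diagnostics say so.

Case–control differences are tested with the two-sided
Wilcoxon–Mann–Whitney test (residuals adhere only imperfectly to
normality): midranks for ties, exact enumeration of all labelings when
both groups have ≤ 10 observations and no ties, otherwise the normal
approximation with continuity and tie corrections. No multiple-testing
correction is applied — matching the presentation style this analysis
emulates — but the output tables carry the number of tests per stratum
so users can apply their own.

## Survival analysis

Each subject is dichotomized by the sign of their residual: accelerated
($+1$, residual $\ge 0$) or decelerated ($-1$). Zero residuals are a
measure-zero event; the $\ge$ convention is documented and tested.
Cases enter the risk set until their time to diagnosis (event = 1);
controls are right-censored at a fixed
`derive_censor_time()` $= 2010 - \tfrac{1993+1998}{2} = 14.5$ years —
the average follow-up implied by a recruitment window when individual
enrollment dates are unavailable. At a tied event/censoring time the
censored subjects remain at risk (events precede censorings, the
standard convention).

Survival per group uses the Kaplan–Meier product-limit estimator;
groups are compared with the Mantel–Haenszel log-rank test (1 df). A
comparison with no events at all is *undefined* and raises an error —
it is never reported as $p = 1$. The implementation is validated against
`survival::survfit()`/`survdiff()` (used strictly as independent test
oracles) on exhaustively enumerated small designs.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a prospective HM450
blood study, with defaults stating a specific world:

* **Strata**: breast–female 233/233, CRC–male 87/84, CRC–female 79/79 —
  the analyzed group sizes of the emulated study.
* **Ages**: uniform on 35–64 years (the recruitment window), giving an
  age sd of ≈ 8.4 years.
* **Clock noise**: for each subject and clock, an *effective epigenetic
  age* = age + $\delta_{\mathrm{clock}}$·[case] + $\varepsilon$,
  $\varepsilon \sim N(0, 3.0^2)$ years. Injecting noise on the age scale
  makes one parameter comparable across clocks. With age sd 8.4 y and
  noise sd 3.0 y the design correlation between a clock CpG and age is
  ≈ 0.94, clearing the ≈ 0.91 reported for the strongest single-CpG
  clocks with margin (the noiseless limit gives 1; noise sd equal to
  the age sd attenuates Spearman to ≈ 0.71 — both verified by
  simulation). Noise is independent across clocks by default;
  `shared_noise = TRUE` gives one latent aging deviation per subject,
  better mimicking real inter-clock correlation.
* **Betas** are obtained by inverting each clock's formula at the
  effective age, e.g. $\beta_{\mathrm{cg16867657}} =
  (\mathrm{eff} + 42.35)/158.81$. The three-CpG clock is split into
  three single-probe sub-models with intercepts (30, 28, −20) years —
  summing to the full 38.0 intercept — each carrying eff/3, so all
  three betas stay inside $[0,1]$ for effective ages ≈ 20–90 and
  re-evaluating the clock reassembles the effective age exactly
  (round-trip tested at $10^{-6}$ in the noiseless limit). Out-of-range
  betas are clipped and counted; if more than 1% of betas clip,
  generation aborts with advice, because systematic clipping would bias
  the clocks.
* **Cell counts**: a Dirichlet draw over the seven leukocyte types
  (concentration ∝ a typical adult differential, granulocytes ≈ 60%)
  scaled by a per-subject lognormal total count (≈ 4–11 × 10⁹/L). The
  scaling matters: raw fractions sum to one and would make the IEAA
  design exactly singular; abundances are what deconvolution tools
  actually report. The underlying fractions are kept in the ground
  truth, where their sum-to-one invariant is tested.
* **Diagnosis times**: truncated normals (at 0.1 y) with means/sds
  3.84 ± 2.87 y (breast-like) and 5.11 ± 2.59 y (CRC-like). No
  published value exists for CRC males; they default to the CRC-female
  parameters, a flagged stand-in.

What the generator does **not** emulate: genome-wide probe content
(only clock CpGs are simulated), batch and chip effects, probe-type
chemistry, cell-composition–age coupling, and non-linear aging. A green
test therefore establishes that the *pipeline machinery* is correct and
well-calibrated under the stated world — not that any biological claim
about real cohorts is reproduced. Real-data headline numbers (specific
p-values near 0.04, specific log-rank tables) depend on the actual
accession and are deliberately outside the test surface.

## Reproducibility

One master seed drives everything. `derive_seed(seed, stage)` hashes a
stage label into a child seed below $2^{31}$, so the simulation and each
stratum's matching have independent, individually reproducible streams;
the same config yields byte-identical numeric outputs, which the tests
assert literally. Every output table is plain delimited text written at
≥ 10 significant digits, plus a JSON manifest echoing seed, versions and
configuration.

## Known limitations

* Only linear age trends are modelled in the anchoring regression; the
  emulated methodology's choice, not a claim about biology.
* The matching optimizes a single diagnostic (age Wilcoxon p); no
  multivariate or propensity matching.
* The log-linear calibrated scale is supported for plug-in clocks, but
  no shipped coefficient set uses it; it is exercised only by synthetic
  fixtures.
* With 87 cases and an 84-strong male control pool the CRC-male stratum
  is structurally unmatched; its diagnostics make that visible rather
  than pretending a selection happened.
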