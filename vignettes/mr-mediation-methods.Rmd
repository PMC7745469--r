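---
title: "Two-sample MR with two-step mediation screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mrmediate)
```

## The problem

Adiposity raises colorectal cancer risk, but the circulating pathways that
carry the effect are unresolved. mrmediate implements the summary-level
causal machinery for interrogating this kind of question: two-sample
Mendelian randomization (MR) of an exposure (e.g. BMI or waist-to-hip
ratio in SD units) on a binary outcome (log-odds scale), a two-step MR
screen of a metabolite panel as candidate mediators, and multivariable MR
(MVMR) to estimate direct effects net of a mediator.

Everything operates on GWAS summary statistics: per-variant effect
estimates $\hat\beta$ with standard errors, alleles and frequencies, from
non-overlapping study samples. The package never touches individual-level
data.

## Model and estimators

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its estimated
effect on the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its effect
on the outcome. If the variant is a valid instrument, the causal effect
$\theta$ satisfies $\beta_{Yj} = \theta \beta_{Xj}$, giving the Wald
ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$ (a second-order form adding the
exposure-uncertainty term is available behind a flag; the first-order
form is the convention of the standard workflow).

With $J \ge 2$ instruments the package fits, each from explicit weighted
normal equations with weights $w_j = 1/\sigma_{Yj}^2$:

* **IVW** — regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through
  the origin; consistent when no instrument is pleiotropic. The reported
  SE is the fixed-effect SE $(\sum_j w_j \hat\beta_{Xj}^2)^{-1/2}$
  multiplied by $\max(1, \sqrt{Q/(J-1)})$, a multiplicative
  random-effects scale floored at one so heterogeneity can widen but
  never narrow the interval. $Q$ is Cochran's statistic; $I^2 = \max(0,
  (Q - \mathrm{df})/Q)$.
* **MR-Egger** — the same regression with a free intercept, fitted after
  orienting all pairs to positive exposure effects. The intercept
  estimates average directional pleiotropy; the slope is consistent
  under the InSIDE assumption (pleiotropic effects independent of
  instrument strength). Residual heterogeneity $Q'$ has $J - 2$ degrees
  of freedom; both SEs carry $\max(1, \sqrt{Q'/(J-2)})$.
* **Weighted median** — the cumulative-weight-interpolated median of the
  $\hat\theta_j$ under weights $\propto \hat\beta_{Xj}^2/\sigma_{Yj}^2$;
  consistent when valid instruments carry more than half the weight.
* **Weighted mode** — the argmax of a weighted Gaussian kernel density
  of the $\hat\theta_j$; consistent when the largest cluster of
  instruments is valid. Bandwidth $h = \phi \cdot 0.9 \min(\mathrm{sd},
  1.4826\,\mathrm{mad}) J^{-1/5}$ with $\phi = 1$ by default, argmax on
  a 10,000-point grid spanning the ratios $\pm 3h$. If every ratio is
  identical, the common value is returned.

Median and mode SEs come from a seeded parametric bootstrap (default
1000 replicates; both beta vectors redrawn from their reported sampling
distributions, weights recomputed per draw), the procedure used in those
estimators' source publications. All intervals use the normal multiplier
1.959964 and two-sided normal p-values; no t-correction is applied to
MR-Egger, for consistency with normal inference throughout.

Inference conventions worth stating once: the random-effects floor means
IVW/Egger SEs never undercut their fixed-effect values; bootstrap SEs
are bit-reproducible under a fixed seed; and with all exposure betas
identical MR-Egger refuses to fit (the regression is unidentified) with
a collinearity error.

## Instrument selection, harmonization, diagnostics

Instruments are genome-wide-significant ($P < 5\times10^{-8}$, strict)
variants thinned by greedy LD clumping at $r^2 < 0.001$: candidates are
ranked by p-value (ties broken lexicographically by variant id, for exact
reproducibility), the best is kept, and everything correlated at or above
the threshold with a kept variant is removed. LD is supplied as an
explicit matrix — user-provided or simulated — rather than computed from
a reference panel, which keeps the package desk-scale.

Harmonization aligns the outcome record of every shared variant onto the
exposure's effect-allele frame, assuming forward-strand coding but
tolerating recorded flips: identical alleles are kept; swapped alleles
flip the outcome beta; strand-complement alleles are complemented first.
Palindromic variants (A/T, C/G) carry no letter information, so they are
resolved by allele-frequency agreement, and only when both studies'
frequencies fall outside the ambiguity window (0.42, 0.58) — otherwise
(or when either frequency is missing) they are dropped. The window is
the conventional default of the standard harmonization workflow; the
counts in published instrument lists cannot pin it down more precisely.
A variant absent from the outcome study is dropped with its own status
tag; no proxy lookup is attempted.

Instrument strength uses the large-sample variance-explained
approximation for a standardized trait, $R^2_j = \hat\beta_j^2 /
(\hat\beta_j^2 + N \sigma_j^2)$, summed over independent instruments,
with the aggregate F-statistic $F = \frac{R^2}{1-R^2}\cdot\frac{N-K-1}{K}$
and per-SNP $F_j = (\hat\beta_j/\sigma_j)^2$. In multivariable models
the relevant quantity is the conditional F: the minimized
variance-weighted discrepancy between one exposure's instrument effects
and the best linear combination of the others', divided by $J - K + 1$.
The minimization is a derivative-free simplex from zero with five
jittered restarts (tolerance $10^{-8}$); nuisance exposures with
identically zero instrument effects are excluded from the search, since
they carry no explanatory signal and would otherwise let the variance
term alone shrink the objective without bound.

## Two-step mediation and MVMR

The mediation design is: (1) total-effect MR of each exposure on the
outcome; (2) step-1 IVW of each exposure on every mediator in the panel,
with Benjamini-Hochberg FDR correction applied within each exposure
across the panel and a mediator taken forward if its adjusted p-value is
at or below 0.05 for *either* exposure (the union rule; a joint
correction over all exposure-mediator pairs is available as a config
option, since the family definition is genuinely open); (3) step-2 MR of
each selected mediator on the outcome using the mediator's own
instruments (IVW with two or more, Wald ratio with one); (4) direction
classification: a mediator is consistent with mediation when
$\mathrm{sign}(\hat\theta_{step1}) \cdot \mathrm{sign}(\hat\theta_{step2})
= \mathrm{sign}(\hat\theta_{total})$, with step-2 intervals spanning zero
flagged weak; (5) MVMR adjusting each exposure one-at-a-time for the
representative of each mediator class — the member with the highest
aggregate F — and for the other adiposity trait as a positive control.
No proportion-mediated point estimate is computed; the sign rule is the
deliverable, matching the screening character of the design.

MVMR itself is the weighted multiple regression of outcome betas on the
$K$ exposure beta columns without intercept (instruments assumed valid
after adjustment; an Egger-style intercept is exposed behind a flag),
with residual heterogeneity $Q_{mv}$ on $J - K$ degrees of freedom
scaling the SEs multiplicatively, floored at one. An exposure column
that is identically zero is dropped with a warning (its estimate
reported NA) rather than poisoning the solve — this makes the nested
single-exposure case exactly reproduce univariable IVW — while genuine
collinearity between non-degenerate exposures raises an error naming
the offending pair.

## The synthetic-data generator

`simulate_summary_stats()` emulates the statistical structure of the
real inputs so every stage is testable without consortium data access.
Defaults are the study conditions of the motivating setting: $J = 312$
exposure instruments (the sex-combined BMI list size) from a GWAS of
$N = 806{,}810$; a mediator GWAS of $N = 24{,}925$; an outcome GWAS of
58,221 cases and 67,694 controls; minor-allele frequencies uniform on
(0.05, 0.5); per-allele effect variance $\tau^2 = 3.5\times10^{-4}$,
chosen so the instrument set explains about 4% of exposure variance
(inside the published 0.3–5.04% range); and a true exposure odds ratio
of 1.12 per SD, the sex-combined headline figure.

Standard errors follow the large-sample forms for standardized traits:
$\sigma = 1/\sqrt{2p(1-p)N}$ for continuous traits and $\sigma =
1/\sqrt{2p(1-p)\,N\,\mathrm{cf}(1-\mathrm{cf})}$ for the log-OR scale
(case fraction cf). The binary-outcome form is the standard GWAS
approximation and is the one consistent with the analytic power formula
below; it is equivalent to $1/\sqrt{2p(1-p)\,n_{\mathrm{eff}}/4}$ with
$n_{\mathrm{eff}} = 4/(1/\mathrm{cases}+1/\mathrm{controls})$. Observed
betas are drawn normally around the truth, independently across study
samples — the outcome is generated directly on the summary-statistic
scale rather than through individual-level logistic simulation, a
deliberate desk-scale choice whose linearization bias at these effect
sizes is far below test tolerances.

The true SNP-outcome effect composes the causal graph:
$\theta_{direct}\gamma_j + \sum_m \theta_m \delta_{mj} + \alpha_j$,
where $\delta_{mj} = \kappa_m\gamma_j + (\text{class-SNP effects})$ is
SNP $j$'s total effect on mediator $m$ and $\alpha_j$ is a direct
(pleiotropic) outcome effect drawn for a configurable fraction of
instruments, optionally correlated with $\gamma_j$ to violate InSIDE.
Mediators come in classes sharing one latent factor per class
(correlation 0.7 by default) with per-mediator loadings, emulating the
redundancy of lipoprotein subclass panels so representative selection is
meaningfully exercised; each class also owns its own instrument SNPs
($\gamma_j = 0$), giving mediators step-2 instruments disjoint from the
exposure's. Block LD is realized as a block-diagonal $r^2$ matrix with
redundant proxy SNPs carrying attenuated marginal effects, and
palindromic alleles, strand flips and allele-order swaps are injected at
configurable rates (zero by default) to exercise harmonization. An
optional second exposure with genetic correlation $\rho$ on the same
variants stands in for the alternative adiposity trait in
positive-control adjustments. A `positive_gamma` switch codes effect
alleles as exposure-increasing — the convention of published instrument
lists, and the frame in which directional pleiotropy is defined.

What the generator does *not* emulate: realistic LD beyond blocks,
allele-frequency differences between studies, sample overlap,
winner's-curse selection of instruments from the same data, population
stratification, or non-collapsibility of the odds ratio. Passing tests
therefore demonstrate correctness of the estimators and pipeline logic
under the stated sampling model, not robustness to those complications
in real data.

## Power

`mr_power()` uses the standard analytic approximation for a binary
outcome: the IVW z-statistic has non-centrality $\log(\mathrm{OR})
\sqrt{N \mathrm{cf}(1-\mathrm{cf}) r^2}$, and power is the two-sided
normal tail beyond the $\alpha$ critical value. It equals $\alpha$ at
OR = 1 and is monotone in $N$, $r^2$ and $|\log \mathrm{OR}|$. The
package validates it against Monte-Carlo power from the generator at
instrument strengths spanning the 0.3%–5% variance-explained range.
Three validation choices matter and are deliberate: the simulation arm
uses the fixed-effect IVW z-test, because the multiplicative
random-effects floor makes the reported test conservative by several
percent of power at moderate $J$ under exact homogeneity, which is a
reporting convention rather than part of the approximation; the
validation scenarios use a very large exposure GWAS, because the
formula treats exposure betas as known — at the real exposure sample
size, weak-instrument attenuation of roughly $1/\bar F$ shaves about
one percentage point of power in the weakest regime; and the realized
instrument $r^2$ is held exactly at its target (the generator's
`exact_r2` calibration), because the analytic curve is conditional on
$r^2$ while the realized value under random effect draws has
coefficient of variation $\approx\sqrt{2/J}$ — power being concave in
$r^2$, leaving it random costs about two percentage points at $J = 30$
by Jensen's inequality.

## Numerical and design choices

* Clump ordering, tie-breaks, and bootstrap seeds are all deterministic;
  two pipeline runs with the same config and seed write byte-identical
  tables. Results tables print doubles with 17 significant digits so a
  written table re-reads bit-exactly.
* The FDR step-up is computed literally as
  $\min_{k \ge i}\, m\,p_{(k)}/k$ (vectorized cumulative minimum) so it
  agrees exactly — not merely to rounding — with a brute-force
  step-up; `stats::p.adjust` is kept as an independent cross-check in
  the test suite.
* Degenerate inputs: a single instrument falls back to the Wald ratio;
  all-identical ratios short-circuit the mode's bandwidth rule; missing
  p-values are recomputed from beta/SE; missing allele frequencies drop
  palindromic variants only.
* Simulation sizes in the test-suite and acceptance script (hundreds of
  replicates at $J$ of 25–150, a 123-trait panel screened over a
  handful of replicates) were chosen so the whole validation runs in a
  few minutes on one core while keeping Monte-Carlo error well inside
  each assertion's margin.

## Known limitations

* The weighted median's robustness advantage is a property of the
  outlier regime: when directional pleiotropic effects are small
  relative to the per-SNP outcome SE, the median's bias approaches
  IVW's (the bias ratio scales like $\sigma_Y/\mu_\alpha$ and is
  insensitive to instrument strength), and no summary-level estimator
  can separate sub-noise pleiotropy from sampling error. The package's
  robustness validation therefore uses pleiotropic effects about four
  times the outcome SE — genuinely invalid instruments.
* Conditional F values here assume zero covariance between exposure
  summary estimates across studies (the non-overlapping two-sample
  setting); overlapping-sample corrections are out of scope, as are
  correlated-instrument (generalized) IVW, MR-PRESSO-type outlier
  removal, and proxy-SNP lookup.
* MR-Egger inference is normal-based; with few instruments its
  intervals are anti-conservative relative to a t-correction.
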