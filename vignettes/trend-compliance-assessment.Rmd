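---
title: "Trend and compliance assessment of contaminants in seafood monitoring series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend and compliance assessment of contaminants in seafood monitoring series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(d9assess)
```

## The assessment problem

Long-term biota monitoring programmes archive one pooled sample per site,
species and year — all mussel soft bodies or all fish fillets collected at
one station in one year, homogenized into a single analytical sample. Each
annual pool yields one concentration per analyte. Assessing such data for
Descriptor 9 of the Marine Strategy Framework Directive ("contaminants in
seafood do not exceed regulatory levels") requires three things per series:
a defensible temporal trend statement, a compliance verdict against the
applicable reference value, and the bookkeeping (bases, units, matrix
corrections, censoring conventions) that makes both auditable. `d9assess`
implements that pipeline end to end.

## Data model

A sample record is one analyte measurement in one annual pool: site,
species, tissue, year, analyte, value, unit (`mg/kg`, `µg/kg`, `ng/kg`,
`pg/g`, converted only by explicit factors of 1000; `pg/g ≡ ng/kg`), basis
(`wet`, `dry`, `lipid`), a censoring flag (`TRUE` means the value *is* the
limit of quantification and the measurement was at or below it), and
optional water, lipid and breathing-water fractions. Series are keyed by
(site, species, tissue, analyte, basis); years must be strictly increasing,
and gaps are allowed — biennial sampling is common — with no imputation
anywhere downstream. Basis is metadata: nothing converts it silently, all
conversions are explicit operations that are logged in assessment notes.

## TEQ aggregation under left-censoring

Dioxins, furans and dioxin-like PCBs are assessed jointly as WHO toxic
equivalents, $TEQ = \sum_i TEF_i \, \tilde c_i$. Congener panels are
routinely left-censored, and the substitution convention matters at the low
concentrations typical of biota:

- **upper bound** (regulatory default): censored congeners enter at their
  LOQ;
- **middle bound**: LOQ/2;
- **lower bound**: zero.

For every panel, lower ≤ middle ≤ upper with equality exactly when nothing
is censored — a property the tests exercise on 1000 random panels. The
TEF table (WHO-2005 consensus values, 29 congeners) is a bundled JSON
config, replaceable and versioned, and its provenance label travels with
every TEQ result. Congener-class tags (`dioxin`, `furan`, `dl-pcb`) allow
the PCDD/F-only and PCDD/F + dl-PCB sub-sums that food legislation limits
separately; plain congener sums (e.g. the six indicator ndl-PCBs) share the
same bound switch and the assessment layer uses the upper bound throughout
for consistency.

## Basis and matrix conversions

All conversions are one-line, positively homogeneous operations kept
deliberately separate from the statistics:

- breathing-water correction: mussel pool samples that retain respiration
  water are diluted by the retained fraction $b$ of sample wet weight, so
  comparisons against food maximum levels use the factor $1/(1-b)$
  ($b = 0.58 \rightarrow 2.38$, $b = 0.67 \rightarrow 3.03$; reports round
  to one decimal, stored values never);
- dry ↔ wet: a dry-weight criterion converts to wet weight as
  $c_{ww} = c_{dw}(1-w)$ with the site's mean water content $w$, and back
  exactly; a dry-mass-fraction formulation is the same operation with
  $w = 1 - d$;
- lipid normalization: $c_{ww}/l$.

Presentation rounding (factors to one decimal, converted criteria to two)
is applied only at report time. With water contents of 0.906, 0.926 and
0.947 the 12 µg/kg dw TBT criterion becomes 1.128, 0.888 and 0.636 µg/kg
ww; published tables using unrounded water contents can differ by one unit
in the last printed digit, which is why the test suite allows ±0.01 on the
latter two.

## Threshold registry and compliance

Reference values live in an editable JSON registry, not in code: regulation
numbers change, and each entry carries its source citation so a compliance
verdict can be audited. Matching is by analyte × matrix class (mussels →
bivalve entries, fish fillet → fish-muscle entries; the mapping itself is
config). Compliance reconciles value and threshold to a common unit and
basis — dry-weight criteria convert per site at assessment time — and the
verdict is `exceedance` only for a ratio strictly above 1: a value equal to
its threshold complies. When bases differ and no water fraction is
available the verdict is `not_assessable` rather than a guess.

## Trend machinery

### The smoother

The temporal trend of each series is estimated with a locally weighted
linear regression at each observation year $t$: observations within a fixed
window of 7 years ($|year - t| \le 3.5$) are weighted by the tricube kernel
in $|year - t|/3.5$ and a degree-1 fit evaluated at $t$. The window is in
*years*, not nearest-$k$ points, so sparse stretches of a series genuinely
smooth over calendar time; when fewer than 3 points fall in a window it is
widened symmetrically to the nearest 3 points (and the kernel rescaled so
all of them carry weight) purely to keep the local fit solvable. Seven
years is the package default because it is the established window in
marine contaminant trend assessment; it is a tunable
(`window_years`). The degree (1) and kernel (tricube) are the classical
LOESS defaults — the method is usually named without these parameters, so
they are stated here as the package's choice.

Each fitted value is a linear combination of the observations; the hat rows
$l_t$ are retained. They sum to 1 (the smoother reproduces constants, and
adding a constant to a series shifts every fitted value by it), and with a
window covering the whole span and uniform weights the smoother reproduces
the ordinary least-squares line to numerical tolerance — the oracle test
the suite runs against `lm()`.

### ANOVA decomposition

Three nested fits — the mean (RSS₀), the OLS line (RSS₁), the smoother
(RSS₂) — decompose the trend. The smoother's model degrees of freedom are
$df_2 = \mathrm{tr}(H)$ (the first-order approximation standard in this
style of assessment; the two-trace correction
$\mathrm{tr}(2H - HH^\top)$ would be slightly more conservative and is
noted, not applied). Then

$$F_{lin} = \frac{(RSS_0 - RSS_1)/1}{RSS_2/(n - df_2)}, \qquad
  F_{nonlin} = \frac{(RSS_1 - RSS_2)/(df_2 - 2)}{RSS_2/(n - df_2)},$$

referred to F distributions with (possibly non-integer) those degrees of
freedom. When the smoother is no rougher than a line ($df_2 \le 2$) the
non-linear test is reported as not applicable. A trend is labelled
increasing or decreasing from the sign of the OLS slope when
$p_{lin} \le \alpha$; $\alpha = 0.05$ by default and configurable, since
assessments conventionally report exact p-levels alongside.

The decomposition's calibration is checked empirically: over 2000
simulated null series (n = 15, lognormal noise, CV 0.2) the linear test
rejects at 5% within [3%, 7%], and against a 50%-per-decade exponential
decline at the same noise and length its power exceeds 80% (in the bundled
runs it is essentially 1). These problem sizes — 2000 null replicates, 500
power replicates — keep Monte-Carlo error near or below one percentage
point while the whole calibration runs in seconds.

### Contrast test and linear endpoints

Because the smoother is linear, the difference between fitted values at two
years $a, b$ has variance $\sigma^2 \lVert l_b - l_a \rVert^2$ with
$\sigma^2$ estimated from the smoother residuals on $n - \mathrm{tr}(H)$
degrees of freedom; the two-sided p comes from the t distribution. The test
refuses spans shorter than 7 years — differences inside one smoothing
window are not meaningfully resolved by it.

Separately, an ordinary least-squares line on the raw concentration scale
supplies the reported endpoints: the trend-line value in the last
monitoring year next to the measured one. Raw scale — not log — is
deliberate: declining series can extrapolate to negative trend-line values,
which the assessment convention reports as "not detected" rather than as a
number; that outcome is impossible on a log scale. (A log-scale fitting option
exists for the smoother but is off by default.)
When calculated and measured last-year values are both positive and differ
by more than a configurable factor (default 2), the series is flagged: the
trend line may not adequately reflect the final year, and compliance should
also consider the measured value. Both values are therefore assessed
against every applicable threshold, uncorrected and breathing-water
corrected; since the correction factor is ≥ 1, the corrected verdict is
never more favourable.

Censored points enter trend fits at their LOQ (consistent with upper-bound
TEQs); a LOQ/2 option exists.

## Site comparison

Two sites are compared with the Mann-Whitney U test on their annual values
over the common year range (unpaired — annual pools from different sites
are distinct material even in the same year). U is reported as
min(U₁, U₂) from midrank rank sums. The p-value is exact — doubled one-tail
probability, capped at 1 — whenever the combined sample size is ≤ 16 and
there are no ties, and otherwise a tie-corrected normal approximation with
continuity correction. The exact path is verified against full enumeration
of all C(n, n₁) assignments for every tie-free arrangement up to n = 10.

## The synthetic generator

Real archive concentrations are not redistributable here, so the package
generates series with the statistical structure the analysis assumes:
$c(t) = c_0 e^{-kt}$ plus an optional mid-series Gaussian hump, times
lognormal noise with mean 1 and coefficient of variation `noise_cv`
(multiplicative, scale-free — concentrations are positive and
right-skewed), left-censored at a configurable LOQ. The generator returns
its ground truth (mean curve, censoring count) so tests can score the
pipeline against it, and it is bit-reproducible given a seed without
disturbing the caller's RNG stream.

The demo campaign mirrors a realistic coastal design: three sites with
mussel water contents 0.906/0.926/0.947 and breathing-water fractions
0.67/0.58/0.67, mussel series 1985–2017 and fish-fillet series 1994–2017,
nine analytes with noise CV 0.25 and decline rates between 0.5% and 12% per
year at order-of-magnitude plausible concentration scales.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: analytical batch effects and method changes across
decades, autocorrelated environmental forcing, varying LOQs over time,
pooling-composition drift, and outlier years from sample-handling issues.
The trend tests assume independent errors; positive autocorrelation in real
series would inflate their type-I error beyond the calibrated rate.

## Numerical and design notes

- Degenerate inputs: constant series fit exactly with σ² = 0 (contrast
  tests then return p = 1 for zero differences); duplicate years are a
  validation error, so ties in time never arise; fully tied Mann-Whitney
  samples return p = 1.
- The widened-window fallback rescales the kernel by the distance of the
  3rd-nearest point (inflated by 1e-6) so no local fit is singular even for
  isolated points in gappy series.
- Intra-year replicates are out of scope by construction: the data model
  assumes exactly one annual pool value, matching how specimen-bank
  archives are built.
- Multiple-testing correction across analytes is deliberately not applied;
  assessments report per-analyte p-values.
- Determinism: identical inputs and configuration reproduce the assessment
  table byte for byte; the pipeline manifest stores an MD5 of the table so
  reruns can be verified.

## Limitations

The compliance layer encodes reference values, not legal interpretation:
which product category of the food regulation applies to a given species
is a config mapping the user owns. Trend inference treats the smoother df
as fixed (conditional on the window), ignores serial correlation, and uses
upper-bound substitution for censored points, which biases fitted levels
high in heavily censored series — the bound switch makes the sensitivity
easy to check. The Mann-Whitney comparison pools overlapping years rather
than pairing them; with strong common-year effects a paired test would be
more powerful.
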