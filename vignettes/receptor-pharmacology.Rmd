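---
title: "Models and methods: receptor pharmacology analysis"
author: "receptorpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: receptor pharmacology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptorpharm)
```

# Scope

`receptorpharm` analyzes the four assay families of a classical
receptor-pharmacology characterization: concentration–response
(e.g. cAMP accumulation), BRET arrestin recruitment, radioligand
competition binding, and real-time binding kinetics. Every analysis
stage is paired with a mass-action generator that produces synthetic
assays with the statistical structure the analysis assumes, so the
whole pipeline can be validated by parameter recovery.

Units are fixed internally: concentrations are nM in the kinetic and
binding equations (matching rate constants in nM⁻¹·min⁻¹ and min⁻¹) and
molar in dose–response tables, converted on the way in. Time is in
minutes. Zero concentrations are legal inputs everywhere (basal wells,
B0 wells) and are never log-transformed: all models are evaluated on
the linear concentration scale, where zero is an ordinary point.

# The logistic dose–response model

All sigmoidal curves are fitted with a three-parameter logistic whose
Hill slope is *fixed* at +1 (activation) or −1 (inhibition):

$$y = \mathrm{basal} + \mathrm{span}\cdot\frac{A}{A + \mathrm{EC}_{50}}
\qquad\text{or}\qquad
y = \mathrm{basal} + \mathrm{span}\cdot\frac{\mathrm{IC}_{50}}{A + \mathrm{IC}_{50}}.$$

Fixing the slope reflects single-site mass-action binding and keeps the
three remaining parameters identifiable on the 8–12-concentration
ranges these plates use. A free-slope (4PL) or biphasic model is
deliberately out of scope.

**Numerical approach.** The fit is parameterized in
pEC50 = −log10(EC50 in M) rather than EC50: the likelihood surface is
far better conditioned in log space, and results are reported as
pEC50 ± SE in any case. For a *given* pEC50 the model is linear in
(basal, span), so the sum of squares is profiled: a deterministic grid
(step 0.1 log units, spanning the tested concentration range extended
one log unit each way) locates the basin, `stats::optimize` refines the
1-D profile to 1e-8, and `minpack.lm::nlsLM` then polishes all three
parameters jointly and supplies standard errors. The grid's first
minimum wins ties, making the multi-start deterministic. If the joint
polish fails or does not improve the profiled optimum, the profile
solution is kept and the fit is flagged `converged = FALSE` rather than
failing silently.

**Degenerate inputs.** Fitting requires at least four distinct positive
concentrations; all-equal responses are an error (nothing to fit). A
curve is *declared non-saturating* — reported as the label `N.A.`, never
as a number — when the fitted span is below three residual standard
deviations, or when the fitted midpoint falls outside the tested
concentration range. The same rule, applied to displacement curves,
produces the `N.B.` (no binding) call.

**Baseline constraint.** After normalization to a reference agonist the
baseline could be pinned to zero; the package leaves it free. A free
baseline costs little precision on well-designed curves and absorbs
plate-to-plate offsets that a hard zero would push into the span.

Normalization itself maps a raw signal y to
100·(y − basal)/(reference − basal), with the assay basal taken from
zero-dose wells when present. It is invariant under rescaling of the
raw signal, which is what makes curves from different plates
comparable.

# Antagonism: dose ratios and Schild regression

A competitive antagonist at fixed concentration B multiplies the
agonist's apparent EC50 by the Gaddum factor (1 + B/K_B). The dose
ratio DR = EC50(+B)/EC50(control) from paired logistic fits therefore
satisfies

$$\log_{10}(\mathrm{DR} - 1) = \log_{10} B - \log_{10} K_B,$$

a line of slope 1. `schildRegression()` fits it by ordinary least
squares; the x-intercept gives pA2 and its concentration-scale
equivalent A2 = 10^(9−pA2) nM. Both are reported, because the
literature prints antagonist potencies in either convention and the
two are easily confused.

Points with DR ≤ 1 carry no information about the antagonist (the shift
is indistinguishable from none); they are excluded with a structured
warning (`DR_LE_1`) and the regression refuses to run on fewer than two
usable points. With exactly two points — a common two-concentration
design — the line is exact, so the slope SE is reported as `NA`
(undefined), never as 0.

# Equilibrium competition binding

Displacement curves are fitted on *specific* binding (total minus the
mock-transfected nonspecific channel, negative differences clamped to
zero with a logged count) with the Hill −1 logistic above. B0, the
total specific binding at zero competitor, is taken from the *fitted
top* of the logistic rather than the raw zero-competitor wells: the fit
pools information from the whole curve and is much less sensitive to
counting noise in two or three B0 wells.

The derived constants are the homologous relations
Bmax = B0·IC50/[L] and KD = IC50 − [L], and the Cheng–Prusoff
correction Ki = IC50/(1 + [L]/KD) for heterologous curves. The mode is
*declared* by the caller, not inferred from the data — a homologous
declaration is checked only through the IC50 ≥ [L] precondition, which
is the one physically testable consequence. When Eq.-style constants
are computed per experiment, the convention is to average the derived
constants (mean ± SEM) across experiments, not to back-transform the
mean pIC50 — which is why a reported mean Ki generally differs from
10^(9 − mean pIC50).

# Binding kinetics

Under pseudo-first-order conditions (free tracer not depleted),
specific binding follows

$$B(t) = B_{eq}\left(1 - e^{-k_{obs}t}\right),\qquad
k_{obs} = k_{on}[L] + k_{off},\qquad
B_{eq} = \frac{B_{max}[L]}{[L] + K_D},$$

and after an excess chase of unlabelled ligand decays as
B(t₀)·e^(−koff·t). `fitAssociation()` enforces B(0) = 0 (the reaction
starts when the tracer is added to spun-down membranes) and
`fitDissociation()` fixes the floor at zero by default — nonspecific
binding is already subtracted, so a persistent plateau would indicate
an incomplete chase rather than a model feature. A free-floor variant
is available behind a flag for exactly that diagnostic. Replicates are
pooled into a single fit by default; per-replicate fitting remains
possible by subsetting the trace.

The derived constants kon = (kobs − koff)/[L] and KD = koff/kon get
delta-method standard errors:

$$\mathrm{SE}(k_{on})^2 =
  \frac{\mathrm{SE}(k_{obs})^2 + \mathrm{SE}(k_{off})^2}{[L]^2}
  + \left(\frac{(k_{obs}-k_{off})\,\mathrm{SE}([L])}{[L]^2}\right)^2,
\qquad
\mathrm{SE}(K_D)^2 =
  \left(\frac{\mathrm{SE}(k_{off})}{k_{on}}\right)^2
  + \left(\frac{k_{off}\,\mathrm{SE}(k_{on})}{k_{on}^2}\right)^2.$$

The kobs − koff correlation induced by reusing koff is ignored, which
is conservative at the rate ratios these assays produce; the test suite
checks the formulas against a 10⁵-draw Monte-Carlo oracle.

# The synthetic-assay generator

The generator emits data with exactly the structure the analysis
assumes: closed-form mass-action expectations, a time- and
competitor-independent nonspecific channel, and Gaussian counting noise
with user-set coefficient of variation, truncated at zero. SPA and
γ-counter readings are large counts, so Gaussian noise on the
expectation is an adequate model and keeps the least-squares analysis
assumptions exact; a Poisson option was considered and rejected as
default for that reason.

Parameters and defaults:

| parameter | units | default | rationale |
|---|---|---|---|
| `bmax_cpm` | CPM | — | receptor capacity on the counter's scale |
| `kon`, `koff` | nM⁻¹min⁻¹, min⁻¹ | — | `kd_nM` is forced equal to koff/kon when both are given |
| `ns_fraction` | — | 0.02 | nonspecific binding as fraction of added counts, emitted as a separate mock-transfected channel |
| `noise_cv` | — | 0.05 | counters' noise magnitude is rarely reported; 5 % CV is a realistic plate-reader figure and is the single noise scale used throughout the tests |
| `added_cpm` | CPM | Beq/0.075 | total added tracer; the default puts equilibrium specific binding at 7.5 % of added counts, the midpoint of the 5–10 % specific-binding design these assays aim for |
| `seed` | — | unset | identical seeds give bit-identical output; expectations are seed-independent |

A guard warns whenever expected bound tracer exceeds 10 % of added
tracer, the point where the pseudo-first-order assumption (no ligand
depletion) becomes questionable. The generator deliberately does *not*
model tracer depletion (no cubic equilibrium solver), receptor
internalization or desensitization, or plate spatial effects.
Consequently, passing recovery tests demonstrates that the *analysis*
is correct and unbiased under its own assumptions — they say nothing
about data that violate those assumptions, e.g. depleted-tracer designs
or internalizing receptors at 37 °C.

The dissociation simulator refuses chase concentrations below 100 × KD,
where rebinding of dissociated tracer would bias koff downward; the
test suite quantifies the residual rebinding window against a
two-ligand ODE oracle (the closed form stays within 1 % pointwise, and
within 0.1 % for association).

# File formats and reporting

Four fixed CSV dialects (exact headers) cover dose–response,
competition, kinetics and BRET tables; `readAssayCsv()` validates the
header, coerces types, and rejects malformed rows with their file line
numbers. Excluded or clamped points always produce structured,
greppable messages (`DR_LE_1`, `NEG_SPECIFIC_CLAMPED`). Report builders
produce deterministic tables in the layouts pharmacologists expect
(potency/efficacy, binding constants, kinetic panels), propagating
`N.A.`/`N.B.` as labels; `writeResultsJson()` serializes results with
unit-explicit keys (`kon_per_nM_per_min`, `kd_nM`). Between-curve
comparisons use the classical paired Student's t-test on matched
per-experiment summaries (`pairedTTest()`), with the zero-variance
degenerate case reported as p = 0 with a warning instead of an error.

# Problem sizes used in validation

The recovery tests run at the assays' own designs, scaled to desk
size: kinetics at 0.21 nM tracer, one read per minute (101 association,
501 dissociation points), 4 replicates, 5 % noise, 20 seeds — kon and
koff medians within 10 % of truth; Schild recovery with K_B = 51.9 nM
at three antagonist concentrations (100, 300, 1000 nM), 20 seeds — A2
median within 15 % at 5 % noise and exact (slope 1.000) at zero noise;
logistic recovery over a pEC50 ∈ [6, 11] × Emax ∈ {0.1, 0.5, 1} grid at
zero noise and 200 noisy curves at pEC50 8.6. The full suite runs in a
few seconds on one CPU.

# Known limitations

* No free-slope, biphasic or operational-model (Black–Leff) fits.
* No two-site competition, ligand-depletion correction, or
  saturation-binding analysis.
* No biexponential kinetics or kinetics-of-competition
  (Motulsky–Mahan) analysis.
* The Schild slope SE from two-concentration designs is undefined and
  reported as `NA`; designs with ≥3 concentrations are needed for a
  meaningful slope test.
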