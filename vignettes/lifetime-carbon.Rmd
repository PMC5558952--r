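---
title: "Reconstructing lifetime carbon accumulation from tree rings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing lifetime carbon accumulation from tree rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringcarbon)
```

## The problem

Whether old trees keep accumulating carbon at high rates, or senesce into
a sigmoid plateau, cannot be settled with plot data that cover a fraction
of a tree's lifespan. Ring-width series measured on stem discs provide
the full lifetime record: the width of ring $t$ is the radial growth of
year $t$, so cumulative ring widths reconstruct the diameter trajectory,
and an allometric model turns diameters into biomass and carbon.
`ringcarbon` implements that chain for multi-radius disc measurements of
tropical species with distinct annual rings, plus the nonparametric
inference used to characterize lifetime growth patterns.

## From rings to carbon

**Mean tree series.** Each tree is measured along $\ge 2$ radii
(`mean_tree_series()` refuses fewer). Radii must arrive cross-dated and
aligned at the outermost (felling-year) ring; the package deliberately
implements no automatic cross-dating — dating is expert work done at the
measuring stage — but `crossdate_check()` reports the Pearson correlation
of first-differenced log widths for every radius pair, the standard
high-frequency coherence signal, flagging pairs below a threshold
(default 0.3) and series shorter than 10 rings. A width of exactly 0
encodes a *wedge ring*: a ring locally absent on that radius. Wedge years
are excluded from the cross-radius mean rather than averaged as zero,
because the tree did grow that year elsewhere on the disc; only a year
that is 0 on every radius keeps mean 0. How a mean series should treat
wedge rings is genuinely open; exclusion is our documented choice and the
generator plants wedge rings so the rule is exercised.

**Diameter.** $D(t) = 2\sum_{i\le t} w_i / 10$ (mm $\to$ cm), under-bark,
with no pith-offset or bark correction: discs are measured from the pith,
and omitting bark biases biomass low, i.e. conservatively.

**Biomass and carbon.** The pantropical height-free allometry

$$\mathrm{AGB} = \exp\{-1.803 - 0.976E + 0.976\ln\rho
  + 2.673\ln D - 0.0339[\ln D]^2\}$$

gives aboveground biomass in kg from diameter $D$ (cm), wood density
$\rho$ (g cm$^{-3}$; species defaults 0.38 for *C. odorata*, 0.72 for
*G. glabra*, 0.77 for *H. courbaril*) and the environmental stress factor
$E$ (dimensionless, site-level; higher $E$ — stronger seasonality and
water deficit — lowers biomass at fixed size). $E$ is a required site
input, default 0 for the synthetic site; its effect is pure scaling by
$e^{-0.976E}$, so no conclusions about growth *patterns* depend on it.
$D = 0$ maps to AGB 0 so trajectories may start at the pith year.

Carbon stock is `carbon_fraction` $\times$ AGB. The carbon fraction is a
separate parameter (default 0.471, a published tropical-angiosperm mean,
overridable per species); wood density acts only inside the allometry.
Annual carbon accumulation is the first difference of the stock, with the
first year's accumulation equal to the first year's stock (zero origin),
so the accumulation series telescopes exactly to the final stock — an
identity the tests assert to machine tolerance.

**Lifetime quartiles.** Each lifetime of $T$ years is split into four
equal periods with boundaries at $\lceil T/4\rceil, \lceil T/2\rceil,
\lceil 3T/4\rceil$; when $T \bmod 4 \ne 0$ each year still belongs to
exactly one quarter (earliest eligible), quarter sizes differ by at most
one year, and shares always total 100%. For constant accumulation the
shares are $[25,25,25,25]$; for a linear ramp with $T = 100$ they are
$100\cdot[325,950,1575,2200]/5050$ — both closed forms are frozen into
the tests.

## The inference toolkit

All tests are implemented from first principles except where base R
already provides the standard step (Holm adjustment = `p.adjust`, ANOVA =
`aov`, pooled-SD pairwise t-tests = `pairwise.t.test`, Pearson p =
`cor.test`'s t-approximation).

* **Cox–Stuart** (`cox_stuart()`): pair $x_i$ with $x_{i+\lfloor n/2
  \rfloor}$ (middle element dropped for odd $n$), discard ties; the count
  of positive differences is Binomial$(m, 1/2)$ under no trend, and the
  p-value is the exact binomial tail — no normal approximation, so the
  minimal attainable one-sided p is $0.5^{\lfloor n/2\rfloor}$. An
  all-ties series is reported degenerate with $p = 1$ rather than an
  error.
* **Pettitt** (`pettitt()`): $U_t = \sum_{i\le t}\sum_{j>t}
  \mathrm{sgn}(x_i - x_j)$, computed via midranks using
  $U_t = \sum_{i \le t} (2r_i - (n+1))$ (within-segment sign terms cancel
  by antisymmetry; ties contribute 0). $K = \max_t |U_t|$, $\tau$ the
  earliest argmax, and $p \approx 2\exp(-6K^2/(T^3+T^2))$ capped at 1 —
  the standard closed-form approximation; no permutation option. The
  tests verify exact agreement with an $O(T^2)$ double loop.
* **Dunn** (`dunn_test()`): joint midranks, tie-corrected variance
  $N(N+1)/12 - \sum(t^3-t)/(12(N-1))$, two-sided normal p, optional Holm.
  Default adjustment is `"none"`, mirroring the common default; the study
  design this mirrors did not state its adjustment.
* **compare_species()**: one-way ANOVA plus pairwise t-tests with the
  pooled SD from all groups and Holm step-down.

Cox–Stuart and Pettitt are sign/rank based, hence invariant under
strictly monotone transformations — asserted as a property test.

## The growth-pattern classifier

`classify_pattern()` assigns one of four archetypes to a lifetime series
(ring widths or annual carbon), after smoothing with a centered
moving average (default window 11 years; edges use a shrinking window so
no years are dropped):

1. *rise_then_decline* if Cox–Stuart on the second half of the smoothed
   series is significantly decreasing (default $\alpha = 0.05$);
2. else *increase_with_depression* if the full-series trend is
   significantly increasing **and** a depression episode is found;
3. else *sustained_increase* if the full-series trend is significantly
   increasing;
4. else *plateau*.

A **depression episode** is a maximal run of at least
`depression_min_years` (default 15) consecutive years spent below the
running maximum held at the episode's entry, during which the series
dips below `depression_factor` (default 0.8) times that pre-dip maximum,
followed by recovery above it. We detect the episode by its *extent
below the high watermark* rather than requiring every year to sit below
the 0.8 threshold: a 40%-deep raised-cosine dip lasting 30 years — the
canonical depression — spends only about 12 consecutive years below
0.8 × max once smoothed by an 11-year window, so the stricter reading
would reject the very pattern the rule exists to find. All ingredients
are relative or rank-based, so labels are invariant to positive
rescaling.

**Width space vs carbon space.** The allometry is convex in $D$ over the
relevant range, so a tree with *constant* ring widths shows *increasing*
annual carbon accumulation. A plateau in ring width is therefore not a
plateau in carbon, and vice versa a carbon plateau implies slowly
narrowing rings. The pipeline reports both readings per tree
(`pattern_width`, `pattern_carbon`), and archetype-recovery checks score
`pattern_width` against the generator's ground truth, because the
generator's archetypes parameterize the width mean structure. This also
explains why "low rates when young, high rates when old" emerges even
for steady diameter growth.

## The synthetic cohort generator

No raw data accompany the study design this package operationalizes, so
`simulate_cohort()` generates cohorts carrying the statistical structure
the analysis assumes, with a ground-truth ledger for recovery scoring.

* **Mean structure** per tree: juvenile ramp (linear, 30% → 100% of the
  base width over 10–25 years), adult drift `trend_slope` (drawn
  0.004–0.012 mm yr$^{-1}$ for increasing archetypes), raised-cosine
  multiplicative depression (start 35–55% of lifetime, length 25–40 y,
  depth 35–50%) or linear late decline (onset at half-life, scale-free
  rate reaching 35% of peak width at death). The plateau archetype has
  no ramp and zero drift: with a ramp the series genuinely increased and
  "plateau" would be the wrong generative label.
* **Noise**: multiplicative lognormal with AR(1) log-deviations
  (defaults CV 0.1, $\phi$ 0.3), mean-corrected so expected widths equal
  the mean structure; ring widths are positive and serially correlated
  like real increment series. Each of the (default 6) radii then gets
  independent per-ring lognormal noise (CV 0.1), wedge rings with
  probability 0.01 per radius-year (never on all radii of a year), and
  rounding to the 0.01 mm measurement resolution.
* **Calibration**: the base width is found by bisection on the
  *deterministic* mean structure so the noiseless final diameter equals
  the tree's target — the noise law is left untouched, so realized
  diameters scatter a little around targets; targets are drawn with a
  4%-of-span interior margin so cohorts stay inside the configured
  diameter range. Default ranges reproduce the published cohort shape:
  20/21/20 trees of the three species, ages 84–180 / 112–189 / 87–255 y,
  diameters 36.7–64.9 / 40.3–75.8 / 40.8–99.2 cm.
* **Archetype mixture** (default 60% sustained increase, 25% depression,
  7% plateau, 8% rise-then-decline) reflects a cohort where the large
  majority of trees trend upward, a minority fluctuates or declines.
* **No climate forcing**: growth phases of the real trees were
  asynchronous across calendar years and uncorrelated with annual
  precipitation and temperature, so the generator imposes no shared
  annual multiplier; per-tree climate correlation is available through
  `pearson_correlation()` against any supplied series.

What the generator does *not* emulate: size-dependent mortality and
sampling bias (only trees that survived to harvest are observed), true
circumferential growth asymmetry beyond independent radial noise,
missing outer rings, dating errors, or competition dynamics. Passing the
recovery tests therefore shows the *pipeline* is correct and the
classifier recovers known structure at realistic noise — not that the
archetype mixture of any real forest matches the defaults.

## Numerical and format choices

* RWL dialect: decadal Tucson layout; read accepts both the 999
  (0.01 mm) and −9999 (0.001 mm) terminators, write defaults to 999. A
  data value equal to the terminator (a 9.99 mm ring at 0.01 mm units)
  is refused with a pointer to the finer dialect, keeping round-trips
  exact. Calendar anchoring comes from the felling year; absent one,
  years are cambial indices.
* Degenerate inputs: all-tied Cox–Stuart pairs → degenerate result, not
  an error; all-identical Dunn input → error (ranking undefined); empty
  species groups are dropped from summaries with a warning; a
  single-radius tree aborts the pipeline naming the tree.
* Quartile boundaries by ceiling indices (deterministic, exhaustive);
  ties in Pettitt's argmax resolved to the earliest split.
* Bisection tolerance $10^{-8}$ mm on the target radius, 200 iterations.

## Problem sizes

The test suite runs the full pipeline on 61-tree cohorts (seconds), the
Cox–Stuart size check with 2000 null replicates at $n = 100$ against the
exact binomial envelope of the test's attainable size, Pettitt
brute-force equivalence on 200 series of length ≤ 30, Dunn brute-force
equivalence on 100 tied instances, and classifier recovery on 80–200
tree cohorts at CV 0.1, $\phi = 0.3$. The acceptance script reruns the
61-tree pipeline and a 200-tree recovery cohort from a single seed.

## Known limitations

* Smoothing before Cox–Stuart inflates the test's size (the smoothed
  points are autocorrelated), so at CV 0.1 a noisy width-plateau is
  labelled `sustained_increase` roughly 40% of the time; the recovery
  suite reports the full confusion matrix rather than hiding this. The
  classifier rule is the documented, tunable decision procedure — not a
  calibrated hypothesis test.
* The allometry is applied outside its fitting uncertainty: no error
  propagation of the allometric residual is attempted, and carbon totals
  inherit any site mismatch in $E$ and $\rho$ as pure scaling.
* Under-bark, trunk-base diameters make absolute biomass conservative;
  relative quantities (quartile shares, trends, archetypes) are
  unaffected by monotone scaling.
* Cross-dating is checked, never performed; misdated input will surface
  as low pairwise coherence, not as an automatic correction.
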