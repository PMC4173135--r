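---
title: "Quantitative pesticide-likeness: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pesticide-likeness: model, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qepest)
```

## The problem

Rule-based likeness filters (Lipinski, Tice, Hao) give a binary verdict:
a molecule either satisfies every descriptor bound or it does not. That
discards ranking information — a molecule missing one bound by 1 Da is
treated like one missing every bound. `qepest` replaces the hard bounds
with a continuous 0–1 likeness score per pesticide class (herbicides H,
insecticides I, fungicides F), built from desirability functions in the
style of the quantitative estimate of drug-likeness (QED).

## The model

Each of six descriptors — molecular weight (MW, Da), octanol–water logP,
hydrogen-bond acceptor and donor counts (HBA, HBD), rotatable bonds (RB)
and aromatic rings (arR) — is summarised, over a reference population of
one class, by a single shared functional form fitted to its frequency
histogram:

$$f(x) = o + a\,\exp\!\left(-e^{-(x-b)/c} - \frac{x-b}{c} + 1\right)$$

a Gumbel-shaped single peak with baseline offset $o \ge 0$, amplitude
$a > 0$, mode $b$ and width $c > 0$ (both in descriptor units). Its
analytic maximum is $f(b) = o + a$; both tails decay to $o$, the right
tail exponentially and the left tail double-exponentially, giving the
right skew typical of molecular property distributions. Dividing by the
maximum and clamping to $[0,1]$ gives the scaled desirability
$df(x) = \min(\max(f(x),0)/(o+a),\,1)$ with $df(b) = 1$.

The class score is the unweighted geometric mean of the six
desirabilities,

$$\mathrm{QEX} = \exp\!\Big(\tfrac{1}{6}\sum_{i=1}^{6}\ln df_i\Big),
\qquad \mathrm{QEX} = 0 \text{ if any } df_i \le 0,$$

the Derringer–Suich combination: one unacceptable property makes the
molecule unacceptable, and improving any property strictly improves the
score. The fused pesticide-likeness scores are
$\mathrm{QEP_{max}} = \max(\mathrm{QEH},\mathrm{QEI},\mathrm{QEF})$ and
$\mathrm{QEP_{avg}}$, their arithmetic mean.

## Fitting procedure

`pesticide_profile()` fits one class in three steps per descriptor.

1. **Binning.** Continuous descriptors (MW, LogP) are binned at the
   width minimising the Shimazaki–Shinomoto cost
   $C(\Delta) = (2\bar k - v)/\Delta^2$, with $\bar k$ and $v$ the mean
   and biased variance of the bin counts; the default candidate grid is
   100 widths log-spaced between range/100 and range/2, ties broken
   toward the smaller width. Integer descriptors (HBA, HBD, RB, arR) use
   unit bins centred on each integer. Bins are half-open
   $[e_i, e_{i+1})$, anchored at the data minimum, last bin closed —
   all counts are conserved.
2. **Curve fit.** `fit_desirability()` minimises
   $\sum_i (k_i - f(x_i))^2$ over bin centers $x_i$ by bounded
   Levenberg–Marquardt least squares (minpack.lm), with bounds $o \ge 0$,
   $a > 0$, $c > 0$ and $b$ free. The $o \ge 0$ bound keeps $df \ge 0$
   without clamping inside the data range; $c > 0$ fixes the peak's
   right-skew orientation (a sign flip would only mirror the curve and
   create a fit degeneracy). Start 1 is heuristic ($o$ = min count,
   $a$ = max − min count, $b$ = modal bin center, $c$ = count-weighted
   standard deviation); the remaining starts (8 by default) perturb $b$
   and $c$ by up to ±50% under a fixed seed, and the best SSE wins.
   Bin centers are the regression abscissae — the standard convention
   for histogram regression. Absolute counts are fitted rather than
   relative frequencies; the normalisation is absorbed by $a$ and
   cancels in the scaling.
3. **Scaling.** The divisor is the analytic maximum $o + a$ — exact,
   parameter-free, and equal to any tabulated per-fit maximum whenever
   the fits agree.

A profile needs at least 50 molecules and at least 5 populated bins per
descriptor (four free parameters). Fitting a noiseless histogram
generated from known parameters recovers them to relative error below
1e-4 (this is tested), so fitted-versus-true discrepancies on real data
reflect sampling noise, not the optimizer.

## Descriptor conventions

Structure handling is delegated to OpenBabel (via ChemmineOB/ChemmineR):

* **MW** — average atomic masses, not monoisotopic.
* **LogP** — one open Crippen-type atom-contribution estimator for all
  uses. Vendor estimators (MLogP, ClogP) differ by systematic offsets;
  where a rule was published against a specific estimator, supply that
  estimator's values through `logp_column` and they are used verbatim.
* **HBA** — OpenBabel's perception, which for typical organic molecules
  equals the Lipinski-style nitrogen-plus-oxygen count (amide nitrogens
  included: urea has HBA 3). **HBD** counts donor heavy atoms bearing at
  least one hydrogen, not the hydrogens themselves (urea: 2).
* **RB** — acyclic single bonds between two non-terminal heavy atoms,
  amide C–N excluded. OpenBabel's built-in rotor count includes amides,
  so the definition is enforced by SMARTS: `[!D1]-!@[!D1]` matches minus
  acyclic `[CX3](=O)-!@[NX3;!D1]` matches. Note this counts bonds
  adjacent to triple bonds (benzonitrile: RB 1).
* **arR / arB** — aromatic members of the smallest set of smallest
  rings, and the union of their edge bonds (fused systems share bonds:
  naphthalene has arR 2, arB 11). arB feeds only the Hao filter.

Normalization (`normalize_structure()`) keeps the largest fragment,
neutralizes charges where a valid neutral form exists (quaternary
nitrogens stay charged), and canonicalizes; it is idempotent. Tautomers
and stereochemistry are left as drawn. Whether charged inputs should be
scored as parent acids/bases or as drawn is a genuine ambiguity; the
package normalizes by default and lets `normalize = FALSE` preserve the
drawn form.

## The synthetic reference populations

No large public pesticide descriptor set ships with the package, so the
generator in `sample_population()` defines the reference conditions.
Class populations draw each descriptor independently from a zero-offset
peak density of the same family the profiles fit (rejection sampling:
uniform envelope over $b \pm 10c$ with height $o+a$; the analytic
acceptance rate is $e/20 \approx 13.6\%$, and a guard rejects any
configuration that drives it below 1% — reachable only with a negative
baseline offset). Integer descriptors are rounded and clamped at zero.

The default class shapes are fixed once, from the qualitative profiles
of the three classes: RB peaks at 2 (F), 5 (H) and 6 (I); insecticides
most hydrophobic, with maximal desirability near logP 5 and at zero
aromatic rings; herbicides and fungicides more hydrophilic (LogP mode
3); MW modes 300–360 Da with widths of 55–70 Da, matching the scale of
marketed pesticides. Decoys draw uniformly over MW 50–1200, logP −5–12,
HBA/RB 0–25, HBD 0–10, arR 0–10 — broad enough to straddle every class
mode, emulating a random compound background at ten times the active
set size.

What the passing tests show: the pipeline recovers generating modes
within one bin, is seed-deterministic, and separates same-class actives
from broad decoys with AUC well above 0.7 at $n = 2000$ actives per
class. What they do not show: performance on real compound collections,
where descriptors are correlated (the generator samples them
independently), classes overlap far more than uniform decoys do, and
the descriptor perception of other toolkits differs on edge cases. The
packaged profiles in `default_profiles()` are fitted on these synthetic
populations and labelled accordingly — they are a working calibration,
not coefficients derived from any proprietary pesticide collection, and
any user-supplied profile JSON overrides them.

## Evaluation utilities

`roc_auc()` sweeps thresholds over descending scores and computes the
AUC by the Mann–Whitney rank statistic with tied pairs contributing ½ —
exactly the trapezoidal area under the threshold-sweep curve, and
exactly equal to brute-force pairwise counting (tested up to n = 500
including all-tied and perfectly separated sets). `quantile_cutoffs()`
interpolates order statistics linearly (type 7). `optimal_cutoff()`
maximises Youden's J over observed thresholds, ties toward the smaller
threshold; it is an extension flagged as discouraged for qualitative
use, since any hard cutoff collapses the continuous score back into a
rule-based filter — the intended use is ranking.

## Numerical notes and limitations

* `eval_f()` is stable for standardized arguments $|(x-b)/c|$ up to 700:
  the inner exponential overflows to `Inf`, the outer exponent to
  `-Inf`, and the value underflows cleanly to $o$ — never NaN.
* The zero rule is an exact-zero test after clamping; with $df$ clamped
  to $[0,1]$ only a true underflow (a descriptor far outside the class
  range) triggers it.
* Score CSVs print four decimals; all internal computation is double
  precision.
* Problem sizes used throughout the tests and the acceptance script —
  2000 molecules per class fit, 2000 fresh actives versus 20000 decoys —
  were chosen as the smallest sizes at which the fitted modes stabilise
  within a bin; larger populations change the fitted coefficients only
  in their sampling noise.
* The package does not model descriptor correlations, activity data, or
  structural alerts; it quantifies physicochemical likeness only, and
  scores should be read as ranking signals, not probabilities.
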