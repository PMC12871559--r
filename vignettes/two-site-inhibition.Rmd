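---
title: "A two-site model for intersecting enzyme inhibition mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-site model for intersecting enzyme inhibition mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibkin)
```

## The model

`inhibkin` analyzes reversible inhibition of a single-active-site,
single-substrate enzyme under rapid-equilibrium initial-rate conditions.
The inhibitor can occupy two sites: one inside the active site
(dissociation constant $\gamma K_i$; occupancy excludes substrate,
giving the IE complex) and one beyond it (dissociation constant $K_i$,
forming EI and the ternary ESI without disturbing substrate binding,
which keeps its constant $K_s$). ESI turns over at a fraction
$\beta \in [0,1]$ of the uninhibited catalytic rate. The
double-reciprocal rate law is

$$\frac{1}{v_0}
 = \frac{K_s}{V_{max}}\,
   \frac{1 + \frac{I}{\gamma K_i} + \frac{I}{K_i}}
        {1 + \frac{\beta I}{K_i}}\,\frac{1}{S}
 + \frac{1}{V_{max}}\,
   \frac{1 + \frac{I}{K_i}}{1 + \frac{\beta I}{K_i}}.$$

Assumptions worth stating: rapid equilibrium (initial rates, no substrate
depletion or progress-curve effects); one substrate site, so no
cooperativity; exactly two inhibitor sites; a single inhibitor species.
Substrate inhibition, multi-inhibitor mixtures and time-course kinetics
are out of scope.

The six classical intersecting mechanisms are regimes of $(\gamma,
\beta)$:

| $\beta$        | $\gamma \ll 1$      | finite $\gamma$      | $\gamma \gg 1$           |
|----------------|---------------------|----------------------|--------------------------|
| $1$            | linear competitive  | partial competitive  | (inhibition vanishes)    |
| $(0,1)$        | —                   | partial mixed        | partial non-competitive  |
| $0$            | —                   | linear mixed         | linear non-competitive   |

The traditional mutual-hindrance factor of the single-site description is
apparent: $\alpha = 1/\gamma + 1$. Matching the double-reciprocal
coefficients of the two descriptions for *all* $I$ gives the exact
reparameterization used by `as_general_params()` /
`as_traditional_params()`:

$$K_i^{\text{two-site}} = \alpha K_i^{\text{trad}},\qquad
  \gamma = \frac{1}{\alpha - 1},\qquad
  \gamma K_i^{\text{two-site}} = \frac{\alpha K_i^{\text{trad}}}{\alpha - 1},$$

with $\beta$ carried over (1 for partial competitive, 0 for linear
mixed). For purely competitive data only the active-site constant
$\gamma K_i = K_i^{\text{trad}}$ is identifiable (the $\gamma \ll 1$
bound); for non-competitive data only the outer-site $K_i$ is (the
$\gamma \gg 1$ bound). Both cases are reported as bounds with notes, not
as numbers.

One typographical point: the $\gamma \ll 1$, $\beta = 1$ limiting form is
implemented with slope factor $1 + I/(\gamma K_i)$, keeping the leading
1. Dropping it would break continuity at $I = 0$ and contradict the
parent equation, so the bare-$I/(\gamma K_i)$ variant sometimes seen in
print is treated as a typesetting loss.

## The analysis pipeline

`inhibfit()` runs the classical chain:

1. **Primary fits** (`fit_lb_lines`): per inhibitor level, replicate
   rates are averaged per substrate concentration and $1/\bar v_0$ is
   regressed on $1/S$ by unweighted OLS. Averaging before inverting
   matches the convention that plotted rates are replicate means (on a
   balanced noiseless design it is identical to pooled fitting; a
   variance-weighted fit was considered and left out of the default to
   keep the route faithful to the classical analysis). Lines with
   $R^2 \le 0.9$ — the conventional acceptance threshold for this assay
   family — are flagged and excluded downstream.
2. **Secondary fits** (`fit_secondary`): apparent slope and intercept
   versus $I$ are each fit with constant, linear $a + bI$ and saturating
   hyperbola $a(1+pI)/(1+qI)$ forms. Selection is by extra-sum-of-squares
   F-test at $\alpha = 0.05$, guarded by a relative-SSE floor of
   $10^{-12}$: a simpler form whose residual is already at numerical zero
   is accepted outright, so exact data are never over-fitted by a richer
   form that also interpolates them. The hyperbola is seeded by the exact
   linearization $y = a + (ap)I - q(Iy)$ and refined by
   Levenberg–Marquardt; it is only accepted if its plateau is finite and
   above the $I=0$ value.
3. **$\Delta$ replots** (`delta_replot`): for hyperbolic profiles,
   $1/(y(I) - y(0))$ against $1/I$ is exactly linear; its intercept gives
   the saturating increment ($\Delta_{max} = 1/\text{intercept}$) and
   hence plateau parameters. $I = 0$ is excluded ($1/I$ undefined) and a
   non-increasing profile raises a replot-inapplicable error rather than
   returning nonsense.
4. **Classification** (`classify_mechanism`): constant slope with rising
   intercept → parallel lines, the uncompetitive pattern, flagged out of
   family; constant intercept → competitive family (linear vs partial by
   the slope form); both rising → non-competitive if the slope/intercept
   ratio is constant across $I$ (coefficient of variation below 1%, a
   numerical stand-in for "the lines cross on the $1/S$ axis"), otherwise
   mixed. Disagreeing forms (one linear, one hyperbolic where the family
   requires agreement) return `inconclusive`, never a silent guess.
5. **Estimation** (`estimate_traditional`): linear mechanisms take
   $K_i = a/b$ from the secondary regressions ($\alpha K_i$ from the
   intercept one); hyperbolic mechanisms use the replots — e.g. partial
   competitive: $\alpha = 1 + \Delta_{max}/\text{slope}(0)$,
   $\alpha K_i$ = ratio of replot coefficients; partial mixed: $\beta$
   from the intercept plateau ($\text{limit} = \text{intercept}(0)/\beta$),
   then $\alpha K_i$ and $K_i$. For partial mechanisms $\beta$ is
   computed both from the replot and from the hyperbolic plateau read-off
   (they agree on exact data; both are reported via the `beta_routes`
   attribute, the replot being primary because it is the linearized,
   classical route).
6. **Reparameterization** (`infer_general`) via the exact mapping above.

`global_fit()` is the alternative estimator: Levenberg–Marquardt least
squares of all five parameters on the *rate* scale (not reciprocal space,
where noise is distorted), with $K_s, V_{max}, K_i, \gamma$ on the log
scale and $\beta$ box-bounded to $[0,1]$. It is initialized from the
classical estimates when obtainable. When $\beta$ lands on a bound, or
$\beta \ge 0.95$ (where intercepts carry no inhibitor information and
only the slope constrains $\gamma K_i$ and $K_i$), a note is attached.

```{r example}
truth <- general_params(Ks = 1.3, Vmax = 1, Ki = 45, gamma = 0.5, beta = 1)
fit <- inhibfit(simulate_rates(truth, reference_design()))
fit
```

## The simulator and what it does (not) emulate

`reference_design()` encodes the benchmark assay: 10 substrate
concentrations spanning 0.625–25 mM (the two-fold ladder 0.625, 1.25,
2.5, 5, 10, 25 completed with the arithmetic midpoints 1.875, 3.75, 7.5,
17.5 — the published description gives the range and count but not the
exact ten values, so the completion is declared here once), inhibitor at
0, 20, 40, 80, 120 mM, triplicate rates.

Noise is multiplicative Gaussian on the rate, $v_0 = v_{true}(1 +
\varepsilon)$, $\varepsilon \sim N(0, \mathrm{CV})$, redrawn while
non-positive; rates span ~40-fold across the design, so a constant CV is
more realistic than additive error for a chromogenic endpoint assay. The
default CV of 0.05 is typical for triplicate plate assays. A seed is
mandatory for any noisy simulation. What the simulator does **not**
emulate: absorbance-to-rate conversion error, ionic-strength and buffer
effects, pipetting correlation between wells, substrate depletion. A
green test suite on simulated data therefore demonstrates correctness of
the analysis machinery under the stated error model, not robustness to
every artefact of real assays.

## Numerical choices and edge behaviour

* Regime thresholds: `limiting_mechanism()` treats $\gamma \le 0.01$ as
  $\ll 1$ and $\gamma \ge 100$ as $\gg 1$ (configurable; theory states the
  regimes only qualitatively), and snaps $\beta \ge 0.95$ / $\le 0.05$ to
  the endpoints, matching one-significant-figure reporting of $\beta$.
* Exact data of a *finite*-$\gamma$ parameter set are genuinely
  hyperbolic however small the curvature; the pipeline detects, e.g.,
  $\gamma = 0.005$ with $I \le 120$ mM as partial competitive because at
  that range the slope profile really does curve by ~3%. "Limiting
  regime" test fixtures therefore use $\gamma = 10^{\pm 8}$, where the
  residual curvature sits below the SSE floor.
* The replot-based estimators invert small differences and amplify noise
  (a 3% rate CV can move the partial-competitive $K_i$ by ~25%); they are
  kept as the faithful classical route and for mechanism evidence, while
  `global_fit()` is the recommended estimator for noisy data (on
  repeat-simulation at 5% CV its $K_i$ is unbiased within Monte-Carlo
  error; single fits land within ±20%).
* Tie-breaks: when slope and intercept forms disagree beyond what any
  mechanism allows, the call is `inconclusive` (CLI exit code 2).
  `uncompetitive_out_of_family` likewise stops before parameter
  estimation.
* `nls.lm` is used directly for the global fit; convergence failure
  raises an error with the optimizer message rather than returning a
  half-converged parameter set.

## Problem sizes

All shipped tests run on the 150-record reference design; the
distributional checks use 10,000 replicates of a reduced two-by-two grid
(noise CV) and 200 repeat simulations (estimator bias), sizes at which
the Monte-Carlo error of the checked statistics is comfortably below the
asserted tolerances.

## Known limitations

Mechanisms outside the two-site scheme (uncompetitive, multi-site,
cooperative, substrate inhibition) are flagged, not modelled.
Identifiability is structural, not just statistical: purely competitive
data bound $\gamma$ from above only, purely non-competitive data from
below only, and $\beta = 1$ removes all inhibitor information from the
intercepts; these cases are reported as bounds/notes and no confidence
intervals are currently attached to the classical estimates (the
bootstrap over replicates, as in the test suite, is the recommended
route).
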