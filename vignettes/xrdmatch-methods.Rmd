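---
title: "Methods: powder-pattern matching and the cross-correlation score"
author: "xrdmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: powder-pattern matching and the cross-correlation score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrdmatch)
```

## The problem

X-ray powder diffraction (XRPD) fingerprints a crystalline substance by the
positions of its diffraction peaks: Bragg's law, $\lambda = 2d\sin\theta$,
ties each peak position to a lattice spacing $d$, and the set of spacings is
characteristic of the crystal structure. Crucially, peak *positions* do not
change with crystal habit, particle size or grinding, whereas relative
*intensities* do (preferred orientation: needle-like crystallites align, so
some lattice planes are over-represented in the measurement). A forensic
screening workflow for seized drug powders therefore keys identification on
positions and treats intensities as soft evidence.

`xrdmatch` implements that workflow end to end: plain-text diffractogram
I/O, preprocessing, peak detection and position matching against a
reference phase library, a quantitative whole-pattern similarity score, and
a synthetic diffractogram simulator that serves as the test substrate for
everything else.

## Preprocessing pipeline

Stages run in a fixed order — background fit/subtraction, smoothing,
K$\alpha_2$ stripping, normalization — and each maps a valid pattern to a
valid pattern on the same grid, so any stage can be toggled off for
ablation.

**Background** is estimated by iterative polynomial clipping: fit a
polynomial of degree `bg_degree` (default 5) by least squares, replace
every point above the fit by the fit, repeat until the curve changes by
less than `bg_tol` (default 1e-6 relative, cap 100 iterations). A single
fit would be biased upward by the peaks; clipping removes that bias. The
degree-5 default follows what laboratory processing software uses for
smooth instrument backgrounds over a 55-degree window.

**Smoothing** is Savitzky–Golay (window 11 points, order 3). On the
0.019-degree instrument grid the window spans about 0.2 degrees, safely
below typical peak FWHM (about 0.1 degrees), so peak shapes survive while
counting noise is attenuated. Any signal that is globally a polynomial of
degree at most the filter order passes through unchanged, edges included.

**K$\alpha_2$ stripping.** An unfiltered Cu tube emits a doublet
($\lambda_1 = 1.540562$ Å, $\lambda_2 = 1.544398$ Å, intensity ratio
$r = 0.5$), so every reflection appears twice. Walking the grid in
ascending angle, the already-stripped K$\alpha_1$ intensity is interpolated
at the back-converted angle
$\theta_1 = 2\arcsin\!\big((\lambda_1/\lambda_2)\sin(\theta_2/2)\big)$ and
$r$ times it is subtracted at $\theta_2$ (Rachinger's method). When the
interpolation interval touches the point being updated (low angles, where
the doublet splitting is below one grid step) the update is solved
implicitly rather than iterated. Stripping is mass-reducing and removes
$r/(1+r)$ of an isolated doublet's integrated intensity; the residual at
the K$\alpha_2$ position is about 2–3% of the companion's height, limited
by linear interpolation of the curved profile on the grid.

**Normalization** defaults to unit maximum. Unit-area normalization is also
provided but makes the literal full-lag cross-correlation score of any two
patterns identically 1 (see below), so unit-max is the default.

## The cross-correlation score

With $f'$ the normalized standard and $g'$ the normalized sample, both are
squared first — $f = f'^2$, $g = g'^2$ — to accentuate peaks over background
noise and minor contaminants, and the score is

$$\mathrm{CCS}_{fg} \;=\; \frac{\int C_{fg}(\tau)\,d\tau}
                               {\int C_{ff}(\tau)\,d\tau},
\qquad C_{fg}(\tau) = \int f(\theta)\,g(\theta+\tau)\,d\theta ,$$

discretized as rectangle sums on the common grid (the grid step cancels in
the ratio). A sample identical to its standard scores exactly 1.

Taken literally over all lags the numerator factorizes,
$\sum_\tau C_{fg} = \Delta\,(\sum f)(\sum g)$, so the full-lag score
collapses to $\sum g / \sum f$: it compares total squared intensity and
carries **no** position information (and under unit-area normalization it
is identically 1). This algebraic fact is asserted as a test. The package
therefore provides two modes:

* `full` — the literal definition, kept for reference;
* `windowed` (default, `max_lag = 0.5` degrees) — the integrals restricted
  to $|\tau| \le$ `max_lag`. The window restores position sensitivity
  while still absorbing small 2$\theta$ misalignments (specimen height,
  zero error). It is the recommended identification score.

Because the denominator is the standard's auto-correlation, the score is
asymmetric: a pairwise score matrix has unit diagonal but
$m_{ij} \ne m_{ji}$ in general.

The windowed score of squared unit-max patterns is dominated by the
strongest lines: a coincident line pair with relative intensities
$r_1, r_2$ contributes roughly $(r_1 r_2/100^2)^2$. Two consequences shape
the package's fixtures. First, under strong intensity perturbation
(log-scale SD 0.5) same-substance scores spread down to roughly 0.1–0.6 —
the score is intensity-weighted even though identification is
position-driven. Second, a comparison set of "unrelated" compounds must
actually be unrelated in this operational sense: `unrelated_phases()`
rejects any candidate with a line within `max_lag + FWHM` of a target line
when the product of relative intensities exceeds 1000 (a contribution of
about 0.01 to the score). Randomly placed phases violate this more than
half the time, which says something practical: a windowed CCS alone cannot
discriminate substances whose strongest lines coincide within the window —
position matching is the primary identification tool, the score a
quantitative companion.

## Peak detection, matching, identification

Peaks are local maxima of the preprocessed pattern exceeding a height and a
prominence threshold (defaults 1% and 0.5% of the pattern maximum), with
the apex refined by a 3-point parabola — positions are not quantized to the
grid, and recovery on simulated noisy data is about an order of magnitude
better than one grid step.

Matching is greedy closest-first pairing of sample and standard peak
positions within a tolerance (default 0.10 degrees, about five grid steps
— below typical inter-peak spacing, above alignment error; distance ties
break toward lower angle, and each peak is used at most once). The match
fraction is the matched share of *standard* peaks; unpaired sample peaks
are reported as possible adulterants. Intensities play no role.

`identify_phases()` ranks library phases by match fraction, converting
reference positions to the sample's wavelength via Bragg's law when they
differ. Ties are broken by the windowed CCS against a noise-free rendering
of the phase — deliberately *not* by relative intensities, which carry
habit and grinding effects.

## The simulator

`render_pattern()` builds each reflection as a pseudo-Voigt profile
(mixing fraction $\eta = 0.5$ by default) whose *area* is proportional to
the relative intensity — the physically conventional choice, which makes
mixture weights interpretable. FWHM is constant across the pattern
(default 0.1 degrees; no Caglioti angle dependence — sufficient for
identification testing and one fewer free function). The K$\alpha$ doublet
is rendered via Bragg conversion of each position with half the area. The
default grid is 5–60 degrees in 0.019-degree steps. A polynomial
background (default: flat, 100 units) is added, and counting noise is
Poisson: returned counts are $\mathrm{Pois}(s\,y)$ with `noise_scale`
$s = 10$ expected counts per unit intensity, so the strongest reflection
accumulates roughly 8000 counts at its apex — typical of a benchtop
Bragg–Brentano instrument counting one second per step on a crystalline
organic, and enough that the smoothed noise floor sits below the peak
detector's thresholds. Far Gaussian tails are flushed to exact zero below
$e^{-690}$; subnormal tail values carry no signal but make vector
arithmetic on the pattern dramatically slower.

`perturb_intensities()` emulates preferred orientation and grinding:
independent lognormal factors (median 1) on each relative intensity,
positions untouched. `fixture_library()` generates reference phases with
8–25 reflections at least 0.3 degrees apart and lognormal intensities
floored at 10% of the strongest line — reference cards tabulate
reflections down to roughly that level, and far weaker lines are not
reliable identification features at bench SNR. Phases 1 and 2 deliberately
share half their positions, a stress case mimicking structurally related
designer-drug analogs.

What the simulator does **not** emulate: angle-dependent peak widths,
Lorentz-polarization and structure-factor physics, March–Dollase
orientation as a function of crystallographic direction, sample
displacement/zero shift, or amorphous humps. Tests passing on this
substrate demonstrate the pipeline's internal consistency and its
robustness to the modelled effects (intensity perturbation, counting
noise, doublets, mixtures), not performance on any real instrument's
quirks.

## Numerical and design choices

* Integrals are rectangle sums; the step cancels in the score ratio, so
  only grid commonality matters. Full-lag correlation uses the FFT
  (exact to round-off, verified against a direct double sum to 1e-9);
  windowed sums are computed directly — patterns are ~3000 points, so no
  further acceleration is warranted.
* Grids must be uniform to 1e-6 relative; files with more jitter are
  rejected and must be resampled explicitly. XY files are written with 6
  significant digits: below instrument precision, above the 1e-6
  round-trip tolerance.
* Background subtraction clips at zero (counts are nonnegative);
  `normalize` refuses all-zero patterns.
* The identification pipeline applies background subtraction before
  scoring by default; every stage can be disabled for the alternative
  processing order.
* Degenerate inputs: a flat pattern yields an empty peak list; an empty
  reflection list renders as background only; a zero standard raises a
  zero-denominator error rather than returning NaN.

## Scale of the built-in checks

The test suite and the acceptance script regenerate everything they
measure: 100 random patterns for the self-score identity, 50 random pairs
(length up to 256) against the double-sum oracle, 200 repetitions of the
13-pattern separation experiment (7 perturbed renders of one phase plus 6
unrelated phases on the full 5–60-degree grid), 100 identification trials
against a 10-phase library with permuted-plus-perturbed intensities
(log-scale SD 0.3, the controlled analog of the grinding experiment),
K$\alpha_2$ doublets every 5 degrees from 10 to 55, 100 noisy
single-peak renders for position recovery, and a 30/70 active/diluent
mixture — the composition regime of street heroin samples. These sizes
keep the full suite within a few minutes on one CPU while leaving the
statistical margins wide (separation succeeds in ~99% of repetitions
against the 95% requirement).

## Known limitations

* The windowed CCS is intensity-weighted; strongly perturbed
  same-substance pairs can score ~0.1 while still matching perfectly on
  positions. Rank by match fraction first, use the score as a tie-break
  and as a whole-pattern similarity summary.
* Quantitative phase-fraction analysis is out of scope; mixture handling
  is limited to detecting and flagging extra peaks.
* Inferring shared batch origin from relative-intensity agreement is
  deliberately unsupported — intensities respond to habit and grinding,
  so such inferences need orthogonal evidence.
* The tolerant XY reader targets the common two-column dialect; binary
  instrument formats and CIF are out of scope.
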