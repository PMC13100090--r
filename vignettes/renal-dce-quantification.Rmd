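---
title: "Quantifying single-kidney function from renal DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-kidney function from renal DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renaldce)
```

## Overview

`renaldce` estimates single-kidney renal plasma flow (RPF), filtration
fraction (FF) and eGFR from dynamic contrast-enhanced (DCE) MRI. The
chain is: ROI-mean signal extraction → SPGR signal-to-concentration
conversion → arterial input function (AIF) preparation → whole-kidney
tracer-kinetic model fitting → eGFR aggregation. This vignette documents
the model, its assumptions, the tunable parameters, the numerical
choices, and what the synthetic phantoms do and do not establish.

## Signal model and concentration conversion

The dynamic acquisition is a spoiled gradient echo (SPGR) sequence. At
short echo time, T2* decay is neglected and the steady-state signal is

$$S(t) = m_0^{\mathrm{eff}} \frac{1 - E(t)}{1 - \cos\alpha\, E(t)},
  \qquad E(t) = e^{-TR/T_1(t)},$$

where $m_0^{\mathrm{eff}}$ absorbs the equilibrium magnetization,
$\sin\alpha$ and receive-coil gain into one scalar. Because coil shading
differs between the aorta and the kidneys, $m_0^{\mathrm{eff}}$ is
calibrated **per ROI**, from the mean of the pre-bolus baseline frames
divided by the SPGR saturation factor at the pre-contrast $T_1$. With a
25-s baseline at 5-s temporal resolution the default baseline length is 5
frames (`acquisition_params(n_baseline_frames = 5)`).

Gadolinium concentration then follows from the fast-exchange linear
relaxivity relation $C(t) = (1/r_1)\,(1/T_1(t) - 1/T_1(0))$. Defaults:
TR 4.53 ms, flip angle 12°, $r_1$ = 5.2 L/mmol/s (gadobutrol),
$T_1(0)$ = 1.0 s for parenchyma and 1.48 s for blood. No B1 or flip-angle
correction is applied; the conversion deliberately mirrors the plain SPGR
model.

**Degenerate frames.** Noise can push a measured signal above
$m_0^{\mathrm{eff}}$, making $E \notin (0,1)$ and the inversion
undefined. Such frames are flagged in a QC vector; inside the baseline
window they clamp to $C = 0$, after it they are linearly interpolated
from valid neighbours. If more than 20% of frames are flagged the curve
is considered unusable and the conversion errors out. These policies are
configurable through the acquisition parameters and are a pragmatic
choice: they keep clinically noisy curves usable while recording exactly
which frames were repaired.

## The arterial input function

Two AIF sources are supported:

* **Image-derived (iAIF)** — the converted aortic ROI curve on the 5-s
  acquisition grid, linearly interpolated to a 1-s grid before
  convolution.
* **Population (pAIF)** — the Parker functional form: two Gaussian
  first-pass kernels plus an exponential washout modulated by a sigmoid,

  $$C_A(t) = \sum_{n=1}^{2} \frac{A_n}{\sigma_n\sqrt{2\pi}}
    e^{-(t-T_n)^2/2\sigma_n^2}
    + \frac{\alpha\, e^{-\beta t}}{1 + e^{-s(t-\tau)}},$$

  with $t$ in minutes and the ten standard population parameters as
  defaults (`parker_params()`). The washout is implemented in this
  multiplicative form — literally "an exponential modulated with a
  sigmoid". The typeset variant with the sigmoid denominator inside the
  exponent circulates in the literature; it is exposed as
  `parker_aif(form = "literal")` for comparison, but it behaves
  non-physiologically at early times (the washout term equals $\alpha$
  at $t = 0$ instead of being suppressed by the sigmoid), so the
  multiplicative form is the default.

The pAIF is evaluated on a 1-s grid — one advantage of a functional AIF
is a temporal resolution finer than the acquisition — and **aligned** to
the individual by a rigid time shift $\Delta = t_{peak}(\mathrm{iAIF}) -
t_{peak}(\mathrm{pAIF})$, so the aortic curve is consulted only for its
peak *time*, never its amplitude. The shift is snapped to the nearest
grid step so shifted samples land on grid nodes and the peak amplitude is
preserved exactly; the shifted curve is zero-padded before bolus arrival.
Peak detection uses a centred 3-frame moving average by default (clinical
5-s curves are noisy; window 1 disables smoothing), with ties broken
toward the earliest time.

## The whole-kidney two-pathway model

The whole parenchyma is treated as one unit with two parallel pathways:
plasma (mean transit time $T_p$) and tubules, which receive the filtered
fraction FF of the plasma flow (transit time $T_t$). The impulse
retention function — the fraction of an instantaneous arterial bolus
still inside the kidney at time $t$ — is

$$R(t) = e^{-t/T_p} + \mathrm{FF}\,\frac{T_t}{T_t - T_p}
  \left(e^{-t/T_t} - e^{-t/T_p}\right),$$

the second term being the convolution of the plasma impulse response
$(1/T_p)e^{-t/T_p}$ with tubular retention $e^{-t/T_t}$, scaled by FF.
$R(0) = 1$, $R \ge 0$, $R \to 0$. In the degenerate limit $T_p = T_t$
(switched at a relative spacing of $10^{-9}$ to avoid catastrophic
cancellation) the closed form becomes
$\mathrm{FF}\,(t/T_p)e^{-t/T_p}$; continuity through the switch is
tested. Tissue concentration follows

$$V_t\, C_t(t) = \frac{\mathrm{RPF}}{1 - \mathrm{Hct}}
  \,(C_A \otimes R)(t),$$

with hematocrit fixed at 0.4 by default (overridable per subject) and
$V_t$ the parenchyma volume from the ROI mask. Single-kidney
eGFR = FF × RPF. For comparison with serum eGFR the left and right
values are summed (serum creatinine reflects both kidneys) and, when a
height and weight are available, normalized to 1.73 m² body surface area
using the DuBois formula
$0.007184\,W^{0.425}(100H)^{0.725}$ — the conventional normalization for
reporting eGFR in mL/min/1.73 m².

**Convolution numerics.** The convolution runs on the AIF's uniform 1-s
grid with the grid step expressed in minutes (RPF is per minute), using
FFT-based discrete convolution with trapezoid end-point corrections, then
linear interpolation to the acquisition frame times. Trapezoid quadrature
makes the leading error $O(h^2)$; halving the grid step changes sampled
tissue concentrations by well under 0.5% for Parker-AIF inputs, and the
implementation is tested against a brute-force double-loop oracle and
adaptive quadrature of the continuous integral.

## Fitting

`fit_whole_kidney()` minimizes the unweighted residual sum of squares
with a classical Levenberg-Marquardt core (`minpack.lm::nls.lm`). Bounds
are realized by a smooth reparameterization — log for RPF, $T_p$, $T_t$,
scaled logit for FF — so the LM algorithm itself runs unconstrained,
with box bounds on the transformed coordinates as a safety net. Defaults:
RPF ∈ [1, 2000] mL/min, FF ∈ [0.001, 0.6], $T_p$ ∈ [1, 60] s,
$T_t$ ∈ [10, 600] s; starts at (200, 0.15, 8, 120). These bounds and
starts are the package's own choices, exposed in `fit_config()`.

Tracer-kinetic fits are notoriously degenerate — different parameter
combinations can produce nearly identical curves — so the fit runs
`n_multistart = 5` starts: the configured init plus deterministic jitters
drawn from `rng_seed` under a private RNG stream (the caller's stream is
untouched). The lowest-RSS convergent start wins, ties broken by start
index, making the fit bit-reproducible for a given seed. A residual
weight vector hook exists but defaults to ones (plain least squares).

## ASL renal blood flow

`rbf_to_rpf()` applies RPF = RBF (1 − Hct). ASL maps are conventionally
per 100 g of tissue while kinetic RPF is a whole-organ volume flow, so
the function supports both an `integrated` mode (mL/min in, mL/min out)
and a `per_100g` mode that bridges via kidney volume × tissue density
(default 1.05 g/mL) before the hematocrit factor; the bridge is an
explicit, recorded assumption rather than a silent unit guess.

## Agreement statistics

* **CV** = sample SD / mean; computable from raw values or directly from
  published summary statistics.
* **Percentage Bland-Altman**: per-pair difference as a percent of the
  reference (default) or of the pair mean — the published "mean
  percentage difference" phrasing does not pin the denominator down, so
  both are available; limits of agreement are bias ± 1.96 SD in either
  case.
* **Pearson r** with the t-based two-sided p and Fisher-z 95% CI.
* **ICC(A,1)**: two-way, absolute agreement, single measurement, via the
  McGraw–Wong mean-square formula (numerically identical for the two-way
  mixed and random absolute-agreement single-measure estimators); CI by
  the F-distribution bounds with Satterthwaite df. Categories: poor
  < 0.50 ≤ moderate < 0.75 ≤ good ≤ 0.90 < excellent.
* **Mann-Whitney U** from pooled midranks; p by the tie-corrected,
  continuity-corrected normal approximation, or full enumeration of all
  group assignments for groups of ≤ 10 (the default below that size).
* **CKD-EPI 2021** (race-free creatinine equation) for serum eGFR.

Display rounding is half-even to 2 decimals (base R's `round`); internal
values keep full precision.

## The synthetic generator

`synthetic_config()` defines the study conditions the package is tested
under: 5-s temporal resolution, 60 frames (300 s), bolus arrival at 25 s
(so a 5-frame baseline), Parker AIF as the true input, two kidneys with
RPF 230/215 mL/min, FF 0.15/0.14, $T_p$ 8/10 s, $T_t$ 120/100 s and
volumes 150/145 mL — magnitudes at the scale of an adult clinical cohort.
Noise is applied in **signal space**, where MRI noise lives (Gaussian by
default, Rician optional; at SNR > 20 the two agree in mean and SD within
2%). The calibration scalars are 1000 a.u. for both ROIs, giving baseline
signals of ≈123 a.u. (aorta) and ≈172 a.u. (kidney).

The aortic **peak-clipping artifact** models inflow/saturation as a hard
ceiling at `aorta_clip_fraction` × the peak concentration, applied to the
aortic concentration before it is mapped to signal. Applying the ceiling
in concentration space keeps the artifact's severity interpretable — a
0.6 clip yields exactly 60% of the true concentration peak after
conversion, which a signal-space ceiling would not, since the SPGR map is
strongly nonlinear at first-pass concentrations.

`make_phantom_volume()` paints a cylindrical aorta and two ellipsoidal
kidneys on a 48 × 48 × 16 grid (3 × 3 × 4 mm voxels) with the case's
noiseless curves plus voxel-wise noise. The ellipsoid semi-axes are
solved from the nominal volumes, and the **realized voxelized mask
volume** is then used as the ground-truth $V_t$ when generating the
curves, so the phantom is self-consistent: end-to-end recovery tests
measure model and fitting fidelity, not voxelization error.

**What the phantom does not emulate:** anatomy, motion, registration
error, B1 inhomogeneity, partial-volume mixtures at ROI boundaries,
T2* effects, water-exchange nonlinearity, or inter-subject AIF shape
variation (the true input *is* the Parker form). Passing recovery tests
therefore demonstrates that the estimation chain is faithful to its own
forward model under realistic noise and artifact levels — not that the
model is an adequate description of any particular patient.

## Problem sizes and test design

The parameter-recovery suite fits 100 synthetic cases with truth drawn
from RPF ∈ [80, 500] mL/min, FF ∈ [0.05, 0.30], $T_p$ ∈ [3, 20] s,
$T_t$ ∈ [40, 300] s under a fixed seed, noiseless (every parameter
recovered within 1%) and at signal noise of 1% of baseline (median RPF
and eGFR errors well under 10%). The artifact suite sweeps clip fractions
{0.9, 0.8, 0.7, 0.6} over 50 replicates spanning noiseless to low noise
and checks that fitted RPF rises monotonically as the peak is clipped and
exceeds the truth at clips ≤ 0.8. `scripts/acceptance.R` re-runs a
40-case recovery and a 20-replicate sweep, which is ample to estimate the
medians and proportions it reports.

## Known limitations

* The rigid peak-shift is the only individualization of the pAIF; cardiac
  output and dispersion differences between subjects are not modelled, so
  the population branch inherits any systematic mismatch between the
  Parker form and the cohort.
* The whole-kidney model has no explicit delay parameter; a late-arriving
  AIF cannot be compensated, which is why peak alignment matters.
* eGFR = FF × RPF propagates errors in both factors; the fit can trade FF
  against RPF when the AIF amplitude is biased (visible in the clipping
  sweep, where RPF inflates while eGFR stays plausible).
* The per-100 g ASL bridge assumes a uniform tissue density and that the
  map's ROI mean is representative of the whole parenchyma.
* Averaged pre-contrast T1 values are used per tissue class; individual
  T1 variation is not accounted for.
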