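# renaldce

Single-kidney function from dynamic contrast-enhanced (DCE) MRI, using a
population-based arterial input function (AIF) and a whole-kidney
two-pathway pharmacokinetic model.

## The problem

DCE-MRI can measure the two core parameters of renal function — the
glomerular filtration rate (GFR) and the renal plasma flow (RPF) — per
kidney, which serum creatinine cannot. Two obstacles keep it out of
routine use: the image-derived aortic input function (iAIF) is corrupted
by inflow/saturation artifacts and coarse temporal sampling, which depress
its first-pass peak and inflate fitted flow; and multi-compartment models
need labor-intensive cortex/medulla segmentation. `renaldce` implements a
streamlined alternative: a fixed population AIF (Parker form), shifted in
time to the individual's bolus arrival, driving a whole-kidney model that
needs only a single parenchyma ROI.

The package is aimed at imaging scientists working on renal perfusion:
it provides the full chain from 4D NIfTI volumes to per-kidney estimates,
a synthetic-phantom generator with known ground truth (including the
peak-clipping artifact), and the method-agreement statistics used to
compare estimates across methods.

## The model

Signal is converted to gadolinium concentration by inverting the spoiled
gradient echo (SPGR) equation

&nbsp;&nbsp;S(t) = M₀ sin α · (1 − E(t)) / (1 − cos α · E(t)), E(t) = exp(−TR/T₁(t)),

and applying the linear relaxivity relation C(t) = (1/r₁)(1/T₁(t) − 1/T₁(0)).
The population AIF is the Parker form — two Gaussian first-pass kernels
plus a sigmoid-modulated exponential washout — evaluated on a 1-s grid and
rigidly shifted so its peak coincides with the individual's aortic peak.
Whole-kidney tissue concentration follows the two-pathway convolution
model

&nbsp;&nbsp;V_t · C_t(t) = RPF/(1 − Hct) · (C_A ⊛ R)(t),

with impulse retention function
R(t) = e^(−t/T_p) + FF · T_t/(T_t − T_p) · (e^(−t/T_t) − e^(−t/T_p)):
a plasma pathway with mean transit time T_p and a tubular pathway
receiving the filtered fraction FF with transit time T_t. Bounded
Levenberg-Marquardt least squares recovers (RPF, FF, T_p, T_t);
single-kidney eGFR = FF × RPF, and the whole-subject value is the
left+right sum, optionally normalized to 1.73 m² body surface area.
ASL-derived blood flow converts to plasma flow as RPF = RBF (1 − Hct).

## Worked example

```r
library(renaldce)

cfg  <- synthetic_config()            # two kidneys, RPF 230/215 mL/min
ph   <- make_phantom_volume(cfg)      # 48x48x16 voxel 4D phantom + masks
rep  <- run_case(series = ph$series, masks = ph$masks, aif_mode = "both")
print(rep)
```

```
<case_report>
  population AIF: total eGFR 64.6 mL/min
    left_kidney    RPF  230.0 mL/min  FF 0.150  eGFR  34.5  R2 1.000
    right_kidney   RPF  215.0 mL/min  FF 0.140  eGFR  30.1  R2 1.000
  image AIF: total eGFR 64.7 mL/min
    left_kidney    RPF  241.8 mL/min  FF 0.142  eGFR  34.4  R2 0.998
    right_kidney   RPF  224.7 mL/min  FF 0.135  eGFR  30.3  R2 0.998
```

The population branch recovers the phantom's ground truth (left kidney:
RPF 230 mL/min, FF 0.150, eGFR 34.5 mL/min) essentially exactly. The
image branch overestimates RPF by ~5% even on this artifact-free phantom,
because the 5-s acquisition grid undersamples the sharp first-pass peak —
the same mechanism, amplified, that makes iAIF-based RPF unreliable when
inflow artifacts clip the peak. Clipping the aortic peak to 60% of its
amplitude inflates fitted RPF by ~53% while eGFR stays plausible, since
the fit compensates with a lower filtration fraction.

A command-line tool wraps the same functions:

```sh
exec/renaldce simulate --out case --seed 3
exec/renaldce run --dir case --out report.json --aif-mode both
exec/renaldce fit --kidney-curve kidney_conc.csv --aif parker --vt 150 --out fit.json
```

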