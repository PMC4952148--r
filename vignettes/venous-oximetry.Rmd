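---
title: "Noninvasive venous oximetry from cuff-stimulated PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive venous oximetry from cuff-stimulated PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venoxim)
```

## The measurement problem

Pulse oximetry estimates arterial oxygen saturation (SpO2) because the
artery pulsates: the cardiac beat modulates the optical path through
arterial blood, and the ratio of the relative intensity modulations at two
wavelengths depends only on the saturation of the blood doing the
modulating. Veins do not pulsate, so venous saturation (SvO2) — the other
half of any oxygen-delivery budget — normally requires an invasive blood
draw.

The idea implemented here is to *make* the vein pulsate: a ring-shaped air
cuff around the finger inflates and deflates at a fixed frequency distinct
from the heart rate, imposing a periodic volume oscillation on the venous
bed. The transmitted-light signal then carries two spectrally separated
components — the natural cardiac pulse and the artificial stimulation —
and the same ratio-of-ratios oximetry can be applied to each band
independently: the pulse band yields SpO2, the stimulation band yields the
saturation of whatever blood the cuff modulates.

## Optical model

Each wavelength channel follows the Beer–Lambert law. For blood at
saturation $s$, the effective absorption coefficient is the linear blend

$$\mu(s,\lambda) = s\,\epsilon_{HbO2}(\lambda) + (1-s)\,\epsilon_{Hb}(\lambda),$$

and the transmitted intensity through a path $l(t)$ is
$I = I_0 \exp(-\mu(s,\lambda)\, l(t))$ (natural logarithms throughout).
Taking two time points and forming

$$R = \frac{\ln\left(I_R(t_1)/I_R(t_2)\right)}{\ln\left(I_{IR}(t_1)/I_{IR}(t_2)\right)}
    = \frac{\mu(s, 660)}{\mu(s, 940)}$$

cancels $I_0$, the static tissue absorbance and the (unknown) path
excursion, leaving a quantity that depends only on $s$. The package
inverts this relation algebraically:

$$s = \frac{\epsilon_{Hb}(660) - R\,\epsilon_{Hb}(940)}
           {R\,(\epsilon_{HbO2}(940) - \epsilon_{Hb}(940)) -
            (\epsilon_{HbO2}(660) - \epsilon_{Hb}(660))}.$$

The inversion is well defined because of two coefficient orderings that
`optical_coefficients()` enforces: Hb absorbs more red light than HbO2,
and HbO2 absorbs more infrared than Hb, which together make $R(s)$
strictly decreasing. The bundled default coefficients are standard
tabulated molar extinction values at 660/940 nm, rescaled so that paths in
centimetres give absorbances of order one; since only the products
$\epsilon \cdot l$ enter any result, any consistent unit system is
accepted. The per-cycle estimator uses the AC/DC small-signal form
$R = (AC/DC)_{660} / (AC/DC)_{940}$, which agrees with the two-time-point
logarithmic form to second order in the modulation depth (about 1–2 % here,
so the approximation error is a fraction of a percentage point of
saturation).

## The three-step extraction

`run_pipeline()` implements the extraction in three steps per 10-s
analysis window (hop 5 s, per-window median over cycles for robustness):

1. **SpO2.** The stimulation is removed by band-pass filtering around the
   cardiac fundamental, and the pulse cycles give SpO2 in the ordinary way.
2. **Stimulation-band saturation.** Signal far from the stimulation
   frequency is filtered out, peaks and troughs of the stimulation cycles
   give AC/DC pairs, and the same oximetry yields the saturation of the
   cuff-modulated blood (reported as `stim_spo2`).
3. **SvO2.** The cuff compresses the venous bed, but the arterial path is
   also affected. If the arterial excursion at the stimulation frequency is
   a fraction $c$ of the venous one, linearity of $\mu$ in $s$ makes the
   stimulation band behave exactly like blood at the amplitude-weighted
   saturation $(c\,S_aO2 + SvO2)/(1+c)$. SvO2 follows by unmixing with
   arterial weight $w = c/(1+c)$:
   $SvO2 = (stim\_spo2 - w\,SpO2)/(1-w)$.

The classical mixed-saturation relation,
$Mixed\_SpO2 = (SpO2 + SvO2)/2$, is the balanced special case $c = 1$
($w = 1/2$), i.e. the cuff disturbing artery and vein equally. The package
treats the weight as a parameter rather than asserting the 50/50 split is
physically right: `run_pipeline()` derives $w$ from the known composition
when the trace carries its generating configuration (the simulator default
couples 10 % of the cuff excursion into the arterial path, giving
$w = 1/11$), accepts an explicit `arterial_weight` in `pipeline_config()`,
and falls back to $w = 1/2$ otherwise. The result table reports both the
raw band reading (`stim_spo2`) and the equal-weight mixed value
`mixed_spo2 = (spo2 + svo2)/2`, so the identity
`svo2 = 2*mixed_spo2 - spo2` holds exactly on every reported window
regardless of the weight actually used; the two columns coincide when the
mixture is balanced. For real data the weight is the main calibration
unknown — on hardware it would be absorbed into the empirical co-oximetry
calibration (`fit_r_calibration()` provides the linear $S = a - bR$ map
for that route).

The oxygen-consumption proxy is the arteriovenous difference
$S_aO2 - SvO2$ in percentage points, with SpO2 standing in for $S_aO2$.

## What the simulator emulates

`simulate_ppg()` evaluates a three-compartment finger in transmission:

* a static tissue absorbance per channel (defaults 0.5 red / 0.4 infrared);
* an arterial compartment (mean path 0.2 cm) whose path carries an
  asymmetric beat template — raised-cosine systolic upstroke over 30 % of
  the cycle, slower quarter-cosine diastolic decay — at 1.2 Hz (72 bpm)
  with 0.02 cm peak-to-trough excursion, plus the coupled fraction of the
  cuff waveform;
* a venous compartment (mean path 0.3 cm) driven by a smoothed-rectangular
  cuff waveform (duty 0.5, raised-cosine rise/fall over 15 % of the cycle)
  at 4 Hz with 0.02 cm excursion.

Defaults: sampling 100 Hz, duration 60 s, SaO2 98 %, SvO2 75 %, additive
white Gaussian noise at 0.2 % of the channel DC (a seed is mandatory for
any stochastic run; identical seeds reproduce traces bit-for-bit). The
stimulation frequency, cuff rise time and coupling fraction are not
physical constants but choices of the simulated device; 4 Hz is used
because it sits between the third and fourth cardiac harmonics at 72 bpm,
and both orderings of pulse and stimulation frequency are supported.

The generator deliberately omits motion artifacts, respiratory baseline
wander, sensor nonlinearity, scattering and tissue heterogeneity: passing
tests demonstrate the correctness of the signal-processing chain under the
stated optical model, not robustness to everything a finger on a ward
does. `hypoxia_protocol()` steps SaO2 through a level sequence (typically
six levels from 100 % down to 70 %, the desaturation range used for
oximeter calibration) with SvO2 tracking at a constant arteriovenous
difference, and returns the per-sample ground truth for recovery testing.
`build_sampling_schedule()` reproduces the blood-draw bookkeeping (six
levels × two samples × two repeats = 24 points).

## Numerical choices

* **Filters.** Windowed-sinc (Hamming) FIR band-passes, order
  $\approx 3.3 f_s / \Delta f$ with transition width
  $\Delta f = \min(f_{pulse}, f_{stim})/2$, forced to an even order
  (type-I symmetric kernel, the safe choice for a band-pass). Kernels are
  applied as centered convolutions, which compensates group delay exactly;
  the half-kernel at each edge is NA and excluded from cycle statistics.
  Band half-widths default to 0.4× the respective fundamental. Stimulation
  harmonics outside the band are discarded on purpose: the waveform-shape
  factor they carry is common to both wavelengths and cancels in $R$.
  The band-pass input is mean-removed first, because the kernel's residual
  DC gain (~3e-3) would otherwise couple the large intensity baseline into
  components of order 1e-2.
* **DC baseline.** A cascade of two centered moving means with widths of
  one pulse period and one stimulation period — this nulls both
  fundamentals and all their harmonics exactly, unlike a single cutoff.
* **Spectra.** Mean/trend-removed, Hann-tapered one-sided periodogram,
  scaled so Parseval's identity holds exactly in the package's convention.
* **Peak prominence.** Three artefacts can mimic a stimulation peak:
  leakage skirts from the pulse line (argmax on the band edge), broadband
  noise (peak below 50× the out-of-band floor), and cardiac harmonics
  inside the stimulation search band (peak within three bins of a multiple
  of the located pulse frequency). Each is screened before the stimulation
  is declared present; a missing stimulation flags the SvO2 columns while
  SpO2 is still produced.
* **Peak detection.** Strict local extrema with a greedy minimum-distance
  rule (0.6 of the component period); ties break to the earlier sample,
  each peak pairs with the deepest trough before the next peak.
* **Saturation range.** Inversions outside [0, 1] by more than a 0.02
  slack are flagged, never silently clipped.

## The feedback controller

`closed_loop_run()` simulates the stimulation control loop: simulate →
spectrum → feedback metrics → rule update. The metrics are the located
pulse frequency, band-power SNRs over the out-of-band floor, and the
distance from the stimulation frequency to the nearest cardiac harmonic
(k = 1..3). The policy is deterministic: below the minimum separation
(0.5 Hz) the frequency steps upward in 0.2 Hz increments (wrapping below
the 10 Hz ceiling) until clear of all considered harmonics; below the SNR
target (15 dB) the amplitude rises by 10 % of the NIBP-derived pressure
threshold, capped at the threshold with a saturation warning. Since no
rule ever reverses a previous move, the loop cannot oscillate, and the
amplitude can never exceed the pressure ceiling. A commanded frequency
that collides exactly with the pulse rate is physically indistinguishable
from the pulse, so that iteration runs as a stimulation-off probe (the
cuff idles, the pulse spectrum is measured, separation reports zero) and
the next update moves the frequency away. All loop step sizes, targets and
margins are package choices — the control concept itself fixes none of
them.

## Evaluation statistics

`rmse()`, `pearson_correlation()` and `difference_analysis()` implement
the agreement statistics used to compare a noninvasive estimate with
invasive co-oximetry: root-mean-square error, product-moment correlation,
and per-pair differences with a ±10 percentage-point band plus
Bland–Altman-style limits of agreement. No outlier exclusion of any kind
is performed. `consumption_comparison()` propagates both sources to the
arteriovenous difference. These functions operate on any paired series;
applied to the simulator they close the loop between programmed truth and
recovered estimates.

## Worked example

```{r example, eval = FALSE}
cfg <- ppg_config(seed = 1)            # 60 s, SaO2 98 %, SvO2 75 %
ppg <- simulate_ppg(cfg)
res <- run_pipeline(ppg)
res[1:3, c("window_time", "spo2", "stim_spo2", "mixed_spo2", "svo2")]
```

Problem sizes used throughout the test-suite and the reproduction script:
60-s traces at 100 Hz (6 000 samples) for end-to-end recovery, 30-s
two-tone fixtures (3 000 samples) for filter characterisation, a
six-level × 30-s ramp (18 000 samples) for the hypoxia trend, and
five-iteration controller runs on 20-s segments.

## Known limitations

* The mixture weight $w$ is known exactly only in simulation; on real
  data it must come from calibration, and the reported SvO2 is conditional
  on it. The raw `stim_spo2` column is always available and
  weight-independent.
* The AC/DC estimator inherits a second-order bias in the modulation
  depth; at the simulated perfusion levels this is < 0.5 percentage point
  of SvO2 but grows quadratically with stimulation amplitude.
* Band-pass separation assumes the stimulation sits away from the cardiac
  harmonics; the controller enforces this, but a heart-rate change faster
  than the control loop would transiently contaminate the stimulation
  band.
* The venous compartment is assumed fully and uniformly modulated by the
  cuff; partial venous recruitment would change the effective mixture, not
  the algebra.
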