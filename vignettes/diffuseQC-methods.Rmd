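---
title: "diffuseQC: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{diffuseQC: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffuseQC)
```

This vignette is the package's own account of its science: the forward
models and their assumptions, the inverse procedures, the quality-control
rules, what the synthetic-data generator does and does not emulate, and the
choices made where the design was genuinely open.

## Forward models and assumptions

### Time-resolved reflectance

`trsReflectance()` evaluates the extrapolated-boundary image-source solution
of the photon diffusion equation for a homogeneous semi-infinite medium.
The assumptions are the usual ones: scattering dominates absorption
($\mu_s' \gg \mu_a$), source–detector separation large compared with one
transport mean free path, and slow temporal variation of the fluence. When
$\mu_s' \le \mu_a$ the functions still evaluate (the optimizer needs them
to), but object construction flags the medium and a warning is emitted —
such curves are exactly the ones that, at the instrument level, the
dynamic-range refusal catches.

Units are fixed throughout: $\mu_a$, $\mu_s'$ in 1/cm, separations in cm,
TRS time in ns, DCS delays in s, BFI in cm²/s. One published source for the
unreliable-BFI bound prints a malformed unit ("cm/s²"); we treat every BFI
as cm²/s, the only dimensionally consistent reading of the normal range
printed alongside it.

The amplitude of the reflectance is deliberately unnormalized: the measured
DTOF is fitted with a free scale factor, because absolute photon budgets
depend on coupling, and displayed curves are conventionally normalized to
their peak (`normalizeToPeak()`).

The boundary coefficient $A$ uses the effective-reflection polynomial
approximation in the relative refractive index, with defaults
$n_\mathrm{tissue} = 1.4$, $n_\mathrm{outside} = 1$ (typical soft-tissue
values; the emulated device's index is not published, and both are
configurable through `probeGeometry()`).

### Correlation diffusion

`dcsG1()` solves the correlation-diffusion equation for the same geometry,
with decay wavenumber $K(\tau)^2 = 3\mu_a\mu_s' + \mu_s'^2 k_0^2
\langle\Delta r^2(\tau)\rangle$ and Brownian dynamics $\langle\Delta
r^2\rangle = 6\,\mathrm{BFI}\,\tau$ — the model that in practice describes
red-blood-cell motion in tissue; the ballistic "random flow" variant is
intentionally not implemented. `siegertG2()` applies $g_2 = 1 + \beta
|g_1|^2$. Heterogeneous volumes (a shallow hematoma over perfused cortex)
are mimicked by `mixG1()`, a convex intensity-weighted combination of
homogeneous solutions; a slow component produces the characteristic
secondary decay and non-zero tail plateau.

The TRS separation defaults to 3.0 cm (the emulated device's 30-mm
interfiber distance); the DCS separation defaults to 2.5 cm — the device's
DCS separation is not published, and 2.5 cm is typical for this instrument
class.

## Instrument model

The default TRS grid is 0–10 ns in 4096 uniform bins (~2.44 ps), enough to
resolve sub-100-ps response functions while keeping the FFT convolution
cheap. The IRF is a unit-area Gaussian bell of FWHM 0.4 ns centered at
2.5 ns — the device response is never tabulated, so a smooth unimodal bell
of realistic width stands in; both parameters are arguments of `makeIRF()`.
The peak sits at 2.5 ns so that the pre-pulse background window (all bins
earlier than IRF peak − 5·FWHM, i.e. 0.5 ns) always holds the ≥ 20 bins the
figures of merit need.

DTOF noise is per-bin Poisson on the expectation (convolved model scaled to
the photon budget plus a flat background). The g2 delay grid is 60
log-spaced points over $10^{-7}$–$10^{-2}$ s, emulating a multi-tau
correlator; g2 noise is zero-mean Gaussian with per-point standard
deviation $1/\sqrt{1000\cdot\mathrm{countRate}\cdot\mathrm{duration}}$
(count rate in kHz). This deliberately simplified variance model — not a
full correlation-noise formula — is adequate for exercising QC thresholds,
which is its only job here; it does not reproduce the delay-dependence of
real correlator noise. Afterpulsing is an additive
$A_\mathrm{ap}e^{-\tau/\tau_\mathrm{ap}}$ term, which inflates the apparent
coherence parameter exactly as spurious detector correlations do.

## Inverse procedures

### TRS fit

`fitDTOF()` fits scale × (reflectance ⊛ IRF) to the counts by
Poisson-weighted least squares (`minpack.lm::nls.lm`), after subtracting
the mean pre-pulse background. The fitted window runs from the rising edge
at 80% of peak to the falling edge at 1% of peak — the region where the
diffusion solution is trustworthy and the tail still carries absorption
information; both fractions are arguments. The amplitude is solved
analytically at each iteration; $\mu_a$ and $\mu_s'$ are optimized on a log
scale (which conditions the problem much better than raw values) within
(0.001, 1) and (1, 30) 1/cm. If the first attempt from the (0.1, 10)
initialization ends far above the shot-noise residual scale, a coarse 3×3
multi-start sweep reinitializes it; ties are broken by the lowest residual.
Histograms with less than one decade of dynamic range are refused outright
(`diffuseQC_dynamic_range_error`) rather than fitted: they do not indicate
a scattering-dominated medium.

Fits at the two wavelengths are independent — nothing in the model couples
$\mu_s'$ across wavelengths, and tying them would presume a scattering
power law we do not model.

### Hemodynamics

`computeHemodynamics()` is an exact 2×2 linear solve of
$\mu_a(\lambda) = \ln 10\,[\varepsilon_{HbO_2}\,C_{HbO_2} +
\varepsilon_{HHb}\,C_{HHb}]$ at 687/830 nm. Water and lipids are excluded
(saturation here is a hemoglobin-only quantity). Negative concentrations
are reported and flagged `physical = FALSE`, never clipped — a non-physical
solve is itself a quality signal. The packaged extinction table is an
approximate snapshot of a standard literature compilation; the unit
convention (1/(cm·M), decadic) is documented in the file, and the tests use
their own self-contained fixture table.

### DCS fit

`fitG2()` works sequentially, mirroring how β and BFI are reported for this
device class: β first as the mean of $g_2-1$ over the early-delay plateau
(τ below the 3×10⁻⁷ s knee), then BFI by least squares on
$g_1 = \sqrt{\max(g_2-1,0)/\beta}$ over points with $g_1 \ge 0.3$. Two
refinements matter:

* **The plateau window is excluded from the BFI fit.** Those points were
  consumed by the β estimate, and short delays are where afterpulsing
  lives. This also gives the "insufficient decay sampled" refusal real
  teeth: a noise-structure curve whose apparent correlation dies within the
  plateau leaves fewer than 5 fittable points and is refused
  (`diffuseQC_decay_error`) instead of producing a fantasy BFI.
* **β is corrected for its own decay.** At high flow the correlation has
  already begun decaying inside the plateau window, biasing the raw mean
  low. After each BFI fit, β is re-estimated as the plateau mean of
  $(g_2-1)/g_{1,\mathrm{model}}^2$ and the fit repeated until stable
  (a few passes; the loop is capped at 4).

A fitted BFI below 3×10⁻¹⁰ cm²/s is flagged `"unreliable"` — at such low
flow the speckle ensemble is no longer sampled ergodically within the
integration time. An rms residual above 0.02 (g1 units; about an order of
magnitude above the healthy-preset noise floor) flags
`"poor model agreement"`.

`detectSecondaryDecay()` compares one-component and two-component mixture
fits. A second decay is declared when the two-component fit halves the
squared residual *and* recovers a slow-component weight ≥ 0.15 (both
configurable). Noiseless single-component curves cannot qualify: their
one-component residual is already at machine level, and a floor of
$10^{-10}n$ on the residual prevents meaningless "improvements" from
counting. Flat curves (no decay at all) raise their own error rather than
being classified.

## Quality-control rules

`defaultQCRules()` encodes the guideline thresholds: SNR ≥ 10, ≥ 3 decades
of dynamic range, DTOF peak delayed ≥ 0.7 ns after the IRF peak, rFWHM > 1
and ΔFWHM > 0, count rate within 0.5–200 kHz (200 is the conservative end
of the published 200–300 saturation range), β within [0.35, 0.55]
(operationalizing "near 0.5" and the afterpulsing-inflated-β signature),
BFI within [1×10⁻⁹, 8×10⁻⁸] cm²/s with the 3×10⁻¹⁰ ergodicity bound, g₁
tail at 10⁻³ s below 0.05, and StO₂ within [50, 75]% — a window wide enough
to reconcile the published healthy range (≈56–66%) with a healthy case
reported at 67%, while catching the elevated saturations of hemorrhagic
tissue. No published numeric threshold exists for "high β" or the tail
plateau; both defaults are therefore exposed in the rule set and
serializable to YAML/JSON.

The **suspect/reject split** follows how such data are handled in
practice: `reject` for failures after which no values can honestly be
reported (starved histograms, sub-noise count rates, refused fits);
`suspect` for measurements whose values exist but should be distrusted
(implausible β, BFI, StO₂, heterogeneity signatures). Reject dominates
suspect; every violation is enumerated with its observed value and bound,
so a verdict is reproducible from its own reasons. `classifyQC()` is
monotone by construction: improving any single metric never worsens the
label. An infinite SNR (a noiseless curve with zero background) raises a
configuration error instead of silently passing.

## The synthetic-data generator

`casePresets()` defines nine study conditions: a healthy head (H0) and
eight pathological signatures — an absorbing low-SNR infarct without skull
(1), swollen high-absorption/low-scattering media (2, 3), CSF-driven signal
starvation with a noise-structure g2 (4), an afterpulsing-inflated β over a
hemorrhage (5), hematoma-driven secondary g1 decays (6, 7), and trapped air
(8). Numbers the emulated cases print are used verbatim (H0: μa = 0.14/cm,
μs′ = 11, StO₂ ≈ 67%, β = 0.49, 90 kHz; case 3: 24 kHz over 4 channels;
case 8: 14 kHz; case 5: μa ≈ 0.09–0.1; case 6: μa 0.07–0.1, μs′ ≈ 6,
StO₂ ≈ 80%). Everything else is a design choice recorded in each preset's
`design` note, e.g. the 10⁶-photon healthy budget with 1 count/bin
background (≈3.4 decades of dynamic range), case 1's photon budgets chosen
so the 687-nm histogram is refused, case 6's 0.25-weight slow component at
BFI 10⁻¹⁰ cm²/s, and case 4's pure afterpulsing + noise with a long 3600-s
integration — long averaging cannot rescue a channel that detects no
correlated light, which is precisely the lesson of that case. Case 3's BFI
(4×10⁻⁹ cm²/s) was chosen to match its narrative: a normal-shaped,
reliably-fitted curve decaying about an order of magnitude slower than
healthy, with BFI below the healthy preset but inside the normal window.

Hierarchical seeding (cohort seed → per-ROI child seeds, all below 2³¹)
makes every subset bit-reproducible. `generateCohort()` samples tissue
compositions with the packaged frequency table, maps each composition to a
preset family (ischemic → 1, hematoma/contusion → 6, subarachnoid blood →
5, air → 8, swollen ± CSF → 3/2, sub-skull CSF → 7), and jitters the
ground-truth values by 5%; curves are only generated on request, since the
dataset table is the product at cohort scale.

**What passing tests do and do not show.** The generator reproduces the
*printed signatures* of real pathological measurements — not their full
statistics. Real DCS noise is delay-correlated; real IRFs have asymmetric
tails and afterpeaks; real heterogeneous media are layered, not convex
mixtures of homogeneous solutions; and real swollen-tissue optics are not a
single effective medium (the homogeneous-analysis framing is deliberate —
multi-layer and Monte-Carlo inverse models are out of scope). A classifier
that is perfect here has demonstrated that the rules encode the guidelines,
not that the guidelines are sufficient for patient data.

## Numerical choices and problem sizes

Convolution is open (zero-padded) discrete linear convolution truncated to
the grid — circular wrap-around is structurally impossible. Degenerate
inputs fail loudly and specifically: empty curve lists, mismatched grids,
all-zero curves, monotone ramps (undefined FWHM), flat g1 (nothing to
analyze), sub-resolution IRF requests, singular extinction matrices,
missing sidecars, shuffled abscissas. The dynamic range uses
`log10(peak / max(mean background, 1))`; the 1-count floor keeps clean
simulations finite.

The shipped tests and the acceptance script use grids of 4096 bins, 60-delay
correlator curves, 10⁶-photon healthy budgets, a 3×3 recovery grid, 5 seeds
per case signature, and a 2000-ROI cohort for the frequency check — sizes
chosen so the whole suite runs in about a minute on one CPU while leaving
every recovery criterion an order of magnitude of headroom.

## Known limitations

Single homogeneous layer only; Brownian dynamics only; simplified g2 noise;
no detector dead-time, pile-up, or gated acquisition; hemoglobin-only
chromophores; no ingestion of the deposited clinical archive (the package
reads its own text curve format and CSV tables, not the archive's MATLAB
structures); probe-position metadata is stored but no geometry is
reconstructed from it.
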