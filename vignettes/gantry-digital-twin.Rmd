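---
title: "A digital twin of a gantry inspection system for caged-rabbit houses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of a gantry inspection system for caged-rabbit houses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GantryInspect)
```

## What this package models

Large commercial rabbit houses are inspected by an overhead three-axis
gantry that travels above the cages, stopping at grid positions to capture
RGB, near-infrared (NIR), depth and thermal-infrared (TIR) images and a row
of environmental telemetry. Mortality shows up as a cold body in the TIR
channel while the NIR channel supplies animal contours in the dim housing;
the two must first be registered pixel-to-pixel. GantryInspect implements
the computational stack of such a system as a fully simulated, testable
digital twin: nothing here talks to hardware, but every algorithm — the
registration chain, the drive synchronization controller, the session
logic, the welfare assessment — runs exactly as it would on the deployed
platform, and a synthetic scene generator supplies inputs with known ground
truth.

## Depth-assisted NIR-to-TIR registration

The TIR camera (256x192 px) has a much smaller field of view than the NIR
camera (1024x768 px), so NIR coordinates are projected into the TIR image
frame. Both cameras are distortion-free pinholes with intrinsics $(k_x,
k_y, u_0, v_0)$ and world poses written camera $= R\,x_{\mathrm{world}} +
p$. The per-pixel chain is:

1. **Back-projection.** An NIR pixel $(u, v)$ with aligned depth $Z$ lifts
   to the NIR camera frame: $X = (u - u_0) Z / k_x$, $Y = (v - v_0) Z /
   k_y$.
2. **Frame transfer.** Because both poses share one world frame,
   $x_{\mathrm{TIR}} = R_{\mathrm{TIR}} R_{\mathrm{NIR}}^{-1}
   (x_{\mathrm{NIR}} - p_{\mathrm{NIR}}) + p_{\mathrm{TIR}}$.
3. **Projection.** $u' = u_0' + k_x' X/Z$, $v' = v_0' + k_y' Y/Z$ in the
   TIR intrinsics.

`mapNirPixelToTir()` composes the three steps; `buildRegistrationMap()`
applies them to every NIR pixel with a depth return and resolves collisions
on a TIR pixel by keeping the smallest TIR-frame depth (a z-buffer —
forward scatter is used rather than inverse lookup because depth lives on
the NIR grid). `warpAndFuse()` scatters NIR intensities through the map and
stacks three channels: registered NIR, TIR, and their mean. The fusion
recipe is a declared convention of this package (the deployed detector's
input packing is not public knowledge); it keeps downstream three-channel
detectors applicable and is trivially replaceable.

Conventions, chosen once and used everywhere:

* pixels are 0-based `(u, v) = (column, row)` with centers at integer
  coordinates, matching raster indexing;
* depth rasters are 16-bit unsigned **millimeters** (0 = no return),
  converted to meters at the API boundary;
* poses map world into camera (`camera = R world + p`), read directly off
  the frame-transfer equation above — the inverse convention is rejected;
* the final pixel is rounded **half away from zero**; the continuous value
  is also exposed;
* rotations must satisfy $\|R^\top R - I\|_\infty \le 10^{-9}$ and
  $|\det R - 1| \le 10^{-9}$.

The NIR sensor resolution is configurable; 1024x768 is the default (the
hardware documentation is ambiguous between 1024x768 and 1080x768, and the
former matches the sensor's native 4:3 raster).

Holes left by the forward scatter are closed by an iterated 3x3 median over
valid neighbors — simple, deterministic, and every filled pixel stays
flagged in the mask so consumers can ignore it. A frame with no valid
pixels at all is filled with a constant and fully flagged.

`screenColdCandidates()` is a deliberately crude mortality screen standing
in for the (out-of-scope) learned detector: a pixel is a candidate when it
is cold in the TIR channel *and* has NIR contour support. The two masks are
intersected **before** connected-component labelling: thresholding TIR
alone would merge a dead body into the equally-cold cage background and no
component could then pass the contour filter. Components must also pass an
area floor; boxes are returned sorted by area, ties broken by box origin.

## The deviation-correction controller

The two X-axis drive units sit on rails 50 m apart-ends and drift apart
through rail unevenness, wheel-diameter differences and asymmetric load.
The left (adjustable) unit is the reference; the controller modulates only
the right (fixed) unit. Each control cycle reads both absolute encoders
(quantized to 1 mm) and compares their absolute difference $d$ to banded
thresholds:

| band | action on the right unit |
|------|--------------------------|
| $d < 50$ mm | none (multiplier 1.0) |
| $50 \le d < 70$ mm | 120% of commanded speed if trailing, 80% if leading |
| $70 \le d < 100$ mm | 140% if trailing, 60% if leading |
| $d \ge 100$ mm | immediate halt + latched alarm |

"Trailing" is evaluated in the direction of travel (forward: right encoder
smaller; backward: mirrored). Band edges are half-open at the left edge —
the prose thresholds do not state inclusivity, so 50 mm already commands a
correction and 100 mm already halts. "Percent of its current speed" is
interpreted against the commanded set-point, not the compounded previous
output (compounding diverges); the banding is memoryless with no
hysteresis.

`simulateTravel()` closes the loop around a simple plant: each side's
effective speed is `commanded x multiplier x (1 + bias) + noise`, with an
optional position-dependent bias for rail slope or joints. The control
cycle is 10 Hz by default (the platform's stability instrumentation
samples at 10 Hz; the rate is configurable). The run ends when the
reference side is within the system's ±10 mm positioning tolerance of the
target, or on alarm; after a halt the alarm stays latched until
`resetAlarm()` — resuming is an explicit human decision. The stop rule
triggers on entering the tolerance window, so at the 0.05 m/s inspection
speed (5 mm per cycle) the stop error cannot exceed the tolerance; at the
envelope's 0.3 m/s top speed a cycle step (30 mm) can overshoot the window,
which mirrors the real system's practice of approaching waypoints at
inspection speed.

A -5% right-side bias at 0.05 m/s would grow the gap at 2.5 mm/s
uncorrected, alarming within a minute; under the controller the gap
saturates just above the 50 mm band edge, where the 20% correction
(+7 mm/s closure) overwhelms the drift. The correction authority is ±40%,
so biases up to roughly that fraction are contained; beyond it the alarm
fires by construction.

The Z-axis posture logic is a lookup: lower-tier imaging keeps the arm
vertical, upper-tier rotates it to 30° (the effective arm length at 30° is
stored as the configured value 86.6 cm rather than derived — the geometry
behind the deployed figure involves the mount offset, not bare
trigonometry), and obstacle bypass lifts the module 65 cm toward the beam
and takes precedence over tier.

## Inspection sessions

The house maps to a 1-based 78x12 cage grid. Physical positions come from
two route coordinate tables (`index,position_mm` CSVs with headers; the
deployed files name only the axes, so the two-column layout is this
package's declared schema). `runSession()` visits each waypoint, selects
the posture, captures the four modalities, names each file
`modality_date_time_x_y` (time is `HHMM` with no seconds, as deployed;
same-minute collisions can be disambiguated with an optional suffix, off
by default) and appends one telemetry row. Capture failures are recorded
as missing-data entries and the session continues — completeness is a
*metric*, reported at the end (per-modality counts, parseable-filename
fraction), not an abort condition. `splitManifest()` reproduces the
dataset tooling: a seeded uniform shuffle split 70/15/15 by the floor
rule, with content tags (`dead-only` / `mixed` / `live-only`) mirroring
the three training datasets built on the deployed system.

## Environmental telemetry and welfare

Telemetry rows carry six measurements (wind, pressure, NH3, CO2,
temperature, humidity, light) plus time and cage location, persisted in
the deployed CSV column order. `assessWelfare()` checks each row against
husbandry bands: NH3 below 20 ppm and CO2 below 3000 ppm (upper bounds are
strict — reaching the bound flags, since the guidance is "controlled
below"), temperature 15–25 °C, humidity 60–70 %RH, light 50–100 lux, wind
0.1–0.2 m/s; atmospheric pressure is left at natural levels and reported
`not-assessed` without affecting the overall verdict.

`sensorErrorStats()` implements the calibration statistic used to qualify
the sensing module against reference instruments: signed mean error plus
an expanded uncertainty $k \cdot s$ with $s$ the sample standard deviation
(n-1) and $k$ the two-sided Student-t quantile at the coverage probability
with $n-1$ degrees of freedom. The coverage factor choice is deliberate:
at the deployed calibration size ($n = 12$, 95%) $k = 2.201$, not the
normal 1.96 — with eleven degrees of freedom the t correction is not
negligible. `combinedUncertainty()` combines independent components in
quadrature; ±2.8 %RH (module) with ±3 %RH (reference) gives ±4.10 %RH,
matching the deployed module's reported total. The CO2 reference
uncertainty is value-dependent, ±(40 ppm + 3% of reading), evaluated per
pair by `co2ReferenceUncertainty()`; the deployed CO2 total cannot be
reproduced without the unpublished readings it was evaluated at, so it is
not asserted anywhere.

## The synthetic scene generator

`renderScene()` ray-casts a flat cage plane 0.384 m below the cameras (the
deployed imaging distance) with half-ellipsoid rabbit phantoms bulging
toward them. Each camera renders through its **own** pose and intrinsics —
a tempting orthographic shortcut was rejected because only full
perspective rendering makes registration errors physically meaningful.
Live phantoms are body-warm in TIR, dead phantoms sit at ambient (the
mortality cue); both are bright contours in NIR. TIR values are arbitrary
8-bit intensities with a declared nominal temperature mapping in the frame
metadata — no radiometric calibration is modeled. The RGB modality is a
grayscale render replicated to three channels: nothing downstream consumes
its content, only its presence, size and naming.

Default geometry: `synthRig()` perturbs the TIR pose by a 20 mm baseline
and 2° rotation (well inside the short-baseline/small-angle regime of a
rigidly co-mounted rig); focal scales 730 px (NIR) and 240 px (TIR)
approximate the deployed sensors' fields of view. `randomScene()` places
phantoms with semi-axes 3.5–5.5 cm within the region both cameras see,
rejection-sampling positions so silhouettes never merge (merged phantoms
would make per-animal ground truth ill-defined). Environmental series
default to the mid-points of the bands observed in a running house (NH3
10–11 ppm, CO2 400–440 ppm, 20–25 °C, 50–55 %RH, wind 0.11–0.15 m/s,
light 6–10 lux, pressure 970–1000 hPa). All generators are pure functions
of their spec and seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: fur texture and emissivity variation, partial
occlusion by cage wire, depth sensor noise and dropout patterns, thermal
gradients across a body, motion blur, and detector-grade appearance
variety. The synthetic suite validates geometric consistency, control
logic and plumbing, not detection performance.

## Problem sizes and numerical choices

The test suite exercises full-resolution rasters (1024x768 NIR against
256x192 TIR) because registration behavior is resolution-dependent; scene
batches use 20 seeded scenes and controller sweeps 100 seeded runs, sizes
at which the checked statistics are stable from run to run. Chain-vs-oracle
agreement is asserted at 1e-6 px over 1000 random rigs; centroid recovery
at mean < 1 / max < 2 TIR px (the residual is silhouette parallax between
the two viewpoints, not numerical error). Degenerate inputs are defined,
not accidental: zero depth is invalid by contract, points at or behind
Z = 0 refuse to project, an all-zero depth raster produces an empty map and
a fully-flagged fused frame, and an empty route or manifest flows through
the session and split tooling without error.

## Known limitations

* The plant model is kinematic: no motor torque, reducer backlash or wheel
  slip dynamics (slippage can be approximated via the position-dependent
  bias hook).
* No lens distortion and no calibration estimation; calibration is an
  input.
* The cold-body screen is a plumbing baseline, not a detector; its
  thresholds are scene-scale constants with no claim of transfer to real
  imagery.
* Only the X axis is simulated dynamically; Y/Z are posture lookups.
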