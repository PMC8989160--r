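# respdepth

Contactless respiratory monitoring from depth-camera image stacks.

`respdepth` reconstructs breath-by-breath **respiratory rate**,
**chest-wall displacement amplitude** and **thoracoabdominal phase shift**
from sequences of depth images, for researchers studying breathing
patterns in settings where contact sensors are impractical — the
motivating case being preterm infants inside an incubator, observed by a
small depth camera that cannot be placed perpendicular to the chest.

## The method

Each depth frame is back-projected to a point cloud through the pinhole
intrinsics. Around an operator-selected pixel on each chest-wall
compartment (ribcage RC, abdomen AB), the points within an 8-pixel radius
are fitted with a regression plane (OLS of z on x, y); a cylinder is
erected with its axis along the plane normal and its radius converted to
millimetres at the patch depth. The cylinder is built once, on frame 1,
and the points inside it are averaged in every frame to a centroid with
camera distance P(i). The breathing signal is the Euclidean distance
between each frame's 3D centroid and the centroid of the frame minimising
P(i) — a quantity independent of the camera orientation, which is the
point: only the motion *magnitude* along the local surface normal is
measured, not its projection on the optical axis.

After outlier interpolation (> 15 cm) and a five-sample moving average,
breaths are segmented as minimum–maximum–minimum triples of the signal
(extrema detected over 33-sample windows). Per breath:

* RR = 60·fs / (min-to-min interval) (bpm),
* A = s(max) − s(following min) (mm),
* ϑ from the Lissajous loop of RC vs AB: |ϑ| = arcsin(m/s) with m the
  loop width at the RC mid-level and s the AB range (obtuse branch when
  the RC–AB covariance is negative), signed by loop orientation; negative
  ϑ means the abdomen leads. 0° = synchronous, ±180° = paradoxical.

A synthetic **bi-compartmental phantom** — two adjacent membranes driven
sinusoidally along their surface normal with configurable amplitude
(1–7 mm), rate (20–60 bpm) and inter-compartment phase (0–90°), rendered
through an arbitrarily posed pinhole depth camera with optional noise,
dropout and occlusion — provides analytic ground truth for end-to-end
validation, replacing both the physical test object and the
optoelectronic reference system of a bench study.

## Worked example

Simulate a noisy phantom breathing at 50 bpm with a 2 mm ribcage and a
3 mm abdominal excursion, the abdomen lagging by 30°, and run the full
pipeline:

```r
library(respdepth)

cfg <- phantom_config(amp_rc = 2, amp_ab = 3, rr = 50, phase_deg = 30,
                      duration_s = 12,
                      intrinsics = default_intrinsics(160, 120),
                      noise_sd = 0.3, seed = 7)
ph <- generate_phantom(cfg)
ph$sequence
#> <depth_sequence> 360 frames of 160x120 px, 30 fps, 12.00 s

sig <- lapply(list(rc = ph$truth$roi_seed_rc,
                   ab = ph$truth$roi_seed_ab), function(s) {
  ser <- extract_raw_series(ph$sequence, roi_spec(s[1], s[2]))
  clean_signal(displacement_from_reference(ser$centroids, ser$distances), 30)
})
bt <- analyze_pair(sig$rc, sig$ab)
print(summarize_recording(bt), digits = 3)
#>      metric  mean     sd  n sd_defined
#> 1 rr_rc_bpm 50.29 0.8874 10       TRUE
#> 2 rr_ab_bpm 50.62 1.9764 10       TRUE
#> 3   a_rc_mm  1.84 0.0236 10       TRUE
#> 4   a_ab_mm  2.84 0.0807 10       TRUE
#> 5 theta_deg 30.50 0.4905 10       TRUE
```

Ten breaths are segmented from the 12 s recording. The mean rate (50.3
and 50.6 bpm per compartment) recovers the commanded 50 bpm; the phase
shift (30.5°) recovers the commanded 30°. Amplitudes are attenuated by
the five-sample smoother — dividing by its analytic gain restores the
commanded values:

```r
mean(bt$rc$a) / boxcar_gain(50 / 60, 30)
#> [1] 1.9
```

The agreement machinery mirrors a bench validation:
`run_invitro_protocol(protocol_presets(...))` pairs pipeline estimates
with the phantom's analytic truth cycle by cycle, and `bland_altman()` /
`error_table()` summarise bias, limits of agreement and per-step errors.

A command-line interface wraps the same functions
(`exec/respdepth simulate | extract | breaths | validate | run`), reading
depth stacks as 16-bit TIFF directories with a `meta.json` sidecar.

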