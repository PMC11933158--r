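# pisaflow

Quantification of mitral regurgitation (MR) from velocity fields, the way it
is done both at the echo machine and at the PIV bench.

Severe MR is graded — and treatment decided — largely from the
**flow-convergence (PISA) method**: in color Doppler, the blood accelerating
toward the leaking orifice is assumed to be an ideal sink flow, so the
isovelocity shell at the aliasing velocity `Va` is taken to be a hemisphere
of radius `r`, giving the regurgitant flow, effective orifice area and
regurgitant volume

    RFlow = 2 pi r^2 * Va
    EROa  = RFlow / Vmax
    RVol  = EROa * VTI

where `Vmax` is the peak jet velocity and `VTI` its velocity-time integral
over systole. Those hemispheric-sink assumptions break down for large and
non-circular orifices, and the method is known to underestimate RVol. This
package implements everything needed to *quantify* that breakdown on velocity
fields with known ground truth:

* **Clinical estimator chain** — beam projection, aliasing-radius extraction
  along the flow axis with sub-cell interpolation, and the RFlow/EROa/RVol
  chain (`beam_project`, `pisa_radius`, `pisa_estimate`).
* **PIV-style reference integrator** — streamwise-flux integration across
  measurement planes and over systole, with a frame-ensemble bootstrap giving
  2-sigma uncertainty (`station_flux`, `flow_rate_series`, `reference_rvol`,
  `bootstrap_ci`).
* **Convergence-zone flow models** — ideal half-space point sink, exact
  circular-aperture potential flow, panel sink sheets over parametric orifice
  polygons (circle / pointed-oval slit / drop), and wall-image confinement
  (`point_sink_field`, `aperture_axial_profile`, `sink_sheet_field`,
  `confined_sink_field`).
* **Aliasing-velocity sensitivity analysis** — error-vs-`Va` curves, optimal
  aliasing velocity (the zero crossing of the error), admissible bands, and
  shape/size sweeps (`error_curve`, `optimal_aliasing`, `admissible_band`,
  `sweep_shapes_sizes`).
* **Synthetic-data generator** — pulsatile regurgitant jets with the measured
  waveform morphology (starting-vortex local peak at 210 ms, global peak at
  245 ms, exponential-like decay), saddle-backed exit profiles, and PIV-like
  sampling: 42 cardiac phases, 0.5323 mm vector spacing, frame ensembles with
  Gaussian noise (`waveform`, `jet_exit_series`, `piv_sample`).
* **Diagnostics and grading** — Q-criterion vortex maps for planar 2D2C
  fields, saddle/block-profile metrics, and American Society of
  Echocardiography severity grading (`q_criterion`, `profile_metrics`,
  `grade_severity`), plus a full study orchestrator (`run_study`).

## Worked example

```r
library(pisaflow)

## the clinical chain on an ideal sink at 244.9 ml/s
grid  <- list(x = seq(-2.6, -0.06, by = 0.025), y = seq(-0.5, 0.5, by = 0.025))
ser   <- field_series(0, list(point_sink_field(244.9, grid)))
pisa_estimate(ser, Va = 20, window = c(0, 300))
#> PISA estimate @ Va = 20 cm/s:
#>   r = 1.396 cm, RFlow = 244.9 ml/s
#>   Vmax = 6929.3 cm/s, VTI = 2078.78 cm
#>   EROa = 0.035 cm^2, RVol = 73.48 ml
```

(`Vmax` here is the sampled speed next to the singular sink origin and the
steady "VTI" is that speed times the nominal 0.3 s window — meaningful
Vmax/VTI/RVol values come from jet series, as below; the point of the sink
case is the exact radius and RFlow.)

On the ideal sink the chain returns the configured flow rate exactly
(`r = sqrt(Q / (2 pi Va)) = 1.396` cm). On a finite circular aperture of
radius `a` it instead returns `Q - 2 pi a^2 Va`: a linear underestimation
growing with aliasing velocity and orifice size —

```r
o  <- make_orifice("circle", 12.2, label = "circle-L")   # area 116.9 mm^2
ec <- error_curve(sink_flow_spec(o, 244.9, model = "aperture_exact"))
subset(ec$curve, Va %in% c(20, 40, 60))
#>    Va         r  rel_error no_crossing
#> 16 20 1.2556906 -0.1909295       FALSE
#> 36 40 0.7761008 -0.3818593       FALSE
#> 56 60 0.5268031 -0.5727923       FALSE
```

i.e. at the aliasing velocities physicians typically choose (30-50 cm/s) the
flow through a 12 mm orifice is underestimated by 30-50%, which is what turns
a moderate regurgitation into an apparently mild one:

```r
grade_severity("RVol", 35)   # "moderate"  (the reference value)
grade_severity("RVol", 22)   # "mild"      (the PISA value at Va = 40)
```

The full bench comparison — synthetic pulsatile jets per orifice phantom,
PISA estimate vs PIV-reference RVol with 2-sigma bootstrap — is one call:

```r
cfg <- study_config(orifices = orifice_catalog(as_specs = TRUE), va = 40)
rep <- run_study(cfg)
plot(rep)   # RVol bars and deviation-vs-orifice-area panels
```

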