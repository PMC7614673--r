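# magsense

Tissue property sensing with wireless magnetoelastic soft robots.

A millimetre-scale magnetized elastomer ribbon, anchored to a soft tissue
surface by two adhesive footpads with a responsive adhesive patch at
mid-body, deforms under a uniform external magnetic field. Because the
distributed magnetic torque and the elastic response of the body are known,
the *tracked body shapes* become a force/strain probe for the tissue
underneath. `magsense` implements the computational core of this sensing
scheme for people building or analysing such experiments:

* a **forward quasi-static elastica model** of the magnetized beam
  (distributed torque `τ(s) = A [M(s) × B]_z`, bending stiffness
  `EI = E w t³/12`, gravity, pinned/conforming substrate contacts, curved
  substrates), solved by Newton collocation with continuation;
* a **static adhesion estimator**: during a stepped peel protocol
  (13.4 mT load, 2.7 mT steps of opposite sign every 2.5 s), the last
  attached shape and the threshold field `B_detach` determine the patch
  pull-off force `F_a` from least-squares moment balance
  (`EI ∂θ/∂s` against the far-segment load moments), and `F_a` maps to
  surface pH through anchored calibrations of the pH-responsive adhesive
  (porcine stomach: 1.08 mN at pH 1 → 0.31 mN at pH 5);
* a **dynamic viscoelasticity estimator**: the mean interface strain
  `ε̄yy = ∫_{0.3L}^{0.7L} ε_yy ds / 0.4L` under a rotating field follows the
  calibrated power law `amp(ε̄yy)/B_y = k (E')^a`
  (`k = 54.128 Pa/mT`, `a = −1.067`), attenuated by a first-order response
  `1/√(1+(ωτ)²)` with `τ = k_τ E'/E''` (`k_τ = 0.0703 s`); a frequency
  sweep yields `E'` (storage) and `E''` (loss);
* the **imaging pipeline** feeding the estimators: robot centerline
  tracking from TIFF stacks, footpad tracking, plane-tilt correction
  `u_y' = u_y / cos(arcsin((l−t)/w))`, image SNR, digital image correlation
  of tracer-particle frames, displacement-field gridding/smoothing, the
  maximum-displacement map `Δu = √(Δu_x² + Δu_y²)`, and wavelet-based
  localization of stiff inclusions along the contact line;
* a **synthetic-data generator** (detachment sequences, frequency sweeps,
  particle fields, x-ray-like renders) so every estimator is testable
  without experimental data, plus a command-line interface.

See `vignettes/methods.Rmd` for the models, defaults and their rationale.

## Worked example

Simulate a detachment experiment on a flat substrate with a ground-truth
adhesion of 0.5 mN, invert it, and read the implied stomach-surface pH:

```r
library(magsense)
robot    <- robot_spec()                       # 6.5 x 2 x 0.15 mm, 163 kPa
scenario <- synthetic_scenario(Fa_N = 0.5e-3, seed = 1)
sim      <- simulate_detachment_sequence(scenario)
est      <- run_detachment_inversion(sim$shapes, sim$field, robot)
est
#> <adhesion_estimate> Fa = 0.5 mN at B_detach = 3.95 mT
#>   footpad reactions 0.2739 / 0.2739 mN, feasible: TRUE
adhesion_to_pH(est$Fa_N * 1e3, ph_calibration("stomach"), clamp = TRUE)$pH
#> [1] 4.012987
```

The estimator recovers the simulated 0.5 mN exactly (noiseless round trips
are accurate to < 0.01%; with 1-pixel tracking noise at 10 µm/px the error
stays below ~20% across adhesions 0.13–0.82 mN and substrate curvatures
±250 m⁻¹). The footpad reactions satisfy `F1 + F2 = W + Fa`; a pull-off
force of 0.5 mN on this calibration corresponds to a pH of about 4.

Viscoelasticity, end to end on a synthetic substrate with
`E' = 6 kPa, E'' = 1.5 kPa` and 2% amplitude noise:

```r
sc   <- synthetic_scenario(E_prime_Pa = 6e3, E_dprime_Pa = 1.5e3,
                           amplitude_noise_frac = 0.02, seed = 1)
recs <- simulate_dynamic_response(sc, c(0.1, 0.5, 1, 2, 5, 10, 15))
run_viscoelastic_pipeline(recs)
#> <visco_estimate> E' = 6.12 kPa  E'' = 1.57 kPa  tau = 0.274 s
```

`E'` comes from the 0.1 Hz amplitude through the inverted power law
(`estimate_storage_modulus(0.19, 20, visco_calibration())` gives 3.31 kPa
for the documented amplitude 0.19 at 20 mT), `τ` from the roll-off fit and
`E''` = `k_τ E'/τ` — here within 2% and 5% of the simulated truth.

## Command line

```sh
Rscript inst/cli/magsense simulate --scenario scenario.json --out run/
Rscript inst/cli/magsense estimate-adhesion --shapes run/shapes.csv \
    --field run/waveform.csv --ph-tissue stomach --out adhesion.json
Rscript inst/cli/magsense estimate-visco --sweep sweep.csv --out visco.json
Rscript inst/cli/magsense calibrate --pairs pairs.csv --out calib.json
Rscript inst/cli/magsense track --images stack.tif --pixel-pitch-um 10 \
    --out curves.csv
Rscript inst/cli/magsense map-inclusion --profile profile.csv --out call.json
```

Every run writes a `manifest.json` (command, option set, config MD5s, seed,
version, timing); identical configuration and seed reproduce identical
result files.

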