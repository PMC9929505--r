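# bitemech

Biomechanics of arthropod bite forces across mandibular opening angles.

Arthropods bite with a lever system: a closer muscle pulls on a tendon-like
apodeme, which rotates the mandible about a (near-)fixed joint axis. How
hard an animal can bite, and how that force changes with how far its
mandibles are open, follows from first principles. `bitemech` implements
the complete forward model

```
|F_b|(θ) = σ(θ) · A_phys · cos[φ(θ)] · MA(θ)
```

where, at opening angle θ (measured between the lateral head axis and the
projected outlever),

* `MA(θ) = sin(γ(θ)) |R̂×L_i| |R̂×Â| / |R̂×L_o|` is the mechanical
  advantage, with the apodeme angle `γ(θ) = θ₀ − θ + γ₀` varying linearly
  with the opening angle,
* `Δ(θ) = [cos γ₀ − cos γ(θ)] |R̂×L_i| |R̂×Â|` is the apodeme
  displacement, which drives fibre shortening,
* `φ(θ) = arctan[sin φ₀ / (cos φ₀ − Δ/L_t0)]` is the pennation angle,
* `σ = σ_max exp(−β (1 − L_f/L_opt)²)` is a Gaussian muscle force–length
  curve evaluated at the fibre length of each population (directly attached
  or attached by inextensible cuticular filaments), and
* `A_phys = V_m / L_opt` is the strain-invariant physiological
  cross-sectional area.

Around the forward model the package provides, as both R functions and a
small command-line tool:

* **sensor corrections** for one-dimensional force sensors
  (`measured_to_bite()`: `|F_b| = Γ |F_m| / cos α`) and for non-distal bite
  contacts (`stimulated_rescale()`),
* **physiology fitting** — bounded multi-start nonlinear least squares that
  extracts `(σ_max, L_opt, β)` from bite-force–angle data through the full
  model (`fit_force_length()`, `confidence_intervals()`),
* **joint kinematics** — rigid-body estimation of the mandible rotation
  axis from multi-pose landmarks and PCA extraction of the apodeme
  displacement axis (`estimate_rotation_axis()`, `displacement_axis()`),
* **micro-CT fibre morphometry** — the rank-matching algorithm pairing
  fibre seeds with apodeme surface points, filament growth through a voxel
  mask, and attachment classification (`rank_match()`, `grow_filament()`,
  `classify_and_measure()`),
* **minimal models** — the head-size/sarcomere-length bite-force bound
  (`minimal_max_force()`, ≈8.25 kPa µm⁻¹ · H_w H_l S_l) and allometric
  weight-specific force bounds (`allometric_bound()`),
* **synthetic data** — generators for apparatus configurations, bite-force
  data sets, rigid pose series and pennate fibre fields, each with ground
  truth, enabling closed-loop validation without any external data
  (`make_reference_apparatus()`, `simulate_bite_measurements()`,
  `make_pose_series()`, `make_fibre_field()`).

## Worked example

```r
library(bitemech)

# the reference apparatus: a leaf-cutter-ant-major closer system back-solved
# from published summary morphology and physiology
app <- make_reference_apparatus()

effective_levers(c(51, 105), app$levers, app$frame)
#>   theta_deg gamma_deg inlever_eff outlever_eff mechanical_advantage
#> 1        51        90       0.645         2.23                0.29
#> 2       105        36       0.379         2.23                0.170

bite_force(c(50, 75, 100), app)
#> [1] 1.2081551 0.6741251 0.1983258
```

The mechanical advantage peaks at 0.29 where the apodeme angle is 90° and
falls by the factor 1.7 at full opening; the predicted bite force drops
from about 1.2 N near closed mandibles to about 0.2 N at 100°, a five-fold
decline driven mostly by muscle stress and gearing.

Simulating the in vivo experiment (138 bites, 50–105°, 5% multiplicative
noise) and refitting recovers the generating physiology:

```r
sim <- simulate_bite_measurements(app, n = 138, theta_range = c(50, 105),
                                  noise_scale = 0.05, seed = 42)
fit_force_length(sim, app, l_opt_range = c(0.85, 1.47))
#> Force-length fit (bounded nonlinear least squares)
#>   n = 138 observations, RSS = 0.1196 N^2, converged: TRUE
#>   sigma_max (MPa)  1.17  [1.154, 1.185]
#>   l_opt (mm)       0.8712  [0.8376, 0.9047]
#>   beta             4.071  [3.293, 4.849]
```

The generating values were `σ_max = 1.16` MPa, `L_opt = 0.92` mm,
`β = 5.34`: a single replicate lands close on stress, within a few percent
on the optimal length, and — as its wide interval warns — least precisely
on the shape parameter β, whose identification needs both flanks of the
force–length curve.

## Command line

```sh
inst/cli/bitemech simulate apparatus --out demo/
inst/cli/bitemech predict --config demo/apparatus.json --theta-grid 35:105:1 --out demo/curve.csv
inst/cli/bitemech fit --measurements demo/bites.csv --config demo/apparatus.json \
    --fibre-range 0.85,1.47 --out demo/fit.json
```

Subcommands: `predict`, `correct`, `fit`, `axis`, `apodeme-axis`,
`fibres`, `simulate`. Angles are degrees, lengths mm, forces N.

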