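# vesselgr

Growth and remodeling (G&R) of arteries under the homogenized constrained
mixture theory, with variable smooth muscle tone — as a desk-scale R package.

Aneurysms of the ascending aorta grow because the load-bearing fabric of the
wall turns over: elastin is degraded and never replaced, collagen is deposited
in response to fiber overstress, and smooth muscle cells (SMCs) contribute an
active tension set by a length–tension relationship. `vesselgr` models an
idealized two-layer (media/adventitia) thick-walled cylinder as a constrained
mixture of elastin, four collagen fiber families and SMCs. Each constituent
carries its own deposition pre-stretch, strain energy (neo-Hookean for
elastin, Fung exponential for fibers), mass turnover and remodeling law; SMC
active stress follows the inverted parabola

σ_act = (ρ_m/ρ₀(0)) · σ_act_max · [1 − (λ_max − λ_act)² / (λ_max − λ_0)²],

clamped at zero, with the active stretch λ_act = λ_m/λ₀ᵐ tracking the total
tissue stretch. The package provides homeostatic initialization of the loaded
in-vivo state (deposition-stretch fixed point), a radial equilibrium solver,
a monthly staggered G&R time loop, and the three-way sensitivity study over
damage time t_dam, collagen gain k_σ and maximal contractility λ_max. It is
aimed at researchers in vascular biomechanics who want a transparent,
scriptable implementation of this model class for exploration and teaching.

## Worked example: the worst-case contractility scenario

When the SMC length–tension curve peaks at λ_max = 1.0 — at, rather than
above, the deposition stretch — dilation drives the cells down the descending
branch and their active stress collapses:

```r
library(vesselgr)

cfg    <- make_preset("table1_worst_case")   # lambda_max = 1.0
vessel <- init_homeostatic(build_two_layer_cylinder(cfg$vessel,
                                                    cfg$materials))
vessel
#> <gr_vessel> two-layer cylinder
#>   inner radius 12.50 mm, thickness 2.38 mm, 10 shells (6 media / 4
#>   adventitia), 1 ring(s)
#>   pressure 10666 Pa, homeostatic initialization: done

traj <- run_simulation(vessel, cfg$damage,      # D_max = 0.5, t_dam = 40 d
                       horizon_months = 180, stop_on_convergence = FALSE)
glance(traj)[, c("months_run", "min_R_t", "max_lambda_m", "failed")]
#> # A tibble: 1 × 4
#>   months_run min_R_t max_lambda_m failed
#>        <int>   <dbl>        <dbl> <lgl>
#> 1        102       0         6.99 TRUE
```

At homeostasis the active stress carries 24% of the wall's circumferential
stress (`traj$R_t[1] = 0.2442`); by month 4 the SMC stretch has passed the
zero of the length–tension parabola and the wall-averaged active/total ratio
`R_t` is exactly 0 — the scenario's headline number. The run also illustrates
the fixture's honest limit: on a free, untethered ring the low collagen gain
(k_σ = 0.05) cannot stabilize a 50% circumferential elastin loss, the
aneurysm runs away (SMC stretch 6.99) and the quasi-static solver reaches a
fold at month 102, after which the partial trajectory is returned with
`failed = TRUE`. See the methods vignette (`vignettes/methods.Rmd`) for the
stability analysis and what passing results do and do not certify.

Further entry points:

```r
stress_ratios(traj)        # R_m, R_t series (active/SMC, active/total)
geometry_series(traj)      # diameter and thickness evolution
stress_stretch_curve(traj) # SMC active stress vs stretch at the probe shell
autoplot(traj)             # trajectory panels (ggplot2)

sw <- sensitivity_sweep()  # 27 cells: t_dam x k_sigma x lambda_max
autoplot(sw)
```

A thin command-line wrapper ships in `exec/vesselgr`, with
`init` / `run` / `sweep` / `report` verbs and YAML configs that accept unit
strings such as `pressure: 80 mmHg`.

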