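# kneealign

Orthogonal-design screening and optimization of tibial-component
implantation parameters in total knee arthroplasty (TKA).

Small deviations in how the tibial component is implanted — coronal
varus–valgus angle, posterior slope of the tibial cut, external rotation of
the tray — change how the femoral condyles load the polyethylene liner.
The peak contact pressure on the liner is the standard proxy for
polyethylene wear risk, and evaluating it (by finite elements or
experiment) is expensive, so the practical question is a screening one:
which angle matters most, and which level combination minimizes the peak
pressure, from as few evaluations as possible.

`kneealign` is aimed at biomechanics researchers and implant-alignment
methodologists. It implements:

* **Design of experiments** — the Taguchi orthogonal array L9(3⁴) over
  three 3-level factors (plus the 27-run full factorial), with balance and
  pairwise-orthogonality validation and delimited-text I/O.
* **Range analysis** — level means *K*ⱼᵢ of the response per factor *j* and
  level *i*, per-factor ranges

  *R*ⱼ = maxᵢ *K*ⱼᵢ − minᵢ *K*ⱼᵢ,

  factor ranking by descending range, and the predicted optimal level
  combination (objective: minimum peak pressure), followed by verification
  of the optimum against every design run.
* **A contact surrogate** — a desk-scale elastic-foundation ("bed of
  springs") model of the femoral condyles on the misaligned liner under a
  1150 N axial load: layer stiffness
  *k* = *E*(1−ν) / ((1+ν)(1−2ν)*t*), rigid femur, damped-Newton rigid-body
  equilibrium, Neo-Hookean collateral-ligament springs
  (σ = 2*C*₁(λ² − λ⁻¹)), gridded pressure maps with per-compartment peaks
  and loads.
* **A reference response table** — the packaged nine-run table of FE peak
  liner pressures (`fe_reference_responses()`) that the analysis examples
  reproduce; these FE magnitudes are consumed as data, not recomputed.
* **A reproducible pipeline** — YAML-configured
  design → evaluate → analyze → verify → report workflow with a thin
  command-line front end (`inst/scripts/kneealign.R`), deterministic given
  config and seed.

## Worked example

Analyze the packaged reference responses:

```r
library(kneealign)
ref <- fe_reference_responses()
ra  <- range_analysis(ref)
ra
#> <range_ranking> objective: minimize
#>   level1 level2 level3
#> A  18.85  22.51  25.55
#> B  21.28  23.64  21.99
#> C  23.33  21.18  22.41
#> Range R: A=6.70, B=2.36, C=2.15
#> Ranking: A > B > C
#> Optimal: A1B1C2 ( varus_deg=0, slope_deg=1, rotation_deg=4 )
#> Response spread: max 29.73, min 17.10, max-min 12.63 MPa (73.9%)
```

Reading this: the varus angle (factor A, range 6.70 MPa) dominates the peak
liner pressure, the posterior slope (B, 2.36) and external rotation
(C, 2.15) matter far less, and the level means predict the optimum at
combination A1B1C2 — 0° varus, 1° posterior-slope cut, 4° external
rotation. Verifying that optimum against an externally evaluated response
of 16.37 MPa:

```r
verify_optimum(ra, ref, supplied_value = 16.37)
#> <verification_record> A1B1C2 -> 16.37 MPa (best of all runs)
#>   reduction vs worst run: 13.36 MPa (44.9% of worst, 81.6% of optimum)
```

The same analysis from the shell, writing `design.csv`, `responses.csv`,
`report.txt`, `report.json` and `log.txt`:

```sh
Rscript inst/scripts/kneealign.R analyze \
  --responses inst/extdata/fe_reference_responses.csv \
  --optimum-value 16.37 --out results/
```

Other subcommands: `design` (emit the L9 design table), `evaluate` / `run`
(evaluate a design with the contact surrogate or a planted analytic
response per a YAML `--config`), `verify`. Running the surrogate instead of
the reference table:

```r
res <- run_pipeline(pipeline_config(list(evaluator = "surrogate")))
res$analysis$ranking      # emergent screening of the surrogate model
res$verification          # surrogate-evaluated optimum, compartment peaks
```

See `vignettes/tibial-alignment-screening.Rmd` for the model, its
assumptions, every tunable parameter with units and defaults, and known
limitations.

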