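# nanopbpk

Mechanistic whole-body PBPK (physiologically based pharmacokinetic)
simulation of nanoparticle biodistribution and tumor delivery in a
reference rat, for nanomedicine researchers who want to ask — *before*
synthesizing a particle — how hydrodynamic size, density and degradation
rate shape plasma circulation, MPS (liver/spleen) capture, excretion and
delivery to a solid tumor.

## The model in brief

Every transport step is parameterized from first principles rather than
fitted to concentration data. At the microvascular scale, for a particle
of radius *r* in blood of viscosity μ and hematocrit *H*:

- sedimentation velocity (Stokes): *v* = (2/9)·((ρ<sub>np</sub> − ρ<sub>p</sub>)/μ)·g·r²
- effective diffusivity: *D* = *D<sub>B</sub>* + *D<sub>S</sub>*, with
  *D<sub>B</sub>* = k<sub>B</sub>T/(6πμr) (Stokes–Einstein) and
  *D<sub>S</sub>* = 0.3·β²·γ̇·H² (shear-induced, erythrocyte-driven)
- wall deposition: k<sub>on</sub> = v·D·l/(u·R³) (sedimentation velocity
  corrected by the capillary Peclet number u·R²/(D·l), per radial length R)
- wall dislodging: k<sub>off</sub> = D<sub>B</sub>/l<sub>g</sub>² (glycocalyx escape)
- phagocytosis: k<sub>mac</sub> = p/(4πr²γ) (inverse membrane-wrapping time)
- pore-hindered extravasation: reflection coefficient
  σ(α) = 1 − \[(1 − (1 − (1−α)²)²)·G + (16/9)·α²·(1−α)²·F\] with
  α = r/r<sub>pore</sub>, and tumor-wall permeability
  P = φ·(1−α)·F·D<sub>B</sub>/l<sub>w</sub>

These rates feed a linear, stiff compartmental ODE system over nine
organs (each with free-vascular, bound-vascular and extravascular pools,
plus phagocytic pools in liver and spleen), plasma, a lymph node, a
facultative spherical tumor (vascular pools plus a diffusively fed
interstitium, PS-limited — the EPR effect), and absorbing urine, feces
and degraded pools. State is kept in %ID amounts so conservation of mass
is exact by construction; the solver is `deSolve::lsoda` with the exact
Jacobian. Outputs are %ID time courses, trapezoidal AUCs, and the tumor
delivery efficiency AUC<sub>tumor</sub>(0–1000 h)/1000 h.

Local (one-at-a-time sensitivity coefficients) and global (Latin
hypercube + standardized regression, partial rank correlation, ANOVA F,
with Tukey-grouped weighted ranking) sensitivity workflows cover the 11
tunable NP/tumor/host parameters against the four headline AUC outputs.

## Worked example

A 15 nm particle (density 2 g cm⁻³, degradation 0.01 h⁻¹) injected into
the reference tumor-bearing rat:

```r
library(nanopbpk)

np  <- nanoparticle(diameter_nm = 15)
res <- pbpk_simulate(np)              # reference body + 5 mm tumor
agg <- aggregate_outputs(res)

cat(sprintf("AUC(plasma)  = %8.1f %%ID.h\n", agg$plasma))
cat(sprintf("AUC(MPS)     = %8.1f %%ID.h\n", agg$mps))
cat(sprintf("AUC(tumor)   = %8.1f %%ID.h\n", agg$tumor))
cat(sprintf("AUC(excreta) = %8.1f %%ID.h\n", agg$excreta))
cat(sprintf("delivery efficiency = %.3f %%ID\n", delivery_efficiency(res)))
cat(sprintf("conservation error  = %.2e %%ID\n",
            res$diagnostics$conservation_error))
```

```
AUC(plasma)  =   1750.9 %ID.h
AUC(MPS)     =   2019.5 %ID.h
AUC(tumor)   =    858.6 %ID.h
AUC(excreta) =  94461.2 %ID.h
delivery efficiency = 0.859 %ID
conservation error  = 4.78e-11 %ID
```

Reading: over 1000 h the particle spends most of its integrated exposure
in the absorbing excreta pools (everything is eventually cleared); a
15 nm particle sits just above the 8 nm renal filtration cutoff, so it
circulates long enough for the tumor interstitium to average 0.86 %ID —
above the ~0.7 %ID benchmark that typical nanoparticles fail to reach,
and near the model's optimum (delivery efficiency versus diameter peaks
around 8 nm and only ~7–20 nm particles exceed the benchmark). Mass is
conserved to solver precision at every output time.

A command-line front end with `params` / `simulate` / `lsa` / `gsa` /
`fixture` / `validate` subcommands lives at `inst/cli/nanopbpk.R`:

```sh
Rscript inst/cli/nanopbpk.R simulate --out sim.csv
Rscript inst/cli/nanopbpk.R gsa --n 5000 --replicates 10 --seed 42 --out gsa.csv
```

Configuration is YAML or JSON with a closed schema (unknown keys are
rejected); all defaults ship in
`inst/extdata/default_params.yaml`.

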