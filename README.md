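# hybkit

Systems-biology models are archived in SBML, but hybrid semiparametric
models — mechanistic material balances combined with data-driven
components such as artificial neural networks (ANNs) — usually are not,
because ML components have no natural home in the format. `hybkit`
bridges that gap for kinetic models. It is aimed at modelers who want to
replace a poorly understood rate law with a trained feedforward network
while keeping the model loadable by ordinary SBML tooling.

The package does three things:

1. **Round-trips kinetic models between SBML and HMOD**, a
   block-structured ASCII format (grammar in [HMOD-SPEC.md](HMOD-SPEC.md))
   that lists the model's compartments, species, parameters, reactions,
   rate rules and assignment rules one record per line, plus an optional
   `[ML]` block holding an ANN's weights and input/output wiring.
2. **Compiles feedforward ANNs into standard SBML constructs.** A
   network with min-max scaled inputs x̂ = (x − x_min)/(x_max − x_min)
   and layers vₗ = σₗ(Wₗ vₗ₋₁ + bₗ) (σ = tanh or identity) becomes:
   one constant parameter per weight and bias, one assignment rule per
   scaled input / hidden node / output node, and the targeted reaction's
   kinetic law replaced by the output-node symbol (optionally times a
   retained mechanistic factor, covering ρ(x)·X rate structures). The
   hybrid model is plain SBML L3V2 — any SBML-aware simulator can run it.
3. **Verifies conversions numerically.** A deterministic stiff-capable
   ODE simulator (deSolve) integrates dS/dt = Σᵣ νᵣ·vᵣ(x)/V plus rate
   rules, with assignment rules evaluated algebraically inside the RHS,
   so format round trips and ANN compilation can be checked by
   trajectory comparison rather than by eye.

Both formats get structural validators that return ordered reports of
coded issues (`DANGLING_REF`, `ANN_SHAPE_MISMATCH`, ...) instead of
throwing, and a seeded fixture generator supplies toy mass-action /
Michaelis–Menten / stiff models, random networks, rate-mimicking
networks fitted by random-feature least squares, and a malformed-file
corpus — no downloads anywhere.

## Worked example

```r
library(hybkit)

m <- make_toy_model("michaelis-menten-pathway", seed = 3)
m
#> <kinetic_model> mmpath_3 (mmpath_3)
#>   compartments: 1  species: 2  parameters: 4  reactions: 2
#>   rate rules: 0  assignment rules: 1

# fit a 1-20-1 tanh network to the Michaelis-Menten rate of reaction v1
ann <- make_rate_mimicking_ann(m, "v1", n_hidden = 20, seed = 7)
ann$metadata$fit_error
#> [1] 5.02e-07

# compile it into the model: weights become parameters, nodes become
# assignment rules, v1's kinetic law becomes the output symbol annY_1
hy <- hybridize(m, ann)
hy$plan
#> <hybridization_plan> shape 1-20-1
#>   83 generated parameters, 22 generated rules

# the hybrid model reproduces the mechanistic trajectory
cmp <- compare_trajectories(run_model(m, 10), run_model(hy$model, 10))
cmp$max
#> [1] 2.27e-07

write_sbml(hy$model, "mm_hybrid.xml")      # plain SBML L3V2
sbml_to_hmod("mm_hybrid.xml", "mm.hmod")   # folds the ANN back into [ML]
```

The fit error is the maximum absolute difference between the network and
the true rate over sampled states; the trajectory difference stays below
`fit_error * t_end`, the first-order error-growth bound. An HMOD
document for this model begins:

```
HMOD/1
model : id=mmpath_3, name=mmpath_3
[COMPARTMENTS]
cell : size=1, constant=true, name=cell
[SPECIES]
S : compartment=cell, init=1.6554686343297362, boundary=false, constant=false, name=S
...
```

## Command line

`inst/scripts/hybkit` is a thin Rscript wrapper:

```sh
hybkit convert model.xml model.hmod        # direction inferred from extensions
hybkit validate model.hmod --machine-report
hybkit hybridize model.xml weights.annw --out hybrid.xml
hybkit simulate hybrid.xml --t-end 10 --n-points 100 --out traj.csv
hybkit fixtures --out-dir fixtures --seed 1
```

Exit codes: 0 success (warnings allowed), 1 validation errors, 2 fatal
problems. Outputs are written atomically; no partial files on failure.

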