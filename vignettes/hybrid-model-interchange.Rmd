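---
title: "Encoding hybrid mechanistic/ANN kinetic models in SBML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding hybrid mechanistic/ANN kinetic models in SBML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybkit)
```

## The modeling problem

A kinetic model of a biochemical system is a set of material balances
over species concentrations,

$$\frac{dS_i}{dt} \;=\; \sum_r \frac{\nu_{ir}\, v_r(\mathbf{x})}{V_i}
\;+\; \text{rate-rule term},$$

where $\nu_{ir}$ is the stoichiometry of species $i$ in reaction $r$,
$v_r$ its kinetic law and $V_i$ the containing compartment's size. Such
models are exchanged in SBML. A *hybrid semiparametric* model keeps the
balances (parametric, fixed structure, from prior knowledge) but
replaces one or more kinetic laws with a data-driven component — here a
feedforward ANN — because that part of the kinetics lacks mechanistic
understanding. The obstacle is representational: SBML has no ANN
construct, so hybrid models typically cannot be archived or exchanged.

`hybkit` resolves this by *compiling* the network into constructs SBML
already has. The observation is that a feedforward pass

$$\hat{x}_i = \frac{x_i - x_i^{\min}}{x_i^{\max} - x_i^{\min}},\qquad
\mathbf{v}_\ell = \sigma_\ell(W_\ell \mathbf{v}_{\ell-1} + \mathbf{b}_\ell)$$

is nothing but a chain of algebraic assignments over constants, and SBML
assignment rules are exactly instantaneous algebraic assignments. Every
weight $W_{\ell,ij}$ and bias $b_{\ell,i}$ becomes a constant parameter
(`annW_<l>_<i>_<j>`, `annB_<l>_<i>`, tagged `ml-weight` / `ml-bias` in a
notes element so a round trip preserves their role); every scaled input,
hidden node and output node becomes an assignment rule (`annX_<i>`,
`annH_<l>_<i>`, `annY_<k>`); and the targeted reaction's kinetic law is
replaced by the output symbol, optionally multiplied by a retained
mechanistic factor so serial structures like $v = \rho(\mathbf{x})\cdot X$
remain expressible. tanh has native content-MathML support, which is why
the activation set is {tanh, linear}: the compiled model needs no
piecewise emulation and stays loadable by standard simulators. The
compiled document is ordinary SBML Level 3 Version 2.

Between SBML and the compiled form sits HMOD, a line-oriented ASCII
format (normative grammar: `HMOD-SPEC.md`) that keeps the mechanistic
skeleton human-readable and stores the network *uncompiled* in an `[ML]`
block — weights, scaling bounds and output wiring as text records. The
two converters are inverse to each other: HMOD → SBML compiles the
`[ML]` block; SBML → HMOD recognizes the generated symbol families
(`recover_plan()`) and folds them back.

## Design choices where the design was open

* **Expression grammar.** Kinetic laws travel as content MathML in SBML
  and as infix text in HMOD. The supported set — `+ - * / ^`, unary
  minus, `exp, ln, log10, sqrt, tanh, abs, min, max, piecewise` — is the
  smallest closed set covering common kinetic laws (mass action,
  Michaelis–Menten, exponentials) plus ANN activations. Piecewise needs
  relational operators, so `lt, leq, gt, geq, eq, neq` are included as
  named functions evaluating to 1/0. Precedence is conventional, with
  power right-associative and unary minus binding tighter than power.
  N-ary MathML `plus`/`times` fold to left-associative binary trees on
  parse; the writers emit binary applies, making parse∘write the
  identity on trees. Unary minus maps to MathML's one-argument `minus`
  apply rather than `0 − x`, which round-trips structurally without a
  spurious operand.
* **Numeric formatting.** All serialized numbers use the shortest
  decimal that reads back to the identical IEEE double (≤ 17 significant
  digits). This is what makes round trips *bit*-stable: weight recovery
  through SBML or HMOD is exact, not approximate, and serialization is
  byte-deterministic.
* **One flat namespace; concentrations canonical.** HMOD is a flat list
  of records, so SBML kinetic-law local parameters are hoisted to global
  parameters named `<reactionId>__<localId>` on read. Species quantities
  are concentrations; `initialAmount` input is divided by compartment
  size. Fixtures use size 1.0 so substance/concentration ambiguity never
  enters the tests; with other sizes, kinetic laws are interpreted as
  concentration rates and fluxes are divided by the species'
  compartment size.
* **Warn-and-drop for unsupported SBML.** Events, constraints and
  function definitions produce `UNSUPPORTED_DROPPED` warnings rather
  than failures, since database models often carry constructs irrelevant
  to the hybrid pipeline. The loss is visible in the report.
* **Input scaling travels with the model.** Min-max bounds are inlined
  as literals in the `annX` rules ((x − min)/(max − min), both bounds as
  literals so both are exactly recoverable), keeping the SBML
  self-contained; the weight/bias parameter count of a compiled
  $n_0$-…-$n_L$ network is exactly $\sum_\ell n_\ell (n_{\ell-1} + 1)$.
  Node-value holder parameters additionally exist because SBML requires
  assignment targets to be declared; they are tagged `ml-scaling` and
  are not part of the trainable-constant count.
* **Collision policy.** If a generated id collides with an existing one,
  the whole generated family gets the first free deterministic suffix
  `_h1`, `_h2`, …, so repeated hybridization of already-hybrid models
  stays reproducible.
* **De-hybridizing foreign documents.** A hybrid SBML file contains no
  record of the mechanistic law the ANN replaced. When such a document
  is folded back to HMOD, the affected reaction receives the placeholder
  law `0`; re-compiling overwrites it, so SBML → HMOD → SBML is exact.

## Simulation semantics and numerics

Assignment rules are algebraic constraints: they are re-evaluated in
topological order inside the RHS at every integrator call (never
lagged), which is what makes the ANN-in-the-loop hybrid model correct.
Expressions are compiled once to R language objects and evaluated in an
environment updated per call. Integration uses `deSolve::lsoda`
(adaptive, stiff-capable) with defaults `rtol = 1e-8`, `atol = 1e-10` —
two orders below the 1e-8 round-trip equivalence threshold, so solver
slack cannot mask a conversion defect. Boundary and constant species
have zero derivative; a species may be governed by reactions or by a
rate rule, never both (`RULE_CONFLICT`).

Degenerate inputs are handled by validation rather than convention:
empty `apply` elements, unknown MathML operators and unknown infix
functions are errors naming the offender; division by zero follows IEEE
semantics at evaluation time; piecewise without a true branch and no
`otherwise` yields NaN, which the trajectory check rejects.

## What the fixture generator emulates — and what it does not

The toy kinds cover the structural features the converters must
preserve: mass-action chains with a rate rule, a reversible pair with a
conserved total, a Michaelis–Menten pathway with an assignment rule, and
a stiff two-timescale pair (rate constants drawn per seed from
U[0.1, 2], stiff branch U[500, 2000] against U[0.1, 1], states of order
1 — magnitudes typical of textbook enzyme kinetics in arbitrary
units). The rate-mimicking generator fits only the linear output layer
over random tanh features (extreme-learning-machine style, minimum-norm
least squares via truncated SVD) on 200 states sampled from the box a
mechanistic trajectory visits, padded 5%; with 20 hidden units it
reaches maximum fit errors around $10^{-7}$–$10^{-3}$ depending on
seed, and the recorded `fit_error` is carried in the spec's metadata.

Passing tests therefore demonstrate *format and compilation
correctness*: that conversion and ANN compilation preserve dynamics to
tight tolerances on models whose structure spans the supported feature
set. They do not demonstrate biological realism — parameterizations are
random, not fitted to data — nor training quality of real hybrid
models, since training is explicitly outside this package (weights
arrive trained).

For the hybrid-vs-mechanistic comparison, a pointwise rate error
$\varepsilon$ does not by itself bound the state error; the comparison
uses the first-order error-growth bound $\varepsilon \cdot t_{end}$,
which is conservative for these dissipative toys (observed trajectory
errors sit one to two orders below it).

## Problem sizes

The default verification runs use 52 seeded fixture models × 3
simulations on 100-point grids for round-trip fidelity, 20 network/model
pairs × 100 random states for compilation equivalence, and a single
1-20-1 network for the hybrid simulation check — sizes chosen so the
whole suite re-runs in well under a minute while every structural
feature combination appears at least a dozen times.

## Known limitations

* SBML packages (comp, fbc, layout), events, algebraic rules, delays and
  RDF annotations are out of scope; model-level notes are the only
  annotation carried through.
* Activations beyond tanh/linear (e.g. ReLU via piecewise) are a
  documented extension point, not implemented.
* Recurrent or convolutional networks are rejected: the container and
  the compiler handle feedforward dense layers only.
* No independent SBML library is consulted at test time; the
  "independent reader path" check is limited to this package's own
  structural validator plus a generic XML parse. Hybrid documents
  produced here follow the L3V2 core schema by construction, but
  cross-simulator verification is left to the user's toolchain.
* The HMOD grammar defined in `HMOD-SPEC.md` is normative for this
  package only; other HMOD dialects may differ lexically.
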