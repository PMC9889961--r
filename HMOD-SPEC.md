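# HMOD/1 — text format for mechanistic and hybrid kinetic models

This document is the normative grammar for the HMOD dialect read and
written by the `hybkit` package. HMOD is a line-oriented, pure-ASCII
format that aggregates a kinetic model's properties (compartments,
species, parameters, reactions, rate rules, assignment rules) with an
optional machine-learning block describing a feedforward ANN whose
outputs drive reaction rates or parameters.

## Lexical rules

* Pure ASCII. Any byte above 127 is an error (`NON_ASCII`).
* `#` starts a comment running to end of line; comments and blank lines
  are ignored (and not preserved by the canonical serializer).
* Numbers use decimal or scientific notation with a period decimal
  separator (`1`, `0.5`, `1.25e-3`). No locale handling.
* Identifiers match `[A-Za-z_][A-Za-z0-9_]*`.

## Document structure

```
HMOD/1
model : id=<identifier>, name=<free text>
[COMPARTMENTS]
<records>
[SPECIES]
<records>
[PARAMETERS]
<records>
[REACTIONS]
<records>
[RATE_RULES]
<records>
[ASSIGNMENT_RULES]
<records>
[ML]
<records>
```

* Line 1 (first non-comment line) is the format version, `HMOD/<major>`.
  Unknown majors are rejected (`BAD_HEADER`).
* The `model` line is required and precedes all blocks.
* Block headers are bracketed uppercase keywords. Blocks appear at most
  once each and in exactly the order above (`ORDER_VIOLATION`
  otherwise); empty blocks may be omitted entirely. The fixed order
  makes definition-before-use checkable in one pass: every identifier a
  record references must be defined in an earlier block (or earlier in
  the expression-free blocks).
* A document without an `[ML]` block is a pure mechanistic model; with
  one, a hybrid model.

## Records

One record per line: `id : field=value, field=value, ...`. A single
space surrounds `:` and follows each `,` in canonical form; the parser
accepts any amount of blank padding. Field values run to the next
`, field=` separator, so commas inside expressions are safe (expressions
never contain `=`). Numeric output uses the shortest decimal that
round-trips the IEEE double (at most 17 significant digits).

Per block (fields in canonical order; `name`/`origin`/`factor` optional
on input, always written on output where applicable):

| Block | Record |
|---|---|
| `[COMPARTMENTS]` | `id : size=<num>, constant=<true\|false>, name=<text>` |
| `[SPECIES]` | `id : compartment=<id>, init=<num>, boundary=<bool>, constant=<bool>, name=<text>` |
| `[PARAMETERS]` | `id : value=<num>, constant=<bool>, origin=<mechanistic\|ml-weight\|ml-bias\|ml-scaling>` |
| `[REACTIONS]` | `id : reversible=<bool>, reactants=<sp:stoich ...\|none>, products=<...\|none>, law=<infix>` |
| `[RATE_RULES]` | `variable : expr=<infix>` |
| `[ASSIGNMENT_RULES]` | `variable : expr=<infix>` |

Assignment rules are serialized in topological evaluation order; their
file order is their evaluation order.

Infix expressions use operators `+ - * / ^` (power right-associative,
unary minus binding tighter than `^`), parentheses, and the function set
`pow, exp, ln, log10, sqrt, tanh, abs, min, max, piecewise` plus the
relational functions `lt, leq, gt, geq, eq, neq` used inside
`piecewise` conditions.

## The `[ML]` block

Describes one feedforward ANN. Records, in canonical order:

```
input_<i>  : id=<model symbol>, min=<num>, max=<num>
layer_<l>  : size=<int>, activation=<tanh|linear>
w_<l>_<r>  : values=<num> <num> ...   # row r of layer l's weight matrix
b_<l>      : values=<num> ...         # bias vector of layer l
output_<k> : target=reaction:<id>|parameter:<id>[, factor=<infix>]
```

* Inputs are min-max scaled to [0,1] with the stored bounds
  (`max > min`).
* Weight row `w_<l>_<r>` has one value per node of the previous layer
  (layer 0 = the inputs); layer `l` has `size` rows and a bias of
  `size` values (`ANN_SHAPE_MISMATCH` otherwise).
* The number of `output_<k>` records equals the size of the last layer.
* `factor` is an optional mechanistic multiplicative factor retained in
  the rewired rate (e.g. a biomass concentration), so rates of the form
  rho(x)·X stay expressible.

The standalone ANN weight container (`.annw`) is this same record
grammar with an `ANNW/1` header and no other blocks.

## Hybrid models and placeholder laws

When a hybrid SBML document (containing the compiled `annX_/annH_/annY_`
assignment rules and `annW_/annB_` parameters) is converted to HMOD, the
compiled network is folded back into the `[ML]` block. The original
mechanistic law of an ANN-driven reaction is not recoverable from such a
document — it was replaced by the output symbol — so the reaction is
written with the placeholder law `0`. Converting the HMOD back to SBML
re-compiles the network and overwrites the placeholder, making the
SBML -> HMOD -> SBML round trip exact.

## Error codes

`NON_ASCII`, `BAD_HEADER`, `UNKNOWN_BLOCK`, `ORDER_VIOLATION`,
`BAD_RECORD`, `BAD_IDENTIFIER`, `BAD_NUMBER`, `MISSING_FIELD`,
`DUPLICATE_ID`, `DANGLING_REF`, `BAD_EXPRESSION`, `ANN_SHAPE_MISMATCH`,
`UNSUPPORTED_ACTIVATION`, plus the model-consistency codes
(`ASSIGNMENT_CYCLE`, `RULE_CONFLICT`, `NEGATIVE_SIZE`,
`NEGATIVE_CONCENTRATION`, `BAD_STOICHIOMETRY`, `DUPLICATE_RULE`).
Validator locations are `block:line` (line within the file) for
syntactic findings and the offending identifier for semantic ones.
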