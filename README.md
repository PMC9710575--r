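# sbml2ode: exact symbolic ODE systems from SBML reaction networks

Most SBML tooling targets numerical simulation. Symbolic computation —
multistationarity analysis, Hopf-bifurcation detection, toricity and
steady-state-variety methods from chemical reaction network theory (CRNT) —
needs something different: exact rational numbers instead of floats,
mathematical variable names instead of free-form SBML identifiers, explicit
ODEs and algebraic constraints instead of rate expressions buried in XML,
and structural indices (deficiency, conservation laws) that SBML only
carries implicitly. `sbml2ode` is an R package for that audience: it
converts an SBML Level 2/3 reaction-network model into a fully explicit,
exact symbolic dataset ready for a computer-algebra system.

For a network with species concentrations `x = (x1, ..., xn)` and
parameters `k = (k1, ..., km)`, the package computes:

* the ODE system `dx_i/dt = f_i(x, k, t)` with `f_i = sum_j S[i,j] * v_j(x, k)`,
  where `v_j` is reaction `j`'s kinetic law rewritten in canonical names and
  divided by the compartment size (concentration semantics);
* the stoichiometric matrix `S` (net change) and kinetic-order matrix `K`
  (reactant-side coefficients) as exact rational matrices;
* a primitive-integer basis of the left kernel of `S` restricted to dynamic
  species — the linear conservation laws `y' x = const`, with exact totals
  when initial values are known;
* the CRNT deficiency `delta = c - l - s` (complexes minus linkage classes
  minus rank), computed exactly;
* a classification of the vector field (polynomial / rational / other) and
  a conservative mass-action test: a reaction passes iff its law differs
  from `const * prod_i x_i^K[i,j]` only by a factor free of species and time;
* a bijective name map between canonical (`x1..xn`, `k1..km`) and original
  SBML names, and exports in Maple, Reduce, SageMath and LaTeX syntax plus
  a JSON manifest.

Every numeric literal is converted from its *decimal text* to an exact
rational (`"0.1"` becomes `1/10`, not the nearest double), all linear
algebra runs over the rationals (fraction-free Bareiss elimination), and no
floating-point number ever appears in an export.

Models using SBML events, parameter rate rules, algebraic rules, or
provably irrational constants (`exp(1)`, `pi`, non-perfect roots) are
outside the supported feature set and are rejected with a machine-readable
violation report. Recognized features include boundary-condition species,
local parameters, assignment rules, initial assignments, species rate
rules and function definitions.

## Worked example

The package ships canonical toy networks. `bind` is reversible
bimolecular binding A + B ⇌ C with mass-action kinetics
(`kon = 4`, `koff = 1/4`, initial concentrations 1, 2, 0):

```r
library(sbml2ode)
ds <- sbml_to_ode(named_toys()$bind$sbml, source_name = "bind")
summary(ds)
```

```
ode_dataset 'toy_bind': 3 species, 1 reactions, 3 parameters
  deficiency 0 (c = 2, l = 1, s = 1); 2 conservation law(s)
  vector field: polynomial; mass-action: TRUE; autonomous
equations:
  dx1/dt = -(k1*x1*x2 - k2*x3)
  dx2/dt = -(k1*x1*x2 - k2*x3)
  dx3/dt = k1*x1*x2 - k2*x3
constraints:
  x2 + x3 = 2   [conservation]
  x1 + x3 = 1   [conservation]
parameter values:
  k1 = 4
  k2 = 1/4
  k3 = 1
```

Reading the output: species were renamed `A, B, C -> x1, x2, x3` and
parameters `kon, koff, cell -> k1, k2, k3` (the compartment size is a
parameter like any other; the map is in `ds$name_map`). The network has two
complexes (`A+B` and `C`) in one linkage class and stoichiometric rank 1,
so its deficiency is `2 - 1 - 1 = 0`. The left kernel of `S` is spanned by
the two totals `x2 + x3` and `x1 + x3`, whose conserved values `2` and `1`
are exact rationals computed from the initial concentrations. The single
kinetic law divided by `x1*x2` (the reactant-order monomial) leaves the
constant `k1`, so the model is flagged mass-action.

Exports follow the same dataset:

```r
cat(render_dataset(ds, "maple")$text)   # Maple; also "reduce", "sagemath", "latex"
```

which renders, e.g., `f_x3 := k1*x1*x2 - k2*x3:` and `k2 := 1/4:` — always
quotients, never decimals. From a shell, the same pipeline runs as

```sh
Rscript inst/cli/sbml2ode convert model.xml --out out/ --format all
```

writing one file per dialect plus `model.manifest.json` (exit 0), or a
`model.rejection.json` naming each unsupported feature (exit 2).

## Generating test networks

`generate_fixture(fixture_spec(...))` builds seeded random SBML models with
mass-action and/or Michaelis–Menten kinetics whose ground truth
(stoichiometry, kinetics labels, deficiency, conservation-law count) is
known by construction, and `named_toys()` returns the five hand-checked
networks used throughout the test suite.

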