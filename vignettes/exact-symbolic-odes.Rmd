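---
title: "Exact symbolic ODE systems from SBML: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact symbolic ODE systems from SBML: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbml2ode)
```

## The problem

SBML stores reaction networks for simulation: kinetic laws as MathML,
values as IEEE doubles, entities under free-form identifiers, and dynamics
only implicitly. Symbolic methods from chemical reaction network theory —
deficiency-based results, conservation-law reduction, toricity and
multistationarity analysis — need the same model as a formal object: an
explicit polynomial or rational ODE system over exact rationals with
canonical variable names. The distance between those two representations is
larger than it looks; this vignette records how `sbml2ode` crosses it and
which design decisions were genuinely open.

## Exact arithmetic

All numbers in a converted dataset are rationals `p/q` in lowest terms,
held as arbitrary-precision integers (base-2^24 limbs; schoolbook
algorithms — reaction-network matrices are tiny, so asymptotics are
irrelevant but exactness is not).

Two conversion routes exist and they are *not* equivalent:

* **Lexical-first** (`literal_to_rational`): the decimal text of an XML
  attribute or `<cn>` element is converted directly, so `"0.1"` means
  `1/10`. This is the route every SBML-sourced number takes, because a
  modeler who wrote `0.1` meant one tenth, not
  `3602879701896397/36028797018963968`.
* **Binary fallback** (`double_to_rational`): an IEEE double, when that is
  all that exists, converts to the dyadic rational it represents exactly.

Irrationality detection is conservative by construction: any transcendental
head (`exp`, `ln`, `sin`, `cos`, `pi`, `e`) applied to anything but its
trivial identity argument flags the value irrational, as does `p^(a/b)`
unless `p` is a perfect `b`-th power (checked exactly). A value that merely
*might* be irrational is rejected; false rejections are safe for a
symbolic-computation consumer, false acceptances are not. Models carrying
such constants are refused at the gate, alongside events, parameter rate
rules, algebraic rules, SBML constraint elements, non-constant compartments
and unsupported MathML constructs (`piecewise`, delays). Feature gating is
all-at-once: the support report enumerates every violation rather than
stopping at the first.

## From document to ODE system

The pipeline is: parse → gate → inline function definitions → lift local
parameters → substitute non-constant parameter assignment rules → build the
network → rename → assemble.

* **Function definitions** are inlined by simultaneous substitution of the
  formal arguments (the expression language has no other binders, so this
  is capture-avoiding); recursive definition cycles are an error.
* **Local parameters** become fresh globals named `<reaction>_<id>`, with
  SBML shadowing semantics: a local `k` wins over a global `k` inside its
  own kinetic law only. The operation is idempotent.
* **Parameter assignment rules** that reference species or time define
  derived quantities, not constants; their right-hand sides are substituted
  into every expression (dependency-ordered, cycles are errors) and the
  parameter disappears from the dataset. Constant assignment rules are
  evaluated exactly and kept as values.
* **Canonical naming**: species become `x1..xn` in document order;
  parameters become `k1..km` — globals in document order, then compartment
  sizes, then lifted locals in reaction order. Naming is fully
  deterministic, so identical inputs give byte-identical outputs.

The right-hand side of a reaction-driven species is
`f_i = (1/c_i) * sum_j S[i,j] v_j` where `c_i` is the species' compartment
size. The division converts SBML's substance/time rate convention to
concentration dynamics. Whether a converter should divide is genuinely
underdetermined by the format; dividing is our documented default, the
exact rational size makes unit compartments a syntactic no-op, and
`divide_by_compartment = FALSE` restores amount semantics
(amount-based species — `hasOnlySubstanceUnits` — are never divided).

Species sort into exactly one of four regimes: reaction-driven (the sum
above), boundary/constant (`f_i = 0`; their rows stay in `S`, which remains
a purely structural object), rate-ruled (`f_i` is the rule expression;
a `time` symbol makes the system non-autonomous), or assignment-ruled
(no ODE at all — the definition is substituted into every law so the
equations close over true state variables, and the species survives as the
formal constraint `x_i = g(x, k, t)`). Consequently the equation list
covers exactly the non-assignment species; every species has an ODE or a
constraint, never both, never neither.

Value resolution follows SBML precedence exactly — initial assignment over
assignment rule over declared attribute — evaluated in dependency order
over the rationals; initial amounts are divided by compartment size.

## Conservation laws

Conservation laws are the left kernel of `S` restricted to *dynamic*
species: boundary, assignment-ruled and rate-ruled rows are excluded, since
a law must be constant along trajectories of the assembled ODEs and those
rows' dynamics are not stoichiometric flows (a boundary species' constancy
is not a conservation law). The kernel is computed by exact Gauss–Jordan
elimination; each basis vector is scaled to coprime integers with positive
leading coefficient, giving a canonical, diff-stable output. When a vector
has mixed signs, a small set of pairwise integer combinations is tried to
find a nonnegative representative; this is best-effort only — a guaranteed
nonnegative basis is an extreme-ray computation and out of scope. Totals
are exact dot products with the initial values when all are known,
otherwise fresh symbolic constants `c1, c2, ...`.

Correct-by-construction cross-checks: a returned basis is valid iff each
vector annihilates `S_dyn` exactly, the vectors are independent, and their
count equals `n_dyn - rank(S_dyn)`; together these force span equality with
any reference kernel, which is what the test suite asserts.

## Deficiency

Complexes are the distinct reactant- and product-side compositions,
compared as exact multisets — `2A` and `A` are different complexes even
though their reaction vectors are parallel, and the empty composition is
the zero complex of inflow/outflow reactions. Linkage classes are connected
components of the undirected complex graph; the rank is the exact rank of
`S` by fraction-free (Bareiss) elimination, which avoids intermediate
fraction blow-up while staying over the integers. Then
`deficiency = c - l - s`, asserted nonnegative.

A reversible SBML reaction contributes one matrix column (the forward
direction as written, since reversible kinetic laws encode net rates) plus
the reverse arrow in the complex graph. The choice of one column versus two
is immaterial for the deficiency — the reverse arrow connects already
connected complexes and the column spans coincide — and the test suite
checks this invariance explicitly.

## Classification

Each right-hand side is classified against the state variables (and time):
*polynomial* if it is a polynomial in them with coefficients that are
rational expressions in the parameters (so dividing by a parameter-only
expression is harmless), *rational* if a denominator involves state, and
*other* as soon as any transcendental head appears. The conservative
direction is "other".

The mass-action test asks whether a law differs from regular mass-action
kinetics only by a constant factor: the quotient
`v_j / prod_i x_i^K[i,j]` must be free of species and time, where
"constant" deliberately admits parameters, compartment sizes and rationals.
The check is structural (generalized-monomial decomposition over products,
quotients, powers and negation); anything that fails to decompose counts as
not mass-action. Two refinements: a *reversible* reaction whose law is a
net rate passes when it splits as a forward monomial matching the reactant
orders minus a reverse monomial matching the product orders (without this,
every reversible mass-action model would be mislabeled); and the
model-level flag additionally requires the vector field to be polynomial,
which is the regime where the mass-action notion is meaningful and keeps
`mass_action ⇒ polynomial` an invariant.

## Exports and round-trip

Maple, Reduce, SageMath and LaTeX renderings contain the variable list,
right-hand sides, exact parameter and initial values, constraints, both
matrices, the deficiency report, classification flags and the name map as
comments. Rationals render as quotients; by construction no decimal point
can appear in a code line, and the test suite greps for exactly that. The
JSON manifest mirrors the full dataset (schema in
`inst/extdata/manifest-schema.json`). The SageMath dialect doubles as a
verification format: `parse_sagemath_export` reads it back with a small
exact-integer expression parser, and equality with the original system is
decided on the rational-function field (cross-multiplied polynomial normal
forms), not by string comparison.

## The fixture generator

`generate_fixture` emulates the document shapes the converter must face:
random small networks (defaults in the tests: 2–7 species, 1–6 reactions)
with mass-action laws `k * prod x^a` written from the generator's own
stoichiometric choices, optional reversible net-rate laws, Michaelis–Menten
laws `V*x/(K+x)`, boundary species, an assignment-rule species and a
parameter initial assignment. Rate constants and initial concentrations are
drawn as small rationals with finite decimal expansions, so the document's
lexical values are exactly the intended numbers and exactness assertions
are meaningful. Stoichiometry and kinetics labels in the manifest are true
by construction; deficiency and conservation counts come from a separate,
deliberately simple code path (string-keyed complexes, union-find,
fraction-free integer elimination in doubles — exact at these sizes), so
pipeline tests never check the code against itself.

What the generator does *not* emulate: curated-database scale (hundreds of
species), deeply nested function definitions, unit systems, annotation
layers, multi-compartment transport with differing sizes, and kinetic-law
idioms beyond mass-action and Michaelis–Menten. Passing its suites
therefore demonstrates correctness of the conversion semantics on networks
whose structure is representative but small; it does not certify
performance or feature coverage on arbitrary curated models.

## Numerical and procedural choices

* Problem sizes in the checked suites: 200 random networks for the
  deficiency oracle, 100 for conservation properties, 50 × 10 evaluation
  points for faithfulness (observed agreement ~1e-16 against a 1e-9 bound,
  the slack covering rounding in the floating oracle itself), 100 labeled
  fixtures for classification. These sizes make the whole suite run in
  well under a minute while exercising every structural regime the
  generator can produce.
* Ties and determinism: document order resolves all naming; complex keys
  sort species indices; fixture generation isolates and restores the
  caller's RNG state.
* Degenerate inputs: empty reactant sides (zero complex), species on both
  sides of a reaction (net coefficients), duplicate species references
  (coefficients accumulate), reactions with zero net change (a zero column
  and two complexes), missing initial values (symbolic totals), models
  without reactions (zero matrices, deficiency 0).
* Division by zero in constant evaluation, cyclic assignment dependencies,
  recursive function definitions and arity mismatches are hard errors with
  specific messages, not silent repairs.

## Limitations

* SBML Level 1 and the package extensions (comp, fbc, layout) are not
  read; algebraic rules and events are rejected rather than approximated.
* The nonnegativity of conservation-law representatives is best-effort.
* The mass-action heuristic is conservative: laws equivalent to a constant
  multiple of the reactant monomial but written in a form the structural
  decomposition cannot cancel (e.g. factored sums that happen to simplify)
  are labeled not mass-action.
* Irrationality flags are conservative in the same direction: a
  transcendental expression that happens to be rational is still rejected.
* No numerical integration, steady-state solving, flux analysis or
  deficiency-theorem conclusions are drawn; the package produces the exact
  symbolic objects such analyses consume.
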