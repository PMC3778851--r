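---
title: "Compiling cell models with exchangeable ODE solving schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling cell models with exchangeable ODE solving schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecgen)
```

## The problem and the two-stage design

A CellML document carries a cell model's mathematics — variables, initial
values, equations — but not the numerical method needed to simulate it.
`tecgen` makes the method a first-class, exchangeable input.  The pipeline
has two stages:

1. **Symbolic expansion.**  A cell model
   $\dot{\mathbf{x}} = \mathbf{f}(\mathbf{x},\mathbf{y},t,\mathbf{z})$,
   $\mathbf{y} = \mathbf{g}(\mathbf{x},\mathbf{y},t,\mathbf{z})$ (state
   $\mathbf{x}$, removable temporal variables $\mathbf{y}$, constants
   $\mathbf{z}$) is woven into an explicit scheme written as ordered, typed
   statements over stage-indexed symbols ($\xi_i$ state copies, $\kappa_i$
   derivative evaluations, $\iota_i$ temporal values, $\tau_i$ stage times,
   $\delta$ the step).  Every statement is scalarized per state variable,
   scheme symbols are replaced by model names with stage suffixes, and the
   bodies of $\mathbf{f}$ and $\mathbf{g}$ are unfolded at each evaluation
   stage.  The result is a *flat program*: an ordered single-assignment
   scalar equation set advancing the state from $t$ to $t+\delta$.
2. **Code generation / interpretation.**  The flat program is either emitted
   as a standalone simulation source (R script or C99) or executed by the
   reference interpreter, in IEEE double or in a decimal floating-point
   context.

Splitting at the flat program keeps both halves simple: the expander never
needs to know about output formats or arithmetic, and the emitters and the
interpreter never see vectors, stages, or MathML — only scalar assignments
in dependency order.  The flat program is also the natural place to audit
what will be computed (`emit_equation_listing()`) and to *measure* the
generated code: one assignment is one execution step, and
`count_steps()` reports 11 / 16 / 26 for the FitzHugh-Nagumo model under
Euler / Heun / classical RK4.

## Statement algebra and the pinned counting conventions

A scheme is an ordered list of statements of seven kinds: the input binding
$\xi_0 = \xi^t$, the time binding $\tau_0 = t$, per-stage `arith-eval`
($\iota_i$, one assignment per temporal equation) and `deriv-eval`
($\kappa_{i+1}$, one per state variable), explicit `stage-update` and
`time-update` formulas, and one output binding
$\xi^{t+\delta} = \xi_{N_\xi}$ (optionally carrying an explicit combine
formula).  Validation enforces definition-before-use over the stage-indexed
symbols, which is exactly explicitness: an implicit scheme (a derivative
evaluation depending on a same-stage state update) cannot be ordered and is
rejected.  Implicit, multistep and adaptive methods, and simultaneous
differential-algebraic systems, are out of scope; a dependency cycle among
temporal equations is reported as an unsupported simultaneous system.

The literature counts "execution steps" of generated simulation codes
without stating a convention, so the shipped schemes pin one, chosen so the
familiar per-model counts come out self-consistently across schemes:

* `euler` carries its time update as a counted statement (FHN: 11);
* `modified_euler` keeps the final corrector and the output bindings as
  separate statements, matching the fully written 16-equation Heun
  expansion of the FHN model (FHN: 16);
* `rk4` folds its final combine
  $\xi^{t+\delta} = \xi_0 + \tfrac{\delta}{6}(\kappa_1 + 2\kappa_2 +
  2\kappa_3 + \kappa_4)$ into the output bindings (FHN: 26).

These conventions are *data* — they live in the scheme encodings, not in the
expander — so a user scheme with different bookkeeping simply produces its
own count.  Temporal variables are recomputed at every stage that evaluates
$\Gamma$ (for FHN, $r$ appears at stage 0 and stage 1); no caching across
stages is attempted, and no simplification, constant folding or common
subexpression elimination is applied to unfolded bodies, because any of
those would silently change both the audit listing and the step counts.

## Scalar naming and determinism

Generated scalars follow a fixed grammar — `x_in`/`x_out` bindings, `x_2`
stage copies, `kappa1_x` derivative evaluations, `delta` — so emission is
byte-stable and programs are diffable across runs.  Expansion is fully
deterministic: ties everywhere are broken by document order.  A generated
name colliding with a model constant is a hard error rather than a silent
rename.  Comparisons against hand-written expansions use
`alpha_equivalent()`, which checks assignment-by-assignment structural
equality under a single bijective renaming, with numeric literals compared
by value.

## Arithmetic: why a decimal context, and its limits

Accuracy studies that push fourth-order schemes to small steps quickly fall
below double-precision round-off.  The interpreter therefore supports a
decimal floating-point context of 1–50 significant digits (default 32 in
the study driver): every operation rounds its exact result half-even to the
context, numeric literals travel as decimal strings from the XML all the way
into the context (no binary-float detour), and division/domain errors are
raised, never silently turned into `NaN`.  Two consequences matter for
testing: closed forms evaluated *in the same context* are exact (Euler on
$dx/dt=-x$ gives exactly $(1-\delta)^n$; one step of any shipped scheme on
$dx/dt=\lambda x$ gives exactly its stability polynomial), and RK4 error
curves keep falling as $\delta^4$ where a double context would plateau.

The context is implemented in `src/decimal.cpp` as sign/coefficient/exponent
with base-$10^9$ limbs in fixed-size arrays (hence the 50-digit cap — no
heap allocation inside the time loop).  Elementary functions (`exp`, `ln`,
`sqrt`, powers) use argument reduction plus series/Newton iteration with 8–10
guard digits and are accurate to 1 ulp, not correctly rounded; the four
basic operations are exactly rounded (they were cross-validated against an
independent arbitrary-precision decimal implementation on tens of thousands
of random cases during development, and the shipped tests pin exact
reference digits).  One subtlety worth recording: numeric inputs coming from
R doubles are converted by *shortest round-trip* spelling, so `1e-5` enters
the context as exactly `0.00001` and not as the 17-digit expansion of its
binary approximation — with fixed 17-digit formatting, the reference run of
the convergence study integrates with a relatively perturbed time step and
every comparison inherits a spurious ~1e-16 error floor.

Emitted standalone sources are double precision only; requesting a decimal
context with an emission target is an error rather than a silent downgrade,
since a standalone script cannot carry the context implementation with it.

## The convergence study

`convergence_study()` runs one high-accuracy reference (default: RK4 at
$\delta = 10^{-5}$, one decade below the smallest candidate) and one
candidate run per (scheme, $\delta$), samples all state variables on a
shared grid (every `max(deltas)` time units), and computes
$\mathrm{RMSE} = \sqrt{\mathrm{mean}(x_\mathrm{cand}-x_\mathrm{ref})^2}$
with the deviations formed in exact decimal arithmetic, so error levels far
below double epsilon remain measurable.  Per scheme, the empirical order is
the least-squares slope of $\log_{10}\mathrm{RMSE}$ vs $\log_{10}\delta$.

Entries are excluded from the fit and flagged when the run diverged or when
the RMSE falls below the *precision floor*
$10 \cdot 10^{-d} \cdot \mathrm{scale}$, where $d$ is the context's digit
count (15 for double, the standard `DBL_DIG` decimal equivalent) and
`scale` is the root-mean-square magnitude of the reference trajectory.
This formalizes the plateau a finite-precision context imposes on
high-order schemes at small steps; in the default 32-digit study the floor
sits near $10^{-31}$ and never activates, which is the point of running the
study in decimal.

Defaults are desk-scale by design: FHN over a horizon of 20 model-time
units, candidates $\delta \in \{10^{-1},\dots,10^{-4}\}$, reference RK4 at
$10^{-5}$ — about 2 million reference steps, roughly half a minute of
compute — with the wider grids available through the `deltas`, `ref` and
`horizon` arguments.  With these settings the fitted FHN orders come out at
$\approx 1.00$, $2.01$ and $4.02$ for Euler, Heun and RK4, and the error
ranking Euler > Heun > RK4 holds at every common step size.  Absolute RMSE
values are *not* portable claims: they depend on the stimulus, the horizon,
the sampled variables and the RMSE definition, none of which are
standardized; only orders and rankings are treated as reproducible.

## Parameters of the shipped FitzHugh-Nagumo fixture

The FHN document encodes $r = x^3$, $\dot{x} = x - r/3.0 - y + a$,
$\dot{y} = b(x + c - d\,y)$.  Parameter values are the package's choice of
the classical FitzHugh parameterization mapped onto this form — $b = 0.08$,
$c = 0.7$, $d = 0.8$, applied current $a = 0.5$, $x(0) = -1.2$,
$y(0) = -0.6$ — which puts the model on its stable limit cycle (a relaxation
oscillation, the action-potential-like regime).  Every structural result
(step counts, expansion shape, alpha-equivalence) is independent of these
values; the convergence study depends on them only through the smoothness of
the trajectory, and its order/ranking conclusions are robust to any
non-degenerate choice.

## What the random-model generator does and does not emulate

`random_model()` draws synthetic models from the supported expression subset
with bounded depth: every state variable gets a rate equation referencing at
least one state variable; temporal variables form a dependency DAG whose
defining equations are emitted in shuffled document order (so consumers must
dependency-sort, exercising `order_arith()`); denominators are generated as
$1 + (\cdot)^2$ so oracle evaluations never hit a singularity.  Alongside
each expression tree the generator writes an independent plain-R source
string, built during generation rather than converted afterwards; the test
oracles evaluate those strings with base R, giving a second route that
shares no code with the package's evaluator.

Passing the property tests on these models demonstrates correctness of the
symbolic pipeline (parse, classify, order, expand, interpret, emit) over the
supported construct space.  It does not demonstrate robustness to what real
repository-scale cardiac models add: hundreds of equations, stiff kinetics,
piecewise-defined stimuli with discontinuities (supported by the expression
layer but excluded from the generator because discontinuities break
convergence-order measurement), unit conversion, or multi-component
documents with deep import hierarchies.  Units are recorded as free text and
never checked.

## Numerical and design choices, in brief

* Single-term left-hand sides only; each variable or derivative defined at
  most once; one independent (time) variable per model.
* Role maps can be read from RelML or inferred mechanically from equation
  shape (`infer_roles()`); when both are available a mismatch is an error,
  never a silent override.  Exact name matching — no aliasing.
* The time loop advances $t$ by repeated addition of $\delta$ in the active
  context; emitted sources do the same, keeping double-mode emitted
  trajectories bit-identical to the interpreter's.
* Trajectories are declared divergent at the first non-finite value (double)
  or at a decimal exponent overflow guard of $10^{5}$; sampling stops there
  and the step index is reported.
* The window must span a whole number of steps; sampling grids align by
  index, not by floating-point time comparison.

## Known limitations

CellML 2.0, units semantics, reactions, metadata and remote imports are not
supported.  Implicit/adaptive/multistep methods and DAE systems are rejected
at validation.  Emitted C/R sources are single-cell: spatial coupling of
cell arrays would require physiology (gap-junction terms) this package does
not invent.  The decimal context caps at 50 significant digits, and its
elementary functions are 1-ulp, not correctly rounded.
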