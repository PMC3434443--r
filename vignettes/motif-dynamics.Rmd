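---
title: "Boolean statechart models of gene regulatory network motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean statechart models of gene regulatory network motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifchart)
```

## The model

Gene regulatory networks are built from a handful of recurring interaction
patterns — *motifs*: simple regulation, reciprocal (feedback) regulation,
feedforward loops, and autoregulation. `motifchart` gives each motif an
executable semantics in a deliberately small statechart fragment:

* the system is one **parallel composition** of components, each a
  **two-state machine** with states "off" (0, gene not expressed / molecule
  absent or inactive) and "on" (1, expressed / present and active);
* a *regulated* component carries two transitions, off→on and on→off, each
  **guarded by a boolean formula** over the presence/absence of the model's
  components (written `X` for presence, `!X` for absence, combined with `&`
  and `|`);
* a component with no transitions is **independent**: its state only changes
  through externally supplied timed events (an *input schedule*) — it is the
  input of the motif;
* time is discrete and the update is **synchronous**: the state of every
  regulated component at instant *t + 1* is determined by the full
  configuration at instant *t*, all components updating simultaneously.

Nothing beyond this fragment is representable: no events or actions on
transitions, no history states, no hierarchy deeper than the single parallel
level. That restriction is what makes the semantics unambiguous — the model
is exactly a synchronous boolean network presented as a statechart, and
every analysis in the package (simulation, attractor enumeration, property
checks) is exact.

### The guard pair and the off-guard convention

A regulated component could in principle carry any two guards. The package's
canonical constructor, `rule_from_next_state(f)`, derives both from a single
boolean *next-state function* `f`: the off→on guard is `f`, the on→off guard
is `!f`. This makes the pair **mutually exclusive and jointly exhaustive**
by construction, so the component is a total deterministic function of the
previous configuration — behaviour is defined in every situation, including
when the regulator is absent. `make_model()` validates exclusivity and
exhaustiveness by exhaustive evaluation over the guards' variables and
reports a witness assignment on violation.

An escape hatch, `make_model(..., allow_partial = TRUE)`, admits guard pairs
that leave a gap; on uncovered assignments the component *holds* its state.
Overlapping guards are rejected outright in either mode — a configuration
where both transitions fire would be silent nondeterminism, and no runtime
tie-break could be justified. No catalogue motif uses partial rules.

## The motif catalogue

All builders use the canonical names `X`, `Y`, `Z` for genes and `S_X`,
`S_Y` for the signals mediating X's and Y's action; `X` and the signals are
independent. An active regulator is the conjunction *gene & signal*: a gene
whose signal is absent cannot act. The catalogue is presence-mediated;
absence-mediated variants are obtained generically by negating the signal
literal in a hand-built model.

| builder | components | regulation |
|---|---|---|
| `build_simple_regulation("s1".."s4")` | X, S_X, Y | `next(Y)` = `X & S_X` (s1), `!(X & !S_X)` (s2), `!(X & S_X)` (s3), `X & !S_X` (s4) |
| `build_feedback("double_positive")` | X, S_X, Y, S_Y | `next(X) = Y & S_Y`, `next(Y) = X & S_X` |
| `build_feedback("double_negative")` | " | `next(X) = !(Y & S_Y)`, `next(Y) = !(X & S_X)` |
| `build_feedback("negative")` | " | `next(X) = Y & S_Y`, `next(Y) = !(X & S_X)` |
| `build_ffl("c1", gate)` | X, S_X, Y, S_Y, Z | `next(Y) = X & S_X`; `next(Z) = (X & S_X) <gate> (Y & S_Y)` |
| `build_ffl("i1", gate)` | " | as c1 but `next(Z) = (X & S_X) <gate> !(Y & S_Y)` |
| `build_autoregulation(sign)` | Y | `next(Y) = Y` (positive) or `!Y` (negative) |
| `build_autoregulation(sign, with_activator = TRUE)` | X, Y | `next(Y) = X & Y` or `X & !Y` |

Two formula choices deserve a note, because they were genuinely open:

* **s2 and s4.** The defining phrases — "repression of Y in absence of
  S_X", "activation of Y in absence of S_X" — do not pin down a formula by
  themselves. We keep the signal as the mediator of X's action: in s2, Y is
  driven off exactly when X is present while its signal is absent, hence
  `next(Y) = !(X & !S_X)`; s4 is the symmetric activation. This is the only
  reading in which s1–s4 remain four pairwise distinct next-state tables
  (checked exhaustively in the test suite) while X's influence always flows
  through S_X.
* **FFL input branches.** Z's two inputs are the active-regulator terms
  `X & S_X` and `Y & S_Y` (negated as a whole for the repressive branch of
  i1). This is the only composition that reproduces the reference timing
  behaviour of both FFLs (below); gating the signal elsewhere either loses
  the delay or breaks the pulse.
* **Autoregulation with activator.** The two-gene form regulates Y by the
  AND of itself and the independent gene X. Whether X's action is itself
  signal-mediated is not fixed by the motif; the builder defaults to the
  plain `X` and offers `with_signals = TRUE` to insert `X & S_X` for
  symmetry with the rest of the catalogue.

## Timing semantics

Input events "happen at" their instant: `simulate_motif()` first overlays
the events scheduled at instant *t* onto the configuration, records the
overlaid configuration as the state at *t*, and then steps to *t + 1*. With
this convention, switching X on at *t = 2* in the coherent type-1 FFL (AND
gate, signals present, genes initially off) gives the reference
sign-sensitive delay exactly:

```{r c1}
m <- build_ffl("c1", gate = "AND")
tr <- simulate_motif(m, initial_state(m, on = c("S_X", "S_Y")),
                     schedule = input_schedule(2, "X", 1), horizon = 8)
tr
first_on_time(tr, "Y")   # 3
first_on_time(tr, "Z")   # 4: one step after Y -- the delayed activation
```

Deactivation is immediate (Y and Z both off at *t = 3* after X disappears at
*t = 2*), and the incoherent type-1 FFL turns the same input step into a
unit-time pulse of Z at *t = 3*:

```{r i1}
mi <- build_ffl("i1", gate = "AND")
tri <- simulate_motif(mi, initial_state(mi, on = c("S_X", "S_Y")),
                      schedule = input_schedule(2, "X", 1), horizon = 8)
detect_pulses(tri, "Z")
```

The boolean domain can only produce a width-1 pulse — the qualitative shape,
not the quantitative rise and decay. The time origin is a label: `start`
shifts the `t` axis so traces can be printed against any reference diagram;
the schedule shares the same axis, so absolute timings are well defined
regardless of origin.

## Attractors and the property checkers

With at most 2^6 configurations per motif, `enumerate_attractors()` is an
exact brute force: it enumerates every configuration of the unclamped
components (clamping holds chosen independent components — typically the
signals — fixed), follows the deterministic successor map to its fixed
points and cycles, and reports basin sizes. Cycles are canonicalized — the
lexicographically smallest member state (component order, 0 < 1) first, and
attractors sorted by that state — so output is reproducible and diffable.

On top of it sit the checkers:

* `check_bistability()` — the double-positive loop has the two *joint*
  steady states (off, off)/(on, on), the double-negative loop the two
  *exclusive* ones (on, off)/(off, on); in both, the remaining two initial
  states are trapped in a period-2 oscillation that the two-valued domain
  cannot funnel into either steady state, and the report lists them.
* `oscillation_period()` — transient removal by first-revisit detection
  (exact in a finite deterministic system, no burn-in parameter): the
  negative feedback loop yields period 4 from every initial state; a
  settled trace yields 1; a trace too short to revisit yields `NULL`.
* `detect_pulses()` / `first_on_time()` — run-length scans of a trace
  column; runs touching the trace boundary are flagged open-ended rather
  than counted as pulses.

A property worth knowing when composing models: with the AND gate and
signals present, the c1 FFL's update is monotone (componentwise larger
configurations have larger successors), while i1's Z-update is antitone in
Y. Both are checked exhaustively in the test suite.

## Serialization

Models travel as BoolNet-style rule files (`targets, factors` header, one
`name, formula` line per component) — the community convention for boolean
regulatory rules, diffable and consumable by other logical-modeling tools.
The dialect has no notion of an exogenous input, so an independent component
is written as the self-hold rule `X, X` marked by an `# independent: X`
comment, and `# signal:` comments preserve component kinds; a round-trip
therefore restores the exact next-state table, independence pattern and
kinds (property-tested on the whole catalogue and on 100 randomly generated
models under a fixed seed). Statechart structure exports as Graphviz DOT
(one cluster per component, two nodes, guard-labelled edges) or SCXML (one
`<parallel>` region, guards in `cond` attributes); both are write-only —
executing third-party SCXML engines is out of scope.

## What the tests do and do not show

Every quantitative claim in the package — the FFL timings, the attractor
inventories, the round-trips — is recomputed at desk scale: state spaces of
at most 2^6, horizons of 8–16 instants, 100-model round-trip batches. These
sizes are the system's natural scale, not an approximation: the dynamics are
deterministic and finite, so the checks are exact, and there is no sampling
error to manage and no seed anywhere in the simulation semantics.

What the boolean abstraction does *not* capture — and no test should
suggest otherwise — is quantitative dynamics: response acceleration of the
incoherent FFL and of negative autoregulation, damped oscillation,
graded expression levels. Those require more than two values per component
(asynchronous or multi-valued semantics are likewise out of scope; every
reference diagram the package reproduces is synchronous). The motifs here
are building blocks: `make_model()` accepts arbitrary compositions, but
only the catalogue motifs ship pre-built and property-tested.
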