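---
title: "The stressosome automaton: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stressosome automaton: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressosim)
```

## The system

The stressosome of *Bacillus subtilis* is a ~1.8 MDa pseudo-icosahedral
signalling complex built from 40 copies of the stress sensor RsbR and 20
copies of the scaffold RsbS. It sequesters the serine–threonine kinase
RsbT; when environmental stress raises the phosphorylation of RsbR and
subsequently of RsbS, RsbT is released, triggering the partner-switching
cascade that frees the alternative sigma factor σB and turns on the
general stress regulon. The feedback phosphatase RsbX dephosphorylates
RsbS-P and resets the switch.

This package implements a stochastic Boolean cellular automaton of the
phosphorylation layer only: each of the 60 proteins is a node on the
stressosome lattice carrying a single bit (1 = phosphorylated), and each
discrete time step every node attempts one reaction whose probability
depends on the phosphorylation pattern of its three nearest neighbours.
Everything downstream of RsbS phosphorylation (RsbT release, the
RsbU/RsbV/RsbW cascade, reporter-gene expression) is outside the model;
fractional RsbS phosphorylation is used as the proxy for σB output.

## The lattice

The stressosome core is a truncated icosahedron: 60 vertices, each of
degree three, with 12 pentagonal and 20 hexagonal faces.
`build_truncated_icosahedron()` constructs it from the 60 directed edges
of a regular icosahedron — the two orientations of an icosahedron edge
form a *dimer pair* (the homodimer partnership), and the five directed
edges leaving a common vertex are linked into a *contact pentagon* in
cyclic angular order. Each protein therefore has exactly one dimer
neighbour and two contact neighbours; hexagons alternate dimer and
contact edges. The construction is purely combinatorial-geometric and
deterministic, so node numbering is stable across calls. Only the graph
invariants, not the labels, affect the dynamics.

Species are assigned by `assign_species()` under three assembly rules:
the stoichiometry is 40 RsbR : 20 RsbS, dimers are homotypic (whole
dimers are R–R or S–S), and RsbS homodimers never touch, i.e. no contact
edge joins two S nodes.

A point worth recording: these rules do **not** single out one assembly.
Exhaustive search over the 30 dimer pairs finds 36 valid colourings
falling into two families that are not related by any symmetry of the
lattice. They differ in their neighbourhood census — (8, 24, 8) versus
(10, 20, 10) nodes of classes R1/R2/R3 (defined below). In the
(10, 20, 10) family every R2 protein has only R2 proteins as its RsbR
neighbours, so the 24-strong R2 population is kinetically isolated from
R1 and R3; under kinase rules that require a phosphorylated neighbour it
possesses an absorbing all-dephosphorylated trap, and simulations show
the whole subpopulation freezing there — behaviour no stressosome
experiment shows. We therefore take the percolating (8, 24, 8) family,
which is also the generic one (30 of the 36 solutions), and return its
lexicographically first member. `enumerate_colourings()` exposes the full
solution set so the choice can be audited.

Each node's *neighbourhood class* is the species composition of the
triangle formed by its three neighbours: `R1` = central R with
neighbours (R, S, S), `R2` = central R with (S, R, R), `R3` = central R
with (R, R, R), and `S1` for every S (always (S, R, R) in a valid
assembly). The canonical census is R1 = 8, R2 = 24, R3 = 8, S1 = 20,
and the accounting identity 2·R1 + R2 = 40 (each S has two R contacts)
holds in every admissible colouring.

## Reaction rules

Dephosphorylation is neighbour-independent: RsbR-P flips off with
probability `kdpr` per step and RsbS-P with `kdps` (the RsbX activity).
Phosphorylation of an unphosphorylated node occurs with probability
`p_a × kph`, where `kph` is the species' maximum phosphorylation
probability (`kphr` for RsbR — the stress input, 0.1 stress-free and 1
under full stress — and `kphs` for RsbS) and `p_a ∈ [0, 1]` is the
*allosteric parameter* of the node's triangle: how strongly that
neighbourhood's phosphorylation pattern stimulates the local RsbT
kinase. Reference values are `kphr = 0.1/1`, `kdpr = 0.06`,
`kphs = 0.4`, `kdps = 1`.

Neighbour patterns are keyed by a canonical state string: the first
character is the bit of the *solitary* neighbour (the species that
occurs once in the triangle — the R dimer partner for R1, the RsbS
contact for R2, the RsbS dimer partner for S1), followed by the
same-species pair sorted descending; for R3, whose neighbours are all
RsbR, the three bits are pooled. That yields 6 keys each for R1, R2 and
S1 plus 4 for R3 — 22 in total, all stored explicitly; a lookup outside
these 22 raises an error rather than silently defaulting, since it would
signal an impossible neighbourhood.

Two rows are shared by all models. `S1` is active (`p_a = 1`) only in
state `011` — both RsbR contacts phosphorylated, RsbS partner not —
because RsbT is stimulated by phosphorylated RsbR and dissociates from
phosphorylated RsbS. `R3` is a constant 0.7: with no adjacent RsbS there
is no resident RsbT, and the value is the empirical one that lets the
reference data be reproduced. The three hypotheses differ on R1 and R2:

* **no cooperation** — kinase activity is neighbour-independent; all R1
  and R2 entries are 1.
* **substrate activation** — unphosphorylated RsbR stimulates RsbT;
  `p_a` falls as R neighbours become phosphorylated.
* **product activation** — phosphorylated RsbR stimulates RsbT; `p_a`
  rises with phosphorylated R neighbours, and a phosphorylated RsbS
  neighbour of R2 forces 0.

Custom tables (`custom_allosteric_table()`, CSV round-trip via
`write_allosteric_csv()`) express mutant phenotypes such as a
reduced-cooperativity RsbR paralogue; `uniform_allosteric_table(1)`
removes all neighbour dependence, giving independent two-state nodes
with stationary phosphorylation `kph/(kph + kdp)` — the analytic control
used in the tests.

## The update engine

Each step visits all 60 nodes in a fresh uniform random permutation; an
unphosphorylated node flips on with probability `p_a × kph`, a
phosphorylated one flips off with `kdp`, with at most one attempted
transition per node per step. A reaction fires when the uniform draw
falls **below** the probability. The verbal description this model
derives from states the comparison the other way around ("smaller than
the random number"), which would make every reaction fire with
probability 1 − p and contradicts both the parameter table's semantics
and every reported behaviour; we treat it as a typo and document the
choice here rather than hiding it.

Updates are applied in place by default — later nodes in the permutation
see earlier flips. Whether the original implementation froze the state
within a step is not recoverable from its description, so a synchronous
mode is provided behind `sim_config(synchronous = TRUE)`; on the
canonical lattice the two give statistically indistinguishable steady
states (stress-free product-activation RsbR-P 0.477 vs 0.482), so the
choice is immaterial here.

Ensembles repeat the run (default 50 replicates) with independent
initial states, each node initially phosphorylated with probability 0.5
for fast equilibration. Replicate seeds are drawn deterministically from
the master seed, so every result is a pure function of (configuration,
seed); the inner loop is compiled C++ driven by R's RNG stream, and the
exact-enumeration oracles used in the tests are independent pure-R code.

Time is step-based. The step↔minute calibration is not specified by the
model's source; we default to 1 step = 1 minute (`steps_per_min` is
configurable) and use it only to translate scenario definitions such as
"stress off at 5 min". Steady states are averaged over 600 recorded
steps after a 200-step burn-in (time courses equilibrate 200 steps
before recording); with relaxation times of order 1/(kph + kdp) ≈ 6–10
steps these windows are comfortably past transients, and the problem
sizes keep every preset and check fast on a single CPU.

## Scenario presets

* `kim2004_timecourse()` — equilibrate stress-free, raise `kphr` to 1
  for 5 minutes, relax; reproduces the transient rise and decay of
  RsbR-P/RsbS-P seen in salt/ethanol shock immunoblots (Kim *et al.*
  2004).
* `dose_response()` — steady-state RsbS-P across a `kphr` grid; the
  discriminating experiment (Marles-Wright *et al.* 2008 reporter
  dose–responses): only product activation is markedly sigmoidal.
* `volker_rsbx()` — RsbX titration (Völker *et al.* 1997): stress onset
  at 20 min with `kdps` at 1, 0.6, 0.3 of wild type, responses
  normalized to the wild-type maximum. The low-RsbX level is quoted as
  0.3 in one place and 0.1 in another in the reference description; the
  preset defaults to 0.3 and accepts any values, so 0.1 is one keystroke
  away. Setting `param = "kdpr"` runs the control in which RsbR-P
  dephosphorylation is reduced by the same factors (relative to its
  wild-type 0.06) — this leaves the normalized post-stress response at
  the wild-type level, reproducing the negative result.
* `akbar_kphs()` — energy-stress-sensing RsbR paralogues modelled as a
  raised RsbS phosphorylation maximum (`kphs` 0.4 → 0.75 → 0.9),
  increasing both basal and stimulated RsbS-P (Akbar *et al.* 2001).
* `mutant_prestress()` — basal `kphr` shifts for point mutants that move
  the pre-stress output without touching the stress response.

Scenario outputs are pure functions of (scenario, seed); trajectory
tables export to CSV and every CLI run writes a manifest sufficient for
bit-identical reproduction.

## Dose–response analysis

Responses are summarised with the hyperbolic tangent

$$f(x) = \frac{a}{2}\left(\tanh\!\big(b\,(x - c)\big) + 1\right),$$

where $a$ is the maximum response, $c$ the inflection (half-maximal)
point in signal units and $b$ the sigmoidality in inverse signal units.
The printed rendering of this equation in the model's source is garbled;
this form is the unique reconstruction consistent with the stated
meanings of the parameters and with every quoted parameter set
($a = 85$ or 60 Miller units and $a = 0.2$; $b = 0.8$, $6\times10^{-3}$
and 12; $c = 3\%$, 488 mM and 0.14 for ethanol, NaCl and simulated
`kphr` respectively).

`fit_tanh()` minimises the sum of squares with deterministic multi-start
bounded quasi-Newton (`nlminb`): 48 fixed starts spanning the signal
range and four orders of magnitude of steepness, best residual wins,
ties broken by first start, bounds $a, b > 0$ and $c$ inside the signal
range, relative tolerance 1e-12. On noiseless model-generated curves it
recovers parameters to well under 1 %. Flat or decreasing responses are
rejected with an explicit error. Fits are made to replicate-averaged
responses; fitting individual replicates and averaging coefficients gave
no material difference and the averaged curve is what the reference
figures show.

`normalize_curve()` divides the signal by the fitted $c$ and the
response by the fitted $a$, mapping every tanh curve onto
$\tfrac12(\tanh(bc(z-1))+1)$: curves with equal $b\,c$ collapse onto one
normalized curve, which is what makes ethanol, salt and simulated-`kphr`
responses directly comparable, and makes the dimensionless product
$b \cdot c$ the natural sigmoidality index of the normalized plot.
Experimental curves in arbitrary units import from two-column CSV
(`import_experimental_curve()`), so digitized reporter measurements can
be overlaid after normalization.

## What the model reproduces — and one number it does not

With the reference parameterisation the package reproduces: the 22-state
rule structure; the transient stress-pulse dynamics with the
no-cooperation model responding fastest; the dose–response maximum
$a \approx 0.195$ and inflection near `kphr` ≈ 0.14–0.17; the markedly
higher sigmoidality of product activation ($b c$ = 1.21 vs 0.80–0.82
for the other models); the RsbX titration ordering and its `kdpr`
negative control; and the `kphs` monotonicity. The exact-chain oracle
checks on small fixtures confirm the engine realises the specified
Markov dynamics, and the independence limit lands on
$kph/(kph+kdp) = 0.625$.

Two reference numbers are not reached. The stress-free
product-activation RsbR-P equilibrium is reported as 0.6 in the
characterisation this model derives from, but under the printed
parameter tables it is analytically unreachable: RsbR-P of 0.6 at
`kphr = 0.1`, `kdpr = 0.06` requires a mean allosteric activity of 0.9,
while the product-activation table caps the self-consistent mean near
0.76 (R3 alone is pinned at 0.7, equilibrating at 0.538). Our automaton
equilibrates at ≈ 0.48 — in-place, synchronous and
dephosphorylate-then-rephosphorylate step semantics all land within
0.48–0.53 — and we report that value rather than tune toward the quoted
one. Notably, 0.6 *is* the no-cooperation baseline (0.61), and the
reference time-course figure plots all three models together.
Relatedly, the fitted sigmoidality for product activation comes out at
$b \approx 7.3$ against the quoted 12: the simulated curve matches the
quoted tanh below its inflection but saturates more slowly above it, the
same signature of a lower-activity RsbR population. Both discrepancies
are surfaced, not patched; the corresponding checks in the test suite
state the quoted values and are expected to stay red until the source of
the extra activity in the original implementation is identified.

## What the toy fixtures do and do not show

`make_fixture()` builds three small synthetic lattices (a 4-node
triangle, a 6-ring, an 8-node mini-lattice) whose joint dynamics are
small enough for exact verification: the one-step transition matrix is
enumerated over all update permutations and Bernoulli outcomes, and the
empirical distributions from the engine are required to match within
sampling error. These fixtures are not stressosomes — absent neighbour
slots contribute a fixed 0 bit — so they validate the update machinery,
not the biology; the biological claims rest on the canonical 60-node
lattice runs above. Passing oracle tests therefore demonstrate that the
simulator computes the specified stochastic process exactly, while
saying nothing about how well that process describes a real cell.

## Known limitations

Single-site phosphorylation only (no T171 + T205 double phosphorylation,
which matters for extreme stress); no RsbR paralogue identity or
localisation bias; RsbT is implicit in the rules rather than an explicit
species; no downstream cascade or reporter delay, so comparisons with
β-galactosidase time courses inherit a 15–30 min offset; discrete-time
step dynamics rather than continuous-time kinetics; and the step↔minute
calibration is a convention, so figure features that depend on absolute
times are only qualitatively meaningful.
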