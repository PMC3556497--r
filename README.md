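# stressosim

Stochastic Boolean simulation of stressosome activation in *Bacillus
subtilis*.

The stressosome is a ~1.8 MDa icosahedral signalling complex of 40 RsbR
(stress sensor) and 20 RsbS (scaffold) proteins that sequesters the
kinase RsbT and releases it upon environmental stress, activating the
general stress sigma factor σB. `stressosim` models its phosphorylation
dynamics as a cellular automaton on the truncated-icosahedron lattice:
every protein carries one bit (phosphorylated or not) and, each discrete
step, attempts one reaction whose probability depends on its three
lattice neighbours.

Phosphorylation of an unphosphorylated node occurs with probability
`p_a × kph`, where `kph` is the species' maximum phosphorylation
probability (`kphr` = 0.1 stress-free / 1 under stress for RsbR,
`kphs` = 0.4 for RsbS) and `p_a ∈ [0, 1]` is an *allosteric parameter*
read from a 22-state truth table keyed by the neighbourhood class
(R1/R2/R3/S1) and the neighbours' phosphorylation pattern.
Dephosphorylation is neighbour-independent (`kdpr` = 0.06,
`kdps` = 1 — the RsbX phosphatase). Three truth tables encode competing
hypotheses about how RsbR regulates the RsbT kinase: **no cooperation**,
**substrate activation** (unphosphorylated RsbR stimulates RsbT) and
**product activation** (phosphorylated RsbR stimulates RsbT). Simulated
dose–response curves are summarised with the sigmoid

    f(x) = (a/2) (tanh(b (x − c)) + 1)

whose fitted steepness separates the hypotheses: only product activation
produces a markedly sigmoidal stimulus–response curve, the behaviour
seen experimentally.

The package provides the lattice constructor (with exhaustive,
auditable species assignment), the truth tables (plus user-defined
variants), a seeded Monte-Carlo ensemble engine with piecewise-constant
stress schedules, scenario presets reproducing published stress-shock,
phosphatase-titration and kinase-rate experiments, and the tanh
fitting/normalization used to compare models with reporter-gene data.

## Worked example

```r
library(stressosim)

g <- stressosome_graph()
g
#> Stressosome lattice: 60 nodes, 30 dimer + 60 contact edges
#>   species: 40 RsbR / 20 RsbS
#>   classes: R1=8, R2=24, R3=8, S1=20

# stress-free equilibrium of the product-activation model
cfg <- sim_config(model = "product_activation", n_steps = 600,
                  burn_in = 200, seed = 1)
round(steady_state(cfg, g), 3)
#>     R     S
#> 0.477 0.058

# dose-response sweep over the stress input kphr, and the sigmoid fit
dr <- dose_response("product_activation", seq(0, 1, length.out = 21),
                    seed = 2, graph = g)
fit_tanh(dr)
#> Tanh dose-response fit: f(x) = (a/2) (tanh(b (x - c)) + 1)
#>   a = 0.1954 (max response)   b = 7.321 (sigmoidality)   c = 0.1662 (inflection)
#>   residual norm = 0.0452 over 21 points
```

At stress-free `kphr = 0.1` about 48% of RsbR but only ~6% of RsbS is
phosphorylated — the sensor layer idles hot while the output stays off.
Sweeping `kphr` to 1 raises steady-state RsbS-P to a maximum `a ≈ 0.2`,
with half-maximal output at `kphr ≈ c` and switch steepness `b`; fitting
the other two models gives clearly smaller normalized steepness `b·c`
(0.80–0.82 vs 1.21), i.e. quasi-hyperbolic responses.

Time-course presets work the same way:

```r
tc <- kim2004_timecourse("product_activation", seed = 3, n_replicates = 50)
tc
#> Stressosome ensemble (product_activation): 50 replicates, 60 recorded steps
#>   final mean RsbR-P = 0.501, mean RsbS-P = 0.057
plot(tc)   # transient RsbR-P/RsbS-P rise during a 5-min stress pulse
```

A thin command-line front end is included for shell use:

```sh
Rscript inst/cli/stressosim.R graph --out out/
Rscript inst/cli/stressosim.R simulate --scenario kim2004 \
    --model product_activation --seed 1 --out out/
Rscript inst/cli/stressosim.R dose-response --model no_cooperation --out out/
Rscript inst/cli/stressosim.R scenarios-list
```

Every run writes a JSON manifest (resolved configuration, seed, package
version, output inventory) sufficient for bit-identical reproduction.

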