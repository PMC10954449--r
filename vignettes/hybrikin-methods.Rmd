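---
title: "Modelling oligonucleotide annealing with defects: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oligonucleotide annealing with defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybrikin)
```

# The problem

When several short oligonucleotides compete for a common partner, the
duplexes present just after mixing are set by association *kinetics*, while
the duplexes present at long times are set by *thermodynamics*. Because
single mismatches, double mismatches and bulges barely change association
rates (they remove a few nucleation sites) but change dissociation rates by
orders of magnitude, a mixture can transiently hold large amounts of
mis-paired duplex that equilibrium calculations say should not exist. These
metastable states last from seconds to hours and can feed downstream
chemistry (primer extension, ligation) with the wrong substrate.

`hybrikin` implements the full modelling chain needed to study this:
nearest-neighbor (NN) duplex thermodynamics with defect penalties, the
analytical nucleation–zippering association model, a stochastic zippering
simulator, mass-action competition dynamics, fitting routines for the
simulated (or real) measurements, and an off-target combinatorics module.

# The nucleation–zippering association model

Hybridization of strands A (length $L_A$) and B (length $L_B$) is treated
as rate-limited by the formation of an $n$-base-pair nucleation region,
which then either dissociates or zips to the full duplex:

$$ k_{on} \;=\; k_{nuc} \sum_{i=1}^{L_A-n+1}\sum_{j=1}^{L_B-n+1}
   \frac{\alpha}{\alpha + e^{\Delta G_{i,j}/RT}} $$

* $k_{nuc}$ — a single bimolecular nucleation rate shared by all sequence
  variants (units 1/(M·s));
* $\Delta G_{i,j}$ — the free energy of the $n$-mer nucleation region
  starting at position $i$ on A and $j$ on B, $+\infty$ unless the segment
  is perfectly antiparallel-complementary;
* $\alpha$ — the ratio of the zippering rate to the basal dissociation rate
  of a freshly nucleated region, fitted per defect class (`perfect`,
  `single_mismatch`, `double_mismatch`, `bulge`).

The double sum runs over *all* segment pairs, so off-register accidental
complements contribute; `enumerate_sites()` flags them (`in_register`).
The default nucleation length is $n = 3$, the segment length that
correlates best with measured association rates; it is exposed as a
parameter. No duplex-length correction factor is applied: that correction
degrades performance on defect-bearing panels, so the model is used in the
bare form above.

`fit_nucleation()` performs least squares on $\log_{10} k_{on}$ with the
shared $k_{nuc}$ (closed form given the $\alpha$s) and one free
$\log_{10}\alpha$ per class (Nelder–Mead followed by BFGS). For classes
whose sites zip with near-unit probability the data only bound $\alpha$
from below; the fit flags a class as a *lower bound* when raising its
$\alpha$ tenfold changes the objective by less than 1% (with a small
absolute floor so that noise-free synthetic data do not defeat the test).
Confidence intervals come from a seeded bootstrap over records.

## The $\Delta G_{i,j}$ convention and the meaning of $\alpha$

`nucleation_dg()` evaluates the $n$-mer mini-duplex with the package's own
NN engine, *including* duplex initiation terms, at 25 °C and 1 M NaCl.
Trimer free energies on this scale sit around $-1$ to $-3$ kcal/mol.
Ensemble free energies from partition-function tools land on a similar
scale (a cross-check with an external folding tool gives $\approx -0.3$
kcal/mol for a trimer duplex). Because $\alpha$ enters only through
$\alpha\,e^{-\Delta G/RT}$, any constant offset in the $\Delta G$ scale is
absorbed into $\alpha$ when refitting: **fitted $\alpha$ values are
meaningful only together with the $\Delta G$ engine they were fitted
against**, and literature $\alpha$ values cannot be combined with a
different engine. For bit-compatible reproduction of an external analysis,
`thermo_params(dg_lookup = ...)` injects externally computed nucleation
free energies.

# Nearest-neighbor thermodynamics

`duplex_thermo()` sums, over the annotated antiparallel register:

* Watson–Crick dinucleotide stacks (unified DNA set; RNA set of Xia et
  al.), shipped as versioned CSVs under `inst/extdata/`;
* internal-mismatch doublet terms (DNA: the published internal-mismatch
  ΔH/ΔS set, which also covers tandem G·T; any other tandem context raises
  an explicit error naming the context — the reference designs avoid
  adjacent mismatches);
* terminal-mismatch doublet terms at duplex ends (DNA);
* a single-base bulge-loop increment (+4.0 kcal/mol DNA, +3.8 RNA at
  25 °C, applied entropically) with the stack of the flanking pairs
  retained — single bulges tend to loop out leaving the helix intact;
* duplex initiation charged on the outermost Watson–Crick pair of each end
  (per-pair-type terms for DNA; a global initiation plus terminal-AU
  penalty for RNA) and a symmetry correction for self-complementary
  duplexes;
* a 2-aminopurine penalty of +0.9 kcal/mol per marked position in DNA
  (0 in RNA), implemented as an entropic term so ΔH is unchanged — the
  marker behaves as adenine for pairing.

For RNA internal mismatches no compact published ΔH/ΔS doublet table is
available to this package, so a documented context-independent per-pair
penalty is used (a 1×1-loop-style term, entropic at 25 °C, ordered
G·U < G·G < G·A < U·U < C·U < A·A < A·C < C·C following the relative
stabilities of single-mismatch loops). This is a deliberate coarse model:
RNA mismatch K_D ratios are reproduced at the order-of-magnitude level,
which is what the competition predictions consume.

All parameters refer to the 1 M NaCl reference state; no salt correction is
applied by default (`thermo_params(salt_correction = ...)` accepts one).
Everywhere kinetics are evaluated, $RT = 0.5925$ kcal/mol (25 °C).
Melting temperatures solve the two-state condition
$K_D(T_m) = c_{excess} - c_{limiting}/2$ by a bracketed scalar root; a
self-consistency test confirms the bound fraction is 0.5 there.

# The zippering simulator

`build_chain()` enumerates the Markov chain of in-register bound states:
all contiguous intervals of the pairing register, plus the dissociated
state. Interval free energies come from the same NN engine applied to the
corresponding sub-duplex, so chain energetics and equilibrium
thermodynamics cannot drift apart; a single-pair state carries
initiation-only energy (both end-initiation terms of the NN scheme).
Intervals consisting solely of mismatched pairs are excluded from the
state space — a lone non-complementary "pair" is not a bound state — so
for a duplex with $m$ aligned pairs and no defects the chain has
$m(m+1)/2$ intervals plus the dissociated state.

Transitions add or remove one pair at either end with Metropolis rates:
$k_{uni}$ (default $4.2\times10^8$ s$^{-1}$) for downhill moves and
$k_{uni} e^{-\Delta G_{move}/RT}$ uphill. A move that steps the zipper
across a declared mismatch is additionally slowed by
$e^{-\Delta G^{\ddagger}_{mm}/RT}$ (default barrier 2.49 kcal/mol) in
*both* directions, which preserves detailed balance exactly; bulge
crossings carry no barrier (consistent with bulges not impeding zippering).
A test verifies Boltzmann stationarity of the ergodic chain by chi-square
against time-weighted occupancies.

Association rates are estimated in the first-step fashion:
trajectories start from single-pair nucleation states at complementary
positions (uniform draw), are absorbed at full zippering or dissociation,
and the rate at concentration $c$ is assembled from the success
probability $p$ and the conditional mean first-passage times:
$k_{on} = 1/(cT)$ with
$T = (p\,k_{coll}\,c)^{-1} + \frac{1-p}{p}E[t|\text{fail}] +
E[t|\text{succ}]$, numerically $\approx k_{coll}\, p$ because microscopic
passage times are nanoseconds while collisions take seconds. The entry
scale is per-site by default (`kmc_config(entry_mode = "per_site")`): a
fitted entry rate of $2\times10^6$ 1/(M·s) per site times roughly ten
sites with $p$ near 0.6 reproduces association rates of order
$10^7$ 1/(M·s) for a perfect 12-mer, matching the per-site reading of the
fitted nucleation scale. The `"total"` convention (one collision rate
split evenly over sites) is available as a flag, as the normalization of a
fitted entry scale is convention-dependent.

`exact_passage()` solves the absorbing chain exactly (linear systems for
absorption probabilities and conditional passage times) and is both the
test oracle for the sampler and the engine of `fit_kmc()`, the
two-parameter (entry scale, mismatch barrier) fit, which therefore is
deterministic and fast. Mismatches are assumed to affect zippering only,
not nucleus formation. Trajectory sampling uses one sequential seeded RNG
stream; execution is single-threaded, so a fixed seed reproduces results
exactly.

# Competition dynamics

`mixture_system()` + `simulate_mixture()` integrate (stiff-capable
`lsoda`, tolerances $10^{-10}$/$10^{-16}$) the mass-action network

* T + P ⇌ T:P and C + P ⇌ C:P,
* optionally C:P + T ⇌ T:P + C (toehold-free strand displacement; the
  reverse rate is derived from $k_{fwd}/k_{rev} = K_D^{C:P}/K_D^{T:P}$ so
  the channel cannot move the equilibrium),
* optionally T:P + S → T$^R$ and C:P + S → C$^R$ (pseudo-bimolecular
  extension/ligation; substrate in excess by default, depletable by flag).

The binding accuracy is $\theta = [T:P]/([T:P]+[C:P])$. Its initial value
is approximated by the kinetic partition
$\theta_{in} \approx k_{on}^{T:P}/(k_{on}^{T:P}+k_{on}^{C:P})$ for
equimolar T and C; the approximation is exact as $t \to 0$ and in the
sub-stoichiometric-probe regime, while at equimolar concentrations strand
depletion skews the frozen partition by a few hundredths (both regimes are
tested). Two operational definitions are available in analysis code:
θ at a fixed early time, or θ when 99% of the probe has bound.

$\theta_{eq}$ comes from `equilibrium_accuracy()`, which solves the
two-$K_D$ competitive equilibrium by a bracketed monotone root in the free
probe concentration (residual below $10^{-12}$ relative). A closed-form
cubic exists for this equilibrium; the bracketed root was chosen for
robustness near the stoichiometric cliff, and the tests verify the
mass-action relations directly.

The lifetime of the metastable state, `equilibration_halflife()`, is the
time at which [C:P] has moved halfway (linear interpolation on log-time)
from its early maximum to its equilibrium value. When the released probe
is recaptured predominantly by the target, this half-life is
$\ln 2 / k_{off}^{C:P}$; with comparable recapture fluxes it is
proportionally longer — the tests exercise the recapture-dominant design.
DNA defaults leave displacement off (negligible at 200 nM without
toeholds); for RNA a forward rate of order 1 1/(M·s) is a sensible
starting value.

# Trace and melting-curve fitting

`normalize_trace()` applies the control normalization
$(F_{mix}-F_{T:P})/(F_T-F_{T:P})$ exactly as written. Note a polarity
subtlety: written this way, the free-target control maps to 1 although
2-aminopurine is *quenched* upon duplex formation, i.e. the formula as
printed returns the free fraction under the physical sign convention. The
`orientation` flag (`"as_printed"`/`"quench"`) makes the choice explicit;
the generator-based round-trip tests use `"quench"`.

`fit_bimolecular()` fits the (optionally reversible) two-species
association ODE by seeded multistart (five starts across
$10^5$–$10^9$ 1/(M·s)); reversibility defaults to "on" when the trace
plateaus below 95% bound. The first 50 ms are excluded by default as a
stopped-flow mixing dead time (configurable; synthetic traces are fitted
with `dead_time = 0`). A flat trace raises an error rather than returning
a boundary estimate silently.

`fit_melt()` fits each curve independently to a two-state van't Hoff model
with linear (configurable to constant) upper/lower baselines, extrapolates
$K_D$ to 25 °C, and aggregates replicates as the lognormal mean and
standard deviation. A curve whose fitted transition does not run its
course inside the temperature window (bound fraction not $>0.75$ at the
low end and $<0.25$ at the high end) is recorded as a per-curve failure;
the aggregate is over the survivors.

`comparison_stats()` implements the two comparison statistics exactly as
defined alongside the reference rate tables: $R^2 = 1 - SS_{res}/SS_{tot}$
and $\mathrm{RMSE} = \frac{100}{m}\sum_i \sqrt{(\hat y_i - y_i)^2}/y_i$ —
the latter is, as printed, a mean absolute percentage deviation, and it is
implemented in that printed form rather than "corrected".

# Off-target combinatorics

For a probe of length $n$ against $L$ random nucleotides,
`expected_sites()` counts windows complementing the probe within a defect
budget: the mismatch term is
$(L-n+1)\sum_{k \le d_m} \binom{n}{k} (3/4)^k (1/4)^{n-k}$, and the
single-bulge term matches $(n-1)$-windows against the probe's
single-deletion patterns. Deletions inside a run of identical bases give
the *same* pattern, so counting one pattern per deletion position
overcounts; for a uniform random probe the expected number of distinct
patterns (deletions at positions 2..$n$, one per maximal base run) is
$(3n-2)/4$, and that is the multiplicity used — the Monte Carlo validator
agrees with this form within sampling error, and would reject the naive
$n-1$ count. `site_probability()` aggregates windows as a Poisson process
($1-e^{-E}$; an exact product form is available for small pools); window
overlap correlations are ignored, which the Monte Carlo grid shows is
adequate at the tested sizes. With this module, a 20-nt probe against
$10^9$ random nt has well above a 5% chance of an off-target site once a
single mismatch or bulge is tolerated — mismatch-only budgets alone cross
the threshold.

# Synthetic data: what it does and does not emulate

The generators produce bimolecular quench traces (0.5–5 μM strands),
two-state melting curves at several concentrations, three-strand
competition time courses (200 nM per strand in the reference design), and
uniform random pools; `t12_panel()` rebuilds the fixed probe
(5'-CACGCATCACCA-3'), its perfect 12-mer target (5'-TGGTGATGCGTG-3'), the
single-mismatch panel m_1..m_12, bulges b_2..b_11, a documented set of
double mismatches (m_1,12, m_2,11, m_4,9, m_3,10 — non-adjacent only), and
RNA twins (U for T throughout). Substituted bases minimize a documented
self-complementarity score with a seeded tie-break; an experimental
panel's exact substitutions can be reproduced by passing explicit bases.

Noise is additive Gaussian with SD a fraction (default 0.02) of the signal
dynamic range; signal polarity is free-bright/duplex-dark. The generators
are deterministic given a seed. They do **not** emulate instrument drift,
photobleaching, mixing artifacts, multi-state melting or secondary
structure in the single strands — so passing round-trip tests demonstrates
estimator correctness under the stated statistical model, not robustness
to every artifact of real instruments.

Problem sizes in the test suite were chosen to make the statistical checks
sharp at desk scale: $10^4$ trajectories for sampler-vs-oracle comparisons
(3-SE agreement), $2\times10^5$ jumps for stationarity, hundreds of Monte
Carlo pools per off-target grid point, 27-record panels for parameter
recovery at 5% lognormal rate noise (2% for the barrier fit, matching the
generator's default noise fraction).

# Known limitations

* Defects are declared, never inferred: there is no gapped alignment, and
  only single-base bulges with paired flanks are modelled.
* The RNA internal-mismatch table is a coarse context-independent model.
* Dangling ends and coaxial stacking are not modelled; nucleation free
  energies therefore exclude flanking-context stabilization, which is one
  plausible source of scale differences against ensemble-based values
  (absorbed by α on refitting, see above).
* The state space excludes out-of-register bound states and complexes of
  more than two strands; the competition module tracks one competitor.
* Salt is fixed at the 1 M NaCl reference; no Mg²⁺ model.
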