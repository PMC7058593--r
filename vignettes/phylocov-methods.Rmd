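---
title: "Models and methods behind phylocov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylocov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocov)
```

phylocov studies a single methodological question from three angles: how
does the phylogenetic breadth of the organisms in a community dataset change
which environmental drivers of species richness receive statistical
support? The package contains three self-contained computational arguments —
a diversification simulation, a taxa-pooling regression analysis with a
synthetic data generator, and a community model of negative density
dependence — plus a command-line front end. This vignette describes each
model, its assumptions, and the numerical and design choices behind the
implementation.

## 1. Temperature-state-dependent diversification

### Model

Lineages evolve on an ordered niche axis of $K$ temperature states
$s \in \{0, \dots, K-1\}$, with 0 the coldest. Three kinds of events occur,
each a Poisson process per extant lineage:

* **Speciation** at rate $\lambda(s) = \lambda_{\min} +
  (\lambda_{\max} - \lambda_{\min})\, s/(K-1)$, a linear ramp from the cold
  to the warm end. Both daughters inherit the parental state (anagenetic
  niche change only, no cladogenetic change).
* **Extinction** at a state-independent rate $\mu$.
* **Niche transition** at rate $q$ to *each* adjacent state, so interior
  states have total transition rate $2q$ and the edge states $q$. An
  alternative interpretation of $q$ as a lineage's *total* transition rate,
  split evenly over its available neighbors, is available via
  `qMode = "total"`; with $K = 2$ the two interpretations coincide exactly,
  which is tested.

This is a multi-state speciation–extinction (MuSSE-type) birth–death
process. The simulator is an exact Gillespie algorithm: one exponential
waiting time is drawn from the summed rate over all extant lineages, then a
(state, event-type) cell is chosen categorically and a lineage is drawn
uniformly within the chosen state. Because event times are continuous,
ties have probability zero and no tie-breaking rule is needed.

### Defaults and the two niche-evolution regimes

The default rates are $\lambda$ ramping 0.18–0.26, $\mu = 0.1$, and two
regimes for the transition rate: *progressive* niche evolution with
$q = 0.26$ (transition rate comparable to the diversification rate) and
*conservative* niche evolution with $q = 0.04$ ($q \ll \lambda$), run until
8000 extant lineages exist. Choices the rate summary leaves open, fixed
here once and exposed as parameters:

* **$K = 8$ states.** The niche axis only needs enough resolution to make
  "hump-shaped" profiles expressible; 8 is comfortably above the minimum
  of 3 and keeps state occupancies large. All downstream analyses read $K$
  from the tree object rather than assuming it.
* **Root state.** Conservative runs start in the coldest state (state 0) —
  the interesting regime is a clade whose ancestral niche is cold, so that
  richness accumulates away from the warm end. Progressive runs start at
  the middle state. Both are configurable.
* **Linear $\lambda$ ramp** between the two endpoint rates; only the
  endpoints are meaningful inputs, the interpolation is the simplest
  monotone choice.

### Stopping, restarts, determinism

Under the `extant_count` rule the run stops the moment the extant lineage
count first reaches the target — the final speciation is included, so the
extant tip count is exact. Under `max_time` the clock simply runs out; the
last inter-event time is truncated at the horizon. If every lineage dies
the run restarts with a fresh, deterministically derived random substream
(conditioning on survival), up to `maxRestarts` (default 100) times; the
consumed restart count is kept on the result. The same seed reproduces the
same tree bit for bit.

The basal branch of the initial lineage (origin to first speciation) is
retained as the tree's `root.edge`, so the depth of every extant tip from
the origin equals the elapsed simulation time; validity of a `PhyloSim`
checks this ultrametricity at a relative tolerance of $10^{-9}$, along with
strict binarity of the full (extinct-tips-included) tree. Per-branch state
histories are not serialized; only tip states are, which is what the
downstream richness summaries need.

## 2. Subclade extraction and relationship classification

`pruneToExtant()` removes extinct tips (delegating to `ape::drop.tip`) and
restores the origin-to-root distance into `root.edge`, preserving all
pairwise path lengths among extant tips. `extractSubclades()` then scans
every node of the pruned tree and keeps clades whose crown age falls in a
window expressed as fractions of the whole tree's crown age and whose size
reaches a minimum (defaults used throughout the package: window
[0.25, 0.6], minimum 30 tips). Stem age is available as an option; crown
age is the default because the richness profile of a clade is a property
of its crown group. All qualifying clades are used — no random subsample —
so the analysis is reproducible without a seed.

The richness-by-state profile of each clade is classified by a
deterministic rule:

1. **hump** if the maximum lies at an interior state and both endpoint
   richnesses are at most $(1-d)$ times the maximum, with $d = 0.25$;
2. otherwise **positive** / **negative** if the Spearman rank correlation
   (midrank ties) between state index and richness is $\ge 0.5$ /
   $\le -0.5$;
3. otherwise **flat**.

The thresholds operationalize a verbal description of profile shapes; both
are exposed as arguments, and the classification is invariant to positive
rescaling of the profile (tested as a property). The hump test is applied
first because a pronounced interior maximum with depressed endpoints can
still have a large monotone rank correlation.

Under these defaults the two regimes separate cleanly: at 2000 extant tips,
progressive-regime whole trees classify as *positive* in effectively all
replicates, while the conservative regime pushes hump-shaped and negative
profiles into young subclades (fractions around 0.97 vs 0.37 for the
progressive regime in the acceptance run). The package's acceptance checks
use 50 replicates of 2000 tips per regime; those sizes keep each check to a
couple of minutes while leaving the contrast far from its decision
boundary.

## 3. Taxa-pooling coverage analysis

### Standardized effect sizes

For a site-level response $y$ (pooled species richness) and $p$ site-level
predictors, `standardizedEffectSizes()` z-scores the response and each
predictor, fits all $2^p$ additive least-squares models (including the
intercept-only model), weights model $m$ by its small-sample-corrected
information criterion,
$$\mathrm{AICc}_m = n \log(\mathrm{RSS}_m / n) + 2k_m +
  \frac{2 k_m (k_m + 1)}{n - k_m - 1},$$
(with $k_m$ counting coefficients plus the error variance; the shared
$n\log 2\pi + n$ constant cancels in the weights), and reports each
predictor's weight-averaged coefficient with the coefficient counted as 0
in models that exclude it (full / shrinkage averaging, the convention that
penalizes weakly supported predictors). Conditional averaging — dividing by
the summed weight of the models containing the predictor — is available as
an option, as is a `log1p` response transform; richness is left
untransformed by default. AICc requires at least one residual degree of
freedom in the largest model, so $n \ge p + 4$ sites are required.

Degenerate inputs: a zero-variance *predictor* is an error (it cannot be
z-scored and carries no information), but a zero-variance *response* yields
all-zero effect sizes with a warning, so that a pathological taxon subset
inside a long coverage run degrades gracefully instead of aborting the
curve. A perfect fit (RSS = 0) is handled by flooring RSS at $10^{-300}$,
which concentrates all weight on the smallest perfect model.

### The coverage curve

`coverageCurve()` evaluates, for every $k = 1, \dots, T$, either all
$\binom{T}{k}$ taxon combinations (when that count is at most `nReps`) or
`nReps` distinct random combinations, pools richness over each combination
(taxon species pools are disjoint by construction, so pooling is a plain
sum), computes effect sizes, and records their mean and standard deviation
per predictor. `nReps` defaults to 200, the combination count used
throughout; enumeration kicks in automatically where it is cheaper. Two
identities pin down the endpoints and are tested to $10^{-12}$: at $k = 1$
the mean equals the unweighted mean of per-taxon effect sizes (the
meta-analysis, single-taxon endpoint), and at $k = T$ exactly one
combination exists with zero spread.

## 4. The synthetic community generator

No field dataset ships with the package, so the generator produces
community data with *known* driver structure for the coverage analysis to
recover. It emulates an elevational gradient: evenly spaced sites, a linear
temperature lapse, and unimodal net primary productivity (NPP). Defaults,
chosen once as a realistic tropical-mountain setting and then frozen: 60
sites spanning 870–4550 m a.s.l., lapse rate 6.5 °C km⁻¹ from a 29 °C
sea-level baseline (so site temperatures run ≈ 23 °C down to ≈ −0.6 °C),
NPP a Gaussian in elevation peaking at 1800 m with 1200 m width, 16
taxonomic groups.

Expected richness of taxon $j$ at site $i$ is log-linear,
$$m_{ij} = \mathrm{scale}_j \exp\{w_{Tj}\, z(\mathrm{temp}_i) +
  w_{Nj}\, z(\mathrm{npp}_i) + w_{Ij}\, u_j(i)\},$$
with $u_j$ a standardized random cubic in elevation — a smooth,
taxon-idiosyncratic nuisance signal that gives single taxa "best
predictors" other than temperature. Temperature weights are drawn
$N(0, 0.5)$ and recentred to mean 0.45, which *guarantees* the aggregate
temperature effect is positive while individual taxa disagree in sign and
strength; NPP weights are $N(0, 0.25)$, nuisance weights $|N(0, 0.5)|$,
and per-taxon baselines lognormal around 25 species. Counts get negative
binomial noise with dispersion 0.3 (variance $m + 0.3\,m^2$); dispersion 0
disables noise entirely (rounded expectations), which the exactness tests
use. Under the frozen default seed the dataset has a pooled
richness–temperature rank correlation of 0.96 while four taxa correlate
below 0.3 — and the resulting coverage curve rises monotonically in $k$.

A second scenario (`generateNppScenario()`) concentrates the drivers on
NPP with heterogeneous per-taxon shapes — increasing, decreasing, humped
(a Gaussian window over a sub-interval of the NPP range), and flat,
assigned cyclically — with scales biased toward the increasing taxa so
pooled richness still rises with NPP while subclade relationships
disagree.

What the generator does *not* emulate: spatial autocorrelation among
sites, species-level identities (only richness counts), sampling effort
differences, or correlated noise across taxa. Tests passing on these data
therefore demonstrate that the analysis machinery recovers a known signal
under realistic count noise — not that any particular field system behaves
this way.

## 5. Negative density dependence with antagonist spillover

A fixed community of $N = 20$ individuals (a 4 × 5 community treated as
well mixed; the spatial grid is presentational) from five species in three
clades — red {red, orange}, blue {dark blue, bright blue}, green {green} —
with strictly ranked competitiveness $1.25 > 1.20 > 1.15 > 1.10 > 1.05$.
The mechanism is usually described verbally; the implementation is the
minimal stochastic model matching that description.
Each generation, species $i$ has fitness
$$w_i = \max\{\,c_i\,(1 - \beta A_i / N),\ \varepsilon\,\},$$
where $A_i$ is the antagonist-shared abundance: 0 (no density dependence),
$n_i$ (conspecific), or the summed abundance of $i$'s clade (clade
spillover — antagonists attack all related hosts). The next generation is
a multinomial draw of $N$ individuals with probabilities $\propto n_i w_i$,
so extinct species stay extinct and abundances are conserved exactly.
Defaults: $\beta = 0.8$, $\varepsilon = 10^{-6}$, 200 generations, 200
replicates (500 in the scale-dissociation comparison), equal initial
abundances with any remainder handed to the most competitive species.
Competitiveness spacing is even by choice; only the ranking is prescribed.

Diversity is scored by the Shannon–Wiener index
$H = -\sum_{n_i > 0} p_i \ln p_i$, in nats by default with the log base
exposed (the conventional index symbol does not fix a base). Within-clade
indices use within-clade relative abundances and are undefined (NA) when a
clade is locally extinct.

The model reproduces three phenomena. Without density dependence, the best
competitor excludes the rest (mean final $H$ far below $\ln 5$).
Conspecific density dependence maintains diversity at both scales. Clade
spillover maintains *community* diversity but not within-clade diversity:
the shared discount suppresses clade totals without protecting the weaker
species inside each clade, so the within-clade change in $H$ against the
no-density-dependence baseline straddles zero while the community-scale
change is strongly positive — `compareScales()` quantifies this with mean
final-generation differences and nonparametric bootstrap percentile
intervals (1000 resamples) over replicates.

## 6. Reproducibility machinery

Every stochastic entry point takes an integer seed and is bit-for-bit
reproducible given it. The command-line front end (`runPhylocov()` and the
`inst/scripts/phylocov` wrapper) resolves options as preset < config file <
flags, validates before computing, computes before writing, and writes a
`manifest.json` holding the fully resolved parameters and package version
next to its outputs; `rerun --manifest` regenerates every output
byte-identically, which is tested for all five presets. Manifests contain
no timestamps for exactly this reason.

## 7. Problem sizes used in the checks

The package's own acceptance checks run, by choice, at: one full
8000-lineage run (the default stopping rule, checked exactly); 1000
pure-birth replicates against the analytic $e^{\lambda t}$ expectation
(three Monte-Carlo standard errors); 50 trees of 2000 extant tips per
niche-evolution regime for the subclade contrast; the full 16-taxon, 200
combinations-per-$k$ coverage curve; and 500 replicates of 200 generations
for the spillover comparison. These sizes put every stochastic check well
inside its decision region while keeping the whole suite to a few minutes.

## 8. Known limitations

* The simulator records states at tips only; ancestral-state summaries
  would need the internal histories it deliberately does not serialize.
* No likelihood-based inference of the diversification parameters from
  trees is provided — simulation only.
* The coverage analysis uses ordinary least squares on (possibly
  transformed) richness; no GLM error families, spatial correction, or
  model diagnostics.
* The relationship classifier is a threshold rule on a $K$-vector; with
  very small clades the rank correlation is noisy, which is why the
  subclade analyses impose a minimum clade size.
* The density-dependence model has no explicit antagonist populations and
  no spatial structure; attack pressure is implicit in $A_i$.
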