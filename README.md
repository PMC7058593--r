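# phylocov

Does the evidence for what drives species-richness gradients depend on how
much of the tree of life your community data cover? `phylocov` packages
three computational arguments around that question, aimed at macroecologists
and phylogeneticists who work with diversity gradients:

1. **Diversification under niche conservatism.** A multi-state
   speciation–extinction (MuSSE-type) Gillespie simulator in which lineages
   carry an ordered temperature state $s \in \{0,\dots,K-1\}$, speciate at
   $\lambda(s) = \lambda_{\min} + (\lambda_{\max}-\lambda_{\min})\,s/(K-1)$,
   go extinct at a constant $\mu$, and shift niche one state at rate $q$ per
   adjacent state. Even when temperature is the *only* driver
   ($\lambda$ increasing with warmth), a low transition rate
   ($q \ll \lambda$, niche conservatism) with a cold ancestral niche
   produces hump-shaped or negative richness–temperature profiles in young
   subclades — the whole clade shows the signal, its parts need not.
2. **Taxa-pooling coverage analysis.** For a site × taxon richness table,
   pool every (or many random) combination(s) of $k$ of the $T$ taxonomic
   groups, regress pooled richness on site predictors with AICc-weighted
   all-subsets model averaging of standardized (z-scored) coefficients, and
   track each predictor's mean standardized effect size as $k$ grows from 1
   (single-taxon studies, the meta-analysis endpoint) to $T$ (the whole
   community). A synthetic elevational-gradient generator with known driver
   structure makes the recovery testable end to end.
3. **Negative density dependence with antagonist spillover.** A 20-individual
   community of five species in three clades evolves by multinomial
   resampling with fitness $w_i = c_i(1-\beta A_i/N)$, where the
   antagonist-shared abundance $A_i$ is species-specific, clade-summed
   (spillover), or absent. Shannon diversity
   $H=-\sum p_i \ln p_i$ is scored at community and within-clade scales:
   spillover keeps community diversity high while within-clade diversity is
   unprotected.

## Worked example

Simulate a conservative-regime tree (cold ancestral niche, $q = 0.04$),
prune to the extant tips, and look at where the richness sits on the
temperature axis:

```r
library(phylocov)

p <- diversificationParams(q = 0.04, rootState = 0L, stopValue = 2000, seed = 42L)
sim <- simulateTree(p)
sim
#> PhyloSim: 3965 tips (2000 extant, 1965 extinct), K = 8 states, age 64.35

tr <- pruneToExtant(sim)
richnessByState(tr)
#> [1] 598 568 361 264  99  79  22   9
classifyRelationship(richnessByState(tr))
#> [1] "negative"
```

Richness piles up in the *cold* states — the opposite of what the
underlying model (speciation increasing with warmth) naively suggests,
because lineages rarely escape the cold ancestral niche. Young subclades
show the same distortion:

```r
cl <- extractSubclades(tr, c(0.25, 0.6), minSize = 30L)
table(cl$relationship)
#>     hump negative
#>       57       32
```

On the coverage side, generate the default synthetic gradient (60 sites,
870–4550 m, 16 taxa) and trace how support for temperature grows with the
number of pooled taxa:

```r
ds <- generateCommunity(communityGenParams())
cv <- coverageCurve(ds, c("temperature", "npp"), nReps = 200L, seed = 1L)
cv
#> EffectSizeCurve: 16 taxa, predictors temperature, npp, <=200 combinations per k
#>   k   predictor    meanSES     sdSES nCombos
#>   1 temperature  0.7171684 0.8589148      16
#>   1         npp -0.2970712 0.7559671      16
#>  16 temperature  1.6905411 0.0000000       1
#>  16         npp -0.8832121 0.0000000       1
```

At $k=1$ the mean temperature effect is modest with a spread (0.86) larger
than many single-taxon effects — individual taxa disagree; at $k=16$ the
pooled community supports temperature strongly and deterministically.

Finally, the density-dependence comparison at two observation scales:

```r
spill <- simulateNDD(nddParams(mode = "clade_spillover", replicates = 500L, seed = 77L))
none  <- simulateNDD(nddParams(mode = "none", replicates = 500L, seed = 77L))
compareScales(spill, none, seed = 1L)
#>       scale clade   deltaH     lower     upper
#> 1 community  <NA> 0.655618 0.6498607 0.6606619
#> 2     clade  blue 0.000000 0.0000000 0.0000000
#> 3     clade   red 0.000000 0.0000000 0.0000000
```

Spillover raises community diversity by ~0.66 nats over the
competitive-exclusion baseline (bootstrap interval excluding 0), while the
within-clade differences sit at zero: the effect is only detectable at the
community scale.

## Command line

A thin wrapper (`inst/scripts/phylocov`) exposes the same functionality as
subcommands with presets and reproducible manifests:

```sh
phylocov simulate --preset fig3-conservative --seed 1 --out-dir runs/cons
phylocov clades --tree runs/cons/tree.nwk --states runs/cons/states.tsv \
  --age-lo 0.25 --age-hi 0.6 --min-size 30 --out clades.csv --out-dir runs/cons
phylocov generate --preset fig1-synthetic --out-dir runs/fig1
phylocov coverage --sites runs/fig1/sites.csv --richness runs/fig1/richness.csv \
  --predictors temperature,npp --reps 200 --seed 1 --out-dir runs/fig1
phylocov ndd --mode clade_spillover --beta 0.8 --gens 200 --reps 200 --seed 1 --out-dir runs/ndd
phylocov rerun --manifest runs/cons/manifest.json --out-dir runs/cons2  # byte-identical
```

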