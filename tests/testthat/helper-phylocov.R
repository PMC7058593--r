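## small parameter builders shared across test files

pureBirthParams <- function(stopValue, seed = 1L, rule = "extant_count") {
  diversificationParams(nStates = 1L, lambdaMin = 0.2, lambdaMax = 0.2,
                        mu = 0, q = 0, rootState = 0L, stopRule = rule,
                        stopValue = stopValue, seed = seed)
}

smallCommunity <- function(nTaxa = 6L, nSites = 30L, seed = 1L, ...) {
  generateCommunity(communityGenParams(nTaxa = nTaxa, nSites = nSites,
                                       seed = seed, ...))
}

## a hand-built two-tip tree: tip tA extant (state 0), tip tB extinct
## (state 1); root branch 0.5, tA branch 2.0, tB branch 1.0
cherrySim <- function() {
  tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
                       edge.length = c(2, 1),
                       tip.label = c("tA", "tB"),
                       Nnode = 1L, root.edge = 0.5), class = "phylo")
  new("PhyloSim", tree = tr,
      tipState = c(tA = 0L, tB = 1L),
      tipExtant = c(tA = TRUE, tB = FALSE),
      totalTime = 2.5, nStates = 2L, restarts = 0L)
}
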