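setOldClass("phylo")

#' Parameters of the temperature-state-dependent diversification model
#'
#' Container for all rates and run controls of the multi-state
#' speciation--extinction simulation. Lineages carry an ordered temperature
#' niche state \eqn{s \in \{0, \dots, K-1\}} (0 = coldest). Speciation rates
#' ramp linearly from \code{lambdaMin} at the coldest state to
#' \code{lambdaMax} at the warmest; extinction is state-independent; niche
#' transitions move a lineage one state up or down.
#'
#' @slot nStates integer, number of ordered temperature states \eqn{K \ge 1}.
#' @slot lambdaMin numeric, speciation rate at state 0 (per lineage per time).
#' @slot lambdaMax numeric, speciation rate at state \eqn{K-1}.
#' @slot mu numeric, state-independent extinction rate.
#' @slot q numeric, niche transition rate. Under \code{qMode =
#'   "per_neighbor"} this is the rate to EACH adjacent state (interior states
#'   have total transition rate \eqn{2q}); under \code{"total"} it is the
#'   total transition rate of a lineage, split evenly among its available
#'   neighbors.
#' @slot qMode character, \code{"per_neighbor"} (default) or \code{"total"}.
#' @slot rootState integer in \eqn{[0, K-1]}, state of the initial lineage.
#' @slot stopRule character, \code{"extant_count"} or \code{"max_time"}.
#' @slot stopValue numeric > 0, target extant lineage count or time horizon.
#' @slot seed integer, RNG seed (same seed, same tree, bit for bit).
#' @slot maxRestarts integer, number of fresh-substream re-runs allowed when
#'   the whole tree goes extinct.
#'
#' @seealso [diversificationParams()], [simulateTree()]
#' @export
setClass("DiversificationParams",
  representation(
    nStates = "integer", lambdaMin = "numeric", lambdaMax = "numeric",
    mu = "numeric", q = "numeric", qMode = "character",
    rootState = "integer", stopRule = "character", stopValue = "numeric",
    seed = "integer", maxRestarts = "integer"
  )
)

setValidity("DiversificationParams", function(object) {
  msg <- character(0)
  if (length(object@nStates) != 1L || is.na(object@nStates) ||
      object@nStates < 1L)
    msg <- c(msg, "nStates must be a single integer >= 1")
  if (object@lambdaMin < 0 || object@lambdaMax < 0 || object@mu < 0 ||
      object@q < 0)
    msg <- c(msg, "all rates must be >= 0")
  if (object@lambdaMin > object@lambdaMax)
    msg <- c(msg, "lambdaMin must be <= lambdaMax")
  if (!object@qMode %in% c("per_neighbor", "total"))
    msg <- c(msg, "qMode must be 'per_neighbor' or 'total'")
  if (is.na(object@rootState) || object@rootState < 0L ||
      object@rootState >= object@nStates)
    msg <- c(msg, "rootState must lie in [0, nStates - 1]")
  if (!object@stopRule %in% c("extant_count", "max_time"))
    msg <- c(msg, "stopRule must be 'extant_count' or 'max_time'")
  if (!is.finite(object@stopValue) || object@stopValue <= 0)
    msg <- c(msg, "stopValue must be > 0")
  if (object@stopRule == "extant_count" &&
      object@stopValue != round(object@stopValue))
    msg <- c(msg, "stopValue must be a whole number under the extant_count rule")
  if (object@maxRestarts < 0L)
    msg <- c(msg, "maxRestarts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A simulated phylogeny with tip temperature states
#'
#' Wraps an [ape][ape::read.tree] \code{phylo} tree together with the niche
#' state and extant/extinct flag of every tip, the total elapsed simulation
#' time, and the size of the state space. The basal branch of the initial
#' lineage (root to first speciation) is kept as the tree's \code{root.edge},
#' so the depth of every extant tip, measured from the origin, equals
#' \code{totalTime} (the tree is ultrametric over extant tips).
#'
#' @slot tree a \code{phylo} object; tip labels are \code{t<id>}.
#' @slot tipState named integer vector, state in \eqn{[0, K-1]} per tip.
#' @slot tipExtant named logical vector, \code{TRUE} for tips alive at the
#'   present.
#' @slot totalTime numeric, elapsed simulation time.
#' @slot nStates integer, state-space size \eqn{K}.
#' @slot restarts integer, number of whole-tree-extinction restarts consumed.
#'
#' @seealso [simulateTree()], [pruneToExtant()], [asPhylo()]
#' @export
setClass("PhyloSim",
  representation(
    tree = "phylo", tipState = "integer", tipExtant = "logical",
    totalTime = "numeric", nStates = "integer", restarts = "integer"
  )
)

setValidity("PhyloSim", function(object) {
  msg <- character(0)
  tr <- object@tree
  labs <- tr$tip.label
  ntip <- length(labs)
  if (!identical(sort(names(object@tipState)), sort(labs)))
    msg <- c(msg, "tipState names must match tip labels")
  if (!identical(sort(names(object@tipExtant)), sort(labs)))
    msg <- c(msg, "tipExtant names must match tip labels")
  if (anyNA(object@tipState) || any(object@tipState < 0L) ||
      any(object@tipState >= object@nStates))
    msg <- c(msg, "tip states must lie in [0, nStates - 1]")
  if (any(tr$edge.length < 0))
    msg <- c(msg, "branch lengths must be >= 0")
  if (ntip >= 2L) {
    ## every internal node has exactly two children
    kids <- tabulate(tr$edge[, 1L], ntip + tr$Nnode)
    if (any(kids[(ntip + 1L):(ntip + tr$Nnode)] != 2L))
      msg <- c(msg, "tree must be strictly binary")
    ## extant tips equidistant from the origin
    if (any(object@tipExtant)) {
      depth <- node.depth.edgelength(tr)[seq_len(ntip)] +
        if (is.null(tr$root.edge)) 0 else tr$root.edge
      d <- depth[match(names(which(object@tipExtant)), labs)]
      tol <- 1e-9 * max(object@totalTime, 1)
      if (any(abs(d - object@totalTime) > tol))
        msg <- c(msg, "extant tips must sit at depth totalTime (ultrametric)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Multi-taxa community dataset on an environmental gradient
#'
#' A \linkS4class{SummarizedExperiment} holding a site-by-taxon
#' species-richness matrix (stored taxa-as-rows in the \code{"richness"}
#' assay) together with site-level environmental predictors in
#' \code{colData}. Taxonomic groups have disjoint species pools by
#' construction, so pooled richness over any taxon subset is the plain sum of
#' the corresponding columns.
#'
#' @seealso [communityDataset()], [generateCommunity()], [coverageCurve()]
#' @export
setClass("CommunityDataset", contains = "SummarizedExperiment")

setValidity("CommunityDataset", function(object) {
  msg <- character(0)
  if (!"richness" %in% assayNames(object))
    msg <- c(msg, "a 'richness' assay is required")
  else {
    m <- assay(object, "richness")
    if (anyNA(m) || any(m < 0)) msg <- c(msg, "richness must be non-negative")
  }
  if (ncol(object) < 3L) msg <- c(msg, "at least 3 sites are required")
  if (nrow(object) < 1L) msg <- c(msg, "at least 1 taxon is required")
  if (ncol(colData(object)) > 0L && anyNA(as.data.frame(colData(object))))
    msg <- c(msg, "site predictors must have no missing values")
  if (length(msg)) msg else TRUE
})

#' Coverage curve of standardized effect sizes
#'
#' Per predictor and per number of pooled taxa \eqn{k = 1, \dots, T}: the
#' mean standardized effect size over taxon combinations, its standard
#' deviation across combinations, and the number of combinations evaluated.
#'
#' @slot curve data.frame with columns \code{k}, \code{predictor},
#'   \code{meanSES}, \code{sdSES}, \code{nCombos}.
#' @slot nTaxa integer, total number of taxonomic groups \eqn{T}.
#' @slot predictors character, predictor names.
#' @slot nReps integer, requested combinations per \eqn{k}.
#' @slot seed integer seed used for combination sampling.
#'
#' @seealso [coverageCurve()]
#' @export
setClass("EffectSizeCurve",
  representation(curve = "data.frame", nTaxa = "integer",
                 predictors = "character", nReps = "integer", seed = "integer")
)

setValidity("EffectSizeCurve", function(object) {
  msg <- character(0)
  need <- c("k", "predictor", "meanSES", "sdSES", "nCombos")
  if (!all(need %in% names(object@curve)))
    msg <- c(msg, "curve must have columns k, predictor, meanSES, sdSES, nCombos")
  else {
    top <- object@curve[object@curve$k == object@nTaxa, ]
    if (nrow(top) && (any(top$nCombos != 1L) || any(top$sdSES != 0)))
      msg <- c(msg, "at k = T exactly one combination exists and its spread is 0")
  }
  if (length(msg)) msg else TRUE
})

#' Parameters of the negative-density-dependence community model
#'
#' A fixed-size, well-mixed community of \code{communitySize} individuals
#' drawn from a small species pool with strict competitiveness ranking and
#' clade membership, evolving by multinomial resampling under one of three
#' density-dependence modes: \code{"none"}, \code{"conspecific"} (a species'
#' own abundance depresses its growth), or \code{"clade_spillover"} (the
#' summed abundance of its clade does, emulating antagonists shared among
#' related hosts).
#'
#' @slot species data.frame with columns \code{name}, \code{clade},
#'   \code{competitiveness} (strictly ranked, > 0).
#' @slot communitySize integer \eqn{N}, number of individuals (default 20).
#' @slot mode character, one of \code{"none"}, \code{"conspecific"},
#'   \code{"clade_spillover"}.
#' @slot beta numeric in \eqn{[0, 1]}, density-dependence strength.
#' @slot generations integer, generations per replicate.
#' @slot replicates integer, independent replicates.
#' @slot seed integer RNG seed.
#' @slot epsilon numeric, positive fitness floor.
#'
#' @seealso [nddParams()], [simulateNDD()]
#' @export
setClass("NDDParams",
  representation(species = "data.frame", communitySize = "integer",
                 mode = "character", beta = "numeric", generations = "integer",
                 replicates = "integer", seed = "integer", epsilon = "numeric")
)

setValidity("NDDParams", function(object) {
  msg <- character(0)
  sp <- object@species
  if (!all(c("name", "clade", "competitiveness") %in% names(sp)))
    msg <- c(msg, "species needs columns name, clade, competitiveness")
  else {
    if (any(sp$competitiveness <= 0))
      msg <- c(msg, "competitiveness values must be > 0")
    if (anyDuplicated(sp$name)) msg <- c(msg, "species names must be unique")
    if (object@communitySize < nrow(sp))
      msg <- c(msg, "communitySize must be >= number of species")
  }
  if (!object@mode %in% c("none", "conspecific", "clade_spillover"))
    msg <- c(msg, "mode must be none, conspecific or clade_spillover")
  if (object@beta < 0 || object@beta > 1)
    msg <- c(msg, "beta must lie in [0, 1]")
  if (object@mode == "none" && object@beta > 0)
    msg <- c(msg, "mode 'none' with beta > 0 is contradictory; set beta = 0")
  if (object@generations < 1L || object@replicates < 1L)
    msg <- c(msg, "generations and replicates must be >= 1")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of a negative-density-dependence simulation
#'
#' @slot abundances integer array species x (generations + 1) x replicates;
#'   generation 0 is the equal-abundance initial state.
#' @slot communityH matrix (generations + 1) x replicates of community
#'   Shannon indices (nats).
#' @slot cladeH named list, one (generations + 1) x replicates matrix per
#'   clade with >= 2 species; \code{NA} where the clade is locally extinct.
#' @slot params the \linkS4class{NDDParams} that produced the result.
#'
#' @seealso [simulateNDD()], [compareScales()]
#' @export
setClass("NDDResult",
  representation(abundances = "array", communityH = "matrix",
                 cladeH = "list", params = "NDDParams")
)

setValidity("NDDResult", function(object) {
  n <- object@params@communitySize
  sums <- apply(object@abundances, c(2L, 3L), sum)
  if (any(sums != n))
    return("abundances must sum to communitySize at every generation")
  if (any(object@communityH < 0, na.rm = TRUE))
    return("Shannon values must be >= 0")
  TRUE
})
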