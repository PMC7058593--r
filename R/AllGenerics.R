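#' @export
setGeneric("simulateTree", function(params) standardGeneric("simulateTree"))

#' @export
setGeneric("asPhylo", function(x, ...) standardGeneric("asPhylo"))

#' @export
setGeneric("tipStates", function(x) standardGeneric("tipStates"))

#' @export
setGeneric("tipExtant", function(x) standardGeneric("tipExtant"))

#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))

#' @export
setGeneric("pruneToExtant", function(x) standardGeneric("pruneToExtant"))

#' @export
setGeneric("extractSubclades",
  function(x, ageWindow, minSize = 1L, ...) standardGeneric("extractSubclades"))

#' @export
setGeneric("richnessByState", function(x, ...) standardGeneric("richnessByState"))

#' @export
setGeneric("richnessMatrix", function(x) standardGeneric("richnessMatrix"))

#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @export
setGeneric("poolRichness",
  function(x, taxa) standardGeneric("poolRichness"))

#' @export
setGeneric("coverageCurve",
  function(x, predictors, nReps = 200L, seed = 1L, ...)
    standardGeneric("coverageCurve"))

#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @export
setGeneric("simulateNDD", function(params) standardGeneric("simulateNDD"))

#' @export
setGeneric("compareScales",
  function(result, baseline, ...) standardGeneric("compareScales"))
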