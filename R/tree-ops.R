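#' Prune a simulated tree to its extant tips
#'
#' Removes extinct tips and the degree-one internal nodes this leaves
#' behind, merging branch lengths additively. The extant tip set, tip
#' states, and all pairwise path lengths among extant tips are unchanged;
#' the basal branch below the new root is accumulated into the tree's
#' \code{root.edge} so extant tip depths still equal \code{totalTime}.
#'
#' @param x a \linkS4class{PhyloSim}.
#' @return a \linkS4class{PhyloSim} whose tips are all extant.
#' @export
setMethod("pruneToExtant", "PhyloSim", function(x) {
  if (!any(x@tipExtant)) stop("tree has no extant tips")
  if (all(x@tipExtant)) return(x)
  keep <- names(which(x@tipExtant))
  if (length(keep) == 1L) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                         edge.length = x@totalTime,
                         tip.label = keep, Nnode = 1L), class = "phylo")
  } else {
    tr <- drop.tip(x@tree, setdiff(x@tree$tip.label, keep))
    depth <- node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    tr$root.edge <- x@totalTime - max(depth)
  }
  new("PhyloSim", tree = tr,
      tipState = x@tipState[tr$tip.label],
      tipExtant = x@tipExtant[tr$tip.label],
      totalTime = x@totalTime, nStates = x@nStates, restarts = x@restarts)
})

#' Count extant tips per temperature state
#'
#' @param x a \linkS4class{PhyloSim}, or a bare integer vector of tip states.
#' @param K state-space size; taken from the object for \code{PhyloSim}.
#' @param ... passed between methods.
#' @return integer vector of length \code{K}; element \eqn{s+1} is the
#'   number of extant tips in state \eqn{s}. Sums to the extant tip count.
#' @examples
#' richnessByState(c(0L, 0L, 1L, 2L), K = 3L)  # 2 1 1
#' @export
setMethod("richnessByState", "PhyloSim", function(x, K = nStates(x), ...) {
  richnessByState(unname(x@tipState[x@tipExtant]), K = K)
})

#' @rdname richnessByState-PhyloSim-method
#' @export
setMethod("richnessByState", "numeric", function(x, K, ...) {
  if (any(x != round(x)) || any(x < 0)) stop("states must be integers >= 0")
  if (any(x >= K)) stop("tip state out of range [0, K - 1]")
  tabulate(as.integer(x) + 1L, as.integer(K))
})

#' @export
setMethod("richnessByState", "integer", function(x, K, ...) {
  richnessByState(as.numeric(x), K = K)
})

#' Classify the shape of a richness-by-state profile
#'
#' Deterministic rule for the qualitative temperature--diversity
#' relationship of a clade. A profile is \code{"hump"} when its maximum sits
#' at an interior state and both endpoint richnesses are at most
#' \eqn{(1 - d)} times the maximum; otherwise the Spearman rank correlation
#' \eqn{\rho} between state index and richness (midrank ties) decides:
#' \code{"positive"} if \eqn{\rho \ge} \code{rhoCutoff}, \code{"negative"}
#' if \eqn{\rho \le -}\code{rhoCutoff}, else \code{"flat"}. The result is
#' invariant to rescaling the profile by a positive constant.
#'
#' @param richness non-negative numeric vector of length \eqn{K \ge 3}.
#' @param rhoCutoff Spearman threshold for a monotone call (default 0.5).
#' @param endpointDrop required relative endpoint drop \eqn{d} for a hump
#'   call (default 0.25).
#' @return one of \code{"positive"}, \code{"negative"}, \code{"hump"},
#'   \code{"flat"}.
#' @examples
#' classifyRelationship(c(1, 2, 4, 8, 16))   # "positive"
#' classifyRelationship(c(2, 8, 3, 1, 1))    # "hump"
#' @export
classifyRelationship <- function(richness, rhoCutoff = 0.5,
                                 endpointDrop = 0.25) {
  K <- length(richness)
  if (K < 3L) stop("at least 3 states are required")
  if (any(richness < 0)) stop("richness must be non-negative")
  if (sum(richness) == 0) stop("relationship undefined for an all-zero profile")
  i_max <- which.max(richness)
  mx <- richness[i_max]
  if (i_max > 1L && i_max < K &&
      richness[1L] <= (1 - endpointDrop) * mx &&
      richness[K] <= (1 - endpointDrop) * mx)
    return("hump")
  rho <- suppressWarnings(cor(seq_len(K), richness, method = "spearman"))
  if (is.na(rho)) return("flat")
  if (rho >= rhoCutoff) "positive"
  else if (rho <= -rhoCutoff) "negative"
  else "flat"
}

#' Extract subclades by age and size
#'
#' Scans every node of an extant-pruned tree and returns the clades whose
#' root age falls inside \code{ageWindow} (expressed as fractions of the
#' crown age of the whole tree) and whose extant size is at least
#' \code{minSize}, together with their richness-by-state profiles and
#' relationship classifications.
#'
#' @param x an extant-pruned \linkS4class{PhyloSim} (see
#'   \code{\link{pruneToExtant}}).
#' @param ageWindow numeric \code{c(lo, hi)} with
#'   \eqn{0 \le lo \le hi \le 1}; clade ages are compared against
#'   \code{c(lo, hi) * crownAge} inclusively.
#' @param minSize minimum extant tip count of a reported clade.
#' @param nonNested if \code{TRUE}, drop clades with a selected ancestor.
#' @param ageType \code{"crown"} (time from the clade's root node to the
#'   present, the default) or \code{"stem"} (adds the clade's subtending
#'   branch).
#' @param rhoCutoff,endpointDrop passed to [classifyRelationship()].
#' @param ... unused.
#' @return a data.frame with one row per clade: \code{cladeId} (node number
#'   in the pruned tree), \code{age}, \code{size}, \code{richness_s0} ...
#'   \code{richness_s<K-1>}, \code{relationship}.
#' @export
setMethod("extractSubclades", "PhyloSim",
  function(x, ageWindow, minSize = 1L, nonNested = FALSE,
           ageType = c("crown", "stem"), rhoCutoff = 0.5,
           endpointDrop = 0.25, ...) {
  ageType <- match.arg(ageType)
  if (length(ageWindow) != 2L || any(!is.finite(ageWindow)) ||
      ageWindow[1L] < 0 || ageWindow[2L] > 1 || ageWindow[1L] > ageWindow[2L])
    stop("ageWindow must be c(lo, hi) with 0 <= lo <= hi <= 1")
  if (minSize < 1L) stop("minSize must be >= 1")
  if (!all(x@tipExtant)) stop("tree must be extant-pruned first")
  tr <- x@tree
  K <- x@nStates
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  depth <- node.depth.edgelength(tr)
  crownAge <- max(depth[seq_len(ntip)])
  age <- crownAge - depth
  if (ageType == "stem") {
    parentLen <- numeric(nnode)
    parentLen[tr$edge[, 2L]] <- tr$edge.length
    parentLen[ntip + 1L] <- if (is.null(tr$root.edge)) 0 else tr$root.edge
    age <- age + parentLen
  }
  ## per-node state counts by postorder accumulation (edges are cladewise)
  counts <- matrix(0L, nnode, K)
  st <- x@tipState[tr$tip.label]
  counts[cbind(seq_len(ntip), st + 1L)] <- 1L
  for (e in rev(seq_len(nrow(tr$edge)))) {
    counts[tr$edge[e, 1L], ] <- counts[tr$edge[e, 1L], ] +
      counts[tr$edge[e, 2L], ]
  }
  size <- rowSums(counts)
  tol <- 1e-9 * max(crownAge, 1)
  sel <- age >= ageWindow[1L] * crownAge - tol &
         age <= ageWindow[2L] * crownAge + tol & size >= minSize
  if (nonNested && any(sel)) {
    ancSel <- logical(nnode)
    for (e in seq_len(nrow(tr$edge))) {   # cladewise => parents before kids
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      ancSel[ch] <- ancSel[p] || sel[p]
    }
    sel <- sel & !ancSel
  }
  ids <- which(sel)
  rel <- vapply(ids, function(v) {
    if (K < 3L) NA_character_
    else classifyRelationship(counts[v, ], rhoCutoff, endpointDrop)
  }, character(1L))
  out <- data.frame(cladeId = ids, age = age[ids], size = size[ids],
                    stringsAsFactors = FALSE)
  cm <- counts[ids, , drop = FALSE]
  colnames(cm) <- paste0("richness_s", seq_len(K) - 1L)
  out <- cbind(out, as.data.frame(cm))
  out$relationship <- rel
  rownames(out) <- NULL
  out
})

#' Write a simulated tree as Newick plus a tip-state table
#'
#' Writes the extant-pruned tree in Newick format (tip labels \code{t<id>})
#' and a companion tab-delimited table \code{tip_id<TAB>state}. With
#' \code{annotated = TRUE} the Newick additionally carries
#' \code{[&state=s]} comments behind each tip label.
#'
#' @param x a \linkS4class{PhyloSim}.
#' @param treeFile,statesFile output paths.
#' @param annotated write state comments into the Newick string?
#' @return invisibly, the paths written.
#' @seealso [readPhyloSim()]
#' @export
writePhyloSim <- function(x, treeFile, statesFile, annotated = FALSE) {
  stopifnot(is(x, "PhyloSim"))
  pr <- pruneToExtant(x)
  nwk <- write.tree(pr@tree)
  if (annotated) {
    labs <- pr@tree$tip.label
    for (lb in labs[order(nchar(labs), decreasing = TRUE)]) {
      nwk <- gsub(paste0("(?<![0-9A-Za-z])", lb, ":"),
                  sprintf("%s[&state=%d]:", lb, pr@tipState[[lb]]),
                  nwk, perl = TRUE)
    }
  }
  writeLines(nwk, treeFile)
  df <- data.frame(tip_id = pr@tree$tip.label,
                   state = unname(pr@tipState[pr@tree$tip.label]))
  write.table(df, statesFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(tree = treeFile, states = statesFile))
}

#' Read a tree and tip-state table back into a PhyloSim
#'
#' @param treeFile Newick file; an optional root edge is honoured.
#' @param statesFile tab-delimited \code{tip_id<TAB>state} table.
#' @param nStates state-space size; defaults to \code{max(state) + 1}.
#' @return a \linkS4class{PhyloSim} with all tips flagged extant.
#' @export
readPhyloSim <- function(treeFile, statesFile, nStates = NULL) {
  tr <- read.tree(treeFile)
  st <- read.delim(statesFile, stringsAsFactors = FALSE)
  if (!all(c("tip_id", "state") %in% names(st)))
    stop("states file needs columns tip_id and state")
  if (!setequal(st$tip_id, tr$tip.label))
    stop("tip labels in tree and states file disagree")
  states <- setNames(as.integer(st$state), st$tip_id)[tr$tip.label]
  K <- if (is.null(nStates)) max(states) + 1L else as.integer(nStates)
  rootEdge <- if (is.null(tr$root.edge)) 0 else tr$root.edge
  total <- max(node.depth.edgelength(tr)[seq_along(tr$tip.label)]) + rootEdge
  new("PhyloSim", tree = tr, tipState = states,
      tipExtant = setNames(rep(TRUE, length(states)), names(states)),
      totalTime = total, nStates = K, restarts = 0L)
}
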