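#' Create diversification-model parameters
#'
#' Defaults encode the progressive-niche-evolution scenario: eight ordered
#' temperature states, speciation ramping linearly from 0.18 (coldest) to
#' 0.26 (warmest) per lineage per time unit, extinction 0.1 everywhere, and a
#' niche transition rate of 0.26 to each adjacent state, run until 8000
#' extant lineages exist. The conservative scenario uses \code{q = 0.04} and
#' a cold root (\code{rootState = 0}).
#'
#' @param nStates number of ordered temperature states \eqn{K}.
#' @param lambdaMin,lambdaMax speciation rates at the coldest and warmest
#'   state; intermediate states interpolate linearly.
#' @param mu state-independent extinction rate.
#' @param q niche transition rate (see \code{qMode}).
#' @param qMode \code{"per_neighbor"}: \code{q} is the rate to each adjacent
#'   state; \code{"total"}: \code{q} is a lineage's total transition rate,
#'   split evenly among available neighbors.
#' @param rootState state of the initial lineage; defaults to the (lower)
#'   middle state.
#' @param stopRule \code{"extant_count"} or \code{"max_time"}.
#' @param stopValue target extant count, or time horizon.
#' @param seed integer RNG seed.
#' @param maxRestarts allowed re-runs after whole-tree extinction.
#' @return a validated \linkS4class{DiversificationParams} object.
#' @examples
#' p <- diversificationParams(nStates = 1L, lambdaMin = 0.2, lambdaMax = 0.2,
#'                            mu = 0, q = 0, stopRule = "extant_count",
#'                            stopValue = 16, seed = 1L)
#' simulateTree(p)
#' @export
diversificationParams <- function(nStates = 8L, lambdaMin = 0.18,
                                  lambdaMax = 0.26, mu = 0.1, q = 0.26,
                                  qMode = c("per_neighbor", "total"),
                                  rootState = (as.integer(nStates) - 1L) %/% 2L,
                                  stopRule = c("extant_count", "max_time"),
                                  stopValue = 8000, seed = 1L,
                                  maxRestarts = 100L) {
  new("DiversificationParams",
      nStates = as.integer(nStates), lambdaMin = as.numeric(lambdaMin),
      lambdaMax = as.numeric(lambdaMax), mu = as.numeric(mu),
      q = as.numeric(q), qMode = match.arg(qMode),
      rootState = as.integer(rootState), stopRule = match.arg(stopRule),
      stopValue = as.numeric(stopValue), seed = as.integer(seed),
      maxRestarts = as.integer(maxRestarts))
}

#' State-dependent speciation rate
#'
#' Linear ramp over the ordered temperature states:
#' \eqn{\lambda(s) = \lambda_{min} + (\lambda_{max}-\lambda_{min})\, s/(K-1)}
#' for \eqn{K > 1}; for \eqn{K = 1} the rate is \code{lambdaMin}. Monotone
#' non-decreasing in \eqn{s}.
#'
#' @param state integer vector of states in \eqn{[0, K-1]}.
#' @param params a \linkS4class{DiversificationParams}.
#' @return numeric vector of speciation rates (per lineage per time).
#' @examples
#' p <- diversificationParams(nStates = 5L)
#' stateSpeciationRate(0:4, p)   # 0.18 ... 0.26
#' @export
stateSpeciationRate <- function(state, params) {
  stopifnot(is(params, "DiversificationParams"))
  K <- params@nStates
  if (any(state != round(state)) || any(state < 0) || any(state >= K))
    stop("state out of range [0, ", K - 1L, "]")
  if (K == 1L) rep(params@lambdaMin, length(state))
  else params@lambdaMin +
    (params@lambdaMax - params@lambdaMin) * state / (K - 1L)
}

## deterministic substream seed for restart r of base seed s (kept < 2^31)
.substreamSeed <- function(seed, r) {
  as.integer((as.numeric(seed) + as.numeric(r) * 1000003) %% 2147483629)
}

#' @rdname simulateTree
#' @details
#' The simulation is an exact Gillespie algorithm on the set of extant
#' lineages: one exponential waiting time is drawn from the summed event
#' rate, then the event (speciation at rate \eqn{\lambda(s)}, extinction at
#' rate \eqn{\mu}, or a one-step niche transition) and the lineage it hits
#' are chosen categorically. Daughters inherit the parental state
#' (anagenetic change only). Under the \code{extant_count} rule the final
#' speciation is included, so the extant tip count equals \code{stopValue}
#' exactly. If every lineage dies the run restarts with a fresh random
#' substream, up to \code{maxRestarts} times, after which an error of class
#' \code{phylocov_sim_failure} (carrying the restart count) is signalled.
#' @export
setMethod("simulateTree", "DiversificationParams", function(params) {
  validObject(params)
  for (attempt in 0:params@maxRestarts) {
    res <- .gillespie(params, .substreamSeed(params@seed, attempt))
    if (!is.null(res))
      return(.assemblePhyloSim(res, params, restarts = attempt))
  }
  stop(structure(class = c("phylocov_sim_failure", "error", "condition"),
                 list(message = sprintf(
                   "all lineages died in every attempt (%d restarts used)",
                   params@maxRestarts),
                   call = sys.call(-1), restarts = params@maxRestarts)))
})

## Core event loop. Returns a node table (parent, branch start time, length,
## tip flag, extinct flag, tip state) plus the elapsed time, or NULL if the
## whole tree died before the stopping rule fired.
.gillespie <- function(p, seed) {
  set.seed(seed)
  K <- p@nStates
  lam <- stateSpeciationRate(0:(K - 1L), p)
  mu <- p@mu
  nn <- if (K == 1L) 0 else c(1, rep(2, max(K - 2L, 0L)), 1) # neighbors/state
  ## per-state transition rate to each available neighbor
  q_up <- q_dn <- numeric(K)
  if (K > 1L) {
    if (p@qMode == "per_neighbor") {
      q_up <- c(rep(p@q, K - 1L), 0)
      q_dn <- c(0, rep(p@q, K - 1L))
    } else {                        # total rate q, split among neighbors
      q_up <- ifelse(seq_len(K) < K, p@q / nn, 0)
      q_dn <- ifelse(seq_len(K) > 1L, p@q / nn, 0)
    }
  }
  stop_n <- if (p@stopRule == "extant_count") as.integer(p@stopValue) else NA_integer_
  horizon <- if (p@stopRule == "max_time") p@stopValue else Inf

  cap <- if (is.na(stop_n)) 256L else max(64L, 2L * stop_n)
  a_state <- integer(cap); a_node <- integer(cap)
  ncap <- 4L * cap
  n_par <- integer(ncap); n_start <- numeric(ncap); n_len <- numeric(ncap)
  n_tip <- logical(ncap); n_ext <- logical(ncap); n_state <- integer(ncap)

  n_nodes <- 1L
  n_par[1L] <- 0L; n_start[1L] <- 0
  a_state[1L] <- p@rootState; a_node[1L] <- 1L
  n_act <- 1L
  t <- 0

  grow_nodes <- function() {
    ncap2 <- 2L * ncap
    n_par <<- c(n_par, integer(ncap)); n_start <<- c(n_start, numeric(ncap))
    n_len <<- c(n_len, numeric(ncap)); n_tip <<- c(n_tip, logical(ncap))
    n_ext <<- c(n_ext, logical(ncap)); n_state <<- c(n_state, integer(ncap))
    ncap <<- ncap2
  }

  if (!is.na(stop_n) && n_act >= stop_n) {
    ## degenerate target of one lineage: stop immediately
  } else repeat {
    cnt <- tabulate(a_state[seq_len(n_act)] + 1L, K)
    r <- c(cnt * lam, cnt * mu, cnt * q_up, cnt * q_dn)
    tot <- sum(r)
    if (tot <= 0) {                         # no events possible; run out clock
      if (is.finite(horizon)) { t <- horizon; break }
      stop("event rates are all zero but the extant-count target was not reached")
    }
    dt <- rexp(1L, tot)
    if (t + dt >= horizon) { t <- horizon; break }
    t <- t + dt
    cell <- sample.int(4L * K, 1L, prob = r)
    type <- (cell - 1L) %/% K
    s <- (cell - 1L) %% K
    idx <- which(a_state[seq_len(n_act)] == s)
    i <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    if (type == 0L) {                       # speciation
      nd <- a_node[i]
      if (n_nodes + 2L > ncap) grow_nodes()
      n_len[nd] <- t - n_start[nd]
      c1 <- n_nodes + 1L; c2 <- n_nodes + 2L; n_nodes <- n_nodes + 2L
      n_par[c1] <- nd; n_par[c2] <- nd
      n_start[c1] <- t; n_start[c2] <- t
      a_node[i] <- c1
      n_act <- n_act + 1L
      if (n_act > length(a_state)) {
        a_state <- c(a_state, integer(length(a_state)))
        a_node <- c(a_node, integer(length(a_node)))
      }
      a_state[n_act] <- s; a_node[n_act] <- c2
      if (!is.na(stop_n) && n_act == stop_n) break
    } else if (type == 1L) {                # extinction
      nd <- a_node[i]
      n_len[nd] <- t - n_start[nd]
      n_tip[nd] <- TRUE; n_ext[nd] <- TRUE; n_state[nd] <- s
      a_state[i] <- a_state[n_act]; a_node[i] <- a_node[n_act]
      n_act <- n_act - 1L
      if (n_act == 0L) return(NULL)
    } else if (type == 2L) {                # transition up
      a_state[i] <- s + 1L
    } else {                                # transition down
      a_state[i] <- s - 1L
    }
  }

  ## surviving lineages become extant tips at time t
  for (j in seq_len(n_act)) {
    nd <- a_node[j]
    n_len[nd] <- t - n_start[nd]
    n_tip[nd] <- TRUE; n_state[nd] <- a_state[j]
  }
  keep <- seq_len(n_nodes)
  list(par = n_par[keep], len = n_len[keep], tip = n_tip[keep],
       ext = n_ext[keep], state = n_state[keep], totalTime = t)
}

## Turn the node table into an ape phylo (cladewise edge order) wrapped in a
## PhyloSim. The basal branch of node 1 becomes the root.edge.
.assemblePhyloSim <- function(res, params, restarts) {
  n <- length(res$par)
  tips <- which(res$tip)
  ntip <- length(tips)
  labs <- paste0("t", tips)

  if (ntip == 1L) {
    ## single lineage that never speciated: one tip below a formal root
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = res$len[tips],
      tip.label = labs, Nnode = 1L), class = "phylo")
  } else {
    ints <- which(!res$tip)                # ascending: root (node 1) first
    new_id <- integer(n)
    new_id[tips] <- seq_len(ntip)
    new_id[ints] <- ntip + seq_along(ints)
    kids <- split(seq_len(n)[-1L], res$par[-1L])
    edge <- matrix(0L, n - 1L, 2L)
    elen <- numeric(n - 1L)
    stack <- 1L; k <- 0L
    while (length(stack)) {                # preorder DFS => cladewise order
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (ch in kids[[as.character(v)]]) {
        k <- k + 1L
        edge[k, ] <- c(new_id[v], new_id[ch])
        elen[k] <- res$len[ch]
        if (!res$tip[ch]) stack <- c(stack, ch)
      }
    }
    tr <- structure(list(edge = edge, edge.length = elen, tip.label = labs,
                         Nnode = length(ints), root.edge = res$len[1L]),
                    class = "phylo")
  }
  new("PhyloSim", tree = tr,
      tipState = setNames(res$state[tips], labs),
      tipExtant = setNames(!res$ext[tips], labs),
      totalTime = res$totalTime, nStates = params@nStates,
      restarts = as.integer(restarts))
}

#' @describeIn PhyloSim the underlying \code{phylo} object.
#' @param x a \code{PhyloSim}.
#' @param extant logical; drop extinct tips first?
#' @export
setMethod("asPhylo", "PhyloSim", function(x, extant = FALSE) {
  if (extant) pruneToExtant(x)@tree else x@tree
})

#' @describeIn PhyloSim named integer vector of tip states.
#' @export
setMethod("tipStates", "PhyloSim", function(x) x@tipState)

#' @describeIn PhyloSim named logical vector of extant flags.
#' @export
setMethod("tipExtant", "PhyloSim", function(x) x@tipExtant)

#' @describeIn PhyloSim state-space size K.
#' @export
setMethod("nStates", "PhyloSim", function(x) x@nStates)

#' @describeIn PhyloSim elapsed simulation time.
#' @export
setMethod("totalTime", "PhyloSim", function(x) x@totalTime)

setMethod("show", "PhyloSim", function(object) {
  cat(sprintf(
    "PhyloSim: %d tips (%d extant, %d extinct), K = %d states, age %.4g\n",
    length(object@tipState), sum(object@tipExtant),
    sum(!object@tipExtant), object@nStates, object@totalTime))
})

setMethod("show", "DiversificationParams", function(object) {
  cat(sprintf(
    "DiversificationParams: K = %d, lambda %.3g-%.3g, mu %.3g, q %.3g (%s)\n",
    object@nStates, object@lambdaMin, object@lambdaMax, object@mu, object@q,
    object@qMode))
  cat(sprintf("  root state %d, stop %s = %g, seed %d\n", object@rootState,
              object@stopRule, object@stopValue, object@seed))
})
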