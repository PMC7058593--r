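#' Shannon--Wiener diversity index
#'
#' \eqn{H = -\sum_{i: n_i > 0} p_i \log p_i} with \eqn{p_i = n_i / \sum_j
#' n_j}, in natural-log units (nats) by default. Bounded by
#' \eqn{0 \le H \le \log(S_{>0})} where \eqn{S_{>0}} is the number of
#' species with positive abundance.
#'
#' @param counts non-negative abundance vector with positive sum.
#' @param base logarithm base (default \code{exp(1)} for nats).
#' @return the diversity index, a single non-negative number.
#' @examples
#' shannonDiversity(c(5, 5, 5, 5))    # log(4)
#' shannonDiversity(c(20, 0, 0, 0))   # 0
#' @export
shannonDiversity <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("diversity undefined for an all-zero community")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Default species pool of the density-dependence model
#'
#' Five species from three clades with a strict competitiveness ranking
#' (red > orange > dark blue > bright blue > green); the red/orange pair
#' and the two blue species each form a two-species clade assumed to share
#' antagonists, green stands alone.
#'
#' @return data.frame with columns \code{name}, \code{clade},
#'   \code{competitiveness}.
#' @export
defaultNDDSpecies <- function() {
  data.frame(
    name = c("red", "orange", "dark_blue", "bright_blue", "green"),
    clade = c("red", "red", "blue", "blue", "green"),
    competitiveness = c(1.25, 1.20, 1.15, 1.10, 1.05),
    stringsAsFactors = FALSE)
}

#' Create density-dependence model parameters
#'
#' @param species species table (see [defaultNDDSpecies()]).
#' @param communitySize number of individuals \eqn{N} (default 20, a 4 x 5
#'   community treated as well mixed).
#' @param mode \code{"none"}, \code{"conspecific"} or
#'   \code{"clade_spillover"}.
#' @param beta density-dependence strength in \eqn{[0, 1]}; defaults to 0.8
#'   (0 when \code{mode = "none"}).
#' @param generations,replicates run length and number of independent runs.
#' @param seed integer RNG seed.
#' @param epsilon positive fitness floor.
#' @return a validated \linkS4class{NDDParams}.
#' @export
nddParams <- function(species = defaultNDDSpecies(), communitySize = 20L,
                      mode = c("none", "conspecific", "clade_spillover"),
                      beta = if (match.arg(mode) == "none") 0 else 0.8,
                      generations = 200L, replicates = 200L, seed = 1L,
                      epsilon = 1e-6) {
  new("NDDParams", species = as.data.frame(species),
      communitySize = as.integer(communitySize), mode = match.arg(mode),
      beta = as.numeric(beta), generations = as.integer(generations),
      replicates = as.integer(replicates), seed = as.integer(seed),
      epsilon = as.numeric(epsilon))
}

#' Density-discounted fitness of each species
#'
#' \eqn{w_i = \max\{c_i (1 - \beta A_i / N), \epsilon\}} where the
#' antagonist-shared abundance \eqn{A_i} is 0 (\code{none}), the species'
#' own abundance (\code{conspecific}) or its clade's summed abundance
#' (\code{clade_spillover}).
#'
#' @param abundances integer vector summing to \code{communitySize}.
#' @param params an \linkS4class{NDDParams}.
#' @return numeric fitness vector, one value per species.
#' @export
nddFitness <- function(abundances, params) {
  stopifnot(is(params, "NDDParams"))
  n <- params@communitySize
  if (sum(abundances) != n)
    stop("abundances must sum to communitySize")
  A <- switch(params@mode,
    none = rep(0, length(abundances)),
    conspecific = abundances,
    clade_spillover = ave(abundances, params@species$clade, FUN = sum))
  pmax(params@species$competitiveness * (1 - params@beta * A / n),
       params@epsilon)
}

#' One generation of the density-dependent community update
#'
#' Each species' fitness is its competitiveness discounted by local density:
#' \eqn{w_i = c_i (1 - \beta A_i / N)}, floored at \code{epsilon}, where the
#' antagonist-shared abundance \eqn{A_i} is the species' own abundance
#' (\code{conspecific}), its clade's summed abundance
#' (\code{clade_spillover}) or 0 (\code{none}). The next generation is a
#' multinomial draw of \eqn{N} individuals with probabilities proportional
#' to \eqn{n_i w_i}; extinct species stay extinct. Uses the current R RNG
#' stream.
#'
#' @param abundances integer vector summing to \code{communitySize}.
#' @param params an \linkS4class{NDDParams}.
#' @return the next abundance vector (sums to \code{communitySize}).
#' @export
stepCommunity <- function(abundances, params) {
  pr <- abundances * nddFitness(abundances, params)
  as.integer(rmultinom(1L, params@communitySize, pr))
}

#' @rdname simulateNDD
#' @details Each replicate starts from equal abundances
#' (\code{communitySize \%/\% nSpecies} each, any remainder handed one
#' individual at a time to the most competitive species) and runs
#' \code{generations} updates of [stepCommunity()]. Community and per-clade
#' Shannon indices (clades with at least two species; \code{NA} when a
#' clade is locally extinct) are recorded every generation. Deterministic
#' given \code{seed}.
#' @export
setMethod("simulateNDD", "NDDParams", function(params) {
  validObject(params)
  sp <- params@species
  S <- nrow(sp)
  N <- params@communitySize
  G <- params@generations
  R <- params@replicates
  init <- rep(N %/% S, S)
  rem <- N - sum(init)
  if (rem > 0) {
    ord <- order(sp$competitiveness, decreasing = TRUE)
    init[ord[seq_len(rem)]] <- init[ord[seq_len(rem)]] + 1L
  }
  clades <- split(seq_len(S), sp$clade)
  clades <- clades[vapply(clades, length, 1L) >= 2L]

  ab <- array(0L, c(S, G + 1L, R),
              dimnames = list(sp$name, NULL, NULL))
  commH <- matrix(NA_real_, G + 1L, R)
  cladeH <- lapply(clades, function(.) matrix(NA_real_, G + 1L, R))

  set.seed(params@seed)
  for (r in seq_len(R)) {
    cur <- init
    for (g in 0:G) {
      if (g > 0) cur <- stepCommunity(cur, params)
      ab[, g + 1L, r] <- cur
      commH[g + 1L, r] <- shannonDiversity(cur)
      for (cl in names(clades)) {
        cc <- cur[clades[[cl]]]
        cladeH[[cl]][g + 1L, r] <-
          if (sum(cc) > 0) shannonDiversity(cc) else NA_real_
      }
    }
  }
  new("NDDResult", abundances = ab, communityH = commH, cladeH = cladeH,
      params = params)
})

#' @describeIn NDDResult mean community Shannon index per generation
#'   (averaged over replicates).
#' @param object an \code{NDDResult}.
#' @export
meanCommunityH <- function(object) {
  stopifnot(is(object, "NDDResult"))
  rowMeans(object@communityH)
}

#' @describeIn NDDResult final-generation community Shannon index, one
#'   value per replicate.
#' @export
finalCommunityH <- function(object) {
  stopifnot(is(object, "NDDResult"))
  object@communityH[nrow(object@communityH), ]
}

setMethod("show", "NDDResult", function(object) {
  p <- object@params
  cat(sprintf(
    "NDDResult: mode %s (beta %.2f), N = %d, %d generations x %d replicates\n",
    p@mode, p@beta, p@communitySize, p@generations, p@replicates))
  cat(sprintf("  mean final community H = %.4f\n",
              mean(finalCommunityH(object))))
})

#' Compare diversity effects across observation scales
#'
#' Contrasts a density-dependent run against a no-density-dependence
#' baseline with the same species pool, generations and replicate count.
#' The effect at each scale is the difference of mean final-generation
#' Shannon indices, \eqn{\Delta H = \bar H_{NDD} - \bar H_{none}}, at the
#' whole-community scale and within every clade of at least two species,
#' with nonparametric bootstrap percentile intervals over replicates
#' (replicates where a clade is extinct are dropped for that clade's
#' within-clade index).
#'
#' @param result an \linkS4class{NDDResult} from a density-dependent run.
#' @param baseline an \linkS4class{NDDResult} with \code{mode = "none"} (or
#'   any comparable configuration).
#' @param nBoot bootstrap resamples (default 1000).
#' @param level interval coverage (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @param ... unused.
#' @return data.frame with columns \code{scale} (\code{"community"} or
#'   \code{"clade"}), \code{clade}, \code{deltaH}, \code{lower},
#'   \code{upper}.
#' @export
setMethod("compareScales", signature("NDDResult", "NDDResult"),
  function(result, baseline, nBoot = 1000L, level = 0.95, seed = 1L, ...) {
  p1 <- result@params; p0 <- baseline@params
  if (!identical(p1@species, p0@species) ||
      p1@generations != p0@generations || p1@replicates != p0@replicates)
    stop("results are not comparable: species table, generations and ",
         "replicates must match")
  set.seed(as.integer(seed))
  alpha <- (1 - level) / 2
  bootDelta <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b))
      return(c(NA_real_, NA_real_, NA_real_))
    d <- mean(a) - mean(b)
    bs <- vapply(seq_len(nBoot), function(.) {
      mean(a[sample.int(length(a), replace = TRUE)]) -
        mean(b[sample.int(length(b), replace = TRUE)])
    }, numeric(1L))
    c(d, quantile(bs, c(alpha, 1 - alpha), names = FALSE))
  }
  gEnd <- nrow(result@communityH)
  rows <- list(data.frame(scale = "community", clade = NA_character_,
                          t(setNames(bootDelta(result@communityH[gEnd, ],
                                               baseline@communityH[gEnd, ]),
                                     c("deltaH", "lower", "upper"))),
                          stringsAsFactors = FALSE))
  for (cl in names(result@cladeH)) {
    est <- bootDelta(result@cladeH[[cl]][gEnd, ],
                     baseline@cladeH[[cl]][gEnd, ])
    rows[[length(rows) + 1L]] <-
      data.frame(scale = "clade", clade = cl,
                 deltaH = est[1L], lower = est[2L], upper = est[3L],
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})
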