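#' Parameters of the synthetic community generator
#'
#' Describes an elevational study gradient and the latent driver structure
#' of the taxa sampled along it. Defaults emulate a tropical mountain
#' gradient: 60 sites spanning 870--4550 m a.s.l., temperature falling
#' linearly with elevation at 6.5 degC per km from a 29 degC sea-level
#' baseline, net primary productivity (NPP) unimodal in elevation, and 16
#' taxonomic groups with disjoint species pools whose expected richness
#' follows a log-linear model in standardized temperature, standardized NPP
#' and a taxon-specific smooth nuisance signal, with overdispersed count
#' noise.
#'
#' @param nSites number of sites (evenly spaced elevations).
#' @param elevRange numeric \code{c(lo, hi)} elevation range, m a.s.l.
#' @param lapseRate temperature lapse rate, degC per km.
#' @param seaLevelTemp temperature at 0 m, degC.
#' @param nppPeak,nppWidth,nppMax elevation (m) of the NPP maximum, Gaussian
#'   width (m), and peak NPP (index units).
#' @param nTaxa number of taxonomic groups \eqn{T}.
#' @param tempWeightMean mean temperature weight across taxa; the per-taxon
#'   weights are recentred onto this value so the aggregate temperature
#'   effect is positive even though individual taxa vary in sign.
#' @param tempWeightSD,nppWeightSD spread of per-taxon driver weights.
#' @param nuisanceSD scale of the taxon-idiosyncratic nuisance weight.
#' @param baselineRichness median expected per-taxon richness at gradient
#'   midpoint (> 0).
#' @param dispersion negative-binomial dispersion of the count noise
#'   (variance \eqn{= m + dispersion\, m^2}); small values approach Poisson
#'   noise and 0 disables noise entirely (rounded expectations).
#' @param seed integer RNG seed.
#' @return a \linkS4class{CommunityGenParams} object.
#' @export
communityGenParams <- function(nSites = 60L, elevRange = c(870, 4550),
                               lapseRate = 6.5, seaLevelTemp = 29,
                               nppPeak = 1800, nppWidth = 1200, nppMax = 1000,
                               nTaxa = 16L, tempWeightMean = 0.45,
                               tempWeightSD = 0.5, nppWeightSD = 0.25,
                               nuisanceSD = 0.5, baselineRichness = 25,
                               dispersion = 0.3, seed = 1L) {
  new("CommunityGenParams",
      nSites = as.integer(nSites), elevRange = as.numeric(elevRange),
      lapseRate = as.numeric(lapseRate), seaLevelTemp = as.numeric(seaLevelTemp),
      nppPeak = as.numeric(nppPeak), nppWidth = as.numeric(nppWidth),
      nppMax = as.numeric(nppMax), nTaxa = as.integer(nTaxa),
      tempWeightMean = as.numeric(tempWeightMean),
      tempWeightSD = as.numeric(tempWeightSD),
      nppWeightSD = as.numeric(nppWeightSD),
      nuisanceSD = as.numeric(nuisanceSD),
      baselineRichness = as.numeric(baselineRichness),
      dispersion = as.numeric(dispersion), seed = as.integer(seed))
}

#' @rdname communityGenParams
#' @export
setClass("CommunityGenParams",
  representation(nSites = "integer", elevRange = "numeric",
                 lapseRate = "numeric", seaLevelTemp = "numeric",
                 nppPeak = "numeric", nppWidth = "numeric", nppMax = "numeric",
                 nTaxa = "integer", tempWeightMean = "numeric",
                 tempWeightSD = "numeric", nppWeightSD = "numeric",
                 nuisanceSD = "numeric", baselineRichness = "numeric",
                 dispersion = "numeric", seed = "integer"))

setValidity("CommunityGenParams", function(object) {
  msg <- character(0)
  if (object@nSites < 3L) msg <- c(msg, "nSites must be >= 3")
  if (length(object@elevRange) != 2L ||
      object@elevRange[1L] >= object@elevRange[2L])
    msg <- c(msg, "elevRange must be c(lo, hi) with lo < hi")
  if (object@nTaxa < 1L) msg <- c(msg, "nTaxa must be >= 1")
  if (object@baselineRichness <= 0)
    msg <- c(msg, "baselineRichness must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@nppWidth <= 0) msg <- c(msg, "nppWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Generate the site table of an elevational gradient
#'
#' Sites are evenly spaced over the elevation range; temperature decreases
#' linearly with elevation (constant lapse rate) and NPP is a Gaussian
#' (unimodal) function of elevation. The table is deterministic given the
#' parameters.
#'
#' @param params a \linkS4class{CommunityGenParams}.
#' @return data.frame with columns \code{site}, \code{elevation},
#'   \code{temperature}, \code{npp}.
#' @export
generateGradient <- function(params) {
  stopifnot(is(params, "CommunityGenParams"))
  validObject(params)
  elev <- seq(params@elevRange[1L], params@elevRange[2L],
              length.out = params@nSites)
  data.frame(
    site = sprintf("site%02d", seq_len(params@nSites)),
    elevation = elev,
    temperature = params@seaLevelTemp - params@lapseRate * elev / 1000,
    npp = params@nppMax *
      exp(-(elev - params@nppPeak)^2 / (2 * params@nppWidth^2)))
}

## overdispersed count noise around expected values; dispersion 0 disables
## noise (rounded expectations), small positive values approach Poisson
.countNoise <- function(mu, dispersion) {
  if (dispersion > 0) rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  else as.integer(round(mu))
}

#' Generate a temperature-driven multi-taxa community dataset
#'
#' Expected richness of taxon \eqn{j} at site \eqn{i} is
#' \deqn{m_{ij} = scale_j \exp\{w_{Tj} z(temp_i) + w_{Nj} z(npp_i)
#'   + w_{Ij} u_j(i)\},}
#' where \eqn{u_j} is a taxon-specific smooth nuisance signal (a
#' standardized random cubic in elevation) and realized richness adds
#' overdispersed count noise. Temperature weights vary in sign and strength
#' across taxa but are recentred so their aggregate is positive: pooled
#' richness tracks temperature even though single taxa disagree about their
#' best predictor.
#'
#' @param params a \linkS4class{CommunityGenParams}.
#' @return a \linkS4class{CommunityDataset}; per-taxon weights are stored in
#'   \code{rowData}.
#' @export
generateCommunity <- function(params) {
  stopifnot(is(params, "CommunityGenParams"))
  validObject(params)
  set.seed(params@seed)
  grad <- generateGradient(params)
  T_ <- params@nTaxa
  n <- params@nSites
  zt <- .zscore(grad$temperature)
  zn <- .zscore(grad$npp)
  ze <- .zscore(grad$elevation)

  wT <- rnorm(T_, 0, params@tempWeightSD)
  wT <- wT - mean(wT) + params@tempWeightMean   # aggregate support positive
  wN <- rnorm(T_, 0, params@nppWeightSD)
  wI <- abs(rnorm(T_, 0, params@nuisanceSD))
  scl <- exp(rnorm(T_, log(params@baselineRichness), 0.4))

  rich <- matrix(0L, n, T_,
                 dimnames = list(grad$site, sprintf("taxon%02d", seq_len(T_))))
  for (j in seq_len(T_)) {
    a <- rnorm(3L)
    u <- .zscore(a[1L] * ze + a[2L] * ze^2 + a[3L] * ze^3)
    m <- scl[j] * exp(wT[j] * zt + wN[j] * zn + wI[j] * u)
    rich[, j] <- .countNoise(m, params@dispersion)
  }
  communityDataset(grad, rich,
                   taxonData = data.frame(tempWeight = wT, nppWeight = wN,
                                          nuisanceWeight = wI, scale = scl))
}

#' Generate an NPP-driven community with heterogeneous subclade responses
#'
#' Emulates the decomposition of a pooled productivity--richness
#' relationship into idiosyncratic per-taxon relationships: each taxon
#' responds to NPP over only a sub-interval of the gradient and with its own
#' shape (increasing, decreasing, humped or flat, assigned cyclically), with
#' scales biased so that pooled richness still increases with NPP.
#'
#' @param params a \linkS4class{CommunityGenParams} with \code{nTaxa >= 8}.
#' @return a \linkS4class{CommunityDataset}; \code{rowData} records each
#'   taxon's shape and NPP support interval (\code{nppLow}, \code{nppHigh}),
#'   clipped to the realized NPP range.
#' @export
generateNppScenario <- function(params) {
  stopifnot(is(params, "CommunityGenParams"))
  validObject(params)
  if (params@nTaxa < 8L)
    stop("the NPP scenario needs at least 8 taxa")
  set.seed(params@seed)
  grad <- generateGradient(params)
  T_ <- params@nTaxa
  n <- params@nSites
  npp <- grad$npp
  rng <- range(npp)
  span <- diff(rng)
  zn <- .zscore(npp)
  shapes <- rep(c("increasing", "decreasing", "hump", "flat"),
                length.out = T_)
  rich <- matrix(0L, n, T_,
                 dimnames = list(grad$site, sprintf("taxon%02d", seq_len(T_))))
  lo <- hi <- numeric(T_)
  for (j in seq_len(T_)) {
    sh <- shapes[j]
    if (sh == "increasing") {
      b <- runif(1L, 0.7, 1.1)
      m <- exp(b * zn)
      scl <- params@baselineRichness * 1.6
      lo[j] <- rng[1L]; hi[j] <- rng[2L]
    } else if (sh == "decreasing") {
      b <- runif(1L, 0.4, 0.8)
      m <- exp(-b * zn)
      scl <- params@baselineRichness * 0.45
      lo[j] <- rng[1L]; hi[j] <- rng[2L]
    } else if (sh == "hump") {
      cj <- runif(1L, rng[1L] + 0.3 * span, rng[1L] + 0.7 * span)
      wj <- runif(1L, span / 6, span / 3)
      m <- exp(-(npp - cj)^2 / (2 * wj^2))
      scl <- params@baselineRichness * 0.8
      lo[j] <- max(rng[1L], cj - 2 * wj); hi[j] <- min(rng[2L], cj + 2 * wj)
    } else {
      m <- rep(1, n)
      scl <- params@baselineRichness * 0.6
      lo[j] <- rng[1L]; hi[j] <- rng[2L]
    }
    rich[, j] <- .countNoise(scl * m, params@dispersion)
  }
  communityDataset(grad, rich,
                   taxonData = data.frame(shape = shapes, nppLow = lo,
                                          nppHigh = hi))
}

#' Write a community dataset to the two-CSV on-disk format
#'
#' @param x a \linkS4class{CommunityDataset}.
#' @param sitesFile CSV of site predictors (one row per site).
#' @param richnessFile CSV site x taxon richness matrix (first column
#'   \code{site}).
#' @return invisibly, the paths written.
#' @seealso [readCommunityDataset()]
#' @export
writeCommunityDataset <- function(x, sitesFile, richnessFile) {
  stopifnot(is(x, "CommunityDataset"))
  write.csv(siteData(x), sitesFile, row.names = FALSE, quote = FALSE)
  rm <- data.frame(site = colnames(x), richnessMatrix(x), check.names = FALSE)
  write.csv(rm, richnessFile, row.names = FALSE, quote = FALSE)
  invisible(c(sites = sitesFile, richness = richnessFile))
}

#' Read a community dataset from the two-CSV on-disk format
#'
#' @param sitesFile,richnessFile paths written by [writeCommunityDataset()].
#' @return a \linkS4class{CommunityDataset}.
#' @export
readCommunityDataset <- function(sitesFile, richnessFile) {
  sites <- read.csv(sitesFile, stringsAsFactors = FALSE)
  rich <- read.csv(richnessFile, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(rich)[1L] != "site")
    stop("richness file must have a leading 'site' column")
  m <- as.matrix(rich[, -1L, drop = FALSE])
  rownames(m) <- rich$site
  communityDataset(sites, m)
}
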