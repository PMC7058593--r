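#' Construct a multi-taxa community dataset
#'
#' @param siteData data.frame of site-level variables (one row per site);
#'   must include every predictor later used in a coverage analysis and may
#'   not contain missing values.
#' @param richness site x taxon matrix of non-negative species counts with
#'   taxon column names; taxonomic groups are assumed to have disjoint
#'   species pools, so pooling is additive.
#' @param taxonData optional data.frame of per-taxon annotations (one row
#'   per taxon), stored as \code{rowData}.
#' @return a \linkS4class{CommunityDataset}.
#' @examples
#' sd <- data.frame(site = paste0("s", 1:4), temperature = c(20, 15, 10, 5))
#' rm <- matrix(rpois(8, 10), 4, 2, dimnames = list(sd$site, c("ants", "moths")))
#' communityDataset(sd, rm)
#' @export
communityDataset <- function(siteData, richness, taxonData = NULL) {
  richness <- as.matrix(richness)
  if (is.null(colnames(richness)))
    colnames(richness) <- paste0("taxon", seq_len(ncol(richness)))
  if (nrow(siteData) != nrow(richness))
    stop("siteData and richness must describe the same sites")
  cd <- DataFrame(siteData)
  if (!is.null(rownames(richness))) rownames(cd) <- rownames(richness)
  args <- list(assays = list(richness = t(richness)), colData = cd)
  if (!is.null(taxonData)) args$rowData <- DataFrame(taxonData)
  se <- do.call(SummarizedExperiment, args)
  new("CommunityDataset", se)
}

#' @describeIn CommunityDataset site x taxon richness matrix.
#' @param x a \code{CommunityDataset}.
#' @export
setMethod("richnessMatrix", "CommunityDataset", function(x) {
  t(assay(x, "richness"))
})

#' @describeIn CommunityDataset site-level variables as a data.frame.
#' @export
setMethod("siteData", "CommunityDataset", function(x) {
  as.data.frame(colData(x))
})

#' @describeIn CommunityDataset taxonomic group names.
#' @export
setMethod("taxonNames", "CommunityDataset", function(x) rownames(x))

#' Pool species richness over a subset of taxa
#'
#' Because taxon species pools are disjoint, the richness of a pooled
#' assemblage is the per-site sum over the selected taxa.
#'
#' @param x a \linkS4class{CommunityDataset}.
#' @param taxa non-empty character vector of taxon names.
#' @return named numeric vector of pooled richness, one value per site.
#' @export
setMethod("poolRichness", "CommunityDataset", function(x, taxa) {
  if (length(taxa) == 0L) stop("taxa subset must be non-empty")
  bad <- setdiff(taxa, taxonNames(x))
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  m <- assay(x, "richness")[taxa, , drop = FALSE]
  colSums(m)
})

## z-score; a zero-variance vector maps to zeros (with optional warning)
.zscore <- function(v, warn = FALSE, label = "variable") {
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    if (warn) warning(label, " has zero variance; standardized to zeros")
    return(rep(0, length(v)))
  }
  (v - mean(v)) / s
}

#' Standardized effect sizes by AICc-weighted all-subsets averaging
#'
#' The response and each predictor are z-scored, every additive linear model
#' over the \eqn{2^p} predictor subsets (including intercept-only) is fitted
#' by least squares, models are weighted by small-sample-corrected
#' information-criterion (AICc) weights, and each predictor's standardized
#' effect size is its weight-averaged coefficient, counted as 0 in models
#' that exclude it (full / shrinkage averaging). With
#' \code{averaging = "conditional"} the average runs only over models that
#' contain the predictor.
#'
#' A zero-variance response is standardized to zeros (all effect sizes 0,
#' with a warning) so that degenerate taxon subsets do not abort a coverage
#' curve; a zero-variance predictor is an error.
#'
#' @param richness per-site response vector (typically pooled richness).
#' @param predictors data.frame or matrix of site-level predictors.
#' @param averaging \code{"shrinkage"} (default) or \code{"conditional"}.
#' @param transform response transform: \code{"identity"} (default) or
#'   \code{"log1p"}, applied before z-scoring.
#' @return named numeric vector, one standardized effect size per predictor.
#' @examples
#' x <- rnorm(40)
#' standardizedEffectSizes(2 + 3 * x, data.frame(x = x))  # ~1
#' @export
standardizedEffectSizes <- function(richness, predictors,
                                    averaging = c("shrinkage", "conditional"),
                                    transform = c("identity", "log1p")) {
  averaging <- match.arg(averaging)
  transform <- match.arg(transform)
  X <- as.data.frame(predictors)
  p <- ncol(X)
  n <- length(richness)
  if (nrow(X) != n) stop("richness and predictors must cover the same sites")
  if (p < 1L) stop("at least one predictor is required")
  ## AICc of the largest model needs n - (p + 2) - 1 >= 1 residual dof
  if (n < p + 4L)
    stop("insufficient data: ", n, " sites cannot support ", p,
         " predictors under AICc")
  for (j in seq_len(p)) {
    if (sd(X[[j]]) == 0)
      stop("degenerate predictor '", names(X)[j], "' (zero variance)")
  }
  y <- if (transform == "log1p") log1p(richness) else as.numeric(richness)
  ys <- sd(y)
  if (!is.finite(ys) || ys == 0) {
    warning("response has zero variance; all effect sizes set to 0")
    return(setNames(rep(0, p), names(X)))
  }
  y <- (y - mean(y)) / ys
  Z <- vapply(X, .zscore, numeric(n))

  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  m <- nrow(subsets)                      # 2^p candidate models
  aicc <- numeric(m)
  betas <- matrix(0, m, p, dimnames = list(NULL, names(X)))
  for (i in seq_len(m)) {
    inc <- which(unlist(subsets[i, ]))
    M <- cbind(`(Intercept)` = 1, Z[, inc, drop = FALSE])
    fit <- stats::lm.fit(M, y)
    rss <- sum(fit$residuals^2)
    k <- length(inc) + 2L                 # coefficients + error variance
    ## log-likelihood up to a constant shared by all models
    aicc[i] <- n * log(max(rss, 1e-300) / n) + 2 * k +
      2 * k * (k + 1) / (n - k - 1)
    if (length(inc)) betas[i, inc] <- fit$coefficients[-1L]
  }
  d <- aicc - min(aicc)
  w <- exp(-0.5 * d)
  w <- w / sum(w)
  ses <- if (averaging == "shrinkage") {
    colSums(w * betas)
  } else {
    vapply(seq_len(p), function(j) {
      inm <- which(unlist(subsets[, j]))
      sum(w[inm] * betas[inm, j]) / sum(w[inm])
    }, numeric(1L))
  }
  setNames(as.numeric(ses), names(X))
}

#' Coverage curve: effect sizes as phylogenetic coverage grows
#'
#' For each number of pooled taxa \eqn{k = 1, \dots, T}, taxon combinations
#' are drawn (all \eqn{C(T,k)} when that is at most \code{nReps}, otherwise
#' \code{nReps} distinct random combinations), their pooled richness is
#' regressed on the predictors via [standardizedEffectSizes()], and the mean
#' and standard deviation of each predictor's standardized effect size
#' across combinations are recorded. At \eqn{k = T} a single combination
#' exists and the spread is 0 by construction; at \eqn{k = 1} the mean
#' equals the unweighted mean of per-taxon effect sizes (the single-taxon,
#' meta-analysis endpoint).
#'
#' @param x a \linkS4class{CommunityDataset}.
#' @param predictors character, column names of \code{siteData(x)} to use.
#' @param nReps maximum combinations per \eqn{k} (default 200).
#' @param seed RNG seed; the curve is deterministic given the seed.
#' @param ... passed to [standardizedEffectSizes()].
#' @return an \linkS4class{EffectSizeCurve}.
#' @export
setMethod("coverageCurve", "CommunityDataset",
  function(x, predictors, nReps = 200L, seed = 1L, ...) {
  if (nReps < 1L) stop("nReps must be >= 1")
  bad <- setdiff(predictors, colnames(colData(x)))
  if (length(bad)) stop("unknown predictors: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  taxa <- taxonNames(x)
  T_ <- length(taxa)
  pred <- siteData(x)[, predictors, drop = FALSE]
  rows <- vector("list", T_)
  for (k in seq_len(T_)) {
    nC <- choose(T_, k)
    combos <- if (nC <= nReps) {
      combn(T_, k, simplify = FALSE)
    } else {
      seen <- new.env(hash = TRUE)
      out <- vector("list", nReps)
      got <- 0L
      while (got < nReps) {
        cm <- sort(sample.int(T_, k))
        key <- paste(cm, collapse = ",")
        if (is.null(seen[[key]])) {
          assign(key, TRUE, envir = seen)
          got <- got + 1L
          out[[got]] <- cm
        }
      }
      out
    }
    ses <- matrix(NA_real_, length(combos), length(predictors),
                  dimnames = list(NULL, predictors))
    for (i in seq_along(combos)) {
      y <- poolRichness(x, taxa[combos[[i]]])
      ses[i, ] <- tryCatch(
        standardizedEffectSizes(y, pred, ...),
        error = function(e) stop("at k = ", k, ", combination {",
                                 paste(taxa[combos[[i]]], collapse = ", "),
                                 "}: ", conditionMessage(e), call. = FALSE))
    }
    sds <- if (nrow(ses) == 1L) rep(0, ncol(ses)) else apply(ses, 2L, sd)
    rows[[k]] <- data.frame(k = k, predictor = predictors,
                            meanSES = colMeans(ses), sdSES = sds,
                            nCombos = length(combos),
                            stringsAsFactors = FALSE)
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  new("EffectSizeCurve", curve = curve, nTaxa = T_,
      predictors = as.character(predictors), nReps = as.integer(nReps),
      seed = as.integer(seed))
})

#' @describeIn EffectSizeCurve the tidy curve table
#'   (\code{k, predictor, meanSES, sdSES, nCombos}).
#' @param x an \code{EffectSizeCurve}.
#' @export
setMethod("curveTable", "EffectSizeCurve", function(x) x@curve)

setMethod("show", "EffectSizeCurve", function(object) {
  cat(sprintf(
    "EffectSizeCurve: %d taxa, predictors %s, <=%d combinations per k\n",
    object@nTaxa, paste(object@predictors, collapse = ", "), object@nReps))
  top <- object@curve[object@curve$k %in% c(1L, object@nTaxa), ]
  print(top, row.names = FALSE)
})

setMethod("show", "CommunityDataset", function(object) {
  cat(sprintf("CommunityDataset: %d taxa x %d sites; predictors: %s\n",
              nrow(object), ncol(object),
              paste(colnames(colData(object)), collapse = ", ")))
})
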