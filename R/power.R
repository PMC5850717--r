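# Power-analysis harness: frequency-matched neutral cores, per-replicate
# scoring, ROC/power, and the allelic-class build-up summary.

#' Frequency-matched neutral core SNPs
#'
#' Selects, in each neutral replicate, the variants whose sampled frequency
#' lies within \code{tolerance} of the balanced equilibrium frequency
#' (relative band \code{target * (1 +/- tolerance)} by default, absolute
#' band \code{target +/- tolerance} with \code{relative = FALSE}).
#' Replicates with no qualifying variant are skipped and counted.
#'
#' @param results list of \linkS4class{SimResult} (neutral replicates).
#' @param targetFreq target (equilibrium) frequency, e.g. from
#'   \code{\link{equilibriumFrequency}}.
#' @param tolerance matching tolerance (default 0.10).
#' @param relative interpret the tolerance as relative (default) or
#'   absolute.
#' @param maxPerReplicate cap on matches per replicate, closest to the
#'   target first (ties by position); use 1 to mimic one matched core per
#'   replicate, Inf (default) to pool all matches.
#' @return A \code{data.frame} with columns \code{replicate, position,
#'   derivedCount, sampleSize, freq}; the number of skipped replicates is in
#'   attribute \code{"skipped"}.
#' @export
matchNeutralCores <- function(results, targetFreq, tolerance = 0.10,
                              relative = TRUE, maxPerReplicate = Inf) {
  stopifnot(targetFreq > 0, targetFreq < 1, tolerance >= 0)
  band <- if (relative) c(targetFreq * (1 - tolerance), targetFreq * (1 + tolerance))
          else c(targetFreq - tolerance, targetFreq + tolerance)
  rows <- vector("list", length(results))
  skipped <- 0L
  for (k in seq_along(results)) {
    sites <- simSites(results[[k]])
    f <- derivedCounts(sites) / sampleSizes(sites)
    hit <- which(f >= band[1L] & f <= band[2L])
    if (!length(hit)) { skipped <- skipped + 1L; next }
    if (is.finite(maxPerReplicate) && length(hit) > maxPerReplicate) {
      ord <- order(abs(f[hit] - targetFreq), positions(sites)[hit])
      hit <- hit[ord[seq_len(maxPerReplicate)]]
    }
    rows[[k]] <- data.frame(replicate = k, position = positions(sites)[hit],
                            derivedCount = derivedCounts(sites)[hit],
                            sampleSize = sampleSizes(sites)[hit],
                            freq = f[hit])
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(replicate = integer(), position = integer(),
                      derivedCount = integer(), sampleSize = integer(),
                      freq = numeric())
  if (skipped)
    message(skipped, " replicate(s) had no variant within the matching band")
  attr(out, "skipped") <- skipped
  out
}

#' Score a core SNP within a simulation replicate
#'
#' Builds the window spectrum around the given core position and returns the
#' beta score components together with Tajima's D on the same window.
#'
#' @param result a \linkS4class{SimResult}.
#' @param corePosition position of the core SNP (must be a segregating
#'   site of the replicate).
#' @param windowBp window span in bp (default 1000).
#' @param p similarity exponent (default 2).
#' @param folded score with the folded statistic.
#' @return One-row \code{data.frame}: \code{position, foldedFreq, thetaBeta,
#'   thetaW, beta, tajimasD, nWindowSNPs}.
#' @export
scoreSimulatedCore <- function(result, corePosition, windowBp = 1000, p = 2,
                               folded = FALSE) {
  sites <- simSites(result)
  i <- match(corePosition, positions(sites))
  if (is.na(i)) stop("position ", corePosition, " is not a segregating site")
  spec <- buildWindow(sites, i, windowBp = windowBp, folded = folded)
  sc <- betaScore(spec, p = p)
  cbind(data.frame(position = corePosition), sc[, c("foldedFreq", "thetaBeta",
                                                    "thetaW", "beta")],
        data.frame(tajimasD = tajimasD(spec), nWindowSNPs = sc$nWindowSNPs))
}

#' Empirical ROC and power at fixed false-positive rates
#'
#' Treats balanced-replicate scores as positives and neutral-replicate
#' scores as negatives, sweeps all thresholds into an empirical ROC (via
#' pROC), and reports power (true-positive rate) at the requested
#' false-positive rates as the highest TPR attainable with FPR at or below
#' each target.
#'
#' @param balancedScores numeric scores from balanced replicates.
#' @param neutralScores numeric scores from neutral replicates.
#' @param fprGrid false-positive rates to report power at (default 0.01 and
#'   0.05).
#' @return A list with \code{roc} (data.frame \code{fpr, tpr, threshold}),
#'   \code{auc}, and \code{power} (data.frame \code{fpr, power}).
#' @export
powerAnalysis <- function(balancedScores, neutralScores,
                          fprGrid = c(0.01, 0.05)) {
  b <- balancedScores[!is.na(balancedScores)]
  nu <- neutralScores[!is.na(neutralScores)]
  stopifnot(length(b) > 0, length(nu) > 0)
  if (length(unique(c(b, nu))) == 1L) {
    warning("degenerate constant scores: ROC is a coin flip")
    roc <- data.frame(fpr = c(0, 1), tpr = c(0, 1), threshold = c(Inf, -Inf))
    return(list(roc = roc, auc = 0.5,
                power = data.frame(fpr = fprGrid, power = fprGrid)))
  }
  r <- pROC::roc(response = c(rep(0L, length(nu)), rep(1L, length(b))),
                 predictor = c(nu, b), direction = "<", quiet = TRUE)
  roc <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                    threshold = r$thresholds)
  roc <- roc[order(roc$fpr, roc$tpr), ]
  rownames(roc) <- NULL
  power <- vapply(fprGrid, function(f) {
    ok <- roc$fpr <= f + 1e-12
    if (!any(ok)) 0 else max(roc$tpr[ok])
  }, numeric(1))
  list(roc = roc, auc = as.numeric(r$auc),
       power = data.frame(fpr = fprGrid, power = power))
}

#' Allelic-class build-up fraction around a core SNP
#'
#' Fraction of the SNPs in the window around \code{corePosition} whose
#' folded frequency lies within \code{band} of the core's folded frequency
#' (proportion scale), the footprint balancing selection leaves as linked
#' variants fix within their allelic class.
#'
#' @param result a \linkS4class{SimResult}.
#' @param corePosition core SNP position (a segregating site).
#' @param windowBp window span in bp (default 1000).
#' @param band folded-frequency half-width (default 0.05).
#' @return The fraction in [0, 1], or NA for an empty window.
#' @export
classBuildupFraction <- function(result, corePosition, windowBp = 1000,
                                 band = 0.05) {
  sites <- simSites(result)
  i <- match(corePosition, positions(sites))
  if (is.na(i)) stop("position ", corePosition, " is not a segregating site")
  pos <- positions(sites)
  b <- windowBounds(pos[i], windowBp)
  j <- which(pos >= b[1L] & pos <= b[2L])
  j <- j[j != i]
  if (!length(j)) return(NA_real_)
  n <- sampleSizes(sites)
  g <- foldCount(derivedCounts(sites), n) / n
  mean(abs(g[j] - g[i]) <= band)
}
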