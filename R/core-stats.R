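# The frequency-similarity measure and the theta estimators behind beta.
#
# For a core SNP at derived count f0 out of n chromosomes, with folded count
# g(f) = min(f, n - f) and maximum possible folded difference
# m = max(g(f0), n/2 - g(f0)), the similarity of a second SNP at count fi is
#   d_i = ((m - |g(f0) - g(fi)|) / m)^p,
# ranging from 0 (maximum folded difference from the core) to 1 (identical
# folded frequency).  beta = theta_beta - theta_w, where theta_beta is the
# d-weighted average of the per-class estimators theta_i = i * S_i and
# theta_w is Watterson's estimator; the d-weight denominator runs over all
# frequency classes 1..n-1 whether occupied or not, so theta_beta is a true
# weighted average of per-class estimators.

#' Folded allele count
#'
#' @param count allele count(s), 0..n.
#' @param n sample size(s) (chromosomes), recycled.
#' @return \code{pmin(count, n - count)}, the minor-allele count.
#' @examples
#' foldCount(75, 100)  # 25
#' @export
foldCount <- function(count, n) {
  if (any(count < 0 | count > n, na.rm = TRUE))
    stop("'count' must lie in [0, n]")
  pmin(count, n - count)
}

#' Maximum possible folded frequency difference from a core SNP
#'
#' On the count scale: \code{max(g0, n/2 - g0)} for a core folded count g0.
#' For odd n, n/2 is used as a real number (no rounding).
#'
#' @param coreFolded folded count of the core SNP (1..n/2).
#' @param n sample size (chromosomes).
#' @return The maximum folded difference m, on the count scale.
#' @examples
#' maxFoldedDiff(10, 100)  # 40
#' @export
maxFoldedDiff <- function(coreFolded, n) {
  if (any(coreFolded < 1 | coreFolded > n / 2, na.rm = TRUE))
    stop("'coreFolded' must lie in [1, n/2]")
  pmax(coreFolded, n / 2 - coreFolded)
}

#' Frequency similarity between a core SNP and other SNPs
#'
#' Computes \code{d = ((m - |g(f0) - g(fi)|)/m)^p}, the similarity in folded
#' frequency between the core SNP and each site, where m is the maximum
#' possible folded difference from the core.  d is 1 when the folded
#' frequencies are identical and 0 at the maximum possible difference, and is
#' symmetric in the derived/ancestral labelling of either site.
#'
#' When all sites share the core's sample size the computation is on the
#' count scale.  If \code{nSite} differs from \code{n} for any site, folded
#' frequencies are put on the proportion scale (g/n, with m likewise
#' proportional), so sites genotyped in different numbers of chromosomes
#' remain comparable.
#'
#' @param coreCount derived (unfolded) count of the core SNP.
#' @param siteCount derived count(s) of the other site(s); vectorised.
#' @param n core sample size (chromosomes).
#' @param p scaling exponent (> 0); default 2.
#' @param nSite per-site sample size(s), defaulting to \code{n}.
#' @return Numeric vector of similarities in [0, 1].
#' @examples
#' freqSimilarity(50, 25, 100, p = 2)  # 0.25
#' @export
freqSimilarity <- function(coreCount, siteCount, n, p = 2, nSite = n) {
  stopifnot(length(coreCount) == 1L, length(n) == 1L, p > 0)
  if (coreCount < 1 || coreCount > n - 1)
    stop("core SNP must be polymorphic (count in 1..n-1)")
  if (any(siteCount < 1 | siteCount > nSite - 1))
    stop("sites must be polymorphic (count in 1..n-1)")
  g0 <- foldCount(coreCount, n)
  gi <- foldCount(siteCount, nSite)
  if (all(nSite == n)) {
    m <- maxFoldedDiff(g0, n)
    frac <- (m - abs(g0 - gi)) / m
  } else {
    x0 <- g0 / n
    xi <- gi / nSite
    m <- max(x0, 0.5 - x0)
    frac <- (m - abs(x0 - xi)) / m
  }
  pmax(frac, 0)^p
}

# nth harmonic number sum_{i=1}^{k} 1/i (a_1 of Watterson/Tajima).
harmonicNumber <- function(k) {
  if (k < 1L) return(0)
  sum(1 / seq_len(k))
}

#' @describeIn thetaWatterson Watterson's estimator on a window spectrum:
#'   total segregating sites divided by the harmonic number a_{n-1}.  The
#'   estimator is invariant to folding.  Returns 0 for an empty window.
#' @param x a \linkS4class{WindowSpectrum}.
#' @export
setMethod("thetaWatterson", "WindowSpectrum", function(x, ...) {
  sum(x@S) / harmonicNumber(x@n - 1L)
})

# d-weights of every frequency class against the spectrum's core, on the
# class grid actually used by the spectrum (unfolded 1..n-1, folded
# 1..floor(n/2)).
classSimilarities <- function(x, p) {
  n <- x@n
  if (x@folded) {
    i <- seq_len(n %/% 2L)
    g0 <- x@coreCount             # already folded
  } else {
    i <- seq_len(n - 1L)
    g0 <- foldCount(x@coreCount, n)
  }
  gi <- foldCount(i, n)           # identity for folded classes (i <= n/2)
  m <- maxFoldedDiff(g0, n)
  pmax((m - abs(g0 - gi)) / m, 0)^p
}

#' @describeIn thetaBeta similarity-weighted theta estimator.  Unfolded:
#'   \code{sum(i * d_i * S_i) / sum(d_i)} with the denominator over all
#'   classes 1..n-1.  Folded: the per-folded-class unbiased estimators
#'   \code{S*_i (1 + [i == n - i]) / (1/i + 1/(n - i))} are averaged with the
#'   same d-weights over classes 1..floor(n/2).  Returns 0 for an empty
#'   window.
#' @param x a \linkS4class{WindowSpectrum}.
#' @param p similarity exponent.
#' @export
setMethod("thetaBeta", "WindowSpectrum", function(x, p = 2, ...) {
  d <- classSimilarities(x, p)
  n <- x@n
  if (x@folded) {
    i <- seq_len(n %/% 2L)
    thetaI <- x@S * (1 + (i == n - i)) / (1 / i + 1 / (n - i))
  } else {
    i <- seq_len(n - 1L)
    thetaI <- x@S * i
  }
  sum(d * thetaI) / sum(d)
})

#' @describeIn betaScore the balancing-selection statistic
#'   beta = theta_beta - theta_w on a window spectrum.  An empty window
#'   yields a missing (NA) beta so SNP deserts do not masquerade as scores.
#' @param x a \linkS4class{WindowSpectrum}.
#' @param p similarity exponent.
#' @return A one-row \code{data.frame} with columns \code{foldedFreq} (core
#'   folded frequency as a proportion), \code{thetaBeta}, \code{thetaW},
#'   \code{beta} and \code{nWindowSNPs}.
#' @export
setMethod("betaScore", "WindowSpectrum", function(x, p = 2, ...) {
  tw <- thetaWatterson(x)
  tb <- thetaBeta(x, p = p)
  nSNP <- sum(x@S)
  g0 <- if (x@folded) x@coreCount else foldCount(x@coreCount, x@n)
  data.frame(foldedFreq = g0 / x@n,
             thetaBeta = tb, thetaW = tw,
             beta = if (nSNP > 0) tb - tw else NA_real_,
             nWindowSNPs = nSNP)
})

#' @describeIn tajimasD Tajima's D on a window spectrum, using the standard
#'   beta-coalescent-free variance normalisation (Tajima 1989 constants).
#'   Works on folded spectra too since i*(n-i) is fold-invariant.  Returns NA
#'   when the window holds no SNPs.
#' @param x a \linkS4class{WindowSpectrum}.
#' @export
setMethod("tajimasD", "WindowSpectrum", function(x, ...) {
  n <- as.numeric(x@n)
  Stot <- sum(x@S)
  if (Stot < 1) return(NA_real_)
  if (x@folded) {
    i <- seq_len(x@n %/% 2L)
  } else {
    i <- seq_len(x@n - 1L)
  }
  piHat <- sum(x@S * i * (n - i)) * 2 / (n * (n - 1))
  a1 <- harmonicNumber(x@n - 1L)
  a2 <- sum(1 / seq_len(x@n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piHat - Stot / a1) / sqrt(e1 * Stot + e2 * Stot * (Stot - 1))
})
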