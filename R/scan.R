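# Sliding-window scan: build a spectrum around each core SNP, score it, and
# call shared top-percentile signals across populations.

#' Construct a ScanConfig
#'
#' @param windowBp total window span in bp (default 1000).
#' @param p similarity exponent (default 2).
#' @param minFoldedFreq minimum core folded frequency, as a proportion
#'   (default 0.15).
#' @param percentile top fraction flagged per population (default 0.01).
#' @param foldMode \code{"unfolded"} (default) or \code{"folded"}.
#' @param sharingFraction fraction of populations required for a shared call
#'   (default 0.5).
#' @return A \linkS4class{ScanConfig}.
#' @export
scanConfig <- function(windowBp = 1000, p = 2, minFoldedFreq = 0.15,
                       percentile = 0.01, foldMode = c("unfolded", "folded"),
                       sharingFraction = 0.5) {
  new("ScanConfig", windowBp = windowBp, p = p, minFoldedFreq = minFoldedFreq,
      percentile = percentile, foldMode = match.arg(foldMode),
      sharingFraction = sharingFraction)
}

# Integer positions covered by the half-open window
# [centre - w/2, centre + w/2): lo..hi inclusive.
windowBounds <- function(centre, windowBp) {
  a <- centre - windowBp / 2
  b <- centre + windowBp / 2
  c(lo = ceiling(a), hi = ceiling(b) - 1)
}

#' Window spectrum around one core SNP
#'
#' Collects the sites whose position falls in the half-open window
#' \code{[pos - windowBp/2, pos + windowBp/2)} around the core SNP, excluding
#' the core site itself, and tabulates them into a
#' \linkS4class{WindowSpectrum}.  All sites in the window must share the
#' core's sample size (see \code{\link{scanPopulation}} for the mixed-n
#' path).
#'
#' @param sites a \linkS4class{SiteCounts} object, position-sorted.
#' @param coreIndex index of the core SNP within \code{sites}.
#' @param windowBp total window span in bp.
#' @param folded build a folded spectrum.
#' @return A \linkS4class{WindowSpectrum}.
#' @export
buildWindow <- function(sites, coreIndex, windowBp = 1000,
                        folded = isFolded(sites)) {
  stopifnot(is(sites, "SiteCounts"), coreIndex >= 1, coreIndex <= length(sites))
  pos <- positions(sites)
  ctg <- contigs(sites)
  b <- windowBounds(pos[coreIndex], windowBp)
  inWin <- which(ctg == ctg[coreIndex] & pos >= b["lo"] & pos <= b["hi"])
  inWin <- setdiff(inWin, coreIndex)
  spectrumFromSites(sites[inWin], coreCount = derivedCounts(sites)[coreIndex],
                    n = sampleSizes(sites)[coreIndex], folded = folded)
}

# Score one core against explicit neighbour vectors; handles mixed sample
# sizes by per-site contributions (similarities on the proportion scale
# against the core's class grid; Watterson term sum_j 1/a_{n_j - 1}).
scoreCoreMixedN <- function(coreCnt, coreN, cnt, nSite, p, folded) {
  aInv <- vapply(nSite, function(n) 1 / harmonicNumber(n - 1L), numeric(1))
  tw <- sum(aInv)
  spec0 <- new("WindowSpectrum", n = as.integer(coreN),
               S = numeric(if (folded) coreN %/% 2L else coreN - 1L),
               coreCount = as.integer(if (folded) foldCount(coreCnt, coreN) else coreCnt),
               folded = folded)
  den <- sum(classSimilarities(spec0, p))
  if (length(cnt) == 0L) {
    g0 <- foldCount(coreCnt, coreN)
    return(data.frame(foldedFreq = g0 / coreN, thetaBeta = 0, thetaW = 0,
                      beta = NA_real_, nWindowSNPs = 0))
  }
  d <- freqSimilarity(coreCnt, cnt, coreN, p = p, nSite = nSite)
  if (folded) {
    g <- foldCount(cnt, nSite)
    thetaJ <- (1 + (g == nSite - g)) / (1 / g + 1 / (nSite - g))
  } else {
    thetaJ <- cnt
  }
  tb <- sum(d * thetaJ) / den
  g0 <- foldCount(coreCnt, coreN)
  data.frame(foldedFreq = g0 / coreN, thetaBeta = tb, thetaW = tw,
             beta = tb - tw, nWindowSNPs = length(cnt))
}

#' Scan one population's sites
#'
#' Computes a beta score in a window of \code{windowBp} bp centred on every
#' polymorphic site whose folded frequency reaches \code{minFoldedFreq}
#' (the per-population core filter; set \code{applyFreqFilter = FALSE} when
#' the any-population rule is applied upstream, see
#' \code{\link{sharedFrequencyFilter}}).  With a mask, the default
#' window-level policy drops a core SNP whenever any base of its window is
#' masked (mirroring strict-mask filtering of windows containing any
#' poor-quality base); \code{maskLevel = "site"} relaxes this to dropping
#' masked sites only.
#'
#' @param sites a \linkS4class{SiteCounts} object.
#' @param config a \linkS4class{ScanConfig}.
#' @param mask optional \code{GRanges} from \code{\link{readMaskBed}}.
#' @param maskLevel \code{"window"} (default) or \code{"site"}.
#' @param applyFreqFilter apply the core folded-frequency filter.
#' @return A \code{data.frame} with one row per scored core SNP: columns
#'   \code{contig, position, foldedFreq, thetaBeta, thetaW, beta,
#'   nWindowSNPs}.  Empty windows give \code{beta = NA}.
#' @export
scanPopulation <- function(sites, config = scanConfig(), mask = NULL,
                           maskLevel = c("window", "site"),
                           applyFreqFilter = TRUE) {
  stopifnot(is(sites, "SiteCounts"), is(config, "ScanConfig"))
  maskLevel <- match.arg(maskLevel)
  folded <- config@foldMode == "folded"
  if (folded && !isFolded(sites)) sites <- foldSites(sites)
  if (!folded && isFolded(sites))
    stop("unfolded scan requested but counts are folded")
  if (!is.null(mask) && maskLevel == "site")
    sites <- applyMask(sites, mask)

  pos <- positions(sites); cnt <- derivedCounts(sites)
  n <- sampleSizes(sites); ctg <- contigs(sites)
  gFreq <- foldCount(cnt, n) / n
  isCore <- if (applyFreqFilter) gFreq >= config@minFoldedFreq else rep(TRUE, length(sites))

  if (!is.null(mask) && maskLevel == "window" && any(isCore)) {
    b <- vapply(pos[isCore], windowBounds, numeric(2), windowBp = config@windowBp)
    winGR <- GenomicRanges::GRanges(ctg[isCore],
                                    IRanges::IRanges(b["lo", ], b["hi", ]))
    isCore[isCore] <- !IRanges::overlapsAny(winGR, mask)
  }

  uniformN <- length(unique(n)) == 1L
  rows <- vector("list", sum(isCore))
  k <- 0L
  for (i in which(isCore)) {
    b <- windowBounds(pos[i], config@windowBp)
    j <- which(ctg == ctg[i] & pos >= b[1L] & pos <= b[2L])
    j <- j[j != i]
    k <- k + 1L
    sc <- if (uniformN) {
      spec <- spectrumFromSites(sites[j], coreCount = cnt[i], n = n[i],
                                folded = folded)
      betaScore(spec, p = config@p)
    } else {
      scoreCoreMixedN(cnt[i], n[i], cnt[j], n[j], config@p, folded)
    }
    rows[[k]] <- cbind(data.frame(contig = ctg[i], position = pos[i],
                                  stringsAsFactors = FALSE), sc)
  }
  if (!k)
    return(data.frame(contig = character(), position = integer(),
                      foldedFreq = numeric(), thetaBeta = numeric(),
                      thetaW = numeric(), beta = numeric(),
                      nWindowSNPs = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sites reaching a folded frequency in at least one population
#'
#' Implements the any-population core filter: a site survives if its folded
#' frequency reaches \code{minFoldedFreq} in at least one population.
#'
#' @param countsList named list of \linkS4class{SiteCounts}, one per
#'   population.
#' @param minFoldedFreq folded-frequency threshold (proportion).
#' @return Character vector of surviving site keys (\code{"contig:position"}).
#' @export
sharedFrequencyFilter <- function(countsList, minFoldedFreq = 0.15) {
  stopifnot(length(countsList) >= 1L)
  keys <- lapply(countsList, function(s) {
    g <- foldCount(derivedCounts(s), sampleSizes(s)) / sampleSizes(s)
    paste0(contigs(s), ":", positions(s))[g >= minFoldedFreq]
  })
  sort(unique(unlist(keys)))
}

#' Flag per-population top scores and call shared signals
#'
#' Within each population the top \code{ceiling(percentile * N)} scores are
#' flagged (N = scored sites with a non-missing beta; ties broken by
#' position for determinism).  A site is a shared signal when it is flagged
#' in at least \code{ceiling(sharingFraction * P)} of the P populations.
#'
#' @param scoresList a score \code{data.frame} or named list of them (one
#'   per population), as returned by \code{\link{scanPopulation}}.
#' @param percentile top fraction flagged (default 0.01).
#' @param sharingFraction fraction of populations required (default 0.5).
#' @return A list with \code{flagged} (per-population character vectors of
#'   \code{"contig:position"} keys), \code{shared} (keys flagged in enough
#'   populations, sorted), and \code{minPopulations}.
#' @export
callTopSites <- function(scoresList, percentile = 0.01, sharingFraction = 0.5) {
  if (is.data.frame(scoresList)) scoresList <- list(pop1 = scoresList)
  stopifnot(length(scoresList) >= 1L, percentile > 0, percentile < 1)
  flagged <- lapply(scoresList, function(df) {
    ok <- !is.na(df$beta)
    df <- df[ok, , drop = FALSE]
    nScores <- nrow(df)
    if (nScores == 0L) return(character())
    k <- ceiling(percentile * nScores)
    if (nScores < 1 / percentile)
      warning("fewer scores (", nScores, ") than 1/percentile; using empirical top-",
              k, " sites")
    ord <- order(-df$beta, df$contig, df$position, method = "radix")
    top <- df[ord[seq_len(k)], , drop = FALSE]
    paste0(top$contig, ":", top$position)
  })
  P <- length(scoresList)
  minPop <- ceiling(sharingFraction * P)
  tab <- table(unlist(flagged))
  shared <- sort(names(tab)[tab >= minPop])
  list(flagged = flagged, shared = shared, minPopulations = minPop)
}

#' Empirical beta cutoff from neutral-simulation scores
#'
#' Type-7 interpolated empirical quantile of a neutral beta score
#' distribution, e.g. the 99.95th percentile used to calibrate genome-wide
#' significance.
#'
#' @param neutralScores numeric vector of beta scores from neutral
#'   replicates (NAs dropped).
#' @param quantile probability (default 0.9995).
#' @return The beta cutoff.
#' @export
neutralThreshold <- function(neutralScores, quantile = 0.9995) {
  neutralScores <- neutralScores[!is.na(neutralScores)]
  if (!length(neutralScores)) stop("no neutral scores supplied")
  unname(stats::quantile(neutralScores, probs = quantile, type = 7))
}
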