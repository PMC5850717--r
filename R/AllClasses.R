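# S4 containers for the scan and simulation machinery.

#' SiteCounts: per-site allele counts along a contig
#'
#' Holds one polymorphic site per element: 1-based position, derived (or
#' minor, if folded) allele count, and the number of sampled chromosomes at
#' that site.  Positions must be strictly increasing within each contig and
#' every site must be polymorphic (count in 1..n-1), because all downstream
#' estimators sum over segregating frequency classes.
#'
#' @slot contig character vector of contig names.
#' @slot position integer vector of 1-based positions.
#' @slot derivedCount integer vector; derived-allele counts, or minor-allele
#'   counts when \code{folded} is \code{TRUE}.
#' @slot sampleSize integer vector; chromosomes sampled at each site.
#' @slot folded single logical; whether counts are folded (minor-allele).
#' @exportClass SiteCounts
setClass("SiteCounts",
  representation(
    contig = "character",
    position = "integer",
    derivedCount = "integer",
    sampleSize = "integer",
    folded = "logical"
  ),
  prototype(contig = character(), position = integer(),
            derivedCount = integer(), sampleSize = integer(), folded = FALSE)
)

setValidity("SiteCounts", function(object) {
  msg <- character()
  len <- length(object@position)
  if (length(object@contig) != len || length(object@derivedCount) != len ||
      length(object@sampleSize) != len)
    msg <- c(msg, "slots contig, position, derivedCount, sampleSize must have equal length")
  if (length(object@folded) != 1L || is.na(object@folded))
    msg <- c(msg, "'folded' must be TRUE or FALSE")
  if (len > 0L && length(msg) == 0L) {
    if (anyNA(object@position) || anyNA(object@derivedCount) || anyNA(object@sampleSize))
      msg <- c(msg, "NA values are not allowed")
    else {
      if (any(object@position < 1L))
        msg <- c(msg, "positions must be >= 1")
      if (any(object@sampleSize < 2L))
        msg <- c(msg, "sampleSize must be >= 2")
      bad <- object@derivedCount < 1L | object@derivedCount > object@sampleSize - 1L
      if (any(bad))
        msg <- c(msg, sprintf("%d site(s) are monomorphic or out of range (counts must lie in 1..n-1)", sum(bad)))
      if (isTRUE(object@folded) &&
          any(object@derivedCount > object@sampleSize / 2))
        msg <- c(msg, "folded counts must not exceed n/2")
      ord <- order(object@contig, method = "radix")
      pos <- split(object@position, object@contig)
      if (any(vapply(pos, function(p) is.unsorted(p, strictly = TRUE), logical(1))))
        msg <- c(msg, "positions must be strictly increasing within each contig")
    }
  }
  if (length(msg)) msg else TRUE
})

#' WindowSpectrum: frequency-class SNP counts around a core SNP
#'
#' The site frequency spectrum of a window centred on a core SNP, with the
#' core site itself excluded.  \code{S[i]} counts SNPs whose derived allele
#' was observed \code{i} times among \code{n} chromosomes (unfolded), or
#' whose minor allele was observed \code{i} times, \code{i = 1..floor(n/2)}
#' (folded).
#'
#' @slot n integer; number of sampled chromosomes.
#' @slot S numeric vector of class counts, length \code{n - 1} (unfolded) or
#'   \code{floor(n / 2)} (folded).
#' @slot coreCount integer; derived (or folded) count of the core SNP.
#' @slot folded single logical.
#' @exportClass WindowSpectrum
setClass("WindowSpectrum",
  representation(n = "integer", S = "numeric", coreCount = "integer",
                 folded = "logical"),
  prototype(n = 2L, S = 0, coreCount = 1L, folded = FALSE)
)

setValidity("WindowSpectrum", function(object) {
  msg <- character()
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 2L)
    msg <- c(msg, "'n' must be a single integer >= 2")
  expLen <- if (isTRUE(object@folded)) n %/% 2L else n - 1L
  if (length(object@S) != expLen)
    msg <- c(msg, sprintf("'S' must have length %d for n = %d (%s)",
                          expLen, n, if (isTRUE(object@folded)) "folded" else "unfolded"))
  if (anyNA(object@S) || any(object@S < 0))
    msg <- c(msg, "'S' must be non-negative")
  cc <- object@coreCount
  if (length(cc) != 1L || is.na(cc) || cc < 1L || cc > expLen)
    msg <- c(msg, sprintf("'coreCount' must lie in 1..%d", expLen))
  if (length(msg)) msg else TRUE
})

#' ScanConfig: parameters of the sliding-window scan
#'
#' @slot windowBp total window span in base pairs (default 1000).
#' @slot p similarity scaling exponent (default 2).
#' @slot minFoldedFreq minimum folded frequency (proportion) a core SNP must
#'   reach, in at least one population, to be scored (default 0.15).
#' @slot percentile top fraction of scores flagged per population
#'   (default 0.01).
#' @slot foldMode \code{"unfolded"} or \code{"folded"}.
#' @slot sharingFraction fraction of populations in which a site must be
#'   flagged to be called shared (default 0.5).
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(windowBp = "numeric", p = "numeric", minFoldedFreq = "numeric",
                 percentile = "numeric", foldMode = "character",
                 sharingFraction = "numeric"),
  prototype(windowBp = 1000, p = 2, minFoldedFreq = 0.15, percentile = 0.01,
            foldMode = "unfolded", sharingFraction = 0.5)
)

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (object@windowBp < 2) msg <- c(msg, "'windowBp' must be >= 2")
  if (object@p <= 0) msg <- c(msg, "'p' must be > 0")
  if (object@percentile <= 0 || object@percentile >= 1)
    msg <- c(msg, "'percentile' must lie in (0, 1)")
  if (object@minFoldedFreq < 0 || object@minFoldedFreq > 0.5)
    msg <- c(msg, "'minFoldedFreq' must lie in [0, 0.5]")
  if (!object@foldMode %in% c("unfolded", "folded"))
    msg <- c(msg, "'foldMode' must be 'unfolded' or 'folded'")
  if (object@sharingFraction <= 0 || object@sharingFraction > 1)
    msg <- c(msg, "'sharingFraction' must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SimConfig: Wright-Fisher / coalescent simulation parameters
#'
#' Parameters are stated on the unscaled (natural) scale; \code{rescaleQ}
#' applies the usual population-genetic rescaling at run time (Ne and all
#' generation counts divided by Q; mu, r and s multiplied by Q), which keeps
#' theta = 4*Ne*mu, rho = 4*Ne*r and 2*Ne*s invariant.
#'
#' @slot Ne diploid effective population size (default 10000).
#' @slot mu per-bp per-generation mutation rate (default 2.5e-8).
#' @slot r per-bp per-generation recombination rate (default 2.5e-8).
#' @slot L region length in bp (default 10000).
#' @slot burnIn burn-in generations before the species split (default 1e5).
#' @slot splitGens generations simulated after the split (default 2.5e5).
#' @slot tSel generations before sampling at which the balanced variant is
#'   introduced at the region centre (default 2.5e5, i.e. at the split).
#' @slot h overdominance coefficient; heterozygote fitness is 1 + h*s.
#' @slot s selection coefficient; derived homozygote fitness is 1 + s.
#' @slot nSample chromosomes sampled from the focal population (default 100).
#' @slot rescaleQ integer rescaling factor (default 1).
#' @slot seed RNG seed (NA = draw from the session RNG).
#' @slot maxRestarts restart budget when conditioning on maintenance of the
#'   balanced allele (default 10000).
#' @slot outgroup logical; also simulate the outgroup (chimpanzee-analog)
#'   population and call substitutions against one sampled chromosome.
#' @slot popSchedule optional piecewise population-size schedule (list of
#'   \code{c(generation, size)} pairs); reserved hook, not used by the
#'   equilibrium-model simulator.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(Ne = "numeric", mu = "numeric", r = "numeric", L = "numeric",
                 burnIn = "numeric", splitGens = "numeric", tSel = "numeric",
                 h = "numeric", s = "numeric", nSample = "integer",
                 rescaleQ = "numeric", seed = "numeric", maxRestarts = "numeric",
                 outgroup = "logical", popSchedule = "list"),
  prototype(Ne = 10000, mu = 2.5e-8, r = 2.5e-8, L = 10000, burnIn = 1e5,
            splitGens = 2.5e5, tSel = 2.5e5, h = 1.5, s = 1e-2, nSample = 100L,
            rescaleQ = 1, seed = NA_real_, maxRestarts = 10000, outgroup = TRUE,
            popSchedule = list())
)

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(Ne = object@Ne, mu = object@mu, r = object@r, L = object@L,
           rescaleQ = object@rescaleQ)
  if (any(is.na(pos)) || any(pos <= 0))
    msg <- c(msg, "Ne, mu, r, L and rescaleQ must be positive")
  if (object@r < 0 || object@mu <= 0) msg <- c(msg, "rates must be non-negative")
  if (object@burnIn < 0 || object@splitGens < 0 || object@tSel < 0)
    msg <- c(msg, "generation counts must be non-negative")
  if (object@tSel > object@splitGens)
    msg <- c(msg, "'tSel' cannot exceed 'splitGens' (variant is introduced after the split)")
  if (object@nSample < 2L) msg <- c(msg, "'nSample' must be >= 2")
  if (object@nSample > 2 * object@Ne / object@rescaleQ)
    msg <- c(msg, "'nSample' exceeds the (rescaled) number of chromosomes")
  if (object@maxRestarts < 1) msg <- c(msg, "'maxRestarts' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SimResult: output of one simulation replicate
#'
#' @slot sites \linkS4class{SiteCounts} of sites segregating in the sample.
#' @slot substitutions numeric positions of fixed differences relative to the
#'   single outgroup chromosome (empty when no outgroup was simulated).
#' @slot balancedPosition position of the balanced variant (NA for neutral
#'   replicates).
#' @slot balancedCount derived count of the balanced variant in the sample
#'   (NA for neutral replicates).
#' @slot restarts number of restarts used to condition on maintenance.
#' @slot seed RNG seed the replicate was generated with.
#' @exportClass SimResult
setClass("SimResult",
  representation(sites = "SiteCounts", substitutions = "numeric",
                 balancedPosition = "numeric", balancedCount = "numeric",
                 restarts = "numeric", seed = "numeric"),
  prototype(substitutions = numeric(), balancedPosition = NA_real_,
            balancedCount = NA_real_, restarts = 0, seed = NA_real_)
)
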