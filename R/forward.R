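# Forward-simulation interface: configuration, the overdominance
# equilibrium, and the Rcpp Wright-Fisher backend.

#' Construct a SimConfig
#'
#' Defaults reproduce the human-parameter study conditions: Ne = 10,000
#' diploids, mu = r = 2.5e-8 per bp per generation, 10-kb regions, a
#' 100,000-generation burn-in, a species split followed by 250,000
#' generations, the balanced variant introduced at the split (tSel =
#' 250,000; use 100,000 for more recent selection), s = 0.01, h = 1.5
#' (equilibrium frequency 0.75), and 100 sampled chromosomes plus one
#' outgroup chromosome.
#'
#' @param Ne,mu,r,L,burnIn,splitGens,tSel,h,s,nSample,rescaleQ,seed,maxRestarts,outgroup,popSchedule
#'   see \linkS4class{SimConfig}.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(Ne = 10000, mu = 2.5e-8, r = 2.5e-8, L = 10000,
                      burnIn = 1e5, splitGens = 2.5e5, tSel = 2.5e5,
                      h = 1.5, s = 1e-2, nSample = 100L, rescaleQ = 1,
                      seed = NA, maxRestarts = 10000, outgroup = TRUE,
                      popSchedule = list()) {
  new("SimConfig", Ne = Ne, mu = mu, r = r, L = L, burnIn = burnIn,
      splitGens = splitGens, tSel = tSel, h = h, s = s,
      nSample = as.integer(nSample), rescaleQ = rescaleQ,
      seed = as.numeric(seed), maxRestarts = maxRestarts,
      outgroup = isTRUE(outgroup), popSchedule = popSchedule)
}

#' Deterministic equilibrium frequency under overdominance
#'
#' For genotype fitnesses 1 (ancestral homozygote), 1 + h*s (heterozygote)
#' and 1 + s (derived homozygote), the deterministic allele-frequency change
#' vanishes at the interior point q* = h / (2h - 1), which is stable exactly
#' when the heterozygote is fittest (h*s > 0 and h*s > s; a protected
#' polymorphism).  This requires h > 1 with s > 0, or h < 0 with s < 0.
#'
#' @param h overdominance coefficient.
#' @param s selection coefficient; if supplied, the protected-polymorphism
#'   condition is checked against it.
#' @return The stable equilibrium frequency of the derived allele.
#' @examples
#' equilibriumFrequency(1.5)        # 0.75
#' equilibriumFrequency(-0.5, -0.01) # 0.25
#' @export
equilibriumFrequency <- function(h, s = NULL) {
  stopifnot(length(h) == 1L, is.finite(h))
  if (!(h > 1 || h < 0))
    stop("no stable interior equilibrium: need h > 1 (with s > 0) or h < 0 (with s < 0)")
  if (!is.null(s)) {
    if (!(h * s > 0 && h * s > s))
      stop("fitness scheme does not admit a protected polymorphism: ",
           "need h*s > 0 and h*s > s (heterozygote fittest)")
  }
  h / (2 * h - 1)
}

#' Overdominance coefficient for a target equilibrium frequency
#'
#' Inverse of \code{\link{equilibriumFrequency}}: h = q / (2q - 1).
#' Undefined at q = 0.5, where h diverges (use a large h, e.g. 100, to
#' place the equilibrium near 0.5).
#'
#' @param q target equilibrium frequency in (0, 1), not 0.5.
#' @return The overdominance coefficient h.
#' @export
hForEquilibrium <- function(q) {
  stopifnot(length(q) == 1L, q > 0, q < 1)
  if (abs(q - 0.5) < 1e-12)
    stop("h diverges at q = 0.5; use a large h (e.g. 100 gives q ~ 0.5025)")
  q / (2 * q - 1)
}

# Apply the rescaling factor Q: Ne and generation counts shrink, rates and
# s grow, keeping theta, rho and 2*Ne*s invariant.
rescaledParams <- function(config) {
  Q <- config@rescaleQ
  list(Ne = as.integer(round(config@Ne / Q)),
       mu = config@mu * Q, r = config@r * Q, s = config@s * Q,
       burnIn = as.integer(round(config@burnIn / Q)),
       splitGens = as.integer(round(config@splitGens / Q)),
       tSel = as.integer(round(config@tSel / Q)))
}

#' Run one forward Wright-Fisher replicate
#'
#' Simulates the two-population protocol: burn-in of an ancestral
#' population, split into focal and outgroup populations, and (for balanced
#' runs) introduction of a single overdominant mutation at the region centre
#' \code{tSel} generations before sampling, conditioning on its maintenance
#' by restarting from the introduction generation whenever it is lost.
#' Sampling takes \code{nSample} focal chromosomes and one outgroup
#' chromosome; substitutions are the variants at which the outgroup
#' chromosome's allele is not found among the sampled focal chromosomes.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param balanced introduce the balanced variant.
#' @return A \linkS4class{SimResult}.
#' @export
runForward <- function(config, balanced = FALSE) {
  stopifnot(is(config, "SimConfig"))
  p <- rescaledParams(config)
  if (balanced) {
    equilibriumFrequency(config@h, config@s)  # errors if not protected
    if (p$tSel < 1L)
      stop("balanced runs need tSel >= 1 (rescaled) generation before sampling")
  }
  seed <- config@seed
  if (is.na(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  res <- .cppRunForward(p$Ne, p$mu, p$r, config@L, p$burnIn, p$splitGens,
                        p$tSel, config@h, p$s, config@nSample, balanced,
                        config@outgroup, config@maxRestarts, seed)
  ord <- order(res$positions)
  pos <- res$positions[ord]
  cnt <- res$counts[ord]
  ipos <- dedupPositions(pos)
  balIdx <- if (balanced) match(res$balancedPos, pos) else NA_integer_
  sites <- SiteCounts(ipos, cnt, config@nSample)
  new("SimResult", sites = sites,
      substitutions = as.numeric(floor(res$substitutions) + 1),
      balancedPosition = if (balanced && !is.na(balIdx)) as.numeric(ipos[balIdx])
                         else if (balanced) floor(res$balancedPos) + 1
                         else NA_real_,
      balancedCount = if (balanced) as.numeric(res$balancedCount) else NA_real_,
      restarts = res$restarts, seed = seed)
}

#' @export
setMethod("simSites", "SimResult", function(x) x@sites)

#' @export
setMethod("substitutions", "SimResult", function(x) x@substitutions)

#' @export
setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d segregating site%s, %d substitution%s%s%s\n",
              length(object@sites), if (length(object@sites) == 1L) "" else "s",
              length(object@substitutions),
              if (length(object@substitutions) == 1L) "" else "s",
              if (!is.na(object@balancedPosition))
                sprintf("; balanced site at %d (sample count %d)",
                        as.integer(object@balancedPosition),
                        as.integer(object@balancedCount)) else "",
              if (object@restarts > 0)
                sprintf("; %d restart(s)", as.integer(object@restarts)) else ""))
  invisible(object)
})

#' @export
setMethod("show", "SimConfig", function(object) {
  p <- rescaledParams(object)
  cat(sprintf(paste0("SimConfig: Ne=%g mu=%g r=%g L=%g bp; burn-in %g, split +%g, ",
                     "tSel %g gens; h=%g s=%g; n=%d (+%s outgroup); Q=%g\n"),
              object@Ne, object@mu, object@r, object@L, object@burnIn,
              object@splitGens, object@tSel, object@h, object@s,
              object@nSample, if (object@outgroup) "1" else "no",
              object@rescaleQ))
  invisible(object)
})

#' @export
setMethod("show", "ScanConfig", function(object) {
  cat(sprintf("ScanConfig: %g-bp windows, p=%g, %s; core folded freq >= %g; top %g%%, shared in >= %g of populations\n",
              object@windowBp, object@p, object@foldMode, object@minFoldedFreq,
              100 * object@percentile, object@sharingFraction))
  invisible(object)
})
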