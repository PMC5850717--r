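# Exact Hardy-Weinberg test, used as a quality filter on candidate
# haplotypes (unknown paralogs inflate heterozygote counts).

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the observed genotype counts at a biallelic
#' site: conditional on the allele counts, the probability of each
#' compatible heterozygote count h is
#' \deqn{P(h) = \frac{N!\, 2^h\, n_A!\, n_B!}{n_{AA}!\, h!\, n_{BB}!\, (2N)!}}
#' (Levene's distribution).  Reports the one-sided P value for an excess of
#' heterozygotes (probability of h at least as large as observed) and the
#' two-sided P value (total probability of configurations no more likely
#' than the observed one), the convention used by common VCF tooling.
#'
#' @param obsHomRef,obsHet,obsHomAlt observed genotype counts.
#' @return A list with elements \code{pHetExcess} and \code{pTwoSided},
#'   both in [0, 1].
#' @examples
#' hweExactTest(25, 50, 25)
#' @export
hweExactTest <- function(obsHomRef, obsHet, obsHomAlt) {
  counts <- c(obsHomRef, obsHet, obsHomAlt)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0))
    stop("genotype counts must be three non-negative numbers")
  N <- sum(counts)
  if (N < 1) stop("at least one genotyped individual is required")
  nA <- 2 * obsHomRef + obsHet
  nB <- 2 * obsHomAlt + obsHet
  if (nA == 0 || nB == 0)              # monomorphic: a single configuration
    return(list(pHetExcess = 1, pTwoSided = 1))
  minAllele <- min(nA, nB)
  h <- seq(minAllele %% 2, minAllele, by = 2)   # parity-compatible het counts
  logP <- lfactorial(N) + h * log(2) + lfactorial(nA) + lfactorial(nB) -
    lfactorial((nA - h) / 2) - lfactorial(h) - lfactorial((nB - h) / 2) -
    lfactorial(2 * N)
  prob <- exp(logP)
  prob <- prob / sum(prob)             # guard accumulated rounding
  iObs <- match(obsHet, h)
  pExcess <- sum(prob[h >= obsHet])
  pTwo <- sum(prob[prob <= prob[iObs] * (1 + 1e-12)])
  list(pHetExcess = min(pExcess, 1), pTwoSided = min(pTwo, 1))
}
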