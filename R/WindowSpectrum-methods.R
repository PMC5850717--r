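# Constructor and accessors for WindowSpectrum.

#' Construct a WindowSpectrum
#'
#' @param n number of sampled chromosomes.
#' @param S class counts: either a full vector of length \code{n - 1}
#'   (unfolded) / \code{floor(n/2)} (folded), or a named vector such as
#'   \code{c(`1` = 2, `2` = 1)} giving only the occupied classes.
#' @param coreCount derived (or folded) count of the core SNP.  The core site
#'   itself must not be included in \code{S}.
#' @param folded logical; \code{S} is a folded (minor-allele) spectrum.
#' @return A \linkS4class{WindowSpectrum}.
#' @examples
#' windowSpectrum(4, c(`1` = 1, `2` = 1), coreCount = 2)
#' @export
windowSpectrum <- function(n, S = numeric(), coreCount, folded = FALSE) {
  n <- as.integer(n)
  len <- if (isTRUE(folded)) n %/% 2L else n - 1L
  full <- numeric(len)
  if (length(S)) {
    if (!is.null(names(S))) {
      idx <- as.integer(names(S))
      if (anyNA(idx) || any(idx < 1L) || any(idx > len))
        stop("named classes in 'S' must lie in 1..", len)
      full[idx] <- full[idx] + as.numeric(S)
    } else {
      if (length(S) != len)
        stop("unnamed 'S' must have length ", len)
      full <- as.numeric(S)
    }
  }
  new("WindowSpectrum", n = n, S = full, coreCount = as.integer(coreCount),
      folded = isTRUE(folded))
}

#' Spectrum of a set of sites around a given core
#'
#' Tabulates \code{sites} (which must all share one sample size) into a
#' \linkS4class{WindowSpectrum}; the caller is responsible for having
#' excluded the core site already (see \code{\link{buildWindow}}).
#'
#' @param sites a \linkS4class{SiteCounts} object with uniform sample size.
#' @param coreCount count of the core SNP.
#' @param n sample size; defaults to the sites' common sample size.
#' @param folded fold the spectrum (also folds \code{coreCount}).
#' @return A \linkS4class{WindowSpectrum}.
#' @export
spectrumFromSites <- function(sites, coreCount, n = NULL, folded = isFolded(sites)) {
  stopifnot(is(sites, "SiteCounts"))
  ns <- unique(sampleSizes(sites))
  if (is.null(n)) {
    if (length(ns) == 0L) stop("'n' must be given for an empty site set")
    n <- ns
  }
  if (length(ns) > 1L)
    stop("sites have heterogeneous sample sizes; use the per-site scan path")
  n <- as.integer(n)
  cnt <- derivedCounts(sites)
  cc <- as.integer(coreCount)
  if (folded) {
    if (!isFolded(sites)) cnt <- foldCount(cnt, n)
    cc <- as.integer(foldCount(cc, n))
  } else if (isFolded(sites)) {
    stop("cannot build an unfolded spectrum from folded counts")
  }
  len <- if (folded) n %/% 2L else n - 1L
  S <- tabulate(cnt, nbins = len)
  new("WindowSpectrum", n = n, S = as.numeric(S), coreCount = cc,
      folded = folded)
}

#' @export
setMethod("sampleSize", "WindowSpectrum", function(x) x@n)

#' @export
setMethod("classCounts", "WindowSpectrum", function(x) {
  setNames(x@S, seq_along(x@S))
})

#' @export
setMethod("coreCount", "WindowSpectrum", function(x) x@coreCount)

#' @export
setMethod("isFolded", "WindowSpectrum", function(x) x@folded)

#' @describeIn foldSpectrum fold an unfolded spectrum: class i and class
#'   n - i are pooled into the minor-allele class min(i, n - i).
#' @param x a \linkS4class{WindowSpectrum}.
#' @export
setMethod("foldSpectrum", "WindowSpectrum", function(x) {
  if (x@folded) return(x)
  n <- x@n
  len <- n %/% 2L
  Sf <- numeric(len)
  for (i in seq_len(n - 1L)) {
    j <- min(i, n - i)
    Sf[j] <- Sf[j] + x@S[i]
  }
  new("WindowSpectrum", n = n, S = Sf,
      coreCount = as.integer(foldCount(x@coreCount, n)), folded = TRUE)
})

#' @export
setMethod("show", "WindowSpectrum", function(object) {
  occ <- which(object@S > 0)
  cat(sprintf("WindowSpectrum (%s): n = %d, core count = %d, %g SNP%s\n",
              if (object@folded) "folded" else "unfolded",
              object@n, object@coreCount, sum(object@S),
              if (sum(object@S) == 1) "" else "s"))
  if (length(occ))
    cat("  occupied classes:",
        paste(sprintf("%d:%g", occ, object@S[occ]), collapse = ", "), "\n")
  invisible(object)
})
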