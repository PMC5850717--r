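# Constructor, accessors and coercions for SiteCounts.

#' Construct a SiteCounts object
#'
#' @param position integer vector of 1-based positions (strictly increasing
#'   within each contig).
#' @param derivedCount integer vector of derived-allele counts (minor-allele
#'   counts when \code{folded = TRUE}).
#' @param sampleSize integer vector (recycled if scalar) of chromosomes
#'   sampled per site.
#' @param contig contig name(s), recycled.
#' @param folded logical; counts are folded (minor-allele) counts.
#' @return A \linkS4class{SiteCounts} object.
#' @examples
#' SiteCounts(c(100L, 250L), c(25L, 50L), 100L)
#' @export
SiteCounts <- function(position, derivedCount, sampleSize, contig = "chr1",
                       folded = FALSE) {
  len <- length(position)
  new("SiteCounts",
      contig = rep_len(as.character(contig), len),
      position = as.integer(position),
      derivedCount = as.integer(derivedCount),
      sampleSize = rep_len(as.integer(sampleSize), len),
      folded = isTRUE(folded))
}

#' @describeIn SiteCounts number of sites.
#' @param x a \code{SiteCounts} object.
#' @export
setMethod("length", "SiteCounts", function(x) length(x@position))

#' @export
setMethod("positions", "SiteCounts", function(x) x@position)

#' @export
setMethod("derivedCounts", "SiteCounts", function(x) x@derivedCount)

#' @export
setMethod("sampleSizes", "SiteCounts", function(x) x@sampleSize)

#' @export
setMethod("contigs", "SiteCounts", function(x) x@contig)

#' @export
setMethod("isFolded", "SiteCounts", function(x) x@folded)

#' @export
setMethod("[", "SiteCounts", function(x, i, j, ..., drop = TRUE) {
  initialize(x, contig = x@contig[i], position = x@position[i],
             derivedCount = x@derivedCount[i], sampleSize = x@sampleSize[i])
})

#' @export
setMethod("show", "SiteCounts", function(object) {
  cat(sprintf("SiteCounts with %d site%s on %d contig%s (%s counts)\n",
              length(object), if (length(object) == 1L) "" else "s",
              length(unique(object@contig)),
              if (length(unique(object@contig)) == 1L) "" else "s",
              if (object@folded) "folded" else "unfolded"))
  if (length(object)) {
    df <- as.data.frame(object)
    print(head(df, 6L), row.names = FALSE)
    if (nrow(df) > 6L) cat("  ...", nrow(df) - 6L, "more\n")
  }
  invisible(object)
})

#' @export
setMethod("as.data.frame", "SiteCounts", function(x, ...) {
  data.frame(contig = x@contig, position = x@position,
             derivedCount = x@derivedCount, sampleSize = x@sampleSize,
             stringsAsFactors = FALSE)
})

#' Fold the counts of a SiteCounts object
#'
#' Replaces each derived count by the minor-allele count min(f, n - f).
#' The result is marked folded; already-folded input is returned unchanged.
#'
#' @param x a \linkS4class{SiteCounts} object.
#' @return A folded \code{SiteCounts}.
#' @export
foldSites <- function(x) {
  stopifnot(is(x, "SiteCounts"))
  if (x@folded) return(x)
  initialize(x, derivedCount = as.integer(foldCount(x@derivedCount, x@sampleSize)),
             folded = TRUE)
}
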