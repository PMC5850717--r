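# Reading and writing the tabular allele-count format, deriving counts from
# VCF, and BED accessibility/repeat masks.

#' Read a per-site allele count table
#'
#' Whitespace-delimited lines \code{position derived_count sample_size}, with
#' an optional single header line starting with a non-digit.  Positions must
#' be strictly increasing; monomorphic lines (count 0 or n) are dropped with
#' a warning by default, since every downstream estimator sums over
#' segregating classes 1..n-1.
#'
#' @param path file path.
#' @param dropMonomorphic drop monomorphic lines with a warning
#'   (default); if \code{FALSE} they are an error.
#' @param contig contig name to assign (the format is single-contig).
#' @param folded mark counts as folded (minor-allele) counts.
#' @return A \linkS4class{SiteCounts} object.
#' @export
readCountTable <- function(path, dropMonomorphic = TRUE, contig = "chr1",
                           folded = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && !grepl("^\\s*[0-9]", lines[1L]))
    lines <- lines[-1L]
  if (!length(lines))
    return(SiteCounts(integer(), integer(), integer(), contig = contig,
                      folded = folded))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("malformed count-table line ", which(nf != 3L)[1L],
         ": expected 'position derived_count sample_size'")
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE))
  if (anyNA(m))
    stop("malformed count-table line ", which(rowSums(is.na(m)) > 0)[1L],
         ": non-numeric field")
  pos <- m[, 1L]; cnt <- m[, 2L]; n <- m[, 3L]
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions are not strictly increasing (first violation at line ",
         which(diff(pos) <= 0)[1L] + 1L, ")")
  mono <- cnt <= 0 | cnt >= n
  if (any(mono)) {
    if (!dropMonomorphic)
      stop(sum(mono), " monomorphic site(s) in ", path,
           "; rerun with dropMonomorphic = TRUE to drop them")
    warning("dropped ", sum(mono), " monomorphic site(s)")
    pos <- pos[!mono]; cnt <- cnt[!mono]; n <- n[!mono]
  }
  SiteCounts(pos, cnt, n, contig = contig, folded = folded)
}

#' Write a per-site allele count table
#'
#' Inverse of \code{\link{readCountTable}}: three whitespace-delimited
#' columns with a header line.
#'
#' @param sites a \linkS4class{SiteCounts} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(sites, path) {
  stopifnot(is(sites, "SiteCounts"))
  df <- data.frame(position = positions(sites),
                   derived_count = derivedCounts(sites),
                   sample_size = sampleSizes(sites))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive per-population allele counts from a VCF
#'
#' Counts the derived allele among the haplotypes of the selected samples at
#' each biallelic SNP.  The ancestral allele is taken from the \code{AA}
#' INFO tag; sites whose AA call matches neither allele (or is absent) are
#' dropped in unfolded mode rather than polarised by REF, to avoid
#' systematic miscalls, and retained in folded mode where polarisation is
#' irrelevant.  Genotypes containing a missing allele reduce that site's
#' sample size.  Sites monomorphic within the selected samples are dropped.
#'
#' @param path VCF (v4.x) file path, plain or bgzipped.
#' @param samples character vector of sample names; default all samples.
#' @param fold return folded (minor-allele) counts and keep AA-less sites.
#' @return A \linkS4class{SiteCounts} object.
#' @export
vcfToCounts <- function(path, samples = NULL, fold = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  avail <- colnames(gt)[-1L]
  if (is.null(samples)) samples <- avail
  missing <- setdiff(samples, avail)
  if (length(missing))
    stop("sample(s) not in VCF header: ", paste(missing, collapse = ", "))
  gt <- gt[, samples, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  nonsnp <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  if (any(multi))
    warning("skipped ", sum(multi), " multiallelic record(s)")
  if (any(nonsnp))
    warning("skipped ", sum(nonsnp), " non-SNP record(s)")
  keep <- !multi & !nonsnp

  aa <- toupper(substr(vcfR::extract.info(vcf, "AA"), 1L, 1L))
  contig <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])

  res <- lapply(which(keep), function(i) {
    alleles <- unlist(strsplit(gt[i, ], "[/|]"))
    alleles <- sub(":.*$", "", alleles)
    ok <- alleles %in% c("0", "1")
    nChr <- sum(ok)
    altCount <- sum(alleles[ok] == "1")
    c(i = i, n = nChr, altCount = altCount)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(SiteCounts(integer(), integer(), integer(), folded = fold))
  i <- res[, "i"]; nChr <- res[, "n"]; altCount <- res[, "altCount"]

  if (fold) {
    derived <- pmin(altCount, nChr - altCount)
  } else {
    polarised <- aa[i] == ref[i] | aa[i] == alt[i]
    polarised[is.na(polarised)] <- FALSE
    nDropped <- sum(!polarised)
    if (nDropped)
      warning("dropped ", nDropped, " site(s) without a usable AA (ancestral allele) call")
    derived <- ifelse(aa[i] == alt[i], nChr - altCount, altCount)
    keepAA <- polarised
    i <- i[keepAA]; nChr <- nChr[keepAA]; derived <- derived[keepAA]
  }
  poly <- !is.na(derived) & derived >= 1 & derived <= nChr - 1
  i <- i[poly]; nChr <- nChr[poly]; derived <- derived[poly]
  ord <- order(contig[i], pos[i], method = "radix")
  SiteCounts(pos[i][ord], derived[ord], nChr[ord], contig = contig[i][ord],
             folded = fold)
}

#' Read a BED mask as the set of masked site coordinates
#'
#' Each BED record \code{(start, end)} (0-based half-open) is mapped to the
#' coordinates it masks under the scan's convention: a site at position
#' \code{pos} is masked iff \code{start <= pos < end}.  Overlapping records
#' are merged.
#'
#' @param path BED file path.
#' @return A \code{GRanges} of masked coordinate runs.
#' @export
readMaskBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::shift(gr, -1L)
  GenomicRanges::reduce(gr)
}

#' Remove (or keep) sites falling in masked intervals
#'
#' @param sites a \linkS4class{SiteCounts} object.
#' @param mask a \code{GRanges} from \code{\link{readMaskBed}} (or any
#'   GRanges of coordinates to mask).
#' @param polarity \code{"drop-inside"} (default) removes sites inside the
#'   mask; \code{"keep-inside"} retains only those sites.
#' @return The filtered \code{SiteCounts}.
#' @export
applyMask <- function(sites, mask, polarity = c("drop-inside", "keep-inside")) {
  stopifnot(is(sites, "SiteCounts"))
  polarity <- match.arg(polarity)
  if (length(mask) == 0L || length(sites) == 0L) {
    return(if (polarity == "drop-inside") sites else sites[integer(0)])
  }
  siteGR <- GenomicRanges::GRanges(contigs(sites),
                                   IRanges::IRanges(positions(sites), width = 1L))
  inside <- IRanges::overlapsAny(siteGR, mask)
  sites[if (polarity == "drop-inside") !inside else inside]
}

#' Write beta scores as TSV
#'
#' Columns \code{contig, position, folded_freq, theta_beta, theta_w, beta,
#' n_window_snps}, tab-separated with a header.
#'
#' @param scores a score \code{data.frame} from \code{\link{scanPopulation}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBetaScores <- function(scores, path) {
  out <- data.frame(contig = scores$contig,
                    position = scores$position,
                    folded_freq = scores$foldedFreq,
                    theta_beta = scores$thetaBeta,
                    theta_w = scores$thetaW,
                    beta = scores$beta,
                    n_window_snps = scores$nWindowSNPs)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read beta scores written by \code{\link{writeBetaScores}}
#'
#' @param path TSV path.
#' @return A score \code{data.frame} in the internal column naming.
#' @export
readBetaScores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  data.frame(contig = df$contig, position = df$position,
             foldedFreq = df$folded_freq, thetaBeta = df$theta_beta,
             thetaW = df$theta_w, beta = df$beta,
             nWindowSNPs = df$n_window_snps, stringsAsFactors = FALSE)
}
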