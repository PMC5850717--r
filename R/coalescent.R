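# Neutral coalescent with recombination (Hudson-style ancestral
# recombination graph), used as the fast exchangeable null for the forward
# simulator's neutral arm.
#
# Each lineage carries the ancestral material it is ancestral to, as a set
# of half-open segments [l, r) over the region, each tagged with the set of
# sampled chromosomes descending from it.  Events compete at the usual
# rates (time in units of 2*Ne generations): pairwise coalescence at
# k*(k-1)/2, recombination at rho/2 per unit of spanned material, and
# mutation at theta/2 per unit of carried material.  Mutations are placed
# online: each lands at a uniform position within the lineage's ancestral
# material and is carried by exactly that material's descendant set, which
# yields the sample frequency directly.  Material whose descendant set
# reaches the full sample has found its MRCA and is discarded, so no fixed
# mutations are produced.

# One replicate: returns data.frame(pos (continuous in [0, L)), count).
coalescentReplicate <- function(n, theta, rho, L) {
  lineages <- vector("list", n)
  for (i in seq_len(n)) {
    set <- logical(n); set[i] <- TRUE
    lineages[[i]] <- list(seg = matrix(c(0, L), 1L, 2L), sets = list(set))
  }
  mutPos <- numeric(0); mutCount <- integer(0)

  segLen <- function(ln) sum(ln$seg[, 2L] - ln$seg[, 1L])
  segSpan <- function(ln) ln$seg[nrow(ln$seg), 2L] - ln$seg[1L, 1L]

  mergeLineages <- function(a, b) {
    bp <- sort(unique(c(a$seg, b$seg)))
    seg <- NULL; sets <- list()
    for (k in seq_len(length(bp) - 1L)) {
      lo <- bp[k]; hi <- bp[k + 1L]; mid <- (lo + hi) / 2
      ia <- which(a$seg[, 1L] <= mid & a$seg[, 2L] > mid)
      ib <- which(b$seg[, 1L] <= mid & b$seg[, 2L] > mid)
      if (!length(ia) && !length(ib)) next
      set <- if (length(ia) && length(ib)) a$sets[[ia]] | b$sets[[ib]]
             else if (length(ia)) a$sets[[ia]] else b$sets[[ib]]
      if (all(set)) next                      # reached its MRCA
      if (!is.null(seg) && seg[nrow(seg), 2L] == lo &&
          identical(sets[[length(sets)]], set)) {
        seg[nrow(seg), 2L] <- hi              # compact equal neighbours
      } else {
        seg <- rbind(seg, c(lo, hi))
        sets[[length(sets) + 1L]] <- set
      }
    }
    if (is.null(seg)) NULL else list(seg = seg, sets = sets)
  }

  repeat {
    k <- length(lineages)
    if (k < 2L) break
    ancLens <- vapply(lineages, segLen, numeric(1))
    spans <- vapply(lineages, segSpan, numeric(1))
    rMut <- theta / 2 * sum(ancLens) / L
    rRec <- rho / 2 * sum(spans) / L
    rCoal <- k * (k - 1) / 2
    u <- runif(1) * (rMut + rRec + rCoal)
    if (u < rMut) {
      i <- sample.int(k, 1L, prob = ancLens)
      ln <- lineages[[i]]
      lens <- ln$seg[, 2L] - ln$seg[, 1L]
      s <- sample.int(length(lens), 1L, prob = lens)
      pos <- runif(1, ln$seg[s, 1L], ln$seg[s, 2L])
      mutPos <- c(mutPos, pos)
      mutCount <- c(mutCount, sum(ln$sets[[s]]))
    } else if (u < rMut + rRec) {
      i <- sample.int(k, 1L, prob = spans)
      ln <- lineages[[i]]
      x <- runif(1, ln$seg[1L, 1L], ln$seg[nrow(ln$seg), 2L])
      splitIdx <- which(ln$seg[, 1L] < x & ln$seg[, 2L] > x)
      left <- ln$seg[, 2L] <= x
      lSeg <- ln$seg[left, , drop = FALSE]; lSets <- ln$sets[left]
      rSeg <- ln$seg[!left & ln$seg[, 1L] >= x, , drop = FALSE]
      rSets <- ln$sets[!left & ln$seg[, 1L] >= x]
      if (length(splitIdx)) {
        lSeg <- rbind(lSeg, c(ln$seg[splitIdx, 1L], x))
        lSets <- c(lSets, ln$sets[splitIdx])
        rSeg <- rbind(c(x, ln$seg[splitIdx, 2L]), rSeg)
        rSets <- c(ln$sets[splitIdx], rSets)
      }
      ordL <- order(lSeg[, 1L]); ordR <- order(rSeg[, 1L])
      lineages[[i]] <- list(seg = lSeg[ordL, , drop = FALSE], sets = lSets[ordL])
      lineages[[length(lineages) + 1L]] <-
        list(seg = rSeg[ordR, , drop = FALSE], sets = rSets[ordR])
    } else {
      pair <- sample.int(k, 2L)
      merged <- mergeLineages(lineages[[pair[1L]]], lineages[[pair[2L]]])
      lineages[pair] <- NULL
      if (!is.null(merged)) lineages[[length(lineages) + 1L]] <- merged
    }
  }
  ord <- order(mutPos)
  data.frame(pos = mutPos[ord], count = mutCount[ord])
}

# Round continuous positions (sorted) to strictly increasing 1-based
# integers; collisions are pushed right.
dedupPositions <- function(pos) {
  ipos <- floor(pos) + 1
  if (length(ipos) > 1L)
    for (i in 2:length(ipos))
      if (ipos[i] <= ipos[i - 1L]) ipos[i] <- ipos[i - 1L] + 1
  as.integer(ipos)
}

#' Neutral coalescent replicates
#'
#' Simulates the standard neutral coalescent with recombination for
#' \code{nSample} chromosomes over a region of \code{L} bp, with
#' theta = 4*Ne*mu*L and rho = 4*Ne*r*L taken from \code{config} (both are
#' invariant under \code{rescaleQ}).  Output has the same shape as
#' \code{\link{runForward}}'s, but carries no outgroup information.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param replicates number of replicates.
#' @return A list of \linkS4class{SimResult} objects.
#' @export
runNeutralCoalescent <- function(config, replicates = 1L) {
  stopifnot(is(config, "SimConfig"))
  if (!is.na(config@seed)) set.seed(config@seed)
  n <- config@nSample
  theta <- 4 * config@Ne * config@mu * config@L
  rho <- 4 * config@Ne * config@r * config@L
  lapply(seq_len(replicates), function(rep) {
    df <- coalescentReplicate(n, theta, rho, config@L)
    sites <- SiteCounts(dedupPositions(df$pos), df$count, n)
    new("SimResult", sites = sites, substitutions = numeric(),
        balancedPosition = NA_real_, balancedCount = NA_real_,
        restarts = 0, seed = if (is.na(config@seed)) NA_real_ else config@seed)
  })
}
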