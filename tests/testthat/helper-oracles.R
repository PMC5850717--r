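# Independent oracles and fixture builders used across the suite.

# Straight-loop reimplementation of the beta components, kept deliberately
# scalar and naive so it shares no code path with the package's vectorised
# estimators.
oracleSimilarity <- function(f0, fi, n, p) {
  g0 <- min(f0, n - f0)
  gi <- min(fi, n - fi)
  m <- max(g0, n / 2 - g0)
  ((m - abs(g0 - gi)) / m)^p
}

oracleThetaW <- function(S, n) {
  a <- 0
  for (i in 1:(n - 1)) a <- a + 1 / i
  tot <- 0
  for (i in seq_along(S)) tot <- tot + S[i]
  tot / a
}

oracleThetaBeta <- function(S, n, coreCount, p) {
  num <- 0; den <- 0
  for (i in 1:(n - 1)) {
    d <- oracleSimilarity(coreCount, i, n, p)
    den <- den + d
    num <- num + i * d * S[i]
  }
  num / den
}

oracleBeta <- function(S, n, coreCount, p) {
  oracleThetaBeta(S, n, coreCount, p) - oracleThetaW(S, n)
}

# Tajima's D from an explicit haplotype matrix (rows = haplotypes): pi as
# the mean pairwise Hamming distance, constants written out from the
# published formulas.
oracleTajimaFromMatrix <- function(mat) {
  n <- nrow(mat)
  S <- ncol(mat)
  piSum <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    piSum <- piSum + sum(mat[i, ] != mat[j, ])
  piHat <- piSum / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (piHat - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Haplotype matrix realising a spectrum: one column per SNP, derived allele
# assigned to the first i haplotypes (pi depends only on counts).
matrixFromSpectrum <- function(S, n) {
  cols <- list()
  for (i in seq_along(S)) {
    for (k in seq_len(S[i])) cols[[length(cols) + 1L]] <- c(rep(1, i), rep(0, n - i))
  }
  do.call(cbind, cols)
}

# Exhaustive Hardy-Weinberg oracle: enumerate every placement of the nA
# copies of allele A among 2N slots, pair consecutive slots into genotypes,
# and tabulate the heterozygote-count distribution.
oracleHWEDistribution <- function(N, nA) {
  slots <- 2 * N
  hets <- integer(0)
  combos <- utils::combn(slots, nA)
  for (c in seq_len(ncol(combos))) {
    isA <- logical(slots)
    isA[combos[, c]] <- TRUE
    het <- sum(isA[seq(1, slots, 2)] != isA[seq(2, slots, 2)])
    hets <- c(hets, het)
  }
  table(hets) / length(hets)
}

# Minimal VCF text fixture.
writeTestVCF <- function(path, rows, samples = c("S1", "S2", "S3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral Allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

vcfRow <- function(pos, ref, alt, aa, gts, chrom = "chr1") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS",
          if (is.na(aa)) "." else paste0("AA=", aa), "GT", gts),
        collapse = "\t")
}

# Small fast simulation configuration for Monte-Carlo unit checks.
miniSimConfig <- function(seed, ...) {
  simConfig(Ne = 500, mu = 1e-6, r = 1e-6, L = 2000, burnIn = 4000,
            splitGens = 3000, tSel = 3000, nSample = 20L, seed = seed, ...)
}
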