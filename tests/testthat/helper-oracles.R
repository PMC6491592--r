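## Independent oracles and small fixtures shared across tests.

## Maximum number of nested base pairs by explicit enumeration over the
## recursion tree (no memoisation, independent of the package's DP).
oraclePairMax <- function(seq, minLoop = 3, allowGU = TRUE) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ok <- function(a, b) {
    wc <- paste0(a, b) %in% c("AU", "UA", "CG", "GC")
    if (allowGU) wc <- wc || paste0(a, b) %in% c("GU", "UG")
    wc
  }
  rec <- function(i, j) {
    if (j - i <= minLoop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + minLoop + 1L):j)
      if (ok(ch[i], ch[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (v > best) best <- v
      }
    best
  }
  if (length(ch) < 2L) 0L else rec(1L, length(ch))
}

## Needleman-Wunsch optimal score by a hand-rolled dynamic program,
## independent of Biostrings.
oracleNWScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in seq_len(n))
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      D[i + 1L, j + 1L] <- max(D[i, j] + s, D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
    }
  D[n + 1L, m + 1L]
}

## Tiny two-gene plastome (one gene per strand) built in code.
## Layout: 1..5 spacer | 6..23 psbT (+) | 24..30 spacer |
##         31..48 ndhX (-) | 49..60 spacer.
toyPlastome <- function() {
  cdsA <- "ATGTCAGGATGCCTATAA"  # psbT, plus strand
  cdsB <- "ATGCATCCGTTATGGTGA"  # ndhX, minus strand
  rcB <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cdsB)))
  seq <- paste0("ACGTA", cdsA, "GGCCTTA", rcB, "ACGTACGTACGT")
  p <- Plastome("toy", seq, genes = data.frame(
    name = c("psbT", "ndhX"), strand = c("+", "-"),
    start = c(6L, 31L), end = c(23L, 48L)))
  attr(p, "cds") <- c(psbT = cdsA, ndhX = cdsB)
  p
}

## One-read truth alignment table.
readRow <- function(start, seq, strand = "+") {
  data.frame(start = start, seq = seq, strand = strand)
}

## Simulation configuration used by several end-to-end tests: 20 genes,
## one injected C-to-U site per gene at fractions 0.15..0.90, interior
## positions so every site sees full read coverage.
recoveryConfig <- function(seed = 42L) {
  simulationConfig(
    seed = seed, lscLen = 12000L, sscLen = 6000L, irLen = 2000L,
    nGenes = 20L, geneLengths = 600L,
    editingSites = data.frame(
      gene = 1:20,
      ntIndex = as.integer(seq(90L, 510L, length.out = 20) %/% 1L),
      conversion = "C-to-U",
      targetFraction = seq(0.15, 0.90, length.out = 20)),
    readLength = 76L, nReads = 50000L, errorRate = 0.001)
}
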