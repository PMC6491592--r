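## Intergenic spacer (IGS) extraction and pairwise percent identity by
## global (Needleman-Wunsch) alignment, used to flag low-identity
## hotspot regions between plastomes.

#' Extract intergenic spacers
#'
#' Walks the genes sorted by start along the plus strand and emits the
#' gap sequence between each adjacent pair with a gap of at least 1 bp;
#' abutting or overlapping pairs emit nothing. tRNA and rRNA genes count
#' as delimiters. Spacer names are `upstreamGene-downstreamGene`.
#'
#' @param plastome A [Plastome-class] object.
#' @return Data frame `name`, `start`, `end`, `length`, `sequence`.
#' @export
extractIGS <- function(plastome) {
  genes <- plastome@genes
  empty <- data.frame(name = character(), start = integer(),
                      end = integer(), length = integer(),
                      sequence = character())
  if (length(genes) < 2L) return(empty)
  o <- order(GenomicRanges::start(genes))
  genes <- genes[o]
  nm <- S4Vectors::mcols(genes)$gene
  s <- GenomicRanges::start(genes); e <- GenomicRanges::end(genes)
  seqChar <- as.character(plastome@sequence)
  rows <- list()
  for (i in seq_len(length(genes) - 1L)) {
    gapStart <- e[i] + 1L
    gapEnd <- s[i + 1L] - 1L
    if (gapEnd < gapStart) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(nm[i], "-", nm[i + 1L]),
      start = gapStart, end = gapEnd, length = gapEnd - gapStart + 1L,
      sequence = substr(seqChar, gapStart, gapEnd))
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Global alignment of two DNA sequences
#'
#' End-to-end Needleman-Wunsch alignment under a simple scoring scheme
#' (default match +1, mismatch -1, linear gap -2). Because many
#' alignments can share the optimal score, percent identity is made
#' canonical: among all optimal-score alignments the one with the most
#' identical columns is used. Under linear gap scoring the score fixes a
#' linear relation between match and mismatch counts, so this choice
#' also determines the mismatch and gap-column counts, making the
#' reported identity well defined (and invariant under reversal or
#' complementation of both sequences).
#'
#' @param seqA,seqB Non-empty DNA sequences (character or
#'   [Biostrings::DNAString]).
#' @param match,mismatch,gap Alignment scores; `gap` is the (negative)
#'   per-position linear gap score.
#' @return List with `score`, `matches`, `mismatches`, `columns`,
#'   `identityPct` (identical columns over all alignment columns, gap
#'   columns in the denominator), `alignedA`, `alignedB` (one
#'   match-maximal optimal alignment).
#' @seealso [percentIdentity()]
#' @export
alignGlobal <- function(seqA, seqB, match = 1, mismatch = -1, gap = -2) {
  seqA <- toupper(as.character(seqA)); seqB <- toupper(as.character(seqB))
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  a <- strsplit(seqA, "")[[1]]; b <- strsplit(seqB, "")[[1]]
  n <- length(a); m <- length(b)
  S <- outer(a, b, function(x, y) ifelse(x == y, match, mismatch))

  ## forward and backward optimal prefix/suffix scores
  D <- matrix(-Inf, n + 1L, m + 1L)
  D[, 1] <- gap * (0:n); D[1, ] <- gap * (0:m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1L, j + 1L] <- max(D[i, j] + S[i, j], D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
  B <- matrix(-Inf, n + 1L, m + 1L)
  B[n + 1L, ] <- gap * (m:0); B[, m + 1L] <- gap * (n:0)
  for (i in rev(seq_len(n)))
    for (j in rev(seq_len(m)))
      B[i, j] <- max(B[i + 1L, j + 1L] + S[i, j], B[i + 1L, j] + gap,
                     B[i, j + 1L] + gap)
  opt <- D[n + 1L, m + 1L]

  ## maximum matches over the sub-graph of optimal alignments
  M <- matrix(-Inf, n + 1L, m + 1L)
  M[1, 1] <- 0
  onPath <- abs(D + B - opt) < 1e-9
  for (i in 0:n)
    for (j in 0:m) {
      if (!onPath[i + 1L, j + 1L] || (i == 0L && j == 0L)) next
      best <- -Inf
      if (i > 0L && j > 0L &&
          abs(D[i, j] + S[i, j] - D[i + 1L, j + 1L]) < 1e-9)
        best <- max(best, M[i, j] + (a[i] == b[j]))
      if (i > 0L && abs(D[i, j + 1L] + gap - D[i + 1L, j + 1L]) < 1e-9)
        best <- max(best, M[i, j + 1L])
      if (j > 0L && abs(D[i + 1L, j] + gap - D[i + 1L, j + 1L]) < 1e-9)
        best <- max(best, M[i + 1L, j])
      M[i + 1L, j + 1L] <- best
    }
  matches <- as.integer(round(M[n + 1L, m + 1L]))
  ## score = (match-2*gap)*Mt + (mismatch-2*gap)*Ms + gap*(n+m)
  mismatches <- as.integer(round(
    (opt - gap * (n + m) - (match - 2 * gap) * matches) /
      (mismatch - 2 * gap)))
  columns <- n + m - matches - mismatches

  ## one representative traceback through the match-maximal sub-graph
  alnA <- character(0); alnB <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    cur <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        abs(D[i, j] + S[i, j] - D[i + 1L, j + 1L]) < 1e-9 &&
        onPath[i, j] && M[i, j] + (a[i] == b[j]) == cur) {
      alnA <- c(a[i], alnA); alnB <- c(b[j], alnB)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(D[i, j + 1L] + gap - D[i + 1L, j + 1L]) < 1e-9 &&
               onPath[i, j + 1L] && M[i, j + 1L] == cur) {
      alnA <- c(a[i], alnA); alnB <- c("-", alnB)
      i <- i - 1L
    } else {
      alnA <- c("-", alnA); alnB <- c(b[j], alnB)
      j <- j - 1L
    }
  }
  list(score = opt, matches = matches, mismatches = mismatches,
       columns = columns, identityPct = 100 * matches / columns,
       alignedA = paste(alnA, collapse = ""),
       alignedB = paste(alnB, collapse = ""))
}

#' Percent identity of two sequences under global alignment
#'
#' @inheritParams alignGlobal
#' @return Identity percentage in \[0, 100\]: identical alignment
#'   columns divided by total alignment columns (gap columns counted in
#'   the denominator).
#' @examples
#' percentIdentity("ACGTACGTAC", "ACGTACGTAA")  # 90
#' @export
percentIdentity <- function(seqA, seqB, match = 1, mismatch = -1,
                            gap = -2) {
  alignGlobal(seqA, seqB, match, mismatch, gap)$identityPct
}

#' Pairwise IGS identity between two plastomes
#'
#' Extracts the spacers of both plastomes, matches them by name, and
#' computes global-alignment percent identity for each shared spacer.
#'
#' @param plastomeA,plastomeB Two annotated [Plastome-class] objects
#'   with comparable gene sets.
#' @param hotspotBelow Identity threshold (percent) under which a spacer
#'   is flagged as a divergence hotspot; strict inequality.
#' @return Data frame `name`, `lengthA`, `lengthB`, `identityPct`,
#'   `hotspot`.
#' @export
compareIGS <- function(plastomeA, plastomeB, hotspotBelow = 95) {
  igsA <- extractIGS(plastomeA)
  igsB <- extractIGS(plastomeB)
  shared <- intersect(igsA$name, igsB$name)
  rows <- lapply(shared, function(nm) {
    a <- igsA$sequence[igsA$name == nm][1]
    b <- igsB$sequence[igsB$name == nm][1]
    pid <- percentIdentity(a, b)
    data.frame(name = nm, lengthA = nchar(a), lengthB = nchar(b),
               identityPct = pid, hotspot = pid < hotspotBelow)
  })
  if (!length(rows))
    return(data.frame(name = character(), lengthA = integer(),
                      lengthB = integer(), identityPct = numeric(),
                      hotspot = logical()))
  do.call(rbind, rows)
}

#' Report divergence hotspots
#'
#' @param records Data frame with `identityPct` (e.g. [compareIGS()]
#'   output).
#' @param below Threshold (percent); records strictly below are kept.
#' @return The flagged records sorted by ascending identity.
#' @export
hotspotReport <- function(records, below = 95) {
  out <- records[records$identityPct < below, , drop = FALSE]
  out <- out[order(out$identityPct), , drop = FALSE]
  rownames(out) <- NULL
  out
}
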