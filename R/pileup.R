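## Per-position base counting on the reference plus strand.
## A pileup is a data.frame with columns position, A, C, G, T, coverage;
## coverage is always the row sum of the four base counts (deleted
## positions and N bases are excluded from both).

.emptyPileup <- function() {
  data.frame(position = integer(), A = integer(), C = integer(),
             G = integer(), T = integer(), coverage = integer())
}

## Accumulate (position, base) pairs into a pileup data.frame.
.accumulatePileup <- function(pos, base, genomeLength) {
  keep <- base %in% c("A", "C", "G", "T")
  pos <- pos[keep]; base <- base[keep]
  if (!length(pos)) return(.emptyPileup())
  m <- matrix(0L, nrow = genomeLength, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T"))
    m[, b] <- tabulate(pos[base == b], nbins = genomeLength)
  cov <- rowSums(m)
  idx <- which(cov > 0L)
  data.frame(position = idx, A = m[idx, "A"], C = m[idx, "C"],
             G = m[idx, "G"], T = m[idx, "T"],
             coverage = as.integer(cov[idx]), row.names = NULL)
}

.parseSamRecords <- function(samPath) {
  lines <- readLines(samPath)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), seq = character(),
                      qual = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM record at line ", which(nf < 11L)[1])
  data.frame(
    qname = vapply(f, `[`, "", 1L), flag = as.integer(vapply(f, `[`, "", 2L)),
    rname = vapply(f, `[`, "", 3L), pos = as.integer(vapply(f, `[`, "", 4L)),
    cigar = vapply(f, `[`, "", 6L), seq = vapply(f, `[`, "", 10L),
    qual = vapply(f, `[`, "", 11L))
}

## Walk one CIGAR, returning reference positions and read offsets of the
## aligned (match/mismatch) bases. Insertions consume query only,
## deletions consume reference only, soft clips are skipped.
.cigarAlignedBases <- function(cigar, pos, recordIndex = NA_integer_) {
  ops <- gregexpr("(\\d+)([MIDSX=])", cigar, perl = TRUE)[[1]]
  if (ops[1] == -1L || sum(attr(ops, "match.length")) != nchar(cigar))
    stop("malformed CIGAR '", cigar, "' at record ", recordIndex)
  lens <- as.integer(gsub("[A-Z=]", "",
            regmatches(cigar, gregexpr("\\d+[MIDSX=]", cigar))[[1]]))
  opch <- gsub("\\d+", "",
            regmatches(cigar, gregexpr("\\d+[MIDSX=]", cigar))[[1]])
  refPos <- integer(0); readOff <- integer(0)
  r <- pos; q <- 1L
  for (k in seq_along(opch)) {
    n <- lens[k]
    switch(opch[k],
      "M" = , "=" = , "X" = {
        refPos <- c(refPos, r:(r + n - 1L))
        readOff <- c(readOff, q:(q + n - 1L))
        r <- r + n; q <- q + n
      },
      "I" = { q <- q + n },
      "S" = { q <- q + n },
      "D" = { r <- r + n },
      stop("malformed CIGAR op '", opch[k], "' at record ", recordIndex))
  }
  list(refPos = refPos, readOff = readOff)
}

#' Build a base pileup from a SAM file
#'
#' Counts, for every reference position, the aligned read bases on the
#' plus strand. Reads are filtered like the original mapping protocol:
#' records that are unmapped, secondary or supplementary are skipped, and
#' a read whose aligned bases disagree with the reference at more than
#' `maxMismatches` positions (default 2) is discarded entirely. Deleted
#' positions and inserted bases contribute nothing; an optional base
#' quality floor drops individual low-quality bases.
#'
#' @param samPath Path to a plain-text SAM file whose reads are aligned
#'   to `seqId(plastome)`.
#' @param plastome The reference [Plastome-class].
#' @param minBaseQuality Minimum Phred base quality (default 0 = off);
#'   ignored when the SAM QUAL field is `"*"`.
#' @param maxMismatches Maximum mismatches per retained read.
#' @return Pileup data frame with columns `position`, `A`, `C`, `G`, `T`,
#'   `coverage`, one row per covered position.
#' @seealso [pileupFromTruth()], [callSites()]
#' @export
pileupFromSam <- function(samPath, plastome, minBaseQuality = 0,
                          maxMismatches = 2) {
  rec <- .parseSamRecords(samPath)
  L <- length(plastome@sequence)
  refChars <- strsplit(as.character(plastome@sequence), "")[[1]]
  skipFlag <- bitwAnd(rec$flag, 0x4L) > 0L |   # unmapped
    bitwAnd(rec$flag, 0x100L) > 0L |           # secondary
    bitwAnd(rec$flag, 0x800L) > 0L             # supplementary
  rec <- rec[!skipFlag & rec$rname != "*", , drop = FALSE]
  if (nrow(rec) && any(rec$rname != plastome@seqId))
    stop("SAM reference '", setdiff(rec$rname, plastome@seqId)[1],
         "' does not match plastome '", plastome@seqId, "'")
  if (!nrow(rec)) return(.emptyPileup())

  allPos <- vector("list", nrow(rec))
  allBase <- vector("list", nrow(rec))
  simple <- grepl("^\\d+M$", rec$cigar)
  for (i in seq_len(nrow(rec))) {
    if (simple[i]) {
      n <- nchar(rec$seq[i])
      refPos <- rec$pos[i]:(rec$pos[i] + n - 1L)
      readOff <- seq_len(n)
    } else {
      ab <- .cigarAlignedBases(rec$cigar[i], rec$pos[i], i)
      refPos <- ab$refPos; readOff <- ab$readOff
    }
    if (length(refPos) && max(refPos) > L)
      stop("alignment overruns the reference at record ", i)
    bases <- substring(rec$seq[i], readOff, readOff)
    nm <- sum(bases != refChars[refPos] & bases != "N")
    if (nm > maxMismatches) next
    if (minBaseQuality > 0 && rec$qual[i] != "*") {
      q <- utf8ToInt(rec$qual[i])[readOff] - 33L
      keep <- q >= minBaseQuality
      refPos <- refPos[keep]; bases <- bases[keep]
    }
    allPos[[i]] <- refPos
    allBase[[i]] <- bases
  }
  .accumulatePileup(unlist(allPos), unlist(allBase), L)
}

#' Build a base pileup from simulator truth alignments
#'
#' Fast indel-free path used with [simulateReads()] output: every base of
#' every alignment increments exactly one position, with no filtering.
#'
#' @param alignments Data frame with columns `start` (1-based plus-strand
#'   position) and `seq` (plus-strand read sequence); a `strand` column
#'   is permitted and ignored, since the sequence is already plus-strand.
#' @param plastome The reference [Plastome-class].
#' @return Pileup data frame as in [pileupFromSam()].
#' @export
pileupFromTruth <- function(alignments, plastome) {
  L <- length(plastome@sequence)
  if (!nrow(alignments)) return(.emptyPileup())
  len <- nchar(alignments$seq)
  if (any(alignments$start < 1L) || any(alignments$start + len - 1L > L))
    stop("alignment overruns the reference")
  pos <- sequence(len, from = alignments$start)
  base <- unlist(strsplit(alignments$seq, ""), use.names = FALSE)
  .accumulatePileup(pos, base, L)
}

#' Mean fold coverage of a genome
#'
#' @param nReads Number of assembled/mapped reads.
#' @param readLength Read length in bp.
#' @param genomeLength Genome length in bp (> 0).
#' @return Fold coverage `nReads * readLength / genomeLength`, rounded to
#'   one decimal.
#' @examples
#' meanCoverage(17473, 301, 152479)  # 34.5
#' @export
meanCoverage <- function(nReads, readLength, genomeLength) {
  if (genomeLength <= 0) stop("genomeLength must be positive")
  if (nReads < 0 || readLength <= 0) stop("invalid read inputs")
  round(nReads * readLength / genomeLength, 1)
}

#' Percentage of reads mapped
#'
#' @param nMapped Number of mapped reads (0 <= nMapped <= nTotal).
#' @param nTotal Total reads (> 0).
#' @return `100 * nMapped / nTotal`, rounded to two decimals.
#' @examples
#' mappedFraction(17473, 3852736)  # 0.45
#' @export
mappedFraction <- function(nMapped, nTotal) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nMapped < 0 || nMapped > nTotal)
    stop("nMapped must lie in [0, nTotal]")
  round(100 * nMapped / nTotal, 2)
}

#' Write a pileup to TSV
#' @param pileup Pileup data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
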