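## Editing-site calling from pileups: conversion frequency with a strict
## > threshold rule, strand-aware conversion content.

.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

## Conversion label on a given strand, in RNA letters (T -> U).
.conversionLabel <- function(refPlus, altPlus, geneStrand) {
  r <- refPlus; a <- altPlus
  if (geneStrand == "-") {
    r <- .DNA_COMP[[r]]; a <- .DNA_COMP[[a]]
  }
  paste0(chartr("T", "U", r), "-to-", chartr("T", "U", a))
}

.ALL_CONVERSIONS <- as.vector(outer(c("A", "C", "G", "U"),
                                    c("A", "C", "G", "U"),
                                    function(x, y) paste0(x, "-to-", y)))
.ALL_CONVERSIONS <- .ALL_CONVERSIONS[substr(.ALL_CONVERSIONS, 1, 1) !=
                                     substr(.ALL_CONVERSIONS, 6, 6)]

#' Per-base conversion frequencies at one pileup site
#'
#' The calling statistic: for each alternative base, the fraction of
#' reads carrying it out of the total coverage at that position.
#'
#' @param counts Named counts for bases A, C, G, T (vector or one pileup
#'   row).
#' @param refBase The reference base at the position.
#' @param coverage Total coverage at the position; defaults to the sum
#'   of `counts`, but can be given explicitly (published per-site tables
#'   sometimes print a coverage exceeding the sum of the two printed
#'   base counts).
#' @return Named numeric vector of frequencies for the three bases other
#'   than `refBase`.
#' @examples
#' conversionFrequency(c(A = 0, C = 39, G = 0, T = 187680), "C",
#'                     coverage = 188389)
#' @export
conversionFrequency <- function(counts, refBase, coverage = NULL) {
  counts <- unlist(counts)[c("A", "C", "G", "T")]
  if (is.null(coverage)) coverage <- sum(counts)
  if (coverage <= 0) stop("zero coverage at site")
  alt <- setdiff(c("A", "C", "G", "T"), refBase)
  counts[alt] / coverage
}

#' Call RNA editing sites from a pileup
#'
#' Emits one editing site per position where the best allowed conversion
#' has frequency strictly greater than `threshold` (the "over 5 percent"
#' rule, by default) and coverage at least `minCoverage`. Conversion
#' content is reported on the gene strand: a plus-strand G-to-A signal
#' under a minus-strand gene is a C-to-U edit. Positions covered by no
#' gene are labelled `IGS` and reported in plus-strand content.
#'
#' @param pileup Pileup data frame from [pileupFromSam()] /
#'   [pileupFromTruth()].
#' @param plastome The reference [Plastome-class] the pileup was built
#'   against.
#' @param threshold Frequency threshold in (0, 1); strict inequality.
#' @param minCoverage Minimum coverage for a callable position.
#' @param allowedConversions Character vector of gene-strand conversion
#'   labels, or `"all"`. The default admits the canonical plastid C-to-U
#'   and reverse U-to-C conversions plus the rarer A-to-G.
#' @return Data frame with one row per called site: `position`,
#'   `refBasePlus`, `editedBasePlus`, `gene`, `region` (`coding`, `rRNA`,
#'   `tRNA` or `IGS`), `geneStrand`, `conversion`, `frequency`,
#'   `coverage`, the four base counts, and `multiAllelic` (TRUE when a
#'   second conversion also exceeded the threshold).
#' @seealso [conversionFrequency()], [substitutionSpectrum()],
#'   [annotateSites()]
#' @export
callSites <- function(pileup, plastome, threshold = 0.05,
                      minCoverage = 10,
                      allowedConversions = c("C-to-U", "U-to-C", "A-to-G")) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  if (identical(allowedConversions, "all"))
    allowedConversions <- .ALL_CONVERSIONS
  empty <- data.frame(position = integer(), refBasePlus = character(),
                      editedBasePlus = character(), gene = character(),
                      region = character(), geneStrand = character(),
                      conversion = character(), frequency = numeric(),
                      coverage = integer(), A = integer(), C = integer(),
                      G = integer(), T = integer(), multiAllelic = logical())
  if (!nrow(pileup)) return(empty)
  pileup <- pileup[pileup$coverage >= minCoverage, , drop = FALSE]
  if (!nrow(pileup)) return(empty)

  refChars <- strsplit(as.character(plastome@sequence), "")[[1]]
  cnt <- as.matrix(pileup[, c("A", "C", "G", "T")])
  ref <- refChars[pileup$position]
  refCount <- cnt[cbind(seq_len(nrow(cnt)), match(ref, colnames(cnt)))]
  refCount[is.na(refCount)] <- 0L  # N reference positions
  ## pre-screen: only positions with at least one non-reference read
  candidate <- which(pileup$coverage - refCount > 0L &
                       ref %in% c("A", "C", "G", "T"))
  if (!length(candidate)) return(empty)

  genes <- plastome@genes
  gpos <- GenomicRanges::GRanges(plastome@seqId,
            IRanges::IRanges(pileup$position, pileup$position))
  hits <- GenomicRanges::findOverlaps(gpos, genes, select = "first")

  rows <- vector("list", length(candidate))
  for (k in seq_along(candidate)) {
    i <- candidate[k]
    coverage <- pileup$coverage[i]
    h <- hits[i]
    if (!is.na(h)) {
      gene <- S4Vectors::mcols(genes)$gene[h]
      kind <- S4Vectors::mcols(genes)$kind[h]
      strandG <- as.character(GenomicRanges::strand(genes))[h]
      region <- if (kind == "protein") "coding" else kind
    } else {
      gene <- NA_character_; strandG <- "+"; region <- "IGS"
    }
    altBases <- setdiff(c("A", "C", "G", "T"), ref[i])
    freqs <- cnt[i, altBases] / coverage
    labels <- vapply(altBases, .conversionLabel, "", refPlus = ref[i],
                     geneStrand = strandG)
    ok <- freqs > threshold & labels %in% allowedConversions &
      cnt[i, altBases] > 0L
    if (!any(ok)) next
    best <- which(ok)[which.max(freqs[ok])]
    rows[[k]] <- data.frame(
      position = pileup$position[i], refBasePlus = ref[i],
      editedBasePlus = altBases[best], gene = gene, region = region,
      geneStrand = strandG, conversion = labels[best],
      frequency = unname(freqs[best]), coverage = coverage,
      A = cnt[i, "A"], C = cnt[i, "C"], G = cnt[i, "G"], T = cnt[i, "T"],
      multiAllelic = sum(ok) > 1L)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally editing sites by conversion content
#'
#' @param sites Data frame with a `conversion` column ([callSites()]
#'   output or the packaged per-site fixture).
#' @return Named integer vector, conversion label -> site count.
#' @export
substitutionSpectrum <- function(sites) {
  if (!nrow(sites)) return(integer(0))
  tab <- table(sites$conversion)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a called-site table to TSV
#' @param sites [callSites()] output.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeSiteReport <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
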