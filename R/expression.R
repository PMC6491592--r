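## Per-gene read assignment and RPKM, mirroring the usual plastid
## expression summary (reads per kilobase of gene per million assigned
## reads).

#' Assign reads to genes by the midpoint rule
#'
#' A read is assigned to the gene whose span contains its alignment
#' midpoint; reads whose midpoint falls in no gene stay unassigned. The
#' midpoint rule gives every read at most one gene without needing a
#' transcript model.
#'
#' @param alignments Data frame with columns `start` and `seq` (as
#'   produced by [simulateReads()]), or with `start` and `end`;
#'   alternatively a SAM path, parsed with the [pileupFromSam()] record
#'   filter but no mismatch filtering.
#' @param plastome The reference [Plastome-class].
#' @return Named integer vector gene -> assigned read count (all genes,
#'   zeros included).
#' @export
assignReads <- function(alignments, plastome) {
  if (is.character(alignments)) {
    rec <- .parseSamRecords(alignments)
    keep <- bitwAnd(rec$flag, 0x4L) == 0L &
      bitwAnd(rec$flag, 0x100L) == 0L & bitwAnd(rec$flag, 0x800L) == 0L
    rec <- rec[keep, , drop = FALSE]
    alignments <- data.frame(start = rec$pos,
                             end = rec$pos + nchar(rec$seq) - 1L)
  }
  if (is.null(alignments$end))
    alignments$end <- alignments$start + nchar(alignments$seq) - 1L
  genes <- plastome@genes
  out <- stats::setNames(integer(length(genes)),
                         S4Vectors::mcols(genes)$gene)
  if (!nrow(alignments)) return(out)
  mid <- (alignments$start + alignments$end) %/% 2L
  gpos <- GenomicRanges::GRanges(plastome@seqId,
            IRanges::IRanges(mid, mid))
  hit <- GenomicRanges::findOverlaps(gpos, genes, select = "first",
                                     ignore.strand = TRUE)
  tab <- table(hit)
  out[as.integer(names(tab))] <- as.integer(tab)
  out
}

#' Reads per kilobase of gene per million assigned reads
#'
#' @param assignedReads Reads assigned to the gene (vectorised).
#' @param lengthBp Spliced gene length in bp (> 0).
#' @param totalAssigned Total assigned reads across all genes (> 0).
#' @return `assignedReads * 1e9 / (lengthBp * totalAssigned)`.
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
#' @export
rpkm <- function(assignedReads, lengthBp, totalAssigned) {
  if (any(lengthBp <= 0)) stop("lengthBp must be positive")
  if (totalAssigned <= 0) stop("totalAssigned must be positive")
  assignedReads * 1e9 / (lengthBp * totalAssigned)
}

#' Rank an expression table by RPKM
#'
#' @param records Data frame with columns `gene` and `rpkm` (extra
#'   columns pass through).
#' @return The same rows sorted by decreasing RPKM, ties broken by gene
#'   name.
#' @export
rankExpression <- function(records) {
  if (!nrow(records)) return(records)
  out <- records[order(-records$rpkm, records$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full per-gene expression table from alignments
#'
#' Runs [assignReads()], computes RPKM for every gene against the total
#' assigned count, and ranks the result.
#'
#' @param alignments As in [assignReads()].
#' @param plastome The reference [Plastome-class].
#' @return Ranked data frame `gene`, `lengthBp`, `assignedReads`,
#'   `rpkm`.
#' @export
expressionTable <- function(alignments, plastome) {
  counts <- assignReads(alignments, plastome)
  genes <- plastome@genes
  lengthBp <- GenomicRanges::width(genes)
  total <- sum(counts)
  vals <- if (total > 0) rpkm(counts, lengthBp, total) else
    rep(0, length(counts))
  rankExpression(data.frame(gene = names(counts), lengthBp = lengthBp,
                            assignedReads = as.integer(counts),
                            rpkm = as.numeric(vals)))
}
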