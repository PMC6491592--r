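## Codon-level annotation of coding editing sites: codon context,
## amino-acid change, substitution class and the conventional display
## string with the edited letter in upper case, e.g. "S(uCa) -> L(uUa)".

.formatCodon <- function(codonRNA, codonPos) {
  s <- strsplit(tolower(codonRNA), "")[[1]]
  s[codonPos] <- toupper(s[codonPos])
  paste(s, collapse = "")
}

.aaLabel <- function(aa) if (identical(aa, "*")) "stop" else aa

## Substitution class from the two translations; start_gain only at the
## first codon, and stop-containing changes are never synonymous.
.classify <- function(aaBefore, aaAfter, aaIndex = NA_integer_,
                      codonAfter = NA_character_) {
  if (!is.na(aaIndex) && aaIndex == 1L && identical(codonAfter, "AUG"))
    return("start_gain")
  if (identical(aaAfter, "*")) return("stop_gain")
  if (identical(aaBefore, "*")) return("stop_loss")
  if (identical(aaBefore, aaAfter)) return("synonymous")
  "nonsynonymous"
}

#' Annotate one editing site with its codon effect
#'
#' Places a called site inside its protein gene, extracts the affected
#' codon on the gene strand, substitutes the edited base, translates both
#' codons under the plastid code and classifies the change. Amino-acid
#' and nucleotide indices are 1-based within the spliced coding sequence.
#'
#' @param site One row of [callSites()] output (or any list with
#'   `position`, `refBasePlus`, `editedBasePlus`).
#' @param plastome The reference [Plastome-class].
#' @param code Codon table, by default [plastidGeneticCode()].
#' @return One-row data frame: `gene`, `aaIndex`, `ntIndex`, `codonPos`,
#'   `codonBefore`, `codonAfter`, `aaBefore`, `aaAfter`, `klass`
#'   (`synonymous`, `nonsynonymous`, `stop_gain`, `stop_loss` or
#'   `start_gain`), and the formatted `display` string.
#' @seealso [annotateSites()], [classifyFixtureRow()]
#' @export
annotateSite <- function(site, plastome, code = plastidGeneticCode()) {
  genes <- plastome@genes
  pos <- site$position
  hit <- which(GenomicRanges::start(genes) <= pos &
                 GenomicRanges::end(genes) >= pos &
                 S4Vectors::mcols(genes)$kind == "protein")
  if (!length(hit))
    stop("site at position ", pos, " lies outside any protein gene")
  g <- genes[hit[1]]
  geneName <- S4Vectors::mcols(g)$gene
  width <- GenomicRanges::width(g)
  if (width %% 3L != 0L)
    stop("gene '", geneName, "' length not divisible by 3")
  strandG <- as.character(GenomicRanges::strand(g))
  ntIndex <- if (strandG == "+") pos - GenomicRanges::start(g) + 1L else
    GenomicRanges::end(g) - pos + 1L
  aaIndex <- (ntIndex - 1L) %/% 3L + 1L
  codonPos <- (ntIndex - 1L) %% 3L + 1L

  cds <- chartr("T", "U", as.character(geneSequence(plastome, geneName)))
  codonBefore <- substr(cds, 3L * aaIndex - 2L, 3L * aaIndex)
  refGeneStrand <- if (strandG == "+") site$refBasePlus else
    .DNA_COMP[[site$refBasePlus]]
  if (substr(codonBefore, codonPos, codonPos) !=
      chartr("T", "U", refGeneStrand))
    stop("reference base mismatch at position ", pos, " in ", geneName)
  editedGeneStrand <- if (strandG == "+") site$editedBasePlus else
    .DNA_COMP[[site$editedBasePlus]]
  codonAfter <- codonBefore
  substr(codonAfter, codonPos, codonPos) <- chartr("T", "U",
                                                   editedGeneStrand)
  aaBefore <- translateCodon(codonBefore, code)
  aaAfter <- translateCodon(codonAfter, code)
  klass <- .classify(aaBefore, aaAfter, aaIndex, codonAfter)
  display <- sprintf("%s(%s) -> %s(%s)",
                     .aaLabel(aaBefore), .formatCodon(codonBefore, codonPos),
                     .aaLabel(aaAfter), .formatCodon(codonAfter, codonPos))
  data.frame(gene = geneName, aaIndex = aaIndex, ntIndex = ntIndex,
             codonPos = codonPos, codonBefore = codonBefore,
             codonAfter = codonAfter, aaBefore = aaBefore,
             aaAfter = aaAfter, klass = klass, display = display)
}

#' Annotate every coding site in a called-site table
#'
#' @param sites [callSites()] output; rows with `region != "coding"` are
#'   skipped.
#' @param plastome The reference [Plastome-class].
#' @param code Codon table.
#' @return Data frame of [annotateSite()] rows plus `position`,
#'   `conversion`, `frequency` and `coverage` carried over.
#' @export
annotateSites <- function(sites, plastome, code = plastidGeneticCode()) {
  coding <- sites[sites$region == "coding", , drop = FALSE]
  if (!nrow(coding)) {
    return(cbind(data.frame(position = integer(), conversion = character(),
                            frequency = numeric(), coverage = integer()),
                 data.frame(gene = character(), aaIndex = integer(),
                            ntIndex = integer(), codonPos = integer(),
                            codonBefore = character(),
                            codonAfter = character(),
                            aaBefore = character(), aaAfter = character(),
                            klass = character(), display = character())))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(coding)), function(i)
    annotateSite(coding[i, ], plastome, code)))
  cbind(coding[, c("position", "conversion", "frequency", "coverage")],
        out, row.names = NULL)
}

#' Classify a transcribed codon pair
#'
#' Classification path for fixture rows that carry printed codons rather
#' than genomic context: both codons are translated and compared. Rows
#' whose codons differ at more than one position (or none) are still
#' classified from the translations but flagged inconsistent, preserving
#' likely typos in the transcribed table.
#'
#' @param codonBefore,codonAfter RNA triplets.
#' @param code Codon table.
#' @return List with `klass`, `aaBefore`, `aaAfter`, `nDiff` (number of
#'   differing codon positions) and `inconsistent` (TRUE when `nDiff`
#'   is not exactly 1).
#' @examples
#' classifyFixtureRow("AUC", "AUU")$klass  # synonymous
#' @export
classifyFixtureRow <- function(codonBefore, codonAfter,
                               code = plastidGeneticCode()) {
  for (cd in c(codonBefore, codonAfter))
    if (nchar(cd) != 3L || grepl("[^ACGUacgu]", cd))
      stop("not an RNA triplet: '", cd, "'")
  codonBefore <- toupper(codonBefore); codonAfter <- toupper(codonAfter)
  aaB <- translateCodon(codonBefore, code)
  aaA <- translateCodon(codonAfter, code)
  nDiff <- sum(strsplit(codonBefore, "")[[1]] !=
                 strsplit(codonAfter, "")[[1]])
  list(klass = .classify(aaB, aaA), aaBefore = aaB, aaAfter = aaA,
       nDiff = nDiff, inconsistent = nDiff != 1L)
}

#' Count editing sites per gene group
#'
#' Tallies sites (called or fixture rows, anything with a `gene` column)
#' by the functional group of their gene, the bar-chart summary
#' conventionally reported for plastid editing studies.
#'
#' @param sites Data frame with a `gene` column; rows with missing gene
#'   (IGS sites) are ignored.
#' @return Named integer vector over all groups from [geneGroups()],
#'   zeros included.
#' @export
summarizeByGroup <- function(sites) {
  out <- stats::setNames(integer(length(geneGroups())), geneGroups())
  if (!nrow(sites)) return(out)
  gene <- sites$gene[!is.na(sites$gene)]
  if (!length(gene)) return(out)
  tab <- table(factor(assignGroup(gene), levels = geneGroups()))
  out[names(tab)] <- as.integer(tab)
  out
}

#' Summarise amino-acid transitions of coding edits
#'
#' Counts nonsynonymous transitions by (before, after) amino-acid pair
#' and synonymous changes separately. Stop-containing changes are counted
#' with the transitions (never as synonymous).
#'
#' @param changes Data frame with `aaBefore` and `aaAfter` columns
#'   ([annotateSites()] output, or fixture rows via their printed
#'   amino-acid letters).
#' @return List with `transitions` (data frame `aaBefore`, `aaAfter`,
#'   `n`, sorted by decreasing `n`), `synonymous` and `nonsynonymous`
#'   counts.
#' @export
summarizeSpectrum <- function(changes) {
  if (!nrow(changes))
    return(list(transitions = data.frame(aaBefore = character(),
                                         aaAfter = character(),
                                         n = integer()),
                synonymous = 0L, nonsynonymous = 0L))
  aaB <- as.character(changes$aaBefore)
  aaA <- as.character(changes$aaAfter)
  isStop <- aaB %in% c("*", "stop") | aaA %in% c("*", "stop")
  syn <- aaB == aaA & !isStop
  nonsyn <- !syn
  tr <- data.frame(aaBefore = aaB[nonsyn], aaAfter = aaA[nonsyn])
  if (nrow(tr)) {
    agg <- stats::aggregate(list(n = rep(1L, nrow(tr))),
                            by = tr, FUN = sum)
    agg <- agg[order(-agg$n, agg$aaBefore, agg$aaAfter), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(aaBefore = character(), aaAfter = character(),
                      n = integer())
  }
  list(transitions = agg, synonymous = sum(syn),
       nonsynonymous = sum(nonsyn))
}
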