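#' @import methods
#' @importFrom Biostrings DNAString RNAString reverseComplement
#' @importFrom GenomicRanges GRanges start end strand width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importClassesFrom Biostrings DNAString RNAString
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Annotated plastid genome
#'
#' Container for a single circular (or linearised) plastid genome: the
#' plus-strand sequence, the quadripartite region layout (LSC, SSC and the
#' two inverted repeats) when known, and the gene models used for editing
#' analysis. Coordinates are 1-based inclusive on the plus strand, the
#' GenBank/GFF3 convention.
#'
#' @slot seqId Sequence identifier (single string).
#' @slot sequence A [Biostrings::DNAString] over A, C, G, T, N.
#' @slot topology `"circular"` or `"linear"`.
#' @slot regions A [GenomicRanges::GRanges] with names among
#'   `LSC`, `SSC`, `IRA`, `IRB`; may be empty when the layout is unknown.
#' @slot genes A [GenomicRanges::GRanges] with metadata columns `gene`
#'   (name), `kind` (`protein`, `rRNA` or `tRNA`), `group` (functional gene
#'   group) and `pseudo` (logical).
#'
#' @seealso [Plastome()], [readPlastome()], [makePlastome()]
#' @export
setClass("Plastome",
  representation(
    seqId    = "character",
    sequence = "DNAString",
    topology = "character",
    regions  = "GRanges",
    genes    = "GRanges"
  )
)

setValidity("Plastome", function(object) {
  msgs <- character()
  if (length(object@seqId) != 1L || !nzchar(object@seqId))
    msgs <- c(msgs, "seqId must be a single non-empty string")
  if (!object@topology %in% c("circular", "linear"))
    msgs <- c(msgs, "topology must be 'circular' or 'linear'")
  L <- length(object@sequence)
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msgs <- c(msgs, paste0("sequence contains letters outside {A,C,G,T,N}: ",
                           paste(bad, collapse = ",")))
  rg <- object@regions
  if (length(rg)) {
    if (is.null(names(rg)) || !all(names(rg) %in% c("LSC", "SSC", "IRA", "IRB")))
      msgs <- c(msgs, "region names must be among LSC, SSC, IRA, IRB")
    if (any(GenomicRanges::start(rg) < 1L) || any(GenomicRanges::end(rg) > L))
      msgs <- c(msgs, "regions must lie within the sequence")
    if (length(rg) == 4L) {
      # full quadripartite layout must tile the genome without overlap
      w <- stats::setNames(GenomicRanges::width(rg), names(rg))
      if (sum(w) != L)
        msgs <- c(msgs, "the four regions must tile the full sequence")
      ov <- GenomicRanges::findOverlaps(rg, drop.self = TRUE)
      if (length(ov))
        msgs <- c(msgs, "regions must not overlap")
      if (w[["IRA"]] != w[["IRB"]])
        msgs <- c(msgs, "IRA and IRB must have equal length")
    }
  }
  gn <- object@genes
  if (length(gn)) {
    need <- c("gene", "kind", "group", "pseudo")
    if (!all(need %in% names(S4Vectors::mcols(gn))))
      msgs <- c(msgs, paste("genes must carry metadata columns",
                            paste(need, collapse = ", ")))
    else {
      if (any(GenomicRanges::start(gn) < 1L) || any(GenomicRanges::end(gn) > L))
        msgs <- c(msgs, "gene outside sequence bounds")
      if (!all(as.character(GenomicRanges::strand(gn)) %in% c("+", "-")))
        msgs <- c(msgs, "gene strand must be '+' or '-'")
      if (!all(S4Vectors::mcols(gn)$kind %in% c("protein", "rRNA", "tRNA")))
        msgs <- c(msgs, "gene kind must be protein, rRNA or tRNA")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Nested RNA secondary structure
#'
#' A set of non-crossing base pairs on an RNA sequence, as produced by
#' [foldRNA()], together with its dot-bracket rendering.
#'
#' @slot sequence A [Biostrings::RNAString].
#' @slot pairs Integer matrix with columns `i`, `j` (`i < j`, 1-based);
#'   zero rows when the structure is open.
#' @slot dotBracket Dot-bracket string of the same length as the sequence.
#' @slot minLoop Minimum number of unpaired bases enclosed by any pair.
#'
#' @seealso [foldRNA()], [structureDelta()]
#' @export
setClass("RNAStructure",
  representation(
    sequence   = "RNAString",
    pairs      = "matrix",
    dotBracket = "character",
    minLoop    = "numeric"
  )
)

setValidity("RNAStructure", function(object) {
  msgs <- character()
  n <- length(object@sequence)
  p <- object@pairs
  if (ncol(p) != 2L) msgs <- c(msgs, "pairs must have two columns")
  if (nchar(object@dotBracket) != n)
    msgs <- c(msgs, "dot-bracket length must equal sequence length")
  if (nrow(p)) {
    if (any(p < 1L) || any(p > n)) msgs <- c(msgs, "pair index out of range")
    if (any(p[, 2] - p[, 1] <= object@minLoop))
      msgs <- c(msgs, "pair violates the minimum loop constraint")
    if (anyDuplicated(as.vector(p)))
      msgs <- c(msgs, "an index occurs in more than one pair")
    # nesting: no two pairs may cross
    if (nrow(p) > 1L) {
      for (a in seq_len(nrow(p) - 1L)) {
        i <- p[a, 1]; j <- p[a, 2]
        k <- p[-seq_len(a), 1, drop = TRUE]; l <- p[-seq_len(a), 2, drop = TRUE]
        if (any((k > i & k < j & l > j) | (i > k & i < l & j > l))) {
          msgs <- c(msgs, "pairs cross (structure is not nested)")
          break
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Plastome", function(object) {
  rg <- object@regions
  cat("Plastome object '", object@seqId, "'\n", sep = "")
  cat("  length: ", length(object@sequence), " bp (", object@topology, ")\n",
      sep = "")
  if (length(rg) == 4L) {
    w <- stats::setNames(GenomicRanges::width(rg), names(rg))
    cat(sprintf("  quadripartite: LSC %d bp, SSC %d bp, IR %d bp x2\n",
                w[["LSC"]], w[["SSC"]], w[["IRA"]]))
  }
  gn <- object@genes
  if (length(gn)) {
    k <- table(S4Vectors::mcols(gn)$kind)
    cat("  genes: ", length(gn), " (",
        paste(sprintf("%s %d", names(k), as.integer(k)), collapse = ", "),
        ")\n", sep = "")
  } else cat("  genes: none\n")
})

setMethod("show", "RNAStructure", function(object) {
  n <- length(object@sequence)
  cat("RNAStructure: ", n, " nt, ", nrow(object@pairs), " base pairs\n",
      sep = "")
  if (n <= 70L) {
    cat("  ", as.character(object@sequence), "\n", sep = "")
    cat("  ", object@dotBracket, "\n", sep = "")
  }
})
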