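#' Construct a Plastome object
#'
#' Builds a validated [Plastome-class] from a sequence, an optional
#' quadripartite region table and a gene table. Gene groups are assigned
#' automatically from the gene names with [assignGroup()].
#'
#' @param seqId Sequence identifier.
#' @param sequence Character string or [Biostrings::DNAString]
#'   (A/C/G/T/N, case-insensitive).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param regions `NULL`, or a data frame with columns `name`
#'   (LSC/SSC/IRA/IRB), `start`, `end` (1-based inclusive).
#' @param genes `NULL`, a [GenomicRanges::GRanges], or a data frame with
#'   columns `name`, `strand`, `start`, `end` and optionally `kind`
#'   (inferred from the name prefix when absent) and `pseudo`.
#' @return A [Plastome-class] object.
#' @examples
#' p <- Plastome("toy", "ATGAAATAG",
#'               genes = data.frame(name = "psbX", strand = "+",
#'                                  start = 1, end = 9))
#' geneNames(p)
#' @export
Plastome <- function(seqId, sequence, topology = "circular",
                     regions = NULL, genes = NULL) {
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(toupper(sequence))
  rg <- GenomicRanges::GRanges()
  if (!is.null(regions) && nrow(as.data.frame(regions))) {
    regions <- as.data.frame(regions)
    rg <- GenomicRanges::GRanges(seqId,
            IRanges::IRanges(regions$start, regions$end))
    names(rg) <- regions$name
  }
  gn <- .asGeneGRanges(genes, seqId)
  methods::new("Plastome", seqId = seqId, sequence = sequence,
               topology = topology, regions = rg, genes = gn)
}

.asGeneGRanges <- function(genes, seqId) {
  if (is.null(genes))
    return(GenomicRanges::GRanges(
      gene = character(), kind = character(), group = character(),
      pseudo = logical()))
  if (methods::is(genes, "GRanges")) return(genes)
  genes <- as.data.frame(genes)
  if (!nrow(genes))
    return(GenomicRanges::GRanges(
      gene = character(), kind = character(), group = character(),
      pseudo = logical()))
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(setdiff(genes$strand, c("+", "-")), collapse = ","))
  if (is.null(genes$kind)) genes$kind <- .inferKind(genes$name)
  if (is.null(genes$pseudo)) genes$pseudo <- FALSE
  gn <- GenomicRanges::GRanges(seqId,
          IRanges::IRanges(genes$start, genes$end), strand = genes$strand,
          gene = genes$name, kind = genes$kind,
          group = assignGroup(genes$name), pseudo = genes$pseudo)
  gn[order(GenomicRanges::start(gn))]
}

.inferKind <- function(name) {
  ifelse(startsWith(name, "rrn"), "rRNA",
         ifelse(startsWith(name, "trn"), "tRNA", "protein"))
}

#' Read a plastome from FASTA + GFF3
#'
#' Loads a single-record reference FASTA and its gene annotations.
#' GFF3 `gene` features supply the gene models (`Name`, strand, optional
#' `pseudo=true`); `region` features named LSC/SSC/IRA/IRB, when present,
#' supply the quadripartite layout. Coordinates are kept 1-based
#' inclusive.
#'
#' @param fastaPath Path to a FASTA file with exactly one record.
#' @param gff3Path Path to a GFF3 annotation file.
#' @return A [Plastome-class] object.
#' @seealso [writePlastome()], [Plastome()]
#' @export
readPlastome <- function(fastaPath, gff3Path) {
  if (!file.exists(fastaPath)) stop("missing FASTA file: ", fastaPath)
  if (!file.exists(gff3Path)) stop("missing GFF3 file: ", gff3Path)
  ss <- Biostrings::readDNAStringSet(fastaPath)
  if (length(ss) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(ss))
  seqId <- sub("\\s.*$", "", names(ss)[1])
  seq <- ss[[1]]
  gff <- rtracklayer::import(gff3Path, format = "gff3")
  mc <- S4Vectors::mcols(gff)
  regions <- NULL
  isRegion <- mc$type == "region" & !is.na(mc$Name) &
    mc$Name %in% c("LSC", "SSC", "IRA", "IRB")
  if (any(isRegion)) {
    rr <- gff[isRegion]
    regions <- data.frame(name = S4Vectors::mcols(rr)$Name,
                          start = GenomicRanges::start(rr),
                          end = GenomicRanges::end(rr))
  }
  gg <- gff[mc$type == "gene"]
  genes <- NULL
  if (length(gg)) {
    gmc <- S4Vectors::mcols(gg)
    if (any(GenomicRanges::end(gg) > length(seq)) ||
        any(GenomicRanges::start(gg) < 1L))
      stop("gene outside sequence bounds in ", gff3Path)
    strand <- as.character(GenomicRanges::strand(gg))
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand symbol in GFF3 gene feature")
    pseudo <- rep(FALSE, length(gg))
    if (!is.null(gmc$pseudo))
      pseudo <- tolower(as.character(gmc$pseudo)) %in% "true" &
        !is.na(gmc$pseudo)
    kind <- if (!is.null(gmc$kind)) as.character(gmc$kind) else
      .inferKind(as.character(gmc$Name))
    genes <- data.frame(name = as.character(gmc$Name), strand = strand,
                        start = GenomicRanges::start(gg),
                        end = GenomicRanges::end(gg),
                        kind = kind, pseudo = pseudo)
  }
  Plastome(seqId, seq, regions = regions, genes = genes)
}

#' Write a plastome to FASTA + GFF3
#'
#' Inverse of [readPlastome()]: emits the plus-strand sequence as a
#' single-record FASTA and the gene/region models as GFF3 features, so a
#' written plastome round-trips to an identical gene table.
#'
#' @param plastome A [Plastome-class] object.
#' @param fastaPath,gff3Path Output paths.
#' @return Invisibly, the plastome.
#' @export
writePlastome <- function(plastome, fastaPath, gff3Path) {
  ss <- Biostrings::DNAStringSet(plastome@sequence)
  names(ss) <- plastome@seqId
  Biostrings::writeXStringSet(ss, fastaPath)
  gn <- plastome@genes
  feats <- GenomicRanges::GRanges()
  if (length(gn)) {
    mc <- S4Vectors::mcols(gn)
    feats <- GenomicRanges::GRanges(plastome@seqId,
      IRanges::IRanges(GenomicRanges::start(gn), GenomicRanges::end(gn)),
      strand = GenomicRanges::strand(gn))
    S4Vectors::mcols(feats) <- S4Vectors::DataFrame(
      source = "plastedit", type = "gene",
      ID = paste0("gene", seq_along(gn)), Name = mc$gene,
      kind = mc$kind, pseudo = ifelse(mc$pseudo, "true", "false"))
  }
  rg <- plastome@regions
  if (length(rg)) {
    rf <- GenomicRanges::GRanges(plastome@seqId,
      IRanges::IRanges(GenomicRanges::start(rg), GenomicRanges::end(rg)))
    S4Vectors::mcols(rf) <- S4Vectors::DataFrame(
      source = "plastedit", type = "region",
      ID = paste0("region", seq_along(rg)), Name = names(rg),
      kind = NA_character_, pseudo = NA_character_)
    feats <- c(rf, feats)
  }
  rtracklayer::export(feats, gff3Path, format = "gff3")
  invisible(plastome)
}

#' Assign a plastid gene to its functional group
#'
#' Maps gene names to the ten conventional plastid gene groups by name
#' prefix: `psa*`/`psb*` photosystems, `rpo*` RNA polymerase, `ndh*` NADH
#' oxidoreductase, `rps*`/`rpl*` ribosomal proteins, `atp*` ATP synthase,
#' `pet*` cytochrome b6/f, `rbcL` Rubisco, `rrn*` rRNAs, `ycf*`
#' hypothetical proteins; anything else (matK, cemA, ccsA, accD, clpP,
#' infA, tRNAs, ...) is `miscellaneous`.
#'
#' @param geneName Character vector of gene names.
#' @return Character vector of group labels.
#' @examples
#' assignGroup(c("ndhB", "rbcL", "matK"))
#' @export
assignGroup <- function(geneName) {
  stopifnot(is.character(geneName), all(nzchar(geneName)))
  out <- rep("miscellaneous", length(geneName))
  out[startsWith(geneName, "psa") | startsWith(geneName, "psb")] <-
    "Photosystem I and II"
  out[startsWith(geneName, "rpo")] <- "RNA polymerase"
  out[startsWith(geneName, "ndh")] <- "NADH oxidoreductase"
  out[startsWith(geneName, "rps") | startsWith(geneName, "rpl")] <-
    "ribosomal proteins"
  out[startsWith(geneName, "atp")] <- "ATP synthase"
  out[startsWith(geneName, "pet")] <- "cytochrome b6/f"
  out[startsWith(geneName, "rrn")] <- "rRNAs"
  out[startsWith(geneName, "ycf")] <- "hypothetical proteins"
  out[geneName == "rbcL"] <- "Rubisco"
  out
}

#' All plastid gene-group labels, in display order.
#' @return Character vector of the ten group labels.
#' @export
geneGroups <- function() {
  c("Rubisco", "NADH oxidoreductase", "RNA polymerase",
    "Photosystem I and II", "ribosomal proteins", "ATP synthase",
    "cytochrome b6/f", "hypothetical proteins", "rRNAs", "miscellaneous")
}

#' The plastid genetic code as an RNA-codon table
#'
#' NCBI translation table 11 (bacterial/plastid), keyed by RNA codons,
#' with stop codons mapped to `"*"`. AUG is M; UAA, UAG and UGA are stop.
#'
#' @return Named character vector of length 64 (codon -> one-letter
#'   amino acid or `"*"`).
#' @export
plastidGeneticCode <- function() {
  code <- Biostrings::getGeneticCode("11")
  names(code) <- chartr("T", "U", names(code))
  code
}

#' Translate a single RNA codon
#'
#' @param codon Three-letter RNA codon (A/C/G/U, case-insensitive).
#' @param code Codon table, by default [plastidGeneticCode()].
#' @return One-letter amino acid, or `"*"` for stop.
#' @examples
#' translateCodon("UCA")  # "S"
#' translateCodon("UAA")  # "*"
#' @export
translateCodon <- function(codon, code = plastidGeneticCode()) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L)
    stop("codon must be 3 RNA letters, got '", codon, "'")
  if (grepl("[^ACGU]", codon))
    stop("codon contains letters outside {A,C,G,U}: '", codon, "'")
  unname(code[[codon]])
}

#' Total length of a quadripartite plastome
#'
#' @param lscLen,sscLen,irLen Lengths (bp) of the large single copy, the
#'   small single copy and one inverted repeat; all must be positive
#'   integers.
#' @return `lscLen + sscLen + 2 * irLen`.
#' @examples
#' quadripartiteLength(81888, 17607, 26492)  # 152479
#' @export
quadripartiteLength <- function(lscLen, sscLen, irLen) {
  vals <- c(lscLen, sscLen, irLen)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals != round(vals)))
    stop("all region lengths must be positive integers")
  lscLen + sscLen + 2L * irLen
}

#' @describeIn geneSequence Gene-strand sequence of a named gene: the
#'   plus-strand slice for plus-strand genes, its reverse complement for
#'   minus-strand genes.
#' @param x A [Plastome-class] object.
#' @param gene Gene name.
#' @return A [Biostrings::DNAString] in gene-strand orientation.
#' @name geneSequence
setMethod("geneSequence", "Plastome", function(x, gene) {
  gn <- x@genes
  hit <- which(S4Vectors::mcols(gn)$gene == gene)
  if (!length(hit)) stop("no gene named '", gene, "' in plastome")
  g <- gn[hit[1]]
  s <- Biostrings::subseq(x@sequence, GenomicRanges::start(g),
                          GenomicRanges::end(g))
  if (as.character(GenomicRanges::strand(g)) == "-")
    s <- Biostrings::reverseComplement(s)
  s
})

#' Detect internal stop codons in a protein gene
#'
#' Translates the spliced coding sequence of a protein gene and reports
#' whether any codon before the terminal one is a stop, the signature
#' used to flag pseudogenes (for example infA or cemA copies disrupted by
#' poly-A length polymorphism).
#'
#' @param plastome A [Plastome-class] object.
#' @param gene Name of a protein gene whose length is divisible by 3.
#' @param code Codon table, by default [plastidGeneticCode()].
#' @return Logical: `TRUE` when an internal stop is present.
#' @export
hasInternalStop <- function(plastome, gene, code = plastidGeneticCode()) {
  s <- chartr("T", "U", as.character(geneSequence(plastome, gene)))
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("gene '", gene, "' length not divisible by 3")
  if (n <= 3L) return(FALSE)
  starts <- seq(1L, n - 3L, by = 3L)  # all codons except the terminal one
  codons <- substring(s, starts, starts + 2L)
  any(code[codons] == "*")
}
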