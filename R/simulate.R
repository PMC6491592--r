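## Synthetic quadripartite plastomes, injected editing sites and
## error-bearing RNA reads, with ground-truth tables so every pipeline
## stage can be tested end to end without external data.

## Canonical plastid gene names, ordered to spread synthetic genes over
## the functional groups.
.SYNTH_GENE_NAMES <- c(
  "rbcL", "ndhB", "rpoB", "psbA", "rps14", "atpA", "petB", "ycf3",
  "matK", "ndhD", "rpoC1", "psaA", "rpl2", "atpB", "petD", "ycf4",
  "ccsA", "ndhF", "rpoA", "psbD", "rps3", "atpF", "petA", "clpP",
  "ndhA", "rpoC2", "psaB", "rpl23", "atpI", "petL", "cemA", "ndhG",
  "psbC", "rps18", "atpE", "petG", "accD", "ndhH", "psbE", "rpl36")

.STOP_DNA <- c("TAA", "TAG", "TGA")
.SENSE_DNA <- setdiff(as.vector(outer(outer(c("A", "C", "G", "T"),
                      c("A", "C", "G", "T"), paste0),
                      c("A", "C", "G", "T"), paste0)), .STOP_DNA)

#' Configuration for the plastome/read simulator
#'
#' Collects and validates every tunable of the synthetic study: the
#' quadripartite layout, gene number and strandedness, per-gene
#' expression weights, injected editing sites, and the RNA read model
#' (length 76 bp and a per-base substitution error rate, matching
#' short-read transcriptome sequencing; the companion genomic platform
#' constant is 301 bp, see [meanCoverage()]).
#'
#' @param seed Integer seed driving all randomness.
#' @param lscLen,sscLen,irLen Region lengths in bp.
#' @param nGenes Number of intronless protein genes to place (in the
#'   single-copy regions).
#' @param strandFractionMinus Probability that a gene goes on the minus
#'   strand.
#' @param geneLengths Optional vector of gene lengths (bp, divisible by
#'   3, recycled); by default lengths are drawn from 300-900 bp.
#' @param expressionWeights Optional positive per-gene weights
#'   (recycled); default 1 for every gene.
#' @param editingSites Optional data frame `gene` (name or 1-based gene
#'   number), `ntIndex` (position in the coding sequence, gene strand),
#'   `conversion` (e.g. `"C-to-U"`), `targetFraction` in (0, 1].
#' @param readLength RNA read length in bp (default 76).
#' @param nReads Number of RNA reads to simulate.
#' @param errorRate Per-base substitution error probability.
#' @return A validated list of class `simConfig`.
#' @seealso [makePlastome()], [simulateReads()]
#' @export
simulationConfig <- function(seed = 1L, lscLen = 5000L, sscLen = 1500L,
                             irLen = 2000L, nGenes = 10L,
                             strandFractionMinus = 0.5,
                             geneLengths = NULL,
                             expressionWeights = NULL,
                             editingSites = NULL,
                             readLength = 76L, nReads = 20000L,
                             errorRate = 0.001) {
  stopifnot(lscLen > 0, sscLen > 0, irLen > 0, nGenes >= 0,
            strandFractionMinus >= 0, strandFractionMinus <= 1,
            readLength > 0, nReads >= 0, errorRate >= 0, errorRate < 1)
  if (!is.null(geneLengths)) {
    if (any(geneLengths %% 3L != 0L))
      stop("gene lengths must be divisible by 3")
    geneLengths <- rep_len(geneLengths, nGenes)
  }
  if (!is.null(expressionWeights)) {
    if (any(expressionWeights <= 0))
      stop("expression weights must be positive")
    expressionWeights <- rep_len(expressionWeights, nGenes)
  }
  if (!is.null(editingSites)) {
    editingSites <- as.data.frame(editingSites)
    need <- c("gene", "ntIndex", "conversion", "targetFraction")
    if (!all(need %in% names(editingSites)))
      stop("editingSites needs columns ", paste(need, collapse = ", "))
    if (any(editingSites$targetFraction <= 0 |
              editingSites$targetFraction > 1))
      stop("targetFraction must lie in (0, 1]")
    if (!all(grepl("^[ACGU]-to-[ACGU]$", editingSites$conversion)))
      stop("conversion must look like 'C-to-U'")
  }
  structure(list(seed = as.integer(seed), lscLen = as.integer(lscLen),
                 sscLen = as.integer(sscLen), irLen = as.integer(irLen),
                 nGenes = as.integer(nGenes),
                 strandFractionMinus = strandFractionMinus,
                 geneLengths = geneLengths,
                 expressionWeights = expressionWeights,
                 editingSites = editingSites,
                 readLength = as.integer(readLength),
                 nReads = as.integer(nReads), errorRate = errorRate),
            class = "simConfig")
}

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random intronless CDS: ATG + sense codons + stop (DNA letters).
.randomCDS <- function(lengthBp) {
  nCodon <- lengthBp %/% 3L
  if (nCodon < 3L) stop("gene too short for start + body + stop")
  body <- sample(.SENSE_DNA, nCodon - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(.STOP_DNA, 1L))
}

## Force a gene-strand base at a CDS position by swapping in a sense
## codon carrying it, leaving the start and stop codons untouched.
.forceBase <- function(cds, ntIndex, base) {
  n <- nchar(cds)
  if (ntIndex <= 3L || ntIndex > n - 3L)
    stop("editing ntIndex must avoid the start and stop codons")
  ci <- (ntIndex - 1L) %/% 3L + 1L
  cp <- (ntIndex - 1L) %% 3L + 1L
  cand <- .SENSE_DNA[substr(.SENSE_DNA, cp, cp) == base]
  codon <- sample(cand, 1L)
  substr(cds, 3L * ci - 2L, 3L * ci) <- codon
  cds
}

#' Generate a synthetic quadripartite plastome
#'
#' Builds a random plastome with the canonical layout LSC-IRA-SSC-IRB
#' (IRB the reverse complement of IRA), places intronless protein genes
#' (ATG start, sense body, single terminal stop) non-overlapping on both
#' strands of the single-copy regions, and plants the requested editing
#' sites by forcing the pre-edit base into the coding sequence. Fully
#' deterministic under the config seed.
#'
#' @param config A [simulationConfig()].
#' @return List with `plastome` (a [Plastome-class]) and `truth`: the
#'   gene table, the editing-site table with plus-strand coordinates and
#'   injected fractions, the per-gene expression weights and the config.
#' @export
makePlastome <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  nGenes <- config$nGenes
  geneLengths <- config$geneLengths
  if (is.null(geneLengths) && nGenes > 0)
    geneLengths <- 3L * sample(100:200, nGenes, replace = TRUE)
  if (nGenes > .SYNTH_GENE_NAMES |> length())
    stop("at most ", length(.SYNTH_GENE_NAMES), " synthetic genes supported")
  names <- .SYNTH_GENE_NAMES[seq_len(nGenes)]
  weights <- config$expressionWeights
  if (is.null(weights) && nGenes > 0) weights <- rep(1, nGenes)

  ## lay genes sequentially into LSC then SSC with random spacers
  lsc <- strsplit(.randomDNA(config$lscLen), "")[[1]]
  ssc <- strsplit(.randomDNA(config$sscLen), "")[[1]]
  regionOffsets <- c(LSC = 0L, SSC = config$lscLen + config$irLen)
  geneTable <- NULL
  cdsList <- list()
  if (nGenes > 0) {
    strandMinus <- stats::runif(nGenes) < config$strandFractionMinus
    cursor <- list(LSC = 1L, SSC = 1L)
    seqs <- list(LSC = lsc, SSC = ssc)
    lens <- c(LSC = config$lscLen, SSC = config$sscLen)
    rows <- vector("list", nGenes)
    for (g in seq_len(nGenes)) {
      cds <- .randomCDS(geneLengths[g])
      es <- config$editingSites
      if (!is.null(es)) {
        mine <- es[es$gene == names[g] | es$gene == g, , drop = FALSE]
        for (r in seq_len(nrow(mine))) {
          src <- chartr("U", "T", substr(mine$conversion[r], 1L, 1L))
          cds <- .forceBase(cds, mine$ntIndex[r], src)
        }
        ## re-roll any internal stop introduced by base forcing
        guard <- 0L
        repeat {
          starts <- seq(1L, nchar(cds) - 3L, by = 3L)
          codons <- substring(cds, starts, starts + 2L)
          if (!any(codons %in% .STOP_DNA) || guard > 100L) break
          bad <- which(codons %in% .STOP_DNA)[1]
          substr(cds, 3L * bad - 2L, 3L * bad) <- sample(.SENSE_DNA, 1L)
          for (r in seq_len(nrow(mine))) {  # re-assert forced bases
            src <- chartr("U", "T", substr(mine$conversion[r], 1L, 1L))
            ci <- (mine$ntIndex[r] - 1L) %/% 3L + 1L
            if (ci == bad) cds <- .forceBase(cds, mine$ntIndex[r], src)
          }
          guard <- guard + 1L
        }
      }
      ## place into whichever single-copy region has more room left
      spacer <- sample(30L:80L, 1L)
      rem <- c(LSC = lens[["LSC"]] - cursor[["LSC"]],
               SSC = lens[["SSC"]] - cursor[["SSC"]])
      region <- names(rem)[which.max(rem)]
      start <- cursor[[region]] + spacer
      end <- start + geneLengths[g] - 1L
      if (end > lens[[region]] - 30L) {  # try the other region
        region <- setdiff(c("LSC", "SSC"), region)
        start <- cursor[[region]] + spacer
        end <- start + geneLengths[g] - 1L
        if (end > lens[[region]] - 30L)
          stop("genes cannot fit into the single-copy regions")
      }
      insert <- if (strandMinus[g])
        strsplit(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds))), "")[[1]]
      else strsplit(cds, "")[[1]]
      seqs[[region]][start:end] <- insert
      cursor[[region]] <- end + 1L
      rows[[g]] <- data.frame(
        name = names[g], strand = if (strandMinus[g]) "-" else "+",
        start = regionOffsets[[region]] + start,
        end = regionOffsets[[region]] + end,
        kind = "protein", pseudo = FALSE)
      cdsList[[names[g]]] <- cds
    }
    geneTable <- do.call(rbind, rows)
    lsc <- seqs$LSC; ssc <- seqs$SSC
  }

  ira <- .randomDNA(config$irLen)
  irb <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ira)))
  sequence <- paste0(paste(lsc, collapse = ""), ira,
                     paste(ssc, collapse = ""), irb)
  totalLen <- quadripartiteLength(config$lscLen, config$sscLen,
                                  config$irLen)
  regions <- data.frame(
    name = c("LSC", "IRA", "SSC", "IRB"),
    start = c(1L, config$lscLen + 1L,
              config$lscLen + config$irLen + 1L,
              config$lscLen + config$irLen + config$sscLen + 1L),
    end = c(config$lscLen, config$lscLen + config$irLen,
            config$lscLen + config$irLen + config$sscLen, totalLen))
  plastome <- Plastome("synthetic_plastome", sequence,
                       regions = regions, genes = geneTable)

  siteTruth <- data.frame(gene = character(), ntIndex = integer(),
                          conversion = character(),
                          targetFraction = numeric(),
                          positionPlus = integer(),
                          refBasePlus = character(),
                          editedBasePlus = character())
  es <- config$editingSites
  if (!is.null(es) && nrow(es) && nGenes > 0) {
    gname <- ifelse(es$gene %in% names, as.character(es$gene),
                    names[suppressWarnings(as.integer(es$gene))])
    gi <- match(gname, geneTable$name)
    strand <- geneTable$strand[gi]
    posPlus <- ifelse(strand == "+",
                      geneTable$start[gi] + es$ntIndex - 1L,
                      geneTable$end[gi] - es$ntIndex + 1L)
    srcGene <- chartr("U", "T", substr(es$conversion, 1L, 1L))
    tgtGene <- chartr("U", "T", substr(es$conversion, 6L, 6L))
    refPlus <- ifelse(strand == "+", srcGene, .DNA_COMP[srcGene])
    edPlus <- ifelse(strand == "+", tgtGene, .DNA_COMP[tgtGene])
    siteTruth <- data.frame(gene = gname, ntIndex = es$ntIndex,
                            conversion = es$conversion,
                            targetFraction = es$targetFraction,
                            positionPlus = as.integer(posPlus),
                            refBasePlus = unname(refPlus),
                            editedBasePlus = unname(edPlus))
  }
  if (is.null(geneTable))
    geneTable <- data.frame(name = character(), strand = character(),
                            start = integer(), end = integer(),
                            kind = character(), pseudo = logical())
  list(plastome = plastome,
       truth = list(genes = geneTable, sites = siteTruth,
                    weights = if (nGenes > 0)
                      stats::setNames(weights, geneTable$name[
                        match(names, geneTable$name)]) else numeric(0),
                    cds = cdsList, config = config))
}

#' Simulate RNA reads with editing and sequencing error
#'
#' Draws reads from the spliced gene sequences in proportion to the
#' expression weights, uniform start positions within each gene. A read
#' covering an injected editing site carries the edited base
#' independently with probability `targetFraction` (the Bernoulli
#' sampling model behind the conversion-frequency statistic); each base
#' is then substituted with probability `errorRate`. Gene-strand reads
#' from minus-strand genes are reverse-complemented into plus-strand
#' alignment records. Deterministic under the config seed.
#'
#' @param plastome The synthetic [Plastome-class] from [makePlastome()].
#' @param truth The matching truth list from [makePlastome()].
#' @param config The same [simulationConfig()].
#' @return List with `alignments` (data frame `qname`, `start`, `seq`,
#'   `strand`, `gene`, `offset`; `seq` is plus-strand) and `truth`
#'   extended with the per-read table.
#' @seealso [writeSam()], [truthCompare()]
#' @export
simulateReads <- function(plastome, truth, config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed + 1L)   # distinct stream from genome construction
  genes <- truth$genes
  rl <- config$readLength
  n <- config$nReads
  if (!nrow(genes) || n == 0L)
    return(list(alignments = data.frame(qname = character(),
                  start = integer(), seq = character(),
                  strand = character(), gene = character(),
                  offset = integer()),
                truth = truth))
  geneLen <- genes$end - genes$start + 1L
  if (any(rl > geneLen))
    stop("read length exceeds the shortest gene length")
  w <- truth$weights[genes$name]
  gi <- sample(seq_len(nrow(genes)), n, replace = TRUE, prob = w)
  offset <- floor(stats::runif(n) * (geneLen[gi] - rl + 1L)) + 1L
  cdsChar <- vapply(genes$name, function(nm) truth$cds[[nm]], "")
  seqs <- substr(cdsChar[gi], offset, offset + rl - 1L)

  ## per-site Bernoulli editing on the gene strand
  sites <- truth$sites
  for (r in seq_len(nrow(sites))) {
    sgi <- match(sites$gene[r], genes$name)
    rel <- sites$ntIndex[r] - offset + 1L
    covered <- which(gi == sgi & rel >= 1L & rel <= rl)
    if (!length(covered)) next
    flip <- covered[stats::runif(length(covered)) <
                      sites$targetFraction[r]]
    if (length(flip)) {
      tgt <- chartr("U", "T", substr(sites$conversion[r], 6L, 6L))
      substr(seqs[flip], rel[flip], rel[flip]) <- tgt
    }
  }

  ## independent substitution errors
  if (config$errorRate > 0) {
    hit <- which(stats::runif(n * rl) < config$errorRate)
    for (k in hit) {
      rd <- (k - 1L) %/% rl + 1L
      pp <- (k - 1L) %% rl + 1L
      old <- substr(seqs[rd], pp, pp)
      substr(seqs[rd], pp, pp) <- sample(setdiff(c("A", "C", "G", "T"),
                                                 old), 1L)
    }
  }

  minus <- genes$strand[gi] == "-"
  startPlus <- ifelse(minus,
                      genes$end[gi] - offset - rl + 2L,
                      genes$start[gi] + offset - 1L)
  plusSeqs <- seqs
  if (any(minus))
    plusSeqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  alignments <- data.frame(
    qname = sprintf("read%06d", seq_len(n)),
    start = as.integer(startPlus), seq = plusSeqs,
    strand = ifelse(minus, "-", "+"),
    gene = genes$name[gi], offset = offset)
  truth$reads <- alignments[, c("qname", "gene", "offset", "start",
                                "strand")]
  list(alignments = alignments, truth = truth)
}

#' Write simulated alignments as a SAM file
#'
#' Minimal single-reference SAM dialect: an `@HD`/`@SQ` header and one
#' ungapped record per read (`FLAG` 0 or 16, full-length `M` CIGAR,
#' plus-strand SEQ, `QUAL` `*`).
#'
#' @param alignments [simulateReads()] alignments.
#' @param plastome The reference [Plastome-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeSam <- function(alignments, plastome, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", plastome@seqId, "\tLN:",
                     length(plastome@sequence)))
  if (!nrow(alignments)) {
    writeLines(header, path)
    return(invisible(path))
  }
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  rec <- paste(alignments$qname, flag, plastome@seqId, alignments$start,
               60L, paste0(nchar(alignments$seq), "M"), "*", 0L, 0L,
               alignments$seq, "*", sep = "\t")
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Compare called sites against simulation truth
#'
#' @param calledSites [callSites()] output.
#' @param truth Truth list from [makePlastome()] / [simulateReads()].
#' @param threshold The calling threshold: injected sites with
#'   `targetFraction` strictly above it form the sensitivity
#'   denominator.
#' @return List with `sensitivity` (called eligible sites / eligible
#'   sites; `NaN` when no site is eligible) and `falsePositives` (called
#'   positions absent from the truth).
#' @export
truthCompare <- function(calledSites, truth, threshold = 0.05) {
  truthPos <- truth$sites$positionPlus
  eligible <- truthPos[truth$sites$targetFraction > threshold]
  called <- calledSites$position
  list(sensitivity = if (length(eligible))
         sum(eligible %in% called) / length(eligible) else NaN,
       falsePositives = sum(!called %in% truthPos))
}
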