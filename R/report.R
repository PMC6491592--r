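## Pipeline orchestration and packaged fixture access.

.FIXTURE_FILES <- c(table2 = "table2_sites.tsv",
                    table3 = "table3_expression.tsv")
## transcription checksums: rows and coverage / length-column totals
.FIXTURE_ROWS <- c(table2 = 91L, table3 = 80L)

#' Load a packaged fixture table
#'
#' The package ships two transcribed summary tables from a published
#' *Lilium lancifolium* plastid transcriptome study: `"table2"`, the
#' per-site editing table (gene, position as printed, codon change,
#' coverage and per-base read counts; printed values preserved verbatim,
#' including internally inconsistent rows, with a recomputed frequency
#' column added), and `"table3"`, the per-gene expression table (gene,
#' length, RPKM as printed).
#'
#' @param name `"table2"` or `"table3"`.
#' @return The schema-validated fixture data frame. `table2` rows carry
#'   `gene`, `site`, `aa_index`, `nt_index_printed`, `position_printed`,
#'   `codon_pos`, `codon_before`, `codon_after`, `aa_before_printed`,
#'   `aa_after_printed`, `conversion`, `coverage`, `count_ref`,
#'   `count_alt`, `printed_pct_ref`, `printed_pct_alt`,
#'   `synonymous_flag_printed`, plus the recomputed `frequency`
#'   (`count_alt / coverage`). `table3` rows carry `gene`, `length_bp`,
#'   `rpkm`.
#' @export
loadFixture <- function(name) {
  if (!name %in% names(.FIXTURE_FILES))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.FIXTURE_FILES), collapse = ", "))
  path <- system.file("extdata", .FIXTURE_FILES[[name]],
                      package = "plastedit", mustWork = TRUE)
  fix <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(fix) != .FIXTURE_ROWS[[name]])
    stop("fixture '", name, "' has ", nrow(fix), " rows, expected ",
         .FIXTURE_ROWS[[name]])
  if (name == "table2") {
    need <- c("gene", "site", "aa_index", "nt_index_printed",
              "position_printed", "codon_pos", "codon_before",
              "codon_after", "aa_before_printed", "aa_after_printed",
              "conversion", "coverage", "count_ref", "count_alt",
              "printed_pct_ref", "printed_pct_alt",
              "synonymous_flag_printed")
    miss <- setdiff(need, names(fix))
    if (length(miss))
      stop("table2 fixture lacks column(s): ",
           paste(miss, collapse = ", "))
    bad <- which(fix$coverage <= 0 | fix$count_alt < 0 |
                   fix$count_ref < 0)
    if (length(bad))
      stop("table2 fixture row ", bad[1], ": invalid count/coverage")
    fix$frequency <- fix$count_alt / fix$coverage
  } else {
    need <- c("gene", "length_bp", "rpkm")
    miss <- setdiff(need, names(fix))
    if (length(miss))
      stop("table3 fixture lacks column(s): ",
           paste(miss, collapse = ", "))
    bad <- which(fix$length_bp <= 0 | fix$rpkm < 0)
    if (length(bad))
      stop("table3 fixture row ", bad[1], ": invalid length/rpkm")
  }
  fix
}

#' Summaries of the per-site fixture
#'
#' Recomputes the study-level editing summaries from the transcribed
#' per-site table: the gene-group tally, the conversion-content
#' spectrum, the amino-acid transition spectrum and the synonymous /
#' nonsynonymous split (from the printed amino-acid letters; coding rows
#' only).
#'
#' @param fixture The `table2` fixture from [loadFixture()].
#' @return List with `nSites`, `groupTally`, `conversionSpectrum`,
#'   `spectrum` (see [summarizeSpectrum()]) and `perGene` site counts.
#' @export
fixtureSummary <- function(fixture) {
  groupTally <- summarizeByGroup(fixture)
  conversionSpectrum <- substitutionSpectrum(fixture)
  coding <- fixture[!is.na(fixture$aa_before_printed), , drop = FALSE]
  spectrum <- summarizeSpectrum(
    data.frame(aaBefore = coding$aa_before_printed,
               aaAfter = coding$aa_after_printed))
  perGene <- table(fixture$gene)
  list(nSites = nrow(fixture), groupTally = groupTally,
       conversionSpectrum = conversionSpectrum, spectrum = spectrum,
       perGene = stats::setNames(as.integer(perGene), names(perGene)))
}

#' Run the full editing-analysis pipeline
#'
#' Orchestrates pileup -> site calling -> codon annotation -> summaries
#' -> expression ranking over one reference and one set of RNA
#' alignments, optionally writing the TSV reports and a plain-text
#' summary.
#'
#' @param plastome A [Plastome-class], or a length-2 character vector
#'   `c(fastaPath, gff3Path)` passed to [readPlastome()].
#' @param sam Path to a SAM file (mutually exclusive with
#'   `alignments`).
#' @param alignments Truth-alignment data frame for
#'   [pileupFromTruth()].
#' @param threshold,minCoverage,allowedConversions Passed to
#'   [callSites()].
#' @param maxMismatches Passed to [pileupFromSam()].
#' @param outDir Optional output directory for the TSV + summary files.
#' @param seed Optional seed recorded in the metadata (the pipeline
#'   itself is deterministic).
#' @return List of class `plasteditReport`: `sites`, `annotations`,
#'   `groupTally`, `conversionSpectrum`, `spectrum`, `expression`,
#'   `igs`, `metadata`.
#' @export
runPipeline <- function(plastome, sam = NULL, alignments = NULL,
                        threshold = 0.05, minCoverage = 10,
                        allowedConversions = c("C-to-U", "U-to-C",
                                               "A-to-G"),
                        maxMismatches = 2, outDir = NULL, seed = NA) {
  if (is.character(plastome)) {
    stopifnot(length(plastome) == 2L)
    plastome <- readPlastome(plastome[1], plastome[2])
  }
  if (is.null(sam) == is.null(alignments))
    stop("provide exactly one of 'sam' or 'alignments'")
  pileup <- if (!is.null(sam))
    pileupFromSam(sam, plastome, maxMismatches = maxMismatches)
  else pileupFromTruth(alignments, plastome)
  sites <- callSites(pileup, plastome, threshold = threshold,
                     minCoverage = minCoverage,
                     allowedConversions = allowedConversions)
  annotations <- annotateSites(sites, plastome)
  groupTally <- summarizeByGroup(sites[sites$region %in%
                                         c("coding", "rRNA"), ,
                                       drop = FALSE])
  spectrum <- summarizeSpectrum(annotations)
  expr <- expressionTable(if (!is.null(sam)) sam else alignments,
                          plastome)
  report <- structure(list(
    sites = sites, annotations = annotations, groupTally = groupTally,
    conversionSpectrum = substitutionSpectrum(sites),
    spectrum = spectrum, expression = expr,
    metadata = list(threshold = threshold, minCoverage = minCoverage,
                    allowedConversions = allowedConversions,
                    maxMismatches = maxMismatches, seed = seed,
                    seqId = plastome@seqId,
                    genomeLength = length(plastome@sequence),
                    package = as.character(utils::packageVersion(
                      "plastedit")))),
    class = "plasteditReport")
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `sites.tsv`, `annotations.tsv`, `group_tally.tsv`,
#' `expression.tsv` and a human-readable `summary.txt` whose every
#' number is reproducible from the TSVs.
#'
#' @param report A `plasteditReport` from [runPipeline()].
#' @param outDir Output directory (created if needed).
#' @return Invisibly, `outDir`.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(report$sites, "sites.tsv")
  wt(report$annotations, "annotations.tsv")
  wt(data.frame(group = names(report$groupTally),
                n = as.integer(report$groupTally)), "group_tally.tsv")
  wt(report$expression, "expression.tsv")
  md <- report$metadata
  lines <- c(
    "plastedit pipeline summary",
    sprintf("reference: %s (%d bp)", md$seqId, md$genomeLength),
    sprintf("threshold: %g  min coverage: %d", md$threshold,
            md$minCoverage),
    sprintf("editing sites called: %d", nrow(report$sites)),
    sprintf("  coding: %d  rRNA: %d  tRNA: %d  IGS: %d",
            sum(report$sites$region == "coding"),
            sum(report$sites$region == "rRNA"),
            sum(report$sites$region == "tRNA"),
            sum(report$sites$region == "IGS")),
    sprintf("synonymous: %d  nonsynonymous: %d",
            report$spectrum$synonymous, report$spectrum$nonsynonymous),
    "conversion spectrum:",
    sprintf("  %s: %d", names(report$conversionSpectrum),
            report$conversionSpectrum),
    "top expressed genes:",
    sprintf("  %s (RPKM %.1f)", utils::head(report$expression$gene, 3),
            utils::head(report$expression$rpkm, 3)))
  writeLines(lines, file.path(outDir, "summary.txt"))
  invisible(outDir)
}

#' @export
print.plasteditReport <- function(x, ...) {
  cat("plastedit report:", nrow(x$sites), "editing sites (",
      x$spectrum$synonymous, "synonymous /",
      x$spectrum$nonsynonymous, "nonsynonymous among coding )\n")
  invisible(x)
}
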