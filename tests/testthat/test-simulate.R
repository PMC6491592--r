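test_that("synthetic plastomes honour the quadripartite contract", {
  cfg <- simulationConfig(seed = 7, lscLen = 5000, sscLen = 1500,
                          irLen = 2000, nGenes = 10, nReads = 0)
  mk <- makePlastome(cfg)
  p <- mk$plastome
  expect_equal(length(plastomeSeq(p)), 10500L)
  rg <- plastomeRegions(p)
  w <- stats::setNames(GenomicRanges::width(rg), names(rg))
  expect_equal(unname(w[c("LSC", "SSC", "IRA", "IRB")]),
               c(5000L, 1500L, 2000L, 2000L))
  ## IR mirror property
  ira <- Biostrings::subseq(plastomeSeq(p),
                            GenomicRanges::start(rg[names(rg) == "IRA"]),
                            GenomicRanges::end(rg[names(rg) == "IRA"]))
  irb <- Biostrings::subseq(plastomeSeq(p),
                            GenomicRanges::start(rg[names(rg) == "IRB"]),
                            GenomicRanges::end(rg[names(rg) == "IRB"]))
  expect_equal(as.character(Biostrings::reverseComplement(ira)),
               as.character(irb))
  ## genes: non-overlapping, ATG start, terminal stop
  g <- mk$truth$genes
  g <- g[order(g$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  for (nm in g$name) {
    cds <- as.character(geneSequence(p, nm))
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("an empty gene table and determinism both hold", {
  cfg0 <- simulationConfig(seed = 3, nGenes = 0, nReads = 0)
  expect_length(geneNames(makePlastome(cfg0)$plastome), 0L)
  cfg <- simulationConfig(seed = 3, nGenes = 5, nReads = 500)
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  gff1 <- tempfile(fileext = ".gff3"); gff2 <- tempfile(fileext = ".gff3")
  mk1 <- makePlastome(cfg); writePlastome(mk1$plastome, fa1, gff1)
  mk2 <- makePlastome(cfg); writePlastome(mk2$plastome, fa2, gff2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gff1), readLines(gff2))
  s1 <- simulateReads(mk1$plastome, mk1$truth, cfg)
  s2 <- simulateReads(mk2$plastome, mk2$truth, cfg)
  expect_identical(s1$alignments, s2$alignments)
  sam1 <- tempfile(); sam2 <- tempfile()
  writeSam(s1$alignments, mk1$plastome, sam1)
  writeSam(s2$alignments, mk2$plastome, sam2)
  expect_identical(readLines(sam1), readLines(sam2))
})

test_that("error-free unedited reads reproduce the reference exactly", {
  cfg <- simulationConfig(seed = 9, nGenes = 6, nReads = 5000,
                          errorRate = 0)
  mk <- makePlastome(cfg)
  sim <- simulateReads(mk$plastome, mk$truth, cfg)
  expect_equal(nrow(sim$alignments), 5000L)   # conservation
  pu <- pileupFromTruth(sim$alignments, mk$plastome)
  refChars <- strsplit(as.character(plastomeSeq(mk$plastome)), "")[[1]]
  cnt <- as.matrix(pu[, c("A", "C", "G", "T")])
  refCount <- cnt[cbind(seq_len(nrow(pu)),
                        match(refChars[pu$position], colnames(cnt)))]
  expect_equal(as.integer(refCount), pu$coverage)
})

test_that("injected fractions are recovered within binomial error", {
  cfg <- simulationConfig(seed = 15, nGenes = 4, geneLengths = 450L,
    editingSites = data.frame(gene = 2, ntIndex = 225,
                              conversion = "C-to-U",
                              targetFraction = 0.5),
    nReads = 6000, errorRate = 0)
  mk <- makePlastome(cfg)
  sim <- simulateReads(mk$plastome, mk$truth, cfg)
  pu <- pileupFromTruth(sim$alignments, mk$plastome)
  site <- mk$truth$sites
  row <- pu[pu$position == site$positionPlus, ]
  edited <- row[[site$editedBasePlus]]
  frac <- edited / row$coverage
  expect_gt(row$coverage, 200)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / row$coverage))
})

test_that("a minus-strand C-to-U edit appears as plus-strand G-to-A", {
  ## force every gene onto the minus strand so the site is mirrored
  cfg <- simulationConfig(seed = 25, nGenes = 2, geneLengths = 450L,
    strandFractionMinus = 1,
    editingSites = data.frame(gene = 1, ntIndex = 100,
                              conversion = "C-to-U",
                              targetFraction = 0.6),
    nReads = 6000, errorRate = 0)
  mk <- makePlastome(cfg)
  expect_true(all(mk$truth$genes$strand == "-"))
  st <- mk$truth$sites
  expect_equal(st$refBasePlus, "G")
  expect_equal(st$editedBasePlus, "A")
  sim <- simulateReads(mk$plastome, mk$truth, cfg)
  pu <- pileupFromTruth(sim$alignments, mk$plastome)
  row <- pu[pu$position == st$positionPlus, ]
  expect_gt(row$A, 0)          # plus-strand A reads carry the edit
  called <- callSites(pu, mk$plastome)
  hit <- called[called$position == st$positionPlus, ]
  expect_equal(hit$conversion, "C-to-U")   # reported on the gene strand
})

test_that("truth comparison scores sensitivity and false positives", {
  truth <- list(sites = data.frame(positionPlus = c(100L, 200L, 300L),
                                   targetFraction = c(0.5, 0.3, 0.02)))
  perfect <- data.frame(position = c(100L, 200L))
  tc <- truthCompare(perfect, truth)
  expect_equal(tc$sensitivity, 1)          # 0.02 site is ineligible
  expect_equal(tc$falsePositives, 0L)
  withFp <- data.frame(position = c(100L, 999L))
  tc2 <- truthCompare(withFp, truth)
  expect_equal(tc2$sensitivity, 0.5)
  expect_equal(tc2$falsePositives, 1L)
})
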