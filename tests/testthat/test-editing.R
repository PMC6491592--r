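test_that("conversion frequency reproduces tabulated per-site values", {
  ## printed counts and printed coverage from the transcribed table
  f1 <- conversionFrequency(c(A = 0, C = 39, G = 0, T = 187680), "C",
                            coverage = 188389)
  expect_equal(unname(f1["T"]), 187680 / 188389, tolerance = 1e-12)
  expect_equal(round(100 * unname(f1["T"]), 2), 99.62)
  f2 <- conversionFrequency(c(A = 0, C = 140, G = 0, T = 8556), "C",
                            coverage = 8704)
  expect_equal(round(100 * unname(f2["T"]), 1), 98.3)
  f3 <- conversionFrequency(c(A = 0, C = 10, G = 0, T = 0), "C")
  expect_true(all(f3 == 0))
  expect_error(conversionFrequency(c(A = 0, C = 0, G = 0, T = 0), "C"),
               "zero coverage")
})

test_that("the calling rule is strictly over threshold with min coverage", {
  p <- toyPlastome()
  ## position 10 is the C of codon UCA in psbT (plus strand)
  mkPileup <- function(cEd, cRef) data.frame(
    position = 10L, A = 0L, C = cRef, G = 0L, T = cEd,
    coverage = cEd + cRef)
  called <- callSites(mkPileup(53, 947), p, minCoverage = 1)   # 5.3%
  expect_equal(nrow(called), 1L)
  expect_equal(called$gene, "psbT")
  expect_equal(called$conversion, "C-to-U")
  boundary <- callSites(mkPileup(50, 950), p, minCoverage = 1)  # 5.0%
  expect_equal(nrow(boundary), 0L)
  ## coverage gate
  expect_equal(nrow(callSites(mkPileup(3, 6), p, minCoverage = 10)), 0L)
  expect_equal(nrow(callSites(mkPileup(3, 6), p, minCoverage = 1)), 1L)
  expect_error(callSites(mkPileup(10, 10), p, threshold = 0), "threshold")
  expect_error(callSites(mkPileup(10, 10), p, threshold = 1), "threshold")
})

test_that("conversion content is reported on the gene strand", {
  p <- toyPlastome()
  ## ndhX is minus-strand; its CDS nt 8 (C of codon CCG) sits at plus
  ## position 41 where the plus base is G; a gene-strand C-to-U edit
  ## appears as plus-strand G->A
  pu <- data.frame(position = 41L, A = 30L, C = 0L, G = 70L, T = 0L,
                   coverage = 100L)
  called <- callSites(pu, p, minCoverage = 1)
  expect_equal(called$gene, "ndhX")
  expect_equal(called$refBasePlus, "G")
  expect_equal(called$editedBasePlus, "A")
  expect_equal(called$conversion, "C-to-U")
  expect_equal(called$frequency, 0.3)
})

test_that("positions outside genes are labelled IGS", {
  p <- toyPlastome()
  pu <- data.frame(position = 2L, A = 0L, C = 80L, G = 0L, T = 20L,
                   coverage = 100L)
  called <- callSites(pu, p, minCoverage = 1)
  expect_equal(called$region, "IGS")
  expect_true(is.na(called$gene))
})

test_that("disallowed conversions are suppressed unless 'all' is chosen", {
  p <- toyPlastome()
  ## plus-strand psbT position 7 is T (codon 1 is ATG... psbT starts
  ## at 6); a T->G signal is U-to-G on the gene strand
  pu <- data.frame(position = 7L, A = 0L, C = 0L, G = 40L, T = 60L,
                   coverage = 100L)
  expect_equal(nrow(callSites(pu, p, minCoverage = 1)), 0L)
  all <- callSites(pu, p, minCoverage = 1, allowedConversions = "all")
  expect_equal(all$conversion, "U-to-G")
})

test_that("raising threshold or coverage never adds called sites", {
  cfg <- simulationConfig(seed = 13, nGenes = 8, nReads = 12000,
    editingSites = data.frame(gene = c(1, 2, 3, 5), ntIndex = c(30, 45,
      60, 75), conversion = "C-to-U",
      targetFraction = c(0.08, 0.2, 0.5, 0.9)))
  mk <- makePlastome(cfg)
  sim <- simulateReads(mk$plastome, mk$truth, cfg)
  pu <- pileupFromTruth(sim$alignments, mk$plastome)
  thresholds <- c(0.02, 0.05, 0.1, 0.3, 0.6)
  nCalls <- vapply(thresholds, function(th)
    nrow(callSites(pu, mk$plastome, threshold = th)), 0L)
  expect_true(all(diff(nCalls) <= 0))
  covs <- c(1, 10, 50, 200, 1000)
  nCov <- vapply(covs, function(mc)
    nrow(callSites(pu, mk$plastome, minCoverage = mc)), 0L)
  expect_true(all(diff(nCov) <= 0))
})

test_that("called frequency concentrates around the injected fraction", {
  cfg <- recoveryConfig(seed = 21)
  mk <- makePlastome(cfg)
  sim <- simulateReads(mk$plastome, mk$truth, cfg)
  pu <- pileupFromTruth(sim$alignments, mk$plastome)
  called <- callSites(pu, mk$plastome)
  truth <- mk$truth$sites
  m <- match(truth$positionPlus, called$position)
  expect_false(anyNA(m))
  for (k in seq_len(nrow(truth))) {
    fr <- called$frequency[m[k]]
    p0 <- truth$targetFraction[k]
    se <- sqrt(p0 * (1 - p0) / called$coverage[m[k]])
    expect_lt(abs(fr - p0), 4 * se + 0.005)  # 0.005 absorbs error reads
  }
})

test_that("the substitution spectrum tallies conversion content", {
  fix <- loadFixture("table2")
  spec <- substitutionSpectrum(fix)
  expect_equal(unname(spec["U-to-C"]), 2L)   # rpl36 and rrn23S
  expect_equal(unname(spec["A-to-G"]), 1L)   # petB site 1
  expect_equal(unname(spec["C-to-U"]),
               nrow(fix) - 2L - 1L)
  expect_equal(substitutionSpectrum(fix[0, ]), integer(0))
  expect_setequal(fix$gene[fix$conversion == "U-to-C"],
                  c("rpl36", "rrn23S"))
})
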