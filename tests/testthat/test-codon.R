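test_that("annotation reproduces the canonical codon-change patterns", {
  ## plus-strand gene carrying the four textbook cases: S->L at codon
  ## position 2, P->P at position 3, Q->stop at position 1, and an
  ## ACG->AUG start gain at codon 1
  cds <- paste0("ACG", "TCA", "CCC", "CAA", "TAA")
  p <- Plastome("x", paste0("AA", cds, "TT"), genes = data.frame(
    name = "ndhD", strand = "+", start = 3, end = 17))
  site <- function(pos) {
    ref <- substr(paste0("AA", cds, "TT"), pos, pos)
    list(position = pos, refBasePlus = ref, editedBasePlus = "T")
  }
  sl <- annotateSite(site(3 + 4), p)          # TCA codon pos 2
  expect_equal(sl$display, "S(uCa) -> L(uUa)")
  expect_equal(sl$klass, "nonsynonymous")
  expect_equal(c(sl$aaIndex, sl$ntIndex, sl$codonPos), c(2, 5, 2))
  pp <- annotateSite(site(3 + 8), p)          # CCC codon pos 3
  expect_equal(pp$display, "P(ccC) -> P(ccU)")
  expect_equal(pp$klass, "synonymous")
  qs <- annotateSite(site(3 + 9), p)          # CAA codon pos 1
  expect_equal(qs$display, "Q(Caa) -> stop(Uaa)")
  expect_equal(qs$klass, "stop_gain")
  sg <- annotateSite(site(3 + 1), p)          # ACG codon 1, pos 2
  expect_equal(sg$display, "T(aCg) -> M(aUg)")
  expect_equal(sg$klass, "start_gain")
  ## nt index arithmetic invariant
  for (ann in list(sl, pp, qs, sg))
    expect_equal(ann$ntIndex, 3 * (ann$aaIndex - 1) + ann$codonPos)
})

test_that("an ACG->AUG edit away from codon 1 is plain nonsynonymous", {
  cds <- paste0("ATG", "ACG", "TAA")
  p <- Plastome("x", cds, genes = data.frame(
    name = "rpl2", strand = "+", start = 1, end = 9))
  ann <- annotateSite(list(position = 5, refBasePlus = "C",
                           editedBasePlus = "T"), p)
  expect_equal(ann$codonAfter, "AUG")
  expect_equal(ann$klass, "nonsynonymous")
  expect_equal(ann$aaBefore, "T")
  expect_equal(ann$aaAfter, "M")
})

test_that("sites outside protein genes or frame-broken genes error", {
  p <- toyPlastome()
  expect_error(annotateSite(list(position = 1, refBasePlus = "A",
                                 editedBasePlus = "G"), p),
               "outside any protein gene")
  broken <- Plastome("x", "ATGAAATAGG", genes = data.frame(
    name = "psbA", strand = "+", start = 1, end = 10))
  expect_error(annotateSite(list(position = 5, refBasePlus = "A",
                                 editedBasePlus = "G"), broken),
               "divisible by 3")
})

test_that("fixture-row classification follows the translations", {
  expect_equal(classifyFixtureRow("AUC", "AUU")$klass, "synonymous")
  expect_equal(classifyFixtureRow("GUC", "GUU")$klass, "synonymous")
  expect_equal(classifyFixtureRow("UCA", "UUA")$klass, "nonsynonymous")
  expect_equal(classifyFixtureRow("CAA", "UAA")$klass, "stop_gain")
  expect_equal(classifyFixtureRow("UAA", "CAA")$klass, "stop_loss")
  ident <- classifyFixtureRow("UCA", "UCA")
  expect_equal(ident$klass, "synonymous")
  expect_true(ident$inconsistent)           # zero differing positions
  expect_equal(ident$nDiff, 0L)
  twoPos <- classifyFixtureRow("UCA", "UUU") # transcribed typo pattern
  expect_true(twoPos$inconsistent)
  expect_equal(twoPos$klass, "nonsynonymous")
  expect_error(classifyFixtureRow("UC", "UUU"), "triplet")
})

test_that("every single-base codon edit classifies like brute force", {
  code <- plastidGeneticCode()
  bases <- c("A", "C", "G", "U")
  codons <- names(code)
  for (cd in codons) {
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(cd, pos, pos))) {
        after <- cd
        substr(after, pos, pos) <- alt
        got <- classifyFixtureRow(cd, after)
        aaB <- unname(code[[cd]]); aaA <- unname(code[[after]])
        expected <- if (aaA == "*") "stop_gain"
          else if (aaB == "*") "stop_loss"
          else if (aaB == aaA) "synonymous" else "nonsynonymous"
        expect_equal(got$klass, expected,
                     info = paste(cd, pos, alt))
        expect_equal(got$aaBefore, aaB)
        expect_equal(got$aaAfter, aaA)
      }
    }
  }
})

test_that("injected coding edits round-trip through annotation", {
  cfg <- simulationConfig(seed = 31, nGenes = 10, nReads = 20000,
    editingSites = data.frame(gene = 1:6,
      ntIndex = c(20, 32, 44, 56, 68, 80), conversion = "C-to-U",
      targetFraction = 0.5))
  mk <- makePlastome(cfg)
  sim <- simulateReads(mk$plastome, mk$truth, cfg)
  pu <- pileupFromTruth(sim$alignments, mk$plastome)
  called <- callSites(pu, mk$plastome)
  ann <- annotateSites(called, mk$plastome)
  truth <- mk$truth$sites
  expect_setequal(called$position, truth$positionPlus)
  m <- match(truth$positionPlus, called$position)
  expect_equal(ann$ntIndex[m], truth$ntIndex)
  ## the injected conversion is C-to-U on the gene strand everywhere
  expect_true(all(substr(ann$codonBefore[m], ann$codonPos[m],
                         ann$codonPos[m]) == "C"))
  expect_true(all(substr(ann$codonAfter[m], ann$codonPos[m],
                         ann$codonPos[m]) == "U"))
})

test_that("group summaries count sites per gene group", {
  fix <- loadFixture("table2")
  tally <- summarizeByGroup(fix)
  expect_equal(unname(tally["NADH oxidoreductase"]), 29L)
  expect_equal(unname(tally["RNA polymerase"]), 16L)
  expect_equal(sum(tally), nrow(fix))
  empty <- summarizeByGroup(fix[0, ])
  expect_true(all(empty == 0L))
  expect_named(empty, geneGroups())
})

test_that("the amino-acid spectrum separates synonymous changes", {
  one <- summarizeSpectrum(data.frame(aaBefore = "S", aaAfter = "L"))
  expect_equal(one$transitions$n, 1L)
  expect_equal(one$synonymous, 0L)
  mixed <- summarizeSpectrum(data.frame(
    aaBefore = c("S", "S", "P", "Q"), aaAfter = c("L", "S", "P", "stop")))
  expect_equal(mixed$synonymous, 2L)
  expect_equal(mixed$nonsynonymous, 2L)   # S->L and the stop gain
  empty <- summarizeSpectrum(data.frame(aaBefore = character(),
                                        aaAfter = character()))
  expect_equal(empty$synonymous, 0L)
  expect_equal(nrow(empty$transitions), 0L)
})
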