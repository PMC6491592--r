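test_that("spacers are emitted only for gapped adjacent gene pairs", {
  seq <- paste(rep("ACGTT", 8), collapse = "")  # 40 bp
  p <- Plastome("x", seq, genes = data.frame(
    name = c("psbA", "rbcL"), strand = "+",
    start = c(1, 20), end = c(9, 30)))
  igs <- extractIGS(p)
  expect_equal(nrow(igs), 1L)
  expect_equal(igs$name, "psbA-rbcL")
  expect_equal(igs$length, 10L)
  expect_equal(igs$sequence, substr(seq, 10, 19))
  ## overlapping genes emit nothing
  pov <- Plastome("x", seq, genes = data.frame(
    name = c("psbA", "rbcL"), strand = "+",
    start = c(1, 8), end = c(9, 30)))
  expect_equal(nrow(extractIGS(pov)), 0L)
})

test_that("synthetic spacer lengths match the generator's gap table", {
  cfg <- simulationConfig(seed = 23, nGenes = 8, nReads = 0)
  mk <- makePlastome(cfg)
  igs <- extractIGS(mk$plastome)
  g <- mk$truth$genes[order(mk$truth$genes$start), ]
  gaps <- g$start[-1] - g$end[-nrow(g)] - 1L
  names(gaps) <- paste0(g$name[-nrow(g)], "-", g$name[-1])
  gaps <- gaps[gaps >= 1L]
  expect_equal(nrow(igs), length(gaps))
  expect_equal(igs$length, unname(gaps[igs$name]))
})

test_that("percent identity behaves on identical and mutated pairs", {
  s <- paste(rep("ACGTAACCGGT", 5), collapse = "")  # 55-mer
  expect_equal(percentIdentity(s, s), 100)
  s2 <- s; substr(s2, 30, 30) <- "T"
  expect_lt(percentIdentity(s, s2), 100)
  expect_equal(percentIdentity("ACGTACGTAC", "ACGTACGTAA"), 90)
  expect_error(percentIdentity("", "ACGT"), "empty")
})

test_that("alignment scores match the dynamic-programming oracle", {
  set.seed(404)
  for (rep in 1:50) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- paste(sample(c("A", "C", "G", "T"), na, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), nb, TRUE), collapse = "")
    expect_equal(alignGlobal(a, b)$score, oracleNWScore(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with an independent aligner", {
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  set.seed(406)
  for (rep in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
               collapse = "")
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "global", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = 2))
    expect_equal(alignGlobal(a, b)$score, ref, info = paste(a, b))
  }
})

test_that("the reported alignment is consistent with its own counts", {
  set.seed(407)
  for (rep in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1), TRUE),
               collapse = "")
    al <- alignGlobal(a, b)
    ca <- strsplit(al$alignedA, "")[[1]]
    cb <- strsplit(al$alignedB, "")[[1]]
    expect_equal(length(ca), al$columns)
    expect_equal(sum(ca == cb & ca != "-"), al$matches)
    expect_equal(gsub("-", "", al$alignedA), a)
    expect_equal(gsub("-", "", al$alignedB), b)
  }
})

test_that("identity is symmetric and reverse-complement invariant", {
  set.seed(505)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = "")
    pab <- percentIdentity(a, b)
    expect_equal(pab, percentIdentity(b, a))
    expect_equal(pab, percentIdentity(rc(a), rc(b)))
  }
})

test_that("hotspots are the spacers strictly below 95 percent", {
  rec <- data.frame(name = c("petA-psbJ", "ndhF-rpl32", "rps8-rpl14",
                             "edge"),
                    identityPct = c(84.2, 93.95, 96.95, 95.0))
  hs <- hotspotReport(rec)
  expect_equal(hs$name, c("petA-psbJ", "ndhF-rpl32"))  # ascending
  expect_false("edge" %in% hs$name)                    # strict <
  expect_equal(nrow(hotspotReport(rec[rec$identityPct == 100, ])), 0L)
})

test_that("two diverged plastomes yield per-spacer identities", {
  cfg <- simulationConfig(seed = 29, nGenes = 6, nReads = 0)
  mk <- makePlastome(cfg)
  pA <- mk$plastome
  ## mutate one spacer heavily to create a hotspot
  igs <- extractIGS(pA)
  seqB <- as.character(plastomeSeq(pA))
  target <- igs[which.max(igs$length), ]
  set.seed(1)
  mutPos <- sample(target$start:target$end,
                   ceiling(target$length * 0.3))
  for (i in mutPos) {
    old <- substr(seqB, i, i)
    substr(seqB, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  g <- mk$truth$genes
  pB <- Plastome(seqId(pA), seqB,
                 genes = g[, c("name", "strand", "start", "end")])
  cmp <- compareIGS(pA, pB)
  expect_true(all(cmp$identityPct >= 0 & cmp$identityPct <= 100))
  expect_true(target$name %in% hotspotReport(cmp)$name)
  untouched <- cmp$identityPct[cmp$name != target$name]
  expect_true(all(untouched == 100))
})
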