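test_that("intron phases follow cumulative coding length mod 3", {
  m45 <- makeModel(c(1, 100), c(45, 150))
  expect_equal(intronPhases(m45)[[1]], 0L)
  m46 <- makeModel(c(1, 100), c(46, 150))
  expect_equal(intronPhases(m46)[[1]], 1L)

  # 7-exon gene vs an independent codon-walk oracle
  lens <- c(120L, 300L, 132L, 246L, 375L, 132L, 375L)
  starts <- cumsum(c(1L, head(lens, -1) + 500L))
  m7 <- makeModel(starts, starts + lens - 1L)
  got <- intronPhases(m7)[[1]]
  # oracle: walk codon positions nucleotide by nucleotide
  posInCodon <- 0L; oracle <- integer(0)
  for (ex in seq_along(lens)) {
    for (nt in seq_len(lens[ex])) posInCodon <- (posInCodon + 1L) %% 3L
    if (ex < length(lens)) oracle <- c(oracle, posInCodon)
  }
  expect_equal(got, oracle)
})

test_that("phase vector is invariant under strand reversal of the locus", {
  set.seed(31)
  for (rep in 1:8) {
    nEx <- sample(2:7, 1)
    lens <- sample(30:200, nEx)
    starts <- cumsum(c(1L, head(lens, -1) + sample(80:300, nEx - 1)))
    ends <- starts + lens - 1L
    L <- max(ends) + 10L
    mPlus <- makeModel(starts, ends)
    mMinus <- makeModel(rev(L - ends + 1L), rev(L - starts + 1L),
                        strand = "-")
    expect_equal(intronPhases(mPlus)[[1]], intronPhases(mMinus)[[1]])
  }
})

test_that("TPS class assignment is the documented pure function of intron count", {
  expect_equal(classifyTpsClass(6), "III")
  expect_equal(classifyTpsClass(9), "II")
  expect_equal(classifyTpsClass(7), "unclassified")
  # exhaustive over 0..20
  got <- classifyTpsClass(0:20)
  want <- rep("unclassified", 21)
  want[6 + 1] <- "III"; want[9 + 1] <- "II"; want[(11:14) + 1] <- "I"
  expect_equal(got, want)
  expect_error(classifyTpsClass(-1), "non-negative")
})

test_that("gene architecture attributes codon remainders to the next exon", {
  # exon nt lengths 46, 45, 44: aa lengths floor-carry -> 15, 15, 15
  m <- makeModel(c(1, 100, 200), c(46, 144, 243))
  arch <- geneArchitecture(m)
  expect_equal(as.list(arch$exon_lengths_aa)[[1]], c(15L, 15L, 15L))
  expect_equal(sum(as.list(arch$exon_lengths_aa)[[1]]) * 3L,
               sum(IRanges::width(exonRanges(m)[[1]])))
  expect_equal(arch$n_introns, 2L)
})

test_that("exon/intron statistics summarize positions and the 81-400 band", {
  m1 <- makeModel(c(1, 100), c(45, 150))       # intron 54 nt
  arch1 <- geneArchitecture(m1)
  st1 <- exonIntronStats(arch1)
  expect_equal(st1$exon_stats$median, c(15, 17))
  expect_equal(st1$intron_summary$min, 54L)

  # an intron of 16 nt is included and reported as the minimum
  m2 <- makeModel(c(1, 62), c(45, 120), tx = "t2", gene = "g2")
  arch <- rbind(arch1, geneArchitecture(m2))
  st <- exonIntronStats(arch)
  expect_equal(st$intron_summary$min, 16L)
  expect_equal(st$intron_summary$n, 2L)
  expect_error(exonIntronStats(arch[0, ]), "empty")
})

test_that("splice consensus reaches 2 - e_n bits at invariant GT/AG bases", {
  set.seed(33)
  # construct 40 two-exon genes with canonical GT..AG introns, random flanks
  nGenes <- 40L
  seqs <- character(nGenes); models <- list()
  for (i in seq_len(nGenes)) {
    ex1 <- randomDnaStr(30); intr <- paste0("GT", randomDnaStr(26), "AG")
    ex2 <- randomDnaStr(30)
    seqs[i] <- paste0(ex1, intr, ex2)
    gr <- GenomicRanges::GRanges(paste0("c", i),
      IRanges::IRanges(c(1, 61), c(30, 90)), strand = "+")
    models[[paste0("t", i)]] <- gr
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs,
                                                     paste0("c", seq_len(nGenes))))
  gm <- GeneModelSet(GenomicRanges::GRangesList(models),
                     geneId = paste0("g", seq_len(nGenes)))
  cons <- spliceConsensus(gm, genome, flank = 10L)
  en <- 3 / (2 * log(2) * nGenes)
  # donor +1,+2 are G,T; acceptor -2,-1 are A,G
  expect_equal(cons@donorIC[["+1"]], 2 - en, tolerance = 1e-12)
  expect_equal(cons@donorIC[["+2"]], 2 - en, tolerance = 1e-12)
  expect_equal(cons@acceptorIC[["-2"]], 2 - en, tolerance = 1e-12)
  expect_equal(cons@acceptorIC[["-1"]], 2 - en, tolerance = 1e-12)
  expect_equal(unname(colSums(cons@donorPFM)), rep(1, 20), tolerance = 1e-9)
  # random flank columns carry little information (entropy limit)
  expect_lt(mean(cons@donorIC[1:10]), 0.25)
})

test_that("a planted purine split at donor -1 carries about one bit", {
  set.seed(34)
  nGenes <- 400L
  seqs <- character(nGenes); models <- list()
  for (i in seq_len(nGenes)) {
    ex1 <- paste0(randomDnaStr(29), sample(c("A", "G"), 1))  # R at donor -1
    intr <- paste0("GT", randomDnaStr(26), "AG")
    seqs[i] <- paste0(ex1, intr, randomDnaStr(30))
    models[[paste0("t", i)]] <- GenomicRanges::GRanges(paste0("c", i),
      IRanges::IRanges(c(1, 61), c(30, 90)), strand = "+")
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs,
                                                     paste0("c", seq_len(nGenes))))
  gm <- GeneModelSet(GenomicRanges::GRangesList(models),
                     geneId = paste0("g", seq_len(nGenes)))
  cons <- spliceConsensus(gm, genome, flank = 10L)
  expect_equal(cons@donorIC[["-1"]], 1, tolerance = 0.12)
})

test_that("short introns are skipped with a warning", {
  m <- makeModel(c(1, 38, 100, 170), c(30, 68, 130, 200))  # 7-nt intron 1
  genome <- Biostrings::DNAStringSet(c(chr1 = randomDnaStr(210)))
  expect_warning(cons <- spliceConsensus(m, genome, flank = 10L), "skipped")
  expect_equal(cons@nDonor, 2L)
})
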