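test_that("FASTA reading parses, normalizes and validates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), fa)
  seqs <- readGenome(fa)
  expect_equal(length(seqs), 1L)
  expect_equal(unname(Biostrings::width(seqs)), 4L)
  expect_equal(as.character(seqs[[1]]), "ACGT")

  writeLines(c(">g1", "ACGT", ">g1", "TTTT"), fa)
  expect_error(readGenome(fa), "duplicated")

  writeLines(character(0), fa)
  expect_error(readGenome(fa), "empty")

  writeLines(c("chr1", "ACGT"), fa)
  expect_error(readGenome(fa), "line 1")
})

test_that("FASTA write-then-read round-trips byte-identically", {
  set.seed(20)
  seqs <- Biostrings::DNAStringSet(c(c1 = randomDnaStr(251),
                                     c2 = randomDnaStr(70)))
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeGenome(seqs, f1)
  writeGenome(readGenome(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("GFF3 reading groups CDS by transcript and validates strands", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  base <- c("##gff-version 3",
            "chr1\tsrc\tgene\t1\t700\t.\t+\t.\tID=g1",
            "chr1\tsrc\tmRNA\t1\t700\t.\t+\t.\tID=t1;Parent=g1")
  cds <- sprintf("chr1\tsrc\tCDS\t%d\t%d\t.\t+\t0\tID=t1.c%d;Parent=t1",
                 seq(1, 601, by = 100), seq(40, 640, by = 100), 1:7)
  writeLines(c(base, cds), gff)
  models <- readGeneModels(gff)
  expect_equal(length(models), 1L)
  expect_equal(length(exonRanges(models)[[1]]), 7L)
  expect_equal(geneIds(models), "g1")
  expect_equal(txStrand(models), c(t1 = "+"))

  # CDS without Parent
  writeLines(c(base, "chr1\tsrc\tCDS\t1\t40\t.\t+\t0\tID=x"), gff)
  expect_error(readGeneModels(gff), "Parent")

  # mixed strands within one transcript
  writeLines(c(base,
               "chr1\tsrc\tCDS\t1\t40\t.\t+\t0\tParent=t1",
               "chr1\tsrc\tCDS\t100\t140\t.\t-\t0\tParent=t1"), gff)
  expect_error(readGeneModels(gff), "[Mm]ixed|strand")

  # CDS beyond chromosome end
  writeLines(c(base, "chr1\tsrc\tCDS\t1\t500\t.\t+\t0\tParent=t1"), gff)
  genome <- Biostrings::DNAStringSet(c(chr1 = randomDnaStr(100)))
  expect_error(readGeneModels(gff, genome = genome), "beyond")
})

test_that("gene model writer round-trips content", {
  m <- makeModel(c(11, 101, 301), c(70, 180, 420), strand = "-",
                 chrom = "chr2", tx = "txA", gene = "gA")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeGeneModels(m, gff)
  back <- readGeneModels(gff)
  expect_equal(names(back), names(m))
  expect_equal(geneIds(back), geneIds(m))
  expect_equal(txStrand(back), txStrand(m))
  expect_equal(IRanges::start(exonRanges(back)[[1]]),
               IRanges::start(exonRanges(m)[[1]]))
  expect_equal(IRanges::end(exonRanges(back)[[1]]),
               IRanges::end(exonRanges(m)[[1]]))
})

test_that("extractCDS concatenates exons and honours the minus strand", {
  # plus-strand two-exon gene: "ATGAAA" + "TGA"
  genome <- Biostrings::DNAStringSet(c(c1 = paste0("TT", "ATGAAA", "GTCCAG",
                                                   "TGA", "CC")))
  m <- makeModel(c(3, 15), c(8, 17), chrom = "c1")
  expect_equal(as.character(extractCDS(m, genome)[[1]]), "ATGAAATGA")

  # the same locus reverse-complemented, with flipped strand and mirrored
  # coordinates, yields the identical transcript
  L <- Biostrings::width(genome)[1]
  rcGenome <- Biostrings::DNAStringSet(stats::setNames(
    as.character(Biostrings::reverseComplement(genome[[1]])), "c1"))
  ex <- exonRanges(m)[[1]]
  m2 <- makeModel(rev(L - IRanges::end(ex) + 1),
                  rev(L - IRanges::start(ex) + 1),
                  strand = "-", chrom = "c1")
  expect_equal(as.character(extractCDS(m2, rcGenome)[[1]]), "ATGAAATGA")

  # out of bounds
  m3 <- makeModel(3, 1000, chrom = "c1")
  expect_error(extractCDS(m3, genome), "out of bounds")
})

test_that("strand symmetry holds for random multi-exon loci", {
  set.seed(7)
  for (rep in 1:10) {
    nEx <- sample(2:6, 1)
    starts <- cumsum(sample(50:150, nEx)) + seq(0, by = 200,
                                                length.out = nEx)
    ends <- starts + sample(30:90, nEx)
    L <- max(ends) + 25
    genome <- Biostrings::DNAStringSet(c(g = randomDnaStr(L)))
    m <- makeModel(starts, ends, chrom = "g")
    rcGenome <- Biostrings::DNAStringSet(stats::setNames(
      as.character(Biostrings::reverseComplement(genome[[1]])), "g"))
    m2 <- makeModel(rev(L - ends + 1), rev(L - starts + 1), strand = "-",
                    chrom = "g")
    expect_identical(as.character(extractCDS(m, genome)[[1]]),
                     as.character(extractCDS(m2, rcGenome)[[1]]))
  }
})

test_that("translation follows the ORF-length arithmetic and flags completeness", {
  p <- translateCDS("ATGTGA")
  expect_equal(as.character(p[[1]]), "M")
  expect_true(S4Vectors::mcols(p)$complete)

  # ORF length in nt -> residue count: len/3 - 1 for a complete ORF
  set.seed(8)
  for (nt in c(1680L, 1689L, 1683L, 1668L)) {
    orf <- randomOrf(nt / 3L)
    pp <- translateCDS(orf)
    expect_equal(nchar(as.character(pp[[1]])), nt / 3L - 1L)
    expect_true(S4Vectors::mcols(pp)$complete)
  }

  expect_error(translateCDS("ATGA"), "frame")

  # ambiguous codons translate to X; internal stop breaks completeness
  px <- translateCDS("ATGANATGA")
  expect_equal(as.character(px[[1]]), "MX")
  expect_true(S4Vectors::mcols(px)$degenerate)   # 50% X >= 10% threshold
  pok <- translateCDS(paste0("ATGANA", strrep("AAA", 20), "TGA"))
  expect_false(S4Vectors::mcols(pok)$degenerate) # 1 X in 21 residues
  pi <- translateCDS("ATGTAAAAATGA")
  expect_equal(as.character(pi[[1]]), "M")
  expect_false(S4Vectors::mcols(pi)$complete)
  expect_equal(S4Vectors::mcols(pi)$n_internal_stops, 1L)
})

test_that("protein length equals cds/3 - 1 over many random complete ORFs", {
  set.seed(9)
  n <- sample(3:400, 1000, replace = TRUE)
  orfs <- vapply(n, randomOrf, character(1))
  prot <- translateCDS(orfs)
  expect_true(all(S4Vectors::mcols(prot)$complete))
  expect_equal(nchar(as.character(prot)), n - 1L)
})

test_that("longest-ORF search scans both strands and breaks ties", {
  set.seed(10)
  inner <- "ATGAAATGA"
  seq <- paste0(randomDnaStr(20), inner, randomDnaStr(20))
  # flanks free of ATG..stop longer than 9 nt are not guaranteed; use a
  # fixed flank without ATG or stops in any frame instead
  seq <- paste0("CCCCCCCCCC", inner, "CCCCCCCCCC")
  r <- findLongestOrf(seq, minLenNt = 9L)
  expect_true(r$found)
  expect_equal(as.character(r$cds), inner)
  expect_equal(r$length_nt, 9L)
  expect_equal(r$strand, "+")

  # two ORFs: 300 nt and 1683 nt; the longer one wins. The separator has
  # stops in all six frames (it is its own reverse complement), so no ORF
  # can extend across it.
  sep <- "TTAATTAATTAA"
  big <- randomOrf(1683L / 3L)
  small <- randomOrf(100L)
  s2 <- paste0(sep, small, sep, big, sep)
  r2 <- findLongestOrf(s2, minLenNt = 150L)
  expect_equal(r2$length_nt, 1683L)
  expect_equal(as.character(r2$cds), big)

  # minus strand detection
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s2)))
  r3 <- findLongestOrf(rc, minLenNt = 150L)
  expect_equal(r3$length_nt, 1683L)
  expect_equal(r3$strand, "-")

  # all-N input finds nothing
  r4 <- findLongestOrf(strrep("N", 300), minLenNt = 30L)
  expect_false(r4$found)
})

test_that("synthetic genomes round-trip through the readers", {
  sim <- assembleGenome(smallSpec())
  dir <- withr::local_tempdir()
  expect_no_warning(assembleGenome(smallSpec(), dir = dir))
  genome <- expect_no_warning(readGenome(file.path(dir, "genome.fasta")))
  models <- expect_no_warning(readGeneModels(file.path(dir, "models.gff3"),
                                             genome = genome))
  expect_equal(sort(names(models)), sort(names(sim@models)))
  m1 <- exonRanges(models)[names(sim@models)]
  m2 <- exonRanges(sim@models)
  expect_equal(unname(lapply(m1, IRanges::start)),
               unname(lapply(m2, IRanges::start)))
  expect_equal(unname(lapply(m1, IRanges::end)),
               unname(lapply(m2, IRanges::end)))
})
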