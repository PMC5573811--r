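test_that("generated genes follow their class template", {
  spec <- smallSpec()
  set.seed(100)
  g3 <- makeGene(spec, "TPS-a", "gA")
  expect_equal(length(exonRanges(g3$model)[[1]]), 7L)   # class III: 6 introns
  expect_equal(classifyTpsClass(6), g3$truth$class)
  g1 <- makeGene(spec, "TPS-c", "gC")
  expect_equal(length(exonRanges(g1$model)[[1]]), 13L)  # class I: 12 introns
  expect_equal(g1$truth$class, "I")
  # the locus re-extracts to the generated CDS and translates completely
  cds <- extractCDS(g3$model, g3$locus)
  expect_equal(as.character(cds[[1]]), g3$cds)
  p <- translateCDS(cds)
  expect_true(S4Vectors::mcols(p)$complete)
  expect_equal(as.character(p[[1]]), g3$protein)
})

test_that("planted motifs are found by the scanner at their positions", {
  spec <- smallSpec()
  set.seed(101)
  g <- makeGene(spec, "TPS-b", "gB")
  kit <- tpsMotifLibrary("TPS-b")
  for (motif in names(kit)) {
    hits <- scanMotif(stats::setNames(g$protein, "p"), kit[[motif]])
    expect_true(g$truth$motifs[[motif]] %in% hits$start,
                label = paste("motif", motif, "found at planted position"))
  }
  mc <- motifCompleteness(stats::setNames(g$protein, "p"))
  expect_true(mc$complete)
})

test_that("emitted introns have GT..AG cores and purine donor context", {
  spec <- smallSpec()
  set.seed(102)
  for (sub in c("TPS-a", "TPS-g")) {
    g <- makeGene(spec, sub, "gX")
    ex <- exonRanges(g$model)[[1]]
    locus <- as.character(g$locus[[1]])
    iStart <- IRanges::end(ex)[-length(ex)] + 1L
    iEnd <- IRanges::start(ex)[-1L] - 1L
    expect_true(all(substring(locus, iStart, iStart + 1L) == "GT"))
    expect_true(all(substring(locus, iEnd - 1L, iEnd) == "AG"))
    expect_true(all(substring(locus, iEnd - 2L, iEnd - 2L) %in% c("C", "T")))
    expect_true(all(substring(locus, iStart - 1L, iStart - 1L) %in%
                      c("A", "G")))
  }
})

test_that("divergent copies hit their identity target within half a point", {
  spec <- smallSpec()
  set.seed(103)
  g <- makeGene(spec, "TPS-a", "gA")
  for (target in c(96, 85)) {
    mut <- mutateToIdentity(g$cds, target)
    pid <- percentIdentity(g$protein,
                           as.character(translateCDS(mut)[[1]]))
    expect_lte(abs(pid - target), 0.5)
  }
  expect_identical(mutateToIdentity(g$cds, 100), g$cds)
  expect_error(mutateToIdentity(g$cds, 50,
                                protect = seq_len(nchar(g$protein))),
               "unreachable")
})

test_that("pseudogene truncation is pure and yields sub-threshold products", {
  spec <- smallSpec()
  set.seed(104)
  g <- makeGene(spec, "TPS-b", "gB")
  before <- g$cds
  tr <- truncateToPseudogene(g$cds)
  expect_identical(g$cds, before)          # input untouched
  expect_equal(nchar(tr), nchar(g$cds))    # in-place stop, same length
  p <- as.character(translateCDS(tr)[[1]])
  expect_lt(nchar(p), 400L)
  expect_false(isPutativeFunctional(p))
})

test_that("assembled genomes honour the planted layout exactly", {
  spec <- smallSpec()
  sim <- assembleGenome(spec)
  truth <- sim@truth
  expect_equal(sum(truth$functional), sum(spec@subfamilyCounts))
  expect_equal(sum(truth$pseudogene), spec@nPseudogenes)
  expect_equal(sum(truth$decoy), spec@nDecoys)
  expect_equal(sum(truth$unplaced), spec@nUnplacedPseudogenes)
  # planted clusters are recovered exactly by detection
  tpsModels <- sim@models[which(geneIds(sim@models) %in%
                                  truth$gene_id[!truth$decoy])]
  cl <- detectClusters(tpsModels, maxGapNt = 67000,
                       unplaced = "^scaffold_un", unplacedIsPattern = TRUE)
  expect_equal(nrow(cl$clusters), length(spec@clusterSizes))
  expect_equal(sort(cl$clusters$n_members), sort(spec@clusterSizes))
  # detected membership equals planted membership
  plant <- truth[!is.na(truth$cluster_id), c("gene_id", "cluster_id")]
  got <- cl$members[, c("gene_id", "cluster_id")]
  m <- merge(plant, got, by = "gene_id")
  expect_equal(nrow(m), nrow(plant))
  tab <- table(m$cluster_id.x, m$cluster_id.y)
  expect_true(all(rowSums(tab > 0) == 1L))   # planted clusters map 1:1
  # paralog pair placed in one cluster at the target identity
  pair <- truth[!is.na(truth$paralog_partner), ]
  expect_equal(nrow(pair), 2L * spec@nParalogPairs)
  expect_equal(pair$cluster_id[1], pair$cluster_id[2])
})

test_that("assembly is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  assembleGenome(smallSpec(seed = 202L), dir = d1)
  assembleGenome(smallSpec(seed = 202L), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = paste("file", f))
  }
  # a different seed changes the emitted genome
  d3 <- withr::local_tempdir()
  assembleGenome(smallSpec(seed = 203L), dir = d3)
  expect_false(identical(
    readBin(file.path(d1, "genome.fasta"), "raw",
            file.size(file.path(d1, "genome.fasta"))),
    readBin(file.path(d3, "genome.fasta"), "raw",
            file.size(file.path(d3, "genome.fasta")))))
})

test_that("simulated expression plants what the rules recover", {
  spec <- smallSpec()
  genes <- sprintf("g%02d", 1:20)
  ex <- simulateExpression(genes, spec)
  expect_true(all(ex$matrix >= 0))
  ts <- tissueSpecific(ex$matrix)
  for (g in names(ex$truth$specific)) {
    expect_equal(unname(ts[g]), unname(ex$truth$specific[g]))
  }
  expect_equal(as.integer(table(ex$truth$specific)[c("leaf", "flower",
                                                     "fruit")]),
               as.integer(spec@nTissueSpecific[c("leaf", "flower",
                                                 "fruit")]))
  for (g in ex$truth$high) {
    expect_true(any(expressionCategory(ex$matrix[g, ]) == "high"))
  }
  for (g in ex$truth$low) {
    expect_true(all(expressionCategory(ex$matrix[g, ]) == "low"))
  }
  # seeded: reproducible
  ex2 <- simulateExpression(genes, spec)
  expect_identical(ex$matrix, ex2$matrix)
})

test_that("spec validation rejects inconsistent blueprints", {
  expect_error(familySpec(seed = 1L, clusterSizes = rep(2L, 60L)),
               "cluster layout")
  expect_error(familySpec(seed = 1L, nPseudogenes = 2L,
                          nUnplacedPseudogenes = 5L,
                          clusterSizes = c(2L, 2L)),
               "unplaced")
  expect_error(familySpec(seed = NA_integer_), "seed")
})
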