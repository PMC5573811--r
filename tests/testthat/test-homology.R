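test_that("global alignment handles identity and single-gap cases", {
  al <- globalAlign("ACDEFG", "ACDEFG")
  expect_equal(al$n_matches, 6L)
  expect_equal(al$n_columns, 6L)
  al2 <- globalAlign("ACDEFG", "ACDFG")
  expect_equal(al2$n_columns, 6L)   # one gap column
  expect_equal(al2$n_matches, 5L)
  expect_equal(gsub("-", "", al2$aligned_b), "ACDFG")
  expect_error(globalAlign("AC1", "AC"), "alphabet")
  expect_error(globalAlign("", "AC"), "empty")
})

test_that("alignment score equals exhaustive search on short sequences", {
  set.seed(61)
  alph <- c("A", "C", "G", "T")
  sub <- matrix(-1, 4, 4, dimnames = list(alph, alph)); diag(sub) <- 2
  for (i in 1:60) {
    a <- paste(sample(alph, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alph, sample(1:6, 1), replace = TRUE), collapse = "")
    got <- globalAlign(a, b, type = "dna", substitutionMatrix = sub,
                       gapOpening = 2, gapExtension = 1)$score
    want <- bruteAlignScore(a, b, sub, gapOpen = 2, gapExt = 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("percent identity reproduces the published arithmetic", {
  set.seed(62)
  a <- randomProtein(559)
  b <- a; substr(b, 479, 479) <- if (substr(a, 479, 479) == "M") "I" else "M"
  expect_equal(percentIdentity(a, b), 99.82)

  a2 <- randomProtein(567)
  b2 <- a2
  for (p in c(105L, 319L)) {
    substr(b2, p, p) <- if (substr(a2, p, p) == "G") "D" else "G"
  }
  expect_equal(percentIdentity(a2, b2, digits = 1), 99.6)

  n1 <- randomOrf(1701L / 3L)
  n2 <- n1
  pos <- sample(4:1694, 12)
  for (p in pos) {
    old <- substr(n2, p, p)
    substr(n2, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(percentIdentity(n1, n2, type = "dna"), 99.29)

  expect_equal(percentIdentity("ACDEF", "ACDEF"), 100)
  expect_equal(percentIdentity("ACDEF", "ACDEF"),
               percentIdentity("ACDEF", "ACDEF"))
  expect_error(percentIdentity("", "A"), "empty")
})

test_that("percent identity is symmetric and 100 iff identical", {
  set.seed(63)
  for (i in 1:10) {
    a <- randomProtein(sample(20:60, 1))
    b <- randomProtein(sample(20:60, 1))
    expect_equal(percentIdentity(a, b), percentIdentity(b, a))
  }
  a <- randomProtein(40)
  expect_equal(percentIdentity(a, a), 100)
  b <- a; substr(b, 10, 10) <- if (substr(a, 10, 10) == "A") "C" else "A"
  expect_lt(percentIdentity(a, b), 100)
})

test_that("identity matrix is symmetric with diagonal 100", {
  set.seed(64)
  p <- c(x = randomProtein(60), y = randomProtein(60), z = randomProtein(60))
  p["y"] <- p[["x"]]
  m <- identityMatrix(p)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(m["x", "y"], 100)
  expect_true(!is.null(attr(m, "mean_identity")))
})

test_that("mutate-to-target round-trips the requested identity", {
  set.seed(65)
  for (target in c(96, 85, 70)) {
    cds <- randomOrf(450L)
    mut <- mutateToIdentity(cds, target)
    pa <- as.character(translateCDS(cds)[[1]])
    pb <- as.character(translateCDS(mut)[[1]])
    expect_equal(percentIdentity(pa, pb), target, tolerance = 0.5 / target)
  }
  cds <- randomOrf(200L)
  expect_identical(mutateToIdentity(cds, 100), cds)
})

test_that("paralog pairs respect the threshold and co-location flag", {
  m <- matrix(c(100, 96, 92, 96, 100, 89, 92, 89, 100), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  pos <- data.frame(id = c("a", "b", "c"),
                    chrom = c("chr1", "chr1", "chr2"))
  got <- findParalogPairs(m, pos, threshold = 94)
  expect_equal(nrow(got), 1L)
  expect_equal(got$id1, "a"); expect_equal(got$id2, "b")
  expect_true(got$same_chromosome)
  # lowering the threshold admits the cross-chromosome pair
  got2 <- findParalogPairs(m, pos, threshold = 91)
  expect_equal(nrow(got2), 2L)
  expect_false(got2$same_chromosome[got2$id2 == "c"])
})

test_that("reference search ranks the true source first", {
  set.seed(66)
  refs <- c(r1 = randomProtein(420), r2 = randomProtein(430))
  hits <- referenceSearch(refs[["r1"]], refs)
  expect_equal(hits$ref_id[1], "r1")
  expect_equal(hits$identity[1], 100)
  expect_equal(hits$coverage[1], 100)
  # an unrelated random protein clears no sensible identity bar end-to-end
  q <- randomProtein(400)
  filt <- referenceSearch(q, refs, minIdentity = 40, minCoverage = 50)
  expect_equal(nrow(filt), 0L)
  expect_error(referenceSearch(q, character(0)), "empty")
})

test_that("truncated fragments still hit their source reference", {
  set.seed(67)
  ref <- c(src = randomProtein(520))
  frag <- substr(ref[["src"]], 1, 150)
  hits <- referenceSearch(frag, ref, minIdentity = 40, minCoverage = 50)
  expect_equal(hits$ref_id[1], "src")
  expect_gt(hits$identity[1], 95)
})
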