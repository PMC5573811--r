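# Shared fixture builders for the suite. Everything is generated in code.

# a GeneModelSet with one transcript from exon (start, end) pairs
makeModel <- function(starts, ends, strand = "+", chrom = "chr1",
                      tx = "t1", gene = "g1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  GeneModelSet(GenomicRanges::GRangesList(stats::setNames(list(gr), tx)),
               geneId = gene)
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

randomProtein <- function(n) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# random complete ORF of n codons (including the terminal stop)
randomOrf <- function(nCodons) {
  sense <- names(tpscan:::GENETIC_CODE_DNA)[tpscan:::GENETIC_CODE_DNA != "*"]
  paste(c("ATG", sample(sense, nCodons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

# a small FamilySpec that keeps generator-backed tests fast
smallSpec <- function(seed = 101L) {
  familySpec(seed = seed,
             subfamilyCounts = c("TPS-a" = 6L, "TPS-b" = 4L, "TPS-c" = 1L,
                                 "TPS-e/f" = 1L, "TPS-g" = 2L),
             nPseudogenes = 6L, nUnplacedPseudogenes = 3L, nDecoys = 2L,
             clusterSizes = c(3L, 2L, 2L), nParalogPairs = 1L)
}

# independent naive motif matcher: per-position character membership check
# against the expanded element sets (used as the brute-force oracle)
bruteScan <- function(protein, elements) {
  ch <- strsplit(protein, "")[[1]]
  k <- length(elements)
  hits <- integer(0)
  if (length(ch) >= k) {
    for (s in seq_len(length(ch) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!ch[s + j - 1L] %in% elements[[j]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}

# exhaustive global alignment score by recursion over all alignments with
# affine gap costs (gap of length L costs open + L * ext); independent of
# the package's aligner
bruteAlignScore <- function(a, b, subMat, gapOpen, gapExt) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    # state: 0 none/match, 1 gap-in-b open, 2 gap-in-a open
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, subMat[ca[i], cb[j]] + rec(i + 1, j + 1, 0))
    }
    if (i <= length(ca)) {
      cost <- if (state == 1) gapExt else gapOpen + gapExt
      best <- max(best, -cost + rec(i + 1, j, 1))
    }
    if (j <= length(cb)) {
      cost <- if (state == 2) gapExt else gapOpen + gapExt
      best <- max(best, -cost + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# least-squares branch fit of a fixed topology to a distance matrix;
# returns the residual sum of squares (negative branch lengths allowed)
lsTopologyRSS <- function(tree, d) {
  tips <- tree$tip.label
  nt <- length(tips)
  pairs <- t(utils::combn(nt, 2))
  X <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (r in seq_len(nrow(pairs))) {
    p <- ape::nodepath(tree, pairs[r, 1], pairs[r, 2])
    for (k in seq_len(length(p) - 1L)) {
      e <- which((tree$edge[, 1] == p[k] & tree$edge[, 2] == p[k + 1]) |
                   (tree$edge[, 2] == p[k] & tree$edge[, 1] == p[k + 1]))
      X[r, e] <- 1
    }
  }
  y <- d[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}
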