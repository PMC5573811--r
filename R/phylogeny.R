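# alignment (character vector of equal-length gapped strings) -> integer
# matrix, gap "-" coded 0, residues coded by alphabet rank
.alnToInt <- function(msa) {
  seqs <- asNamedChr(msa)
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(seqs, ""))
  codes <- match(m, c(AA_STANDARD20, "X", "A", "C", "G", "T", "N"))
  codes[m == "-"] <- 0L
  codes[is.na(codes)] <- 0L
  out <- matrix(as.integer(codes), nrow = nrow(m))
  rownames(out) <- names(seqs)
  out
}

#' p-distance matrix from a multiple alignment
#'
#' d(i, j) = mismatches / compared columns, with pairwise deletion of gap
#' positions. A Poisson correction (-ln(1 - p)) is available behind
#' \code{model = "poisson"}.
#'
#' @param msa a named \code{AAStringSet} or character vector of equal-length
#'   aligned rows (gap symbol \code{"-"}).
#' @param model \code{"p"} (default) or \code{"poisson"}.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  seqs <- asNamedChr(msa)
  if (length(seqs) < 2L) stop("need at least two rows")
  im <- .alnToInt(seqs)
  d <- .pDistC(im, seq_len(ncol(im)))
  if (anyNA(d))
    stop("pair(s) with zero comparable columns")
  if (model == "poisson") {
    dd <- -log(1 - pmin(d, 0.999999))
    diag(dd) <- 0
    d <- dd
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  dimnames(d) <- list(ids, ids)
  d
}

# Core NJ agglomeration. Returns the newick string and the list of
# non-trivial splits (each a sorted integer vector of tip indices).
# Tie-break: the (i, j) pair with the smallest Q, then lowest index pair.
# Negative branch lengths are clamped to 0 with the deficit moved to the
# sister branch.
.njCore <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  if (any(grepl("[(),:;]", labels)))
    stop("leaf labels must not contain newick metacharacters")
  nodes <- as.list(labels)           # newick fragment per active cluster
  tipsets <- lapply(seq_len(n), identity)  # tip indices per active cluster
  act <- seq_len(n)
  D <- d
  splits <- list()
  clamp2 <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    c(max(vi, 0), max(vj, 0))
  }
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index-pair tie-break on the minimum
    minQ <- min(Q)
    cand <- which(Q - minQ <= abs(minQ) * 1e-12 + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    v <- clamp2(vi, vj)
    newNode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], v[1],
                       nodes[[j]], v[2])
    newTips <- sort(c(tipsets[[i]], tipsets[[j]]))
    splits[[length(splits) + 1L]] <- newTips
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    nodes <- c(nodes[keep], list(newNode))
    tipsets <- c(tipsets[keep], list(newTips))
    act <- act[-1L]  # bookkeeping only (size)
  }
  if (length(act) == 3L) {
    va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    v <- c(va, vb, vc)
    if (any(v < 0)) {   # move deficits onto the longest branch
      deficit <- sum(v[v < 0]); v[v < 0] <- 0
      v[which.max(v)] <- max(v[which.max(v)] + deficit, 0)
    }
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[[1]], v[1],
                   nodes[[2]], v[2], nodes[[3]], v[3])
  } else if (length(act) == 2L) {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", nodes[[1]], D[1, 2] / 2,
                   nodes[[2]], D[1, 2] / 2)
  } else stop("need at least 3 taxa")
  list(newick = nwk, splits = splits, labels = labels)
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration (Q-matrix minimization) on a
#' symmetric distance matrix. Ties in the Q matrix are broken towards the
#' lowest index pair; negative branch lengths are clamped to 0 with the
#' deficit shifted to the sister branch. NJ is consistent: an additive
#' matrix is recovered exactly (topology and branch lengths).
#'
#' @param d symmetric numeric matrix with zero diagonal and dimnames
#'   (n >= 3).
#' @return an unrooted \code{phylo} tree (class from \pkg{ape}).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)$edge.length   # A:1, B:1, C:3
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  ape::read.tree(text = .njCore(d)$newick)
}

# canonical split keys on labels: the side not containing the
# lexicographically smallest label, as a collapsed sorted string
.splitKeys <- function(splits, labels) {
  anchor <- which(labels == min(labels))[1]  # lexicographically smallest
  vapply(splits, function(s) {
    side <- if (anchor %in% s) setdiff(seq_along(labels), s) else s
    paste(sort(labels[side]), collapse = "\r")
  }, character(1))
}

# non-trivial splits of a phylo tree as canonical keys (+ the node each
# split hangs below)
.treeSplits <- function(tree) {
  nt <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  # prop.part: first element is all tips (the root); drop trivial parts
  keys <- character(0); nodeIds <- integer(0)
  for (k in seq_along(pp)) {
    tipIdx <- pp[[k]]
    if (length(tipIdx) <= 1L || length(tipIdx) >= nt - 1L) next
    side <- tree$tip.label[tipIdx]
    anchorLab <- min(tree$tip.label)
    if (anchorLab %in% side)
      side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodeIds <- c(nodeIds, nt + k)
  }
  data.frame(node = nodeIds, key = keys, stringsAsFactors = FALSE)
}

#' Bootstrap supports on the neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances for each replicate, and reports for every internal edge of
#' the reference tree the percentage of replicates containing the same
#' bipartition. Bit-reproducible under a fixed seed.
#'
#' @param msa aligned sequences (named, equal length).
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed integer seed (mandatory for reproducibility).
#' @param model distance model passed to \code{\link{pDistanceMatrix}}.
#' @return a list: \code{tree} (the reference NJ tree with supports as node
#'   labels, rounded to 1 decimal), \code{supports} (data.frame of node,
#'   support).
#' @export
bootstrapSupports <- function(msa, nReps = 1000L, seed = 1L,
                              model = "p") {
  if (nReps < 1L) stop("nReps must be >= 1")
  seqs <- asNamedChr(msa)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  im <- .alnToInt(stats::setNames(seqs, ids))
  dist0 <- pDistanceMatrix(stats::setNames(seqs, ids), model = model)
  core0 <- .njCore(dist0)
  refTree <- ape::read.tree(text = core0$newick)
  refKeys <- .splitKeys(core0$splits, core0$labels)
  counts <- stats::setNames(integer(length(refKeys)), refKeys)
  nc <- ncol(im)
  withSeed(seed, {
    for (rep in seq_len(nReps)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      db <- .pDistC(im, cols)
      if (anyNA(db)) next  # unresolvable replicate (no comparable columns)
      dimnames(db) <- dimnames(dist0)
      coreb <- .njCore(db)
      bk <- unique(.splitKeys(coreb$splits, coreb$labels))
      hit <- refKeys %in% bk
      counts[hit] <- counts[hit] + 1L
    }
  })
  supports <- 100 * counts / nReps
  # attach supports as node labels of the reference tree
  sp <- .treeSplits(refTree)
  lab <- rep("", refTree$Nnode)
  m <- match(sp$key, refKeys)
  lab[sp$node - length(refTree$tip.label)] <-
    ifelse(is.na(m), "", sprintf("%.1f", supports[m]))
  refTree$node.label <- lab
  list(tree = refTree,
       supports = data.frame(split = names(supports),
                             support = unname(supports),
                             stringsAsFactors = FALSE))
}

#' Reference-anchored subfamily assignment
#'
#' Assigns each query leaf the subfamily of the smallest edge-induced
#' bipartition side that contains the query together with references of
#' exactly one subfamily; queries for which no such side exists are
#' \code{"ambiguous"}.
#'
#' @param tree a \code{phylo} tree.
#' @param referenceLabels named character vector: reference leaf ->
#'   subfamily.
#' @return named character vector: query leaf -> subfamily (or
#'   \code{"ambiguous"}).
#' @export
assignSubfamily <- function(tree, referenceLabels) {
  if (length(referenceLabels) == 0L) stop("no references")
  tips <- tree$tip.label
  refs <- intersect(names(referenceLabels), tips)
  if (length(refs) == 0L) stop("no reference leaf present in the tree")
  queries <- setdiff(tips, refs)
  # both sides of every edge (clades from prop.part + their complements +
  # terminal-edge sides)
  pp <- ape::prop.part(tree)
  sides <- list()
  for (k in seq_along(pp)) {
    s <- tips[pp[[k]]]
    if (length(s) < length(tips)) {
      sides <- c(sides, list(s), list(setdiff(tips, s)))
    }
  }
  for (t in tips) sides <- c(sides, list(t), list(setdiff(tips, t)))
  sizes <- vapply(sides, length, integer(1))
  ord <- order(sizes)
  sides <- sides[ord]; sizes <- sizes[ord]
  out <- stats::setNames(rep("ambiguous", length(queries)), queries)
  for (q in queries) {
    for (k in seq_along(sides)) {
      s <- sides[[k]]
      if (!q %in% s) next
      rin <- intersect(s, refs)
      if (length(rin) == 0L) next
      fams <- unique(referenceLabels[rin])
      # sides mixing subfamilies are not candidates; keep looking at the
      # next-smallest side
      if (length(fams) == 1L) { out[q] <- fams; break }
    }
  }
  out
}

#' Fractional common k-mer distance
#'
#' d(i, j) = 1 - (number of shared k-mers, counted with multiplicity) /
#' (min(L_i, L_j) - k + 1); the quick guide-tree distance used by
#' progressive alignment.
#'
#' @param seqs a named \code{AAStringSet} or character vector.
#' @param k k-mer length.
#' @return a symmetric distance matrix.
#' @export
kmerDistance <- function(seqs, k = 3L) {
  seqs <- asNamedChr(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  tabs <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  })
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    common <- sum(pmin(
      as.numeric(tabs[[i]][names(tabs[[j]])]),
      as.numeric(tabs[[j]])), na.rm = TRUE)
    denom <- min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L
    v <- if (denom > 0) 1 - common / denom else 1
    d[i, j] <- v; d[j, i] <- v
  }
  d
}

# column count encoding of a profile (rows = 20 aa + X + gap)
.profileCounts <- function(mat) {
  alph <- c(AA_STANDARD20, "X", "-")
  apply(mat, 2, function(col) {
    tabulate(match(col, alph), nbins = length(alph))
  })
}

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive alignment: a guide tree is built by average-
#' linkage clustering of fractional common k-mer distances, and profiles are
#' merged by global profile--profile alignment (mean BLOSUM62 column score,
#' affine gaps, same parameters as \code{\link{globalAlign}}). With two
#' sequences this reduces exactly to \code{\link{globalAlign}}.
#'
#' @param seqs a named \code{AAStringSet} or character vector (>= 2).
#' @param gapOpening,gapExtension affine gap parameters.
#' @param k k-mer length for the guide distances.
#' @return an aligned \code{AAStringSet} in the input order.
#' @export
progressiveMSA <- function(seqs, gapOpening = 10, gapExtension = 0.5,
                           k = 3L) {
  seqs <- asNamedChr(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  names(seqs) <- ids
  if (n == 2L) {
    al <- globalAlign(seqs[1], seqs[2], type = "protein",
                      gapOpening = gapOpening, gapExtension = gapExtension)
    out <- Biostrings::AAStringSet(c(al$aligned_a, al$aligned_b))
    names(out) <- ids
    return(out)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  alph <- c(AA_STANDARD20, "X", "-")
  S <- matrix(0, length(alph), length(alph), dimnames = list(alph, alph))
  S[AA_STANDARD20, AA_STANDARD20] <- B62[AA_STANDARD20, AA_STANDARD20]
  S["X", ] <- -1; S[, "X"] <- -1; S["X", "X"] <- -1
  S["-", ] <- 0; S[, "-"] <- 0   # existing gaps score 0 against anything
  d <- kmerDistance(seqs, k = k)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # profiles as character matrices; follow hclust merge order
  profiles <- vector("list", n - 1L)
  leafProfile <- function(i) {
    m <- matrix(strsplit(seqs[i], "")[[1]], nrow = 1)
    rownames(m) <- ids[i]
    m
  }
  getProfile <- function(idx) {
    if (idx < 0) leafProfile(-idx) else profiles[[idx]]
  }
  for (step in seq_len(n - 1L)) {
    A <- getProfile(hc$merge[step, 1])
    Bp <- getProfile(hc$merge[step, 2])
    ca <- .profileCounts(A); cb <- .profileCounts(Bp)
    colScore <- t(ca) %*% S %*% cb / (nrow(A) * nrow(Bp))
    path <- .gotohAlign(colScore, gapOpening, gapExtension)
    la <- length(path$a)
    MA <- matrix("-", nrow(A), la); MB <- matrix("-", nrow(Bp), la)
    MA[, path$a > 0] <- A[, path$a[path$a > 0], drop = FALSE]
    MB[, path$b > 0] <- Bp[, path$b[path$b > 0], drop = FALSE]
    merged <- rbind(MA, MB)
    rownames(merged) <- c(rownames(A), rownames(Bp))
    profiles[[step]] <- merged
  }
  final <- profiles[[n - 1L]]
  out <- Biostrings::AAStringSet(apply(final, 1, paste, collapse = ""))
  out[ids]
}
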