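#' Global pairwise alignment
#'
#' Optimal global (Needleman--Wunsch) alignment with affine gaps. The
#' default scoring for proteins is BLOSUM62 with gap open 10 and gap
#' extension 0.5; nucleotide sequences default to match +2 / mismatch -1
#' with the same gap costs. A gap of length L costs open + L * extension,
#' terminal gaps included.
#'
#' @param a,b sequences (character, \code{AAString}/\code{DNAString}).
#' @param type \code{"protein"} or \code{"dna"}; guessed from the alphabet
#'   when missing.
#' @param substitutionMatrix scoring matrix (defaults as above).
#' @param gapOpening,gapExtension affine gap parameters (positive costs).
#' @return a list with \code{aligned_a}, \code{aligned_b} (gapped strings of
#'   equal length), \code{score}, \code{n_matches} and \code{n_columns}.
#' @examples
#' globalAlign("ACDEFG", "ACDFG")$n_matches
#' @export
globalAlign <- function(a, b, type = NULL, substitutionMatrix = NULL,
                        gapOpening = 10, gapExtension = 0.5) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (is.null(type)) {
    dnaish <- function(s) all(strsplit(s, "")[[1]] %in%
                                c("A", "C", "G", "T", "N"))
    type <- if (dnaish(a) && dnaish(b)) "dna" else "protein"
  }
  if (type == "protein") {
    bad <- setdiff(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])),
                   c(AA_STANDARD20, "X"))
    if (length(bad)) stop("alphabet mismatch: unexpected letter(s) ",
                          paste(bad, collapse = ", "))
    if (is.null(substitutionMatrix)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      substitutionMatrix <- get("BLOSUM62", envir = environment())
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = substitutionMatrix, gapOpening = gapOpening,
      gapExtension = gapExtension)
  } else {
    if (is.null(substitutionMatrix))
      substitutionMatrix <- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -1, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = substitutionMatrix, gapOpening = gapOpening,
      gapExtension = gapExtension)
  }
  alnA <- as.character(Biostrings::alignedPattern(pa))
  alnB <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(alnA, "")[[1]]; cb <- strsplit(alnB, "")[[1]]
  list(aligned_a = alnA, aligned_b = alnB,
       score = Biostrings::score(pa),
       n_matches = sum(ca == cb & ca != "-"),
       n_columns = length(ca))
}

# matches / columns after dropping terminal gap runs; raw percentage
.pidFromAligned <- function(alnA, alnB) {
  ca <- strsplit(alnA, "")[[1]]; cb <- strsplit(alnB, "")[[1]]
  gapA <- ca == "-"; gapB <- cb == "-"
  # terminal gap runs in either sequence
  lead <- max(match(FALSE, gapA), match(FALSE, gapB))
  trail <- max(match(FALSE, rev(gapA)), match(FALSE, rev(gapB)))
  keep <- seq.int(lead, length(ca) - trail + 1L)
  matches <- sum(ca[keep] == cb[keep] & ca[keep] != "-")
  list(pid = 100 * matches / length(keep), n_columns = length(keep),
       n_matches = matches)
}

#' Percent identity of two sequences
#'
#' 100 x matches / aligned columns of the optimal global alignment, with
#' terminal gap columns excluded from the denominator; for equal-length
#' gap-free pairs this reduces to matches / length. Rounded half-up to
#' \code{digits} decimals (default 2). When several alignments are
#' co-optimal the traceback depends on argument order, so the pair is
#' ordered canonically (lexicographically) before aligning; the measure is
#' therefore symmetric by construction.
#'
#' @inheritParams globalAlign
#' @param digits decimals for half-up rounding.
#' @return a percentage.
#' @examples
#' percentIdentity("ACDEF", "ACDEF")   # 100
#' @export
percentIdentity <- function(a, b, type = NULL, digits = 2,
                            substitutionMatrix = NULL, gapOpening = 10,
                            gapExtension = 0.5) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  al <- globalAlign(a, b, type = type,
                    substitutionMatrix = substitutionMatrix,
                    gapOpening = gapOpening, gapExtension = gapExtension)
  roundHalfUp(.pidFromAligned(al$aligned_a, al$aligned_b)$pid, digits)
}

#' Pairwise identity matrix
#'
#' Symmetric percent-identity matrix over a protein collection, diagonal
#' 100; the overall mean off-diagonal identity is attached as attribute
#' \code{"mean_identity"}.
#'
#' @param proteins a named \code{AAStringSet} or character vector (>= 2).
#' @param digits decimals for half-up rounding of each entry.
#' @return a numeric matrix with id dimnames.
#' @export
identityMatrix <- function(proteins, digits = 2) {
  seqs <- asNamedChr(proteins)
  n <- length(seqs)
  if (n < 2L) stop("need at least two proteins")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("protein", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- if (identical(seqs[i], seqs[j])) 100
         else percentIdentity(seqs[i], seqs[j], digits = digits)
    m[i, j] <- p; m[j, i] <- p
  }
  attr(m, "mean_identity") <- roundHalfUp(mean(m[upper.tri(m)]), digits)
  m
}

#' Detect paralog pairs from an identity matrix
#'
#' Reports all unordered pairs whose protein identity meets the threshold
#' (default 94\%, the level at which high-identity pairs are interpreted as
#' paralogs), annotated with whether the two genes share a chromosome.
#'
#' @param mat identity matrix from \code{\link{identityMatrix}}.
#' @param positions a data.frame with columns \code{id} and \code{chrom}
#'   covering the matrix ids (extra rows allowed), or NULL to skip the
#'   co-location flag.
#' @param threshold minimum identity (pairs with identity >= threshold are
#'   reported).
#' @return a data.frame: \code{id1}, \code{id2}, \code{identity},
#'   \code{chrom1}, \code{chrom2}, \code{same_chromosome}.
#' @export
findParalogPairs <- function(mat, positions = NULL, threshold = 94) {
  ids <- rownames(mat)
  idx <- which(upper.tri(mat) & mat >= threshold, arr.ind = TRUE)
  out <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                    identity = mat[idx], stringsAsFactors = FALSE)
  if (!is.null(positions)) {
    ch <- stats::setNames(as.character(positions$chrom),
                          as.character(positions$id))
    out$chrom1 <- unname(ch[out$id1])
    out$chrom2 <- unname(ch[out$id2])
    out$same_chromosome <- !is.na(out$chrom1) & !is.na(out$chrom2) &
      out$chrom1 == out$chrom2
  }
  out[order(-out$identity, out$id1, out$id2), , drop = FALSE]
}

#' Homology search against a reference protein set
#'
#' Aligns a query against every reference with an ends-free (overlap)
#' alignment -- terminal gaps are unpenalized, so truncated pseudogene
#' products still align cleanly to full-length references, as in a
#' BLASTp-style screen -- and ranks the references by alignment score.
#' Identity is computed over the aligned (non-terminal-gap) columns;
#' coverage is the fraction of query residues inside those columns. Serves
#' as the TPS-candidate gate in the pipeline.
#'
#' @param query a single protein (character or \code{AAString}).
#' @param references a named \code{AAStringSet} or character vector.
#' @param minIdentity,minCoverage filters in percent (defaults keep
#'   everything).
#' @param gapOpening,gapExtension affine gap parameters.
#' @return a data.frame ranked by score: \code{ref_id}, \code{score},
#'   \code{identity}, \code{coverage}.
#' @export
referenceSearch <- function(query, references, minIdentity = 0,
                            minCoverage = 0, gapOpening = 10,
                            gapExtension = 0.5) {
  refs <- asNamedChr(references)
  if (length(refs) == 0L) stop("empty reference set")
  ids <- names(refs)
  if (is.null(ids)) ids <- paste0("ref", seq_along(refs))
  q <- as.character(query)
  if (!nzchar(q)) stop("empty query")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  rows <- lapply(seq_along(refs), function(i) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(refs[i]),
      type = "overlap", substitutionMatrix = B62,
      gapOpening = gapOpening, gapExtension = gapExtension)
    alnA <- as.character(Biostrings::alignedPattern(pa))
    alnB <- as.character(Biostrings::alignedSubject(pa))
    st <- .pidFromAligned(alnA, alnB)
    ca <- strsplit(alnA, "")[[1]]
    cov <- 100 * sum(ca != "-") / nchar(q)
    data.frame(ref_id = ids[i], score = Biostrings::score(pa),
               identity = roundHalfUp(st$pid, 2),
               coverage = roundHalfUp(cov, 2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$identity >= minIdentity & out$coverage >= minCoverage, ,
             drop = FALSE]
  out[order(-out$score, out$ref_id), , drop = FALSE]
}
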