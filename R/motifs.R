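#' Compile a degenerate motif pattern
#'
#' Parses the compact consensus notation used for terpene-synthase motifs:
#' plain residues match themselves, parenthesized slash-separated sets such
#' as \code{(D/N)} match any member, \code{X} is a wildcard over the 20
#' standard residues, and \code{X} followed by an integer repeats the
#' wildcard, so \code{"RRX8W"} is an 11-position pattern (R, R, eight
#' wildcards, W).
#'
#' @param notation pattern string, e.g. \code{"R(D/N)R"} or \code{"DDXXD"}.
#' @param name motif name (defaults to the notation itself).
#' @return a \code{\link{MotifPattern}}.
#' @examples
#' length(compileMotif("RRX8W"))   # 11
#' @export
compileMotif <- function(notation, name = notation) {
  chars <- strsplit(notation, "")[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    c0 <- chars[i]
    if (c0 == "(") {
      j <- i
      while (j <= length(chars) && chars[j] != ")") j <- j + 1L
      if (j > length(chars))
        stop("parse error at column ", i, ": unclosed '(' in '", notation,
             "'")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      alts <- strsplit(body, "/", fixed = TRUE)[[1]]
      if (length(alts) == 0L || any(nchar(alts) != 1L) ||
          !all(alts %in% AA_STANDARD20))
        stop("parse error at column ", i, ": bad alternation '(", body,
             ")' in '", notation, "'")
      elements <- c(elements, list(alts))
      i <- j + 1L
    } else if (c0 == "X") {
      j <- i + 1L
      digits <- ""
      while (j <= length(chars) && grepl("[0-9]", chars[j])) {
        digits <- paste0(digits, chars[j]); j <- j + 1L
      }
      reps <- if (nzchar(digits)) as.integer(digits) else 1L
      if (reps < 1L)
        stop("parse error at column ", i, ": zero-length wildcard repeat")
      elements <- c(elements, rep(list(AA_STANDARD20), reps))
      i <- j
    } else if (c0 %in% AA_STANDARD20) {
      elements <- c(elements, list(c0))
      i <- i + 1L
    } else {
      stop("parse error at column ", i, ": unexpected character '", c0,
           "' in '", notation, "'")
    }
  }
  new("MotifPattern", name = name, notation = notation, elements = elements)
}

#' Scan a protein for motif matches
#'
#' Reports all (possibly overlapping) match positions of a compiled pattern,
#' in ascending order. An \code{X} in the protein matches nothing
#' (conservative).
#'
#' @param proteins an \code{AAStringSet} or (named) character vector.
#' @param pattern a \code{\link{MotifPattern}} (or a notation string, which
#'   is compiled on the fly).
#' @return a data.frame with columns \code{protein_id}, \code{motif},
#'   \code{start} (1-based) and \code{match}.
#' @examples
#' scanMotif(c(p1 = "ADDIYDK"), "DDXXD")
#' @export
scanMotif <- function(proteins, pattern) {
  if (is.character(pattern)) pattern <- compileMotif(pattern)
  stopifnot(is(pattern, "MotifPattern"))
  seqs <- asNamedChr(proteins)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("protein", seq_along(seqs))
  k <- length(pattern@elements)
  rows <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    ch <- strsplit(seqs[s], "")[[1]]
    L <- length(ch)
    if (L < k) next
    ok <- rep(TRUE, L - k + 1L)
    for (j in seq_len(k)) {
      ok <- ok & (ch[j:(L - k + j)] %in% pattern@elements[[j]])
      if (!any(ok)) break
    }
    hits <- which(ok)
    if (length(hits))
      rows[[s]] <- data.frame(protein_id = ids[s], motif = pattern@name,
                              start = hits,
                              match = substring(seqs[s], hits, hits + k - 1L),
                              stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows)
  else data.frame(protein_id = character(0), motif = character(0),
                  start = integer(0), match = character(0),
                  stringsAsFactors = FALSE)
}

#' Packaged terpene-synthase motif library
#'
#' Loads the plain-text motif table shipped with the package (name,
#' subfamily, pattern notation): the generic kit (RRX8W, R(D/N)R, DDXXD and
#' the NSE/DTE consensus (D/N)D(V/M/L/I)X(S/T)XXXE), the TPS-a and TPS-b
#' subfamily kits, the TPS-g markers DDIFD and DDLGSAKDE, and the TPS-c
#' marker DXDD.
#'
#' @param subfamily which kit to return (default \code{"generic"}); use
#'   \code{"all"} for the whole table as compiled patterns.
#' @param path optional path to an alternative library TSV.
#' @return a named list of \code{\link{MotifPattern}} objects.
#' @export
tpsMotifLibrary <- function(subfamily = c("generic", "TPS-a", "TPS-b",
                                          "TPS-g", "TPS-c", "all"),
                            path = NULL) {
  subfamily <- match.arg(subfamily)
  if (is.null(path))
    path <- system.file("extdata", "motif_library.tsv", package = "tpscan")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (subfamily != "all") tab <- tab[tab$subfamily == subfamily, ]
  pats <- lapply(seq_len(nrow(tab)), function(i)
    compileMotif(tab$pattern[i], name = tab$name[i]))
  names(pats) <- tab$name
  pats
}

#' Motif completeness of proteins
#'
#' Checks each protein for the presence of a required motif set (default:
#' the generic kit RRX8W, RDR, DDXXD, NSE/DTE needed for terpene-synthase
#' activity). \code{complete} is TRUE when all required motifs are present;
#' whether their first occurrences appear in the canonical N-to-C order is
#' reported separately (\code{in_order}) and not enforced.
#'
#' @param proteins an \code{AAStringSet} or named character vector.
#' @param required a named list of \code{\link{MotifPattern}} objects in
#'   canonical order (default \code{tpsMotifLibrary("generic")}).
#' @return a data.frame with one row per protein: a logical presence column
#'   per motif, \code{complete} and \code{in_order}.
#' @export
motifCompleteness <- function(proteins, required = tpsMotifLibrary("generic")) {
  seqs <- asNamedChr(proteins)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("protein", seq_along(seqs))
  pres <- matrix(FALSE, nrow = length(seqs), ncol = length(required),
                 dimnames = list(ids, names(required)))
  firstPos <- matrix(NA_integer_, nrow = length(seqs),
                     ncol = length(required))
  for (j in seq_along(required)) {
    hits <- scanMotif(stats::setNames(seqs, ids), required[[j]])
    if (nrow(hits)) {
      f <- tapply(hits$start, hits$protein_id, min)
      pres[names(f), j] <- TRUE
      firstPos[match(names(f), ids), j] <- as.integer(f)
    }
  }
  inOrder <- apply(firstPos, 1, function(p) {
    p <- p[!is.na(p)]
    length(p) < 2L || !is.unsorted(p, strictly = FALSE)
  })
  out <- data.frame(protein_id = ids, pres, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$complete <- rowSums(pres) == length(required)
  out$in_order <- as.logical(inOrder)
  rownames(out) <- NULL
  out
}
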