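#' Read a genome FASTA file
#'
#' Reads a (multi-record) FASTA file into a \code{DNAStringSet}. Sequences
#' are normalized to uppercase; record identifiers are the first
#' whitespace-delimited token of each header. Duplicated identifiers and
#' empty files are rejected, and the alphabet is restricted to A, C, G, T, N.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  firstNonEmpty <- ""
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0L) break
    if (nzchar(trimws(l))) { firstNonEmpty <- l; break }
  }
  if (!nzchar(firstNonEmpty)) stop("empty FASTA file: ", path)
  if (!startsWith(firstNonEmpty, ">"))
    stop("malformed FASTA header at line 1 of ", path,
         ": expected '>' , got '", substr(firstNonEmpty, 1, 20), "'")
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicated FASTA record identifier(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- Biostrings::alphabetFrequency(seqs)
  other <- rowSums(bad[, !colnames(bad) %in% c("A", "C", "G", "T", "N"),
                       drop = FALSE])
  if (any(other > 0))
    stop("sequence(s) with letters outside A/C/G/T/N: ",
         paste(names(seqs)[other > 0], collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence record(s): ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  seqs
}

#' Write a genome FASTA file
#'
#' Deterministic writer (fixed line width 70) so that write-then-read
#' round-trips are byte identical.
#'
#' @param seqs a named \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses the gene/mRNA/CDS hierarchy of a GFF3 file into a
#' \code{\link{GeneModelSet}}: CDS features are grouped by their
#' \code{Parent} transcript, kept in 1-based inclusive coordinates, and
#' sorted by genomic start. Transcripts are mapped to genes through the mRNA
#' features' \code{Parent} attribute (transcripts without an mRNA feature get
#' their own id as gene id). CDS features without a \code{Parent} and
#' transcripts with mixed strands are rejected; if \code{genome} is supplied,
#' models extending beyond chromosome ends are rejected too.
#'
#' @param path path to a GFF3 file.
#' @param genome optional \code{DNAStringSet} for bounds checking.
#' @return a \code{GeneModelSet}.
#' @export
readGeneModels <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gff$type)
  cds <- gff[types == "CDS"]
  if (length(cds) == 0L)
    return(GeneModelSet(GRangesList(), geneId = character(0)))
  par <- mcols(cds)$Parent
  npar <- vapply(par, length, integer(1))
  if (any(npar == 0L))
    stop("CDS feature(s) without a Parent attribute in ", path)
  # expand CDS features attached to several transcripts
  idx <- rep(seq_along(cds), npar)
  txOfCds <- unlist(par)
  cds <- cds[idx]
  # transcript -> gene map from mRNA features
  mrna <- gff[types %in% c("mRNA", "transcript")]
  txGene <- character(0)
  if (length(mrna)) {
    ids <- as.character(mcols(mrna)$ID)
    gpar <- vapply(mcols(mrna)$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
    txGene <- stats::setNames(gpar, ids)
  }
  ord <- order(txOfCds, as.character(seqnames(cds)), start(cds))
  cds <- cds[ord]; txOfCds <- txOfCds[ord]
  mcols(cds) <- NULL
  grl <- GenomicRanges::split(cds, factor(txOfCds, levels = unique(txOfCds)))
  # reject mixed strands explicitly for a clear message
  mixed <- vapply(grl, function(g)
    length(unique(as.character(strand(g)))) != 1L, logical(1))
  if (any(mixed))
    stop("mixed strands within transcript(s): ",
         paste(names(grl)[mixed], collapse = ", "))
  gid <- txGene[names(grl)]
  gid[is.na(gid)] <- names(grl)[is.na(gid)]
  if (!is.null(genome)) {
    for (i in seq_along(grl)) {
      ch <- as.character(seqnames(grl[[i]]))[1]
      if (!ch %in% names(genome))
        stop("transcript '", names(grl)[i], "' on unknown sequence '", ch, "'")
      if (max(end(grl[[i]])) > Biostrings::width(genome)[match(ch, names(genome))])
        stop("CDS of '", names(grl)[i], "' extends beyond the end of '",
             ch, "'")
    }
  }
  GeneModelSet(grl, geneId = unname(gid))
}

#' Write gene models to a GFF3 file
#'
#' Emits a gene/mRNA/CDS hierarchy with deterministic ordering (chromosome,
#' then start). Coordinates are written 1-based inclusive as required by
#' GFF3.
#'
#' @param models a \code{GeneModelSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  stopifnot(is(models, "GeneModelSet"))
  lines <- "##gff-version 3"
  n <- length(models)
  if (n > 0L) {
    ch <- txChrom(models); st <- txStrand(models)
    gstart <- vapply(models@exons, function(g) min(start(g)), numeric(1))
    gend <- vapply(models@exons, function(g) max(end(g)), numeric(1))
    ord <- order(ch, gstart, names(models))
    # gene spans aggregate their transcripts
    recs <- character(0)
    geneSeen <- character(0)
    for (i in ord) {
      tx <- names(models)[i]; g <- geneIds(models)[i]
      grp <- which(geneIds(models) == g)
      if (!g %in% geneSeen) {
        recs <- c(recs, sprintf("%s\ttpscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
          ch[i], as.integer(min(gstart[grp])), as.integer(max(gend[grp])),
          st[i], g))
        geneSeen <- c(geneSeen, g)
      }
      recs <- c(recs, sprintf(
        "%s\ttpscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        ch[i], as.integer(gstart[i]), as.integer(gend[i]), st[i], tx, g))
      ex <- models@exons[[i]]
      recs <- c(recs, sprintf(
        "%s\ttpscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
        ch[i], start(ex), end(ex), st[i], tx, seq_along(ex), tx))
    }
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Assemble the spliced coding sequence of gene models
#'
#' Concatenates the exon substrings of each model in 5'-to-3' transcript
#' orientation: on the minus strand the exon order is reversed and the
#' concatenation reverse-complemented.
#'
#' @param models a \code{GeneModelSet} (all transcripts are processed).
#' @param genome a named \code{DNAStringSet} holding the chromosomes.
#' @return a \code{DNAStringSet} of spliced CDS, named by transcript.
#' @export
extractCDS <- function(models, genome) {
  stopifnot(is(models, "GeneModelSet"))
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chromStr <- asNamedChr(genome)
  strands <- txStrand(models)
  out <- character(length(models))
  for (i in seq_along(out)) {
    gr <- models@exons[[i]]
    ch <- as.character(seqnames(gr))[1]
    if (!ch %in% names(chromStr))
      stop("chromosome '", ch, "' of transcript '", names(models)[i],
           "' not in genome")
    if (min(start(gr)) < 1L || max(end(gr)) > nchar(chromStr[[ch]]))
      stop("exon out of bounds for transcript '", names(models)[i], "'")
    cds <- paste(substring(chromStr[[ch]], start(gr), end(gr)),
                 collapse = "")
    if (strands[i] == "-") cds <- revcompStr(cds)
    out[i] <- cds
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(models)
  res
}

#' Translate coding sequences
#'
#' Translates spliced CDS with the standard genetic code. Residues are
#' reported up to (not including) the first stop codon; codons containing N
#' translate to X. A transcript is flagged \code{complete} when it begins
#' with ATG, ends with exactly one stop codon, and has no internal stop.
#' Proteins with 10\% or more X residues are flagged \code{degenerate}.
#'
#' @param cds a \code{DNAStringSet}, \code{DNAString} or character vector;
#'   every sequence length must be divisible by 3.
#' @return an \code{AAStringSet} with metadata columns \code{complete},
#'   \code{starts_atg}, \code{n_internal_stops}, \code{terminal_stop} and
#'   \code{degenerate}.
#' @examples
#' translateCDS("ATGAAATGA")   # "MK", complete
#' @export
translateCDS <- function(cds) {
  if (is(cds, "DNAString")) cds <- Biostrings::DNAStringSet(list(cds))
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  seqs <- toupper(as.character(cds))
  if (any(nchar(seqs) %% 3L != 0L))
    stop("frame error: CDS length(s) not divisible by 3: ",
         paste(utils::head(which(nchar(seqs) %% 3L != 0L)), collapse = ", "))
  res <- character(length(seqs))
  complete <- logical(length(seqs)); startsAtg <- logical(length(seqs))
  nInternal <- integer(length(seqs)); termStop <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    nc <- nchar(s) %/% 3L
    if (nc == 0L) { res[i] <- ""; next }
    codons <- substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
    aa <- GENETIC_CODE_DNA[codons]
    aa[is.na(aa)] <- "X"   # ambiguous codons (containing N)
    stops <- which(aa == "*")
    firstStop <- if (length(stops)) stops[1] else nc + 1L
    res[i] <- paste(aa[seq_len(firstStop - 1L)], collapse = "")
    startsAtg[i] <- codons[1] == "ATG"
    termStop[i] <- aa[nc] == "*"
    nInternal[i] <- sum(aa[-nc] == "*")
    complete[i] <- startsAtg[i] && termStop[i] && nInternal[i] == 0L
  }
  out <- Biostrings::AAStringSet(res)
  names(out) <- names(cds)
  xfrac <- ifelse(nchar(res) > 0,
                  vapply(strsplit(res, ""), function(ch) mean(ch == "X"),
                         numeric(1)), 0)
  mcols(out) <- DataFrame(complete = complete, starts_atg = startsAtg,
                          n_internal_stops = nInternal,
                          terminal_stop = termStop,
                          degenerate = xfrac >= 0.10)
  out
}

#' Find the longest open reading frame
#'
#' Scans both strands and all three frames for ATG-to-stop open reading
#' frames (the stop codon is counted in the ORF length, matching the usual
#' ORF-finder convention where a 1,680-nt ORF encodes 559 residues). Ties
#' are broken in favour of the plus strand, then the earliest start.
#'
#' @param seq a \code{DNAString} or single character string.
#' @param minLenNt minimum ORF length in nucleotides (stop included).
#' @return a list with elements \code{found} (logical), \code{cds}
#'   (\code{DNAString} of the ORF, ATG..stop, or NULL), \code{start},
#'   \code{end} (1-based positions on the input, plus-strand coordinates),
#'   \code{strand} and \code{length_nt}.
#' @export
findLongestOrf <- function(seq, minLenNt = 300L) {
  s <- toupper(if (is.character(seq)) seq else as.character(seq))
  n <- nchar(s)
  empty <- list(found = FALSE, cds = NULL, start = NA_integer_,
                end = NA_integer_, strand = NA_character_,
                length_nt = 0L)
  if (n < 6L) return(empty)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  best <- NULL
  for (strandChar in c("+", "-")) {
    str <- if (strandChar == "+") s else rc
    for (frame in 0:2) {
      nc <- (n - frame) %/% 3L
      if (nc < 2L) next
      starts <- 3L * seq_len(nc) - 2L + frame
      codons <- substring(str, starts, starts + 2L)
      aa <- GENETIC_CODE_DNA[codons]
      aa[is.na(aa)] <- "X"
      stopPos <- which(aa == "*")
      atgPos <- which(codons == "ATG")
      prevStop <- 0L
      for (sp in stopPos) {
        cand <- atgPos[atgPos > prevStop & atgPos < sp]
        if (length(cand)) {
          a <- cand[1]
          lenNt <- (sp - a + 1L) * 3L
          # position on the oriented string
          oStart <- starts[a]; oEnd <- starts[sp] + 2L
          if (strandChar == "+") { gs <- oStart; ge <- oEnd }
          else { gs <- n - oEnd + 1L; ge <- n - oStart + 1L }
          cnd <- list(len = lenNt, strand = strandChar, oStart = oStart,
                      gs = gs, ge = ge,
                      cds = substr(str, oStart, oEnd))
          if (is.null(best) || cnd$len > best$len ||
              (cnd$len == best$len &&
               ((cnd$strand == "+" && best$strand == "-") ||
                (cnd$strand == best$strand && cnd$gs < best$gs))))
            best <- cnd
        }
        prevStop <- sp
      }
    }
  }
  if (is.null(best) || best$len < minLenNt) return(empty)
  list(found = TRUE, cds = Biostrings::DNAString(best$cds),
       start = best$gs, end = best$ge, strand = best$strand,
       length_nt = best$len)
}
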