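#' Intron phases of a gene model
#'
#' The phase of intron i is the cumulative coding length of the exons
#' upstream of it, modulo 3: phase 0 introns fall between codons, phase 1
#' after the first nucleotide of a codon, phase 2 after the second.
#'
#' @param models a \code{GeneModelSet}.
#' @return a named list of integer phase vectors, one per transcript (a
#'   transcript with a single exon gets an empty vector).
#' @examples
#' gr <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("c1",
#'     IRanges::IRanges(c(1, 100), c(45, 199)), strand = "+"))
#' intronPhases(GeneModelSet(gr, "g1"))   # first exon 45 nt -> phase 0
#' @export
intronPhases <- function(models) {
  stopifnot(is(models, "GeneModelSet"))
  strands <- txStrand(models)
  out <- vector("list", length(models))
  names(out) <- names(models)
  for (i in seq_along(out)) {
    w <- exonWidthsTxOrder(models, i, strands[i])
    out[[i]] <- if (length(w) > 1L)
      as.integer(cumsum(w)[-length(w)] %% 3L) else integer(0)
  }
  out
}

# exon widths in transcript (5'->3') order
exonWidthsTxOrder <- function(models, i, strand = txStrand(models)[i]) {
  w <- width(models@exons[[i]])
  if (strand == "-") w <- rev(w)
  w
}

# intron widths in transcript order
intronWidthsTxOrder <- function(models, i, strand = txStrand(models)[i]) {
  gr <- models@exons[[i]]
  if (length(gr) < 2L) return(integer(0))
  g <- start(gr)[-1L] - end(gr)[-length(gr)] - 1L
  if (strand == "-") g <- rev(g)
  g
}

#' Assign terpene-synthase classes from intron counts
#'
#' Gene-architecture classes of plant terpene synthases are defined by
#' intron count: class I genes carry 12--14 introns (class I members with 11
#' introns / 12 exons and 14 introns / 15 exons occur, so 11--14 are
#' admitted), class II genes 9, class III genes 6; anything else is
#' unclassified.
#'
#' @param nIntrons integer vector of intron counts.
#' @return character vector of \code{"I"}, \code{"II"}, \code{"III"} or
#'   \code{"unclassified"}.
#' @examples
#' classifyTpsClass(c(6, 9, 13, 7))
#' @export
classifyTpsClass <- function(nIntrons) {
  nIntrons <- as.integer(nIntrons)
  if (any(is.na(nIntrons)) || any(nIntrons < 0L))
    stop("intron counts must be non-negative integers")
  out <- rep("unclassified", length(nIntrons))
  out[nIntrons >= 11L & nIntrons <= 14L] <- "I"
  out[nIntrons == 9L] <- "II"
  out[nIntrons == 6L] <- "III"
  out
}

#' Gene architecture table
#'
#' Computes, per transcript, the exon coding lengths in amino acids (floor
#' of coding nucleotides / 3, with the fractional-codon remainder carried to
#' the next exon), intron lengths, intron phases, intron count and TPS
#' class.
#'
#' @param models a \code{GeneModelSet}.
#' @return a \code{DataFrame} with one row per transcript and list columns
#'   \code{exon_lengths_aa}, \code{intron_lengths_nt}, \code{intron_phases},
#'   plus \code{n_introns} and \code{tps_class}.
#' @export
geneArchitecture <- function(models) {
  stopifnot(is(models, "GeneModelSet"))
  n <- length(models)
  strands <- txStrand(models)
  exAA <- vector("list", n); intNt <- vector("list", n)
  phases <- vector("list", n); nInt <- integer(n)
  for (i in seq_len(n)) {
    w <- exonWidthsTxOrder(models, i, strands[i])
    carry <- 0L; aa <- integer(length(w))
    for (j in seq_along(w)) {
      tot <- carry + w[j]
      aa[j] <- tot %/% 3L
      carry <- tot %% 3L
    }
    exAA[[i]] <- aa
    intNt[[i]] <- intronWidthsTxOrder(models, i, strands[i])
    phases[[i]] <- if (length(w) > 1L)
      as.integer(cumsum(w)[-length(w)] %% 3L) else integer(0)
    nInt[i] <- length(w) - 1L
  }
  DataFrame(transcript_id = names(models), gene_id = geneIds(models),
            exon_lengths_aa = IRanges::IntegerList(exAA),
            intron_lengths_nt = IRanges::IntegerList(intNt),
            intron_phases = IRanges::IntegerList(phases),
            n_introns = nInt, tps_class = classifyTpsClass(nInt))
}

#' Exon/intron summary statistics
#'
#' Per-exon-position median, minimum and maximum coding lengths (in amino
#' acids), and an intron-length summary reporting the 81--400 nt band in
#' which plant TPS introns concentrate, plus the extreme lengths.
#'
#' @param arch a \code{DataFrame} from \code{\link{geneArchitecture}} (one or
#'   more rows).
#' @return a list with \code{exon_stats} (data.frame: position, n, median,
#'   min, max), \code{intron_summary} (list: n, min, max, n_in_81_400,
#'   fraction_81_400) and \code{intron_histogram} (table over length bands).
#' @export
exonIntronStats <- function(arch) {
  if (nrow(arch) == 0L) stop("empty input")
  exl <- as.list(arch$exon_lengths_aa)
  maxPos <- max(vapply(exl, length, integer(1)))
  exonStats <- do.call(rbind, lapply(seq_len(maxPos), function(p) {
    v <- unlist(lapply(exl, function(e) if (length(e) >= p) e[p] else NULL))
    data.frame(position = p, n = length(v), median = stats::median(v),
               min = min(v), max = max(v))
  }))
  introns <- unlist(as.list(arch$intron_lengths_nt))
  if (length(introns)) {
    bands <- cut(introns, breaks = c(0, 80, 400, Inf),
                 labels = c("<=80", "81-400", ">400"))
    intronSummary <- list(
      n = length(introns), min = min(introns), max = max(introns),
      n_in_81_400 = sum(introns >= 81 & introns <= 400),
      fraction_81_400 = mean(introns >= 81 & introns <= 400))
    hist <- table(bands)
  } else {
    intronSummary <- list(n = 0L, min = NA, max = NA, n_in_81_400 = 0L,
                          fraction_81_400 = NA)
    hist <- table(factor(character(0),
                         levels = c("<=80", "81-400", ">400")))
  }
  list(exon_stats = exonStats, intron_summary = intronSummary,
       intron_histogram = hist)
}

#' Splice-boundary consensus matrices
#'
#' Builds position frequency matrices over a window of \code{flank}
#' nucleotides on each side of every intron donor (exon|intron) and acceptor
#' (intron|exon) boundary, in transcript orientation, and computes the
#' per-position information content
#' \eqn{IC = 2 - (H + e_n)} bits, where H is the Shannon entropy of the
#' column and \eqn{e_n = 3 / (2 \ln(2) n)} is the standard small-sample
#' correction, floored at 0. Introns or exons shorter than the flank are
#' skipped with a warning.
#'
#' @param models a \code{GeneModelSet} contributing at least two introns.
#' @param genome a named \code{DNAStringSet}.
#' @param flank window half-width in nucleotides (default 10).
#' @return a \code{\link{SpliceConsensus}}.
#' @export
spliceConsensus <- function(models, genome, flank = 10L) {
  stopifnot(is(models, "GeneModelSet"))
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chromStr <- asNamedChr(genome)
  strands <- txStrand(models)
  flank <- as.integer(flank)
  donorList <- vector("list", length(models))
  acceptorList <- vector("list", length(models))
  skipped <- 0L
  for (i in seq_along(models@exons)) {
    gr <- models@exons[[i]]
    if (length(gr) < 2L) next
    ch <- as.character(seqnames(gr))[1]
    minus <- strands[i] == "-"
    # genomic-order intron boundaries
    iStart <- end(gr)[-length(gr)] + 1L
    iEnd <- start(gr)[-1L] - 1L
    exLeftLen <- width(gr)[-length(gr)]   # exon upstream in genomic order
    exRightLen <- width(gr)[-1L]
    usable <- (iEnd - iStart + 1L) >= flank & exLeftLen >= flank &
      exRightLen >= flank
    skipped <- skipped + sum(!usable)
    if (!any(usable)) next
    leftB <- substring(chromStr[[ch]], iStart[usable] - flank,
                       iStart[usable] + flank - 1L)
    rightB <- substring(chromStr[[ch]], iEnd[usable] - flank + 1L,
                        iEnd[usable] + flank)
    if (!minus) {
      donorList[[i]] <- leftB
      acceptorList[[i]] <- rightB
    } else {
      donorList[[i]] <- revcompStr(rightB)
      acceptorList[[i]] <- revcompStr(leftB)
    }
  }
  donors <- unlist(donorList)
  acceptors <- unlist(acceptorList)
  if (skipped > 0L)
    warning(skipped, " boundary site(s) skipped (intron or exon shorter ",
            "than the flank window)")
  if (length(donors) < 2L)
    stop("need at least two usable introns for a splice consensus")
  list2pfm <- function(windows) {
    m <- do.call(rbind, strsplit(windows, ""))
    pfm <- sapply(seq_len(ncol(m)), function(j) {
      tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
      as.numeric(tab) / sum(tab)
    })
    rownames(pfm) <- c("A", "C", "G", "T")
    colnames(pfm) <- posLabels(ncol(pfm) / 2L)
    pfm
  }
  posLabels <- function(f) c(paste0("-", f:1), paste0("+", 1:f))
  ic <- function(pfm, n) {
    en <- 3 / (2 * log(2) * n)
    apply(pfm, 2, function(p) {
      h <- -sum(ifelse(p > 0, p * log2(p), 0))
      max(0, 2 - (h + en))
    })
  }
  dP <- list2pfm(donors); aP <- list2pfm(acceptors)
  new("SpliceConsensus", donorPFM = dP, acceptorPFM = aP,
      donorIC = ic(dP, length(donors)), acceptorIC = ic(aP, length(acceptors)),
      nDonor = length(donors), nAcceptor = length(acceptors),
      flank = flank)
}

#' Export splice consensus matrices as TSV
#'
#' Writes one table per boundary type with columns position, A, C, G, T and
#' bits.
#'
#' @param consensus a \code{SpliceConsensus}.
#' @param donorPath,acceptorPath output paths.
#' @return invisibly, a list of the two written paths.
#' @export
writeSpliceConsensus <- function(consensus, donorPath, acceptorPath) {
  wr <- function(pfm, ic, path) {
    df <- data.frame(position = colnames(pfm), t(pfm), bits = ic,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(consensus@donorPFM, consensus@donorIC, donorPath)
  wr(consensus@acceptorPFM, consensus@acceptorIC, acceptorPath)
  invisible(list(donor = donorPath, acceptor = acceptorPath))
}
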