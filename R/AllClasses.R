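#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges start end width
#' @importClassesFrom GenomicRanges GRangesList
#' @importFrom GenomicRanges GRanges GRangesList strand seqnames
#' @importFrom Rcpp sourceCpp
#' @useDynLib tpscan, .registration = TRUE
NULL

#' GeneModelSet: a set of stranded, exon-structured gene models
#'
#' A light container around a \link[GenomicRanges]{GRangesList} in which each
#' element holds the CDS parts (exons of the coding region) of one
#' transcript, in 1-based inclusive genomic coordinates, sorted by genomic
#' start and non-overlapping. Gene identifiers and biotypes are carried as
#' parallel vectors.
#'
#' @slot exons GRangesList, one element per transcript (names are transcript
#'   identifiers); each element must lie on a single chromosome and strand.
#' @slot geneId character vector parallel to \code{exons}.
#' @slot biotype character vector parallel to \code{exons}; one of
#'   \code{"putative_functional"}, \code{"pseudogene"}, \code{"partial"},
#'   \code{"unclassified"}.
#'
#' @examples
#' gr <- GenomicRanges::GRangesList(
#'   tx1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(11, 101), c(40, 130)), strand = "+"))
#' gm <- GeneModelSet(gr, geneId = "g1")
#' transcriptIds(gm)
#' @export
setClass("GeneModelSet",
  representation(exons = "GRangesList", geneId = "character",
                 biotype = "character"))

.validGeneModelSet <- function(object) {
  msg <- character()
  n <- length(object@exons)
  if (is.null(names(object@exons)) && n > 0)
    msg <- c(msg, "transcripts must be named")
  if (length(object@geneId) != n)
    msg <- c(msg, "geneId must be parallel to exons")
  if (length(object@biotype) != n)
    msg <- c(msg, "biotype must be parallel to exons")
  ok <- object@biotype %in% c("putative_functional", "pseudogene", "partial",
                              "unclassified")
  if (!all(ok))
    msg <- c(msg, "invalid biotype")
  for (i in seq_len(n)) {
    gr <- object@exons[[i]]
    id <- names(object@exons)[i]
    if (length(gr) == 0L) {
      msg <- c(msg, sprintf("transcript '%s' has no exons", id)); next
    }
    if (length(unique(as.character(seqnames(gr)))) != 1L)
      msg <- c(msg, sprintf("transcript '%s' spans multiple chromosomes", id))
    st <- unique(as.character(strand(gr)))
    if (length(st) != 1L || !st %in% c("+", "-"))
      msg <- c(msg, sprintf("transcript '%s' has mixed or unknown strand", id))
    s <- start(gr)
    if (is.unsorted(s, strictly = TRUE))
      msg <- c(msg, sprintf("exons of '%s' not sorted by start", id))
    if (length(gr) > 1L && any(start(gr)[-1L] <= end(gr)[-length(gr)]))
      msg <- c(msg, sprintf("exons of '%s' overlap", id))
    if (any(width(gr) < 1L))
      msg <- c(msg, sprintf("zero-length exon in '%s'", id))
  }
  if (length(msg)) msg else TRUE
}
setValidity("GeneModelSet", .validGeneModelSet)

#' Construct a GeneModelSet
#'
#' @param exons a \code{GRangesList} of CDS parts, one element per transcript.
#' @param geneId character vector of gene identifiers (recycled if length 1).
#' @param biotype character vector of biotypes (default
#'   \code{"unclassified"}).
#' @return a \code{GeneModelSet}.
#' @export
GeneModelSet <- function(exons, geneId = names(exons),
                         biotype = "unclassified") {
  n <- length(exons)
  geneId <- rep_len(as.character(geneId), n)
  biotype <- rep_len(as.character(biotype), n)
  new("GeneModelSet", exons = exons, geneId = geneId, biotype = biotype)
}

#' @describeIn GeneModelSet number of transcripts
#' @param x,object a \code{GeneModelSet}
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@exons))

#' @describeIn GeneModelSet transcript identifiers
#' @export
setMethod("names", "GeneModelSet", function(x) names(x@exons))

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet with %d transcript(s) over %d gene(s)\n",
              length(object), length(unique(object@geneId))))
  if (length(object)) {
    k <- min(5L, length(object))
    for (i in seq_len(k)) {
      gr <- object@exons[[i]]
      cat(sprintf("  %s (%s) %s:%d-%d [%s] %d exon(s), %s\n",
                  names(object@exons)[i], object@geneId[i],
                  as.character(seqnames(gr))[1], min(start(gr)),
                  max(end(gr)), as.character(strand(gr))[1], length(gr),
                  object@biotype[i]))
    }
    if (length(object) > k) cat(sprintf("  ... and %d more\n",
                                        length(object) - k))
  }
})

#' @param i index
#' @describeIn GeneModelSet subset transcripts
#' @export
setMethod("[", "GeneModelSet", function(x, i) {
  new("GeneModelSet", exons = x@exons[i], geneId = x@geneId[i],
      biotype = x@biotype[i])
})

#' Accessors for GeneModelSet
#'
#' @param x a \code{GeneModelSet}
#' @return character vectors parallel to transcripts (or, for
#'   \code{exonRanges}, the underlying \code{GRangesList}).
#' @name geneModel-accessors
NULL

#' @rdname geneModel-accessors
#' @export
transcriptIds <- function(x) names(x@exons)

#' @rdname geneModel-accessors
#' @export
geneIds <- function(x) x@geneId

#' @rdname geneModel-accessors
#' @export
biotypes <- function(x) x@biotype

#' @rdname geneModel-accessors
#' @export
exonRanges <- function(x) x@exons

#' @rdname geneModel-accessors
#' @export
txChrom <- function(x)
  vapply(x@exons, function(gr) as.character(seqnames(gr))[1], character(1))

#' @rdname geneModel-accessors
#' @export
txStrand <- function(x)
  vapply(x@exons, function(gr) as.character(strand(gr))[1], character(1))

#' MotifPattern: a degenerate protein motif consensus
#'
#' An ordered list of match elements over the 20-letter amino-acid alphabet.
#' Each element is the set of residues allowed at that position; wildcard
#' positions allow all 20 standard residues (an \code{X} in the scanned
#' protein never matches, conservatively).
#'
#' @slot name motif name.
#' @slot notation the notation string the pattern was compiled from.
#' @slot elements list of character vectors of allowed residues.
#' @export
setClass("MotifPattern",
  representation(name = "character", notation = "character",
                 elements = "list"))

.validMotifPattern <- function(object) {
  if (length(object@elements) < 1L) return("pattern must have >= 1 element")
  ok <- vapply(object@elements, function(e)
    length(e) >= 1L && all(e %in% AA_STANDARD20), logical(1))
  if (!all(ok)) return("elements must be non-empty subsets of the 20-aa alphabet")
  TRUE
}
setValidity("MotifPattern", .validMotifPattern)

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern '%s' (%s), length %d\n", object@name,
              object@notation, length(object@elements)))
})

#' @describeIn MotifPattern number of positions in the pattern
#' @param x a \code{MotifPattern}
#' @export
setMethod("length", "MotifPattern", function(x) length(x@elements))

#' SpliceConsensus: splice-boundary base frequency matrices
#'
#' Position frequency matrices (PFMs) over a fixed window around intron
#' donor and acceptor sites, with per-position information content in bits
#' (2 - (Shannon entropy + small-sample correction), floored at 0).
#'
#' @slot donorPFM,acceptorPFM 4 x (2 * flank) matrices (rows A,C,G,T; columns
#'   sum to 1).
#' @slot donorIC,acceptorIC numeric vectors of per-position bits.
#' @slot nDonor,nAcceptor number of sites used.
#' @slot flank flank width in nucleotides on each side of the boundary.
#' @export
setClass("SpliceConsensus",
  representation(donorPFM = "matrix", acceptorPFM = "matrix",
                 donorIC = "numeric", acceptorIC = "numeric",
                 nDonor = "integer", nAcceptor = "integer",
                 flank = "integer"))

.validSpliceConsensus <- function(object) {
  msg <- character()
  for (nm in c("donorPFM", "acceptorPFM")) {
    p <- slot(object, nm)
    if (nrow(p) != 4L) msg <- c(msg, sprintf("%s must have 4 rows", nm))
    if (ncol(p) > 0 && any(abs(colSums(p) - 1) > 1e-9))
      msg <- c(msg, sprintf("columns of %s must sum to 1", nm))
  }
  ic <- c(object@donorIC, object@acceptorIC)
  if (any(ic < 0 | ic > 2 + 1e-9))
    msg <- c(msg, "information content must lie in [0, 2] bits")
  if (length(msg)) msg else TRUE
}
setValidity("SpliceConsensus", .validSpliceConsensus)

setMethod("show", "SpliceConsensus", function(object) {
  cat(sprintf(
    "SpliceConsensus: %d donor / %d acceptor sites, flank %d nt\n",
    object@nDonor, object@nAcceptor, object@flank))
  cat(sprintf("  donor IC (bits):    %s\n",
              paste(sprintf("%.2f", object@donorIC), collapse = " ")))
  cat(sprintf("  acceptor IC (bits): %s\n",
              paste(sprintf("%.2f", object@acceptorIC), collapse = " ")))
})

#' FamilySpec: blueprint for a synthetic terpene-synthase family
#'
#' Parameters of the synthetic-genome generator: subfamily sizes, pseudogene
#' and decoy counts, tandem-cluster layout, divergence targets, intron-length
#' distribution, expression planting, and the mandatory seed. The defaults
#' mirror the family shape the analysis is designed for: 28 TPS-a, 18 TPS-b,
#' 2 TPS-c, 2 TPS-e/f and 5 TPS-g functional genes plus 40 pseudogenes, 61
#' genes arranged in 19 tandem clusters (inter-gene gaps below 67 kb), and
#' 24 loci on unplaced scaffolds.
#'
#' @slot subfamilyCounts named integer vector of functional gene counts.
#' @slot nPseudogenes,nUnplacedPseudogenes,nDecoys integer counts.
#' @slot clusterSizes integer vector of tandem-cluster sizes (2--6).
#' @slot nParalogPairs,paralogIdentity paralog planting controls.
#' @slot identityRange member-to-template protein identity range (percent).
#' @slot intronMeanlog,intronSdlog,intronRange intron-length log-normal
#'   parameters and truncation range (nt).
#' @slot intraClusterGap,interClusterGap inter-gene gap ranges (nt).
#' @slot tissues tissue labels for expression simulation.
#' @slot nTissueSpecific named integer vector of planted tissue-specific
#'   genes per tissue.
#' @slot nHighExpression,nLowExpression planted high/low expression genes.
#' @slot seed mandatory integer seed.
#' @export
setClass("FamilySpec",
  representation(subfamilyCounts = "integer", nPseudogenes = "integer",
                 nUnplacedPseudogenes = "integer", nDecoys = "integer",
                 clusterSizes = "integer", nParalogPairs = "integer",
                 paralogIdentity = "numeric", identityRange = "numeric",
                 intronMeanlog = "numeric", intronSdlog = "numeric",
                 intronRange = "numeric", intraClusterGap = "numeric",
                 interClusterGap = "numeric", tissues = "character",
                 nTissueSpecific = "integer", nHighExpression = "integer",
                 nLowExpression = "integer", seed = "integer"))

.validFamilySpec <- function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (any(object@subfamilyCounts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (!all(names(object@subfamilyCounts) %in% TPS_SUBFAMILIES))
    msg <- c(msg, "unknown subfamily in subfamilyCounts")
  if (any(object@clusterSizes < 2L))
    msg <- c(msg, "clusters need >= 2 members")
  if (object@nUnplacedPseudogenes > object@nPseudogenes)
    msg <- c(msg, "more unplaced pseudogenes than pseudogenes")
  nPlacedTps <- sum(object@subfamilyCounts) + object@nPseudogenes -
    object@nUnplacedPseudogenes
  if (sum(object@clusterSizes) > nPlacedTps)
    msg <- c(msg, "cluster layout needs more placed genes than available")
  if (object@paralogIdentity < 50 || object@paralogIdentity > 100)
    msg <- c(msg, "paralogIdentity must be in [50, 100]")
  if (object@interClusterGap[1] < 0 || object@intraClusterGap[1] < 0)
    msg <- c(msg, "gaps must be positive")
  if (!all(names(object@nTissueSpecific) %in% object@tissues))
    msg <- c(msg, "tissue-specific plant names must be tissues")
  if (length(msg)) msg else TRUE
}
setValidity("FamilySpec", .validFamilySpec)

setMethod("show", "FamilySpec", function(object) {
  cat("FamilySpec\n")
  cat("  functional genes:",
      paste(sprintf("%s=%d", names(object@subfamilyCounts),
                    object@subfamilyCounts), collapse = ", "), "\n")
  cat(sprintf("  pseudogenes: %d (%d unplaced); decoys: %d\n",
              object@nPseudogenes, object@nUnplacedPseudogenes,
              object@nDecoys))
  cat(sprintf("  clusters: %d (sizes %s)\n", length(object@clusterSizes),
              paste(object@clusterSizes, collapse = ",")))
  cat(sprintf("  seed: %d\n", object@seed))
})

#' TpsSimulation: a synthetic genome with planted ground truth
#'
#' @slot genome \code{DNAStringSet} of chromosome and scaffold sequences.
#' @slot models \code{GeneModelSet} of all planted gene models.
#' @slot truth per-gene ground-truth table (subfamily, class, functional
#'   status, cluster membership, paralog partner and target identity).
#' @slot motifTruth planted motif positions (gene, motif, residue start).
#' @slot references reference protein set (\code{AAStringSet}) whose names
#'   carry \code{subfamily=} tags, for homology anchoring.
#' @slot spec the \code{FamilySpec} the simulation was drawn from.
#' @export
setClass("TpsSimulation",
  representation(genome = "ANY", models = "GeneModelSet",
                 truth = "data.frame", motifTruth = "data.frame",
                 references = "ANY", spec = "FamilySpec"))

setMethod("show", "TpsSimulation", function(object) {
  cat(sprintf(
    "TpsSimulation: %d sequence(s), %d gene model(s); seed %d\n",
    length(object@genome), length(object@models), object@spec@seed))
  cat(sprintf("  functional %d, pseudogene %d, decoy %d; %d cluster(s)\n",
              sum(object@truth$functional),
              sum(object@truth$pseudogene),
              sum(object@truth$decoy),
              length(unique(stats::na.omit(object@truth$cluster_id)))))
})

#' TpsPipelineResult: outputs of the characterization pipeline
#'
#' @slot summary named list of headline counts and percentages.
#' @slot tables named list of per-stage tables (dispositions, architecture,
#'   motif completeness, protein properties, clusters, identities, paralogs,
#'   subfamily assignments, expression summaries).
#' @slot tree the neighbor-joining tree (\code{phylo}) with bootstrap
#'   supports as node labels, or NULL.
#' @slot consensus the \code{SpliceConsensus}, or NULL.
#' @slot config the configuration list used for the run.
#' @export
setClass("TpsPipelineResult",
  representation(summary = "list", tables = "list", tree = "ANY",
                 consensus = "ANY", config = "list"))

setMethod("show", "TpsPipelineResult", function(object) {
  s <- object@summary
  cat("TpsPipelineResult\n")
  cat(sprintf("  genes: %d total; %d functional TPS, %d pseudogene, %d non-TPS, %d unplaced\n",
              s$n_genes, s$n_functional, s$n_pseudogene, s$n_non_tps,
              s$n_unplaced))
  if (!is.null(s$subfamily_counts)) {
    cat("  subfamilies:",
        paste(sprintf("%s=%d", names(s$subfamily_counts),
                      s$subfamily_counts), collapse = ", "), "\n")
  }
  cat(sprintf("  clusters: %d (%.2f%% of placed TPS genes clustered)\n",
              s$n_clusters, s$pct_clustered_placed))
})
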