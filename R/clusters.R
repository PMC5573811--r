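# gene-level spans from a GeneModelSet (one row per gene)
.geneSpans <- function(models) {
  ch <- txChrom(models); st <- txStrand(models)
  gstart <- vapply(models@exons, function(g) min(start(g)), numeric(1))
  gend <- vapply(models@exons, function(g) max(end(g)), numeric(1))
  df <- data.frame(gene_id = geneIds(models), chrom = ch, start = gstart,
                   end = gend, strand = st, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$chrom, agg$start, agg$gene_id), , drop = FALSE]
}

#' Detect tandem gene clusters
#'
#' Single-linkage chaining per chromosome: consecutive genes (sorted by
#' start) join one cluster when the inter-gene gap (next gene's start minus
#' current gene's end minus 1) is strictly below \code{maxGapNt}. Singletons
#' are not clusters. Overlapping genes are treated as gap 0 (joined, with a
#' warning); strand is ignored for membership. Genes on unplaced sequences
#' are excluded from clustering and reported separately.
#'
#' @param models a \code{GeneModelSet} (clustering is on genes: transcripts
#'   of one gene are merged into its span).
#' @param maxGapNt maximum inter-gene gap in nucleotides (default 67,000).
#' @param unplaced character vector of sequence names to exclude (or a
#'   single regular expression when \code{unplacedIsPattern}).
#' @param unplacedIsPattern treat \code{unplaced} as a regex on chromosome
#'   names.
#' @return a list: \code{clusters} (data.frame cluster_id, chrom, start,
#'   end, span, n_members), \code{members} (data.frame gene_id, cluster_id,
#'   chrom, start, end, strand), \code{singletons} (gene ids),
#'   \code{unplaced} (gene ids excluded).
#' @export
detectClusters <- function(models, maxGapNt = 67000L, unplaced = NULL,
                           unplacedIsPattern = FALSE) {
  genes <- .geneSpans(models)
  excl <- rep(FALSE, nrow(genes))
  if (!is.null(unplaced) && length(unplaced)) {
    excl <- if (unplacedIsPattern) grepl(unplaced[1], genes$chrom)
            else genes$chrom %in% unplaced
  }
  unplacedIds <- genes$gene_id[excl]
  placed <- genes[!excl, , drop = FALSE]
  members <- list(); clusters <- list(); singles <- character(0)
  warnOverlap <- FALSE
  for (ch in unique(placed$chrom)) {
    g <- placed[placed$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    if (nrow(g) == 1L) { singles <- c(singles, g$gene_id); next }
    gaps <- g$start[-1L] - g$end[-nrow(g)] - 1L
    if (any(gaps < 0)) { warnOverlap <- TRUE; gaps[gaps < 0] <- 0L }
    grp <- cumsum(c(1L, as.integer(!(gaps < maxGapNt))))
    for (k in unique(grp)) {
      sub <- g[grp == k, , drop = FALSE]
      if (nrow(sub) < 2L) { singles <- c(singles, sub$gene_id); next }
      clusters[[length(clusters) + 1L]] <- data.frame(
        chrom = ch, start = min(sub$start), end = max(sub$end),
        span = max(sub$end) - min(sub$start) + 1L,
        n_members = nrow(sub), stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- sub
    }
  }
  if (warnOverlap)
    warning("overlapping gene(s): gap treated as 0 (joined)")
  if (length(clusters)) {
    cl <- do.call(rbind, clusters)
    ord <- order(cl$chrom, cl$start)
    cl <- cl[ord, , drop = FALSE]
    members <- members[ord]
    cl$cluster_id <- sprintf("CL%02d", seq_len(nrow(cl)))
    cl <- cl[, c("cluster_id", "chrom", "start", "end", "span",
                 "n_members")]
    mem <- do.call(rbind, lapply(seq_along(members), function(k) {
      cbind(members[[k]], cluster_id = cl$cluster_id[k],
            stringsAsFactors = FALSE)
    }))
    rownames(cl) <- rownames(mem) <- NULL
  } else {
    cl <- data.frame(cluster_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     span = integer(0), n_members = integer(0))
    mem <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), cluster_id = character(0))
  }
  list(clusters = cl, members = mem, singletons = sort(singles),
       unplaced = sort(unplacedIds))
}

#' Write clusters as BED plus a membership table
#'
#' BED columns: chrom, 0-based cluster start, cluster end, cluster_id,
#' member count.
#'
#' @param clustering result of \code{\link{detectClusters}}.
#' @param bedPath,membersPath output paths.
#' @return invisibly, the two paths.
#' @export
writeClusters <- function(clustering, bedPath, membersPath) {
  cl <- clustering$clusters
  bed <- data.frame(cl$chrom, cl$start - 1L, cl$end, cl$cluster_id,
                    cl$n_members)
  utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(clustering$members, membersPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(bed = bedPath, members = membersPath))
}

#' Chromosome, strand and clustering summary
#'
#' Per-chromosome and per-strand gene counts, unplaced-gene count, and the
#' percentage of clustered genes reported against two denominators: placed
#' genes only, and all genes including the unplaced ones (percentages half-
#' up rounded to 2 decimals).
#'
#' @param models a \code{GeneModelSet}.
#' @param clustering result of \code{\link{detectClusters}} on the same set.
#' @return a list of summary components.
#' @export
distributionSummary <- function(models, clustering) {
  genes <- .geneSpans(models)
  unpl <- clustering$unplaced
  placedGenes <- genes[!genes$gene_id %in% unpl, , drop = FALSE]
  nClustered <- nrow(clustering$members)
  nPlaced <- nrow(placedGenes)
  nTotal <- nrow(genes)
  list(
    per_chromosome = table(placedGenes$chrom),
    per_strand = table(placedGenes$strand),
    n_genes = nTotal,
    n_placed = nPlaced,
    n_unplaced = length(unpl),
    n_clusters = nrow(clustering$clusters),
    n_clustered = nClustered,
    pct_clustered_placed = roundHalfUp(100 * nClustered / max(nPlaced, 1), 2),
    pct_clustered_total = roundHalfUp(100 * nClustered / max(nTotal, 1), 2))
}
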