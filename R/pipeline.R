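#' Pipeline configuration
#'
#' Collects inputs and thresholds for \code{\link{runPipeline}}. Inputs may
#' be file paths (FASTA/GFF3/TSV) or in-memory objects
#' (\code{DNAStringSet}, \code{GeneModelSet}, \code{AAStringSet}, matrix).
#'
#' @param genome genome FASTA path or \code{DNAStringSet}.
#' @param models GFF3 path or \code{GeneModelSet}.
#' @param references reference protein FASTA path or \code{AAStringSet};
#'   headers may carry \code{subfamily=...} tags used for subfamily
#'   anchoring.
#' @param referenceLabels optional named character vector (reference id ->
#'   subfamily) overriding header tags.
#' @param expression optional RPKM TSV path or matrix (genes x tissues).
#' @param motifLibrary optional path to an alternative motif library TSV.
#' @param minProteinLen functionality threshold in residues (default 400).
#' @param clusterGap tandem-cluster gap threshold in nt (default 67,000).
#' @param paralogIdentity paralog identity threshold in percent (default
#'   94).
#' @param bootstrapReps bootstrap replicates (default 1000).
#' @param minRefIdentity,minRefCoverage TPS-candidate gate: minimum identity
#'   and query coverage (percent) against the reference set (defaults 40 and
#'   50).
#' @param expressionBounds category boundaries (detection, low/moderate,
#'   high) in RPKM.
#' @param unplaced character vector of sequence names, or a regular
#'   expression (see \code{unplacedIsPattern}), marking unplaced scaffolds.
#' @param unplacedIsPattern treat \code{unplaced} as a regex (default TRUE,
#'   matching the simulator's \code{scaffold_un_} names).
#' @param seed integer seed for the bootstrap.
#' @param outDir optional output directory for the report bundle.
#' @return a validated configuration list.
#' @export
pipelineConfig <- function(genome, models, references,
                           referenceLabels = NULL, expression = NULL,
                           motifLibrary = NULL, minProteinLen = 400L,
                           clusterGap = 67000L, paralogIdentity = 94,
                           bootstrapReps = 1000L, minRefIdentity = 40,
                           minRefCoverage = 50,
                           expressionBounds = c(0.1, 0.5, 60),
                           unplaced = "^scaffold_un", unplacedIsPattern = TRUE,
                           seed = 1L, outDir = NULL) {
  cfg <- list(genome = genome, models = models, references = references,
              referenceLabels = referenceLabels, expression = expression,
              motifLibrary = motifLibrary,
              minProteinLen = as.integer(minProteinLen),
              clusterGap = as.integer(clusterGap),
              paralogIdentity = paralogIdentity,
              bootstrapReps = as.integer(bootstrapReps),
              minRefIdentity = minRefIdentity,
              minRefCoverage = minRefCoverage,
              expressionBounds = expressionBounds, unplaced = unplaced,
              unplacedIsPattern = unplacedIsPattern,
              seed = as.integer(seed), outDir = outDir)
  thresholds <- c(cfg$minProteinLen, cfg$clusterGap, cfg$paralogIdentity,
                  cfg$bootstrapReps, cfg$expressionBounds)
  if (any(thresholds <= 0)) stop("validation error: thresholds must be positive")
  if (is.na(cfg$seed)) stop("validation error: seed must be set")
  for (f in c("genome", "models", "references", "expression",
              "motifLibrary")) {
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1L && !file.exists(v))
      stop("validation error: ", f, " file not found: ", v)
  }
  cfg
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

# strip descriptions; extract subfamily= tags when present
.referenceLabels <- function(refs, override = NULL) {
  full <- names(refs)
  ids <- sub("\\s.*$", "", full)
  if (!is.null(override)) return(override)
  tag <- regmatches(full, regexpr("subfamily=\\S+", full))
  hasTag <- grepl("subfamily=", full)
  labels <- rep(NA_character_, length(full))
  labels[hasTag] <- sub("subfamily=", "", tag)
  stats::setNames(labels[hasTag], ids[hasTag])
}

#' Run the full characterization pipeline
#'
#' Executes, in order: CDS extraction and translation; TPS-candidate gating
#' by homology to the reference set; disposition of every gene into exactly
#' one of functional / pseudogene / non-TPS / unplaced; exon--intron
#' architecture, class assignment and splice consensus; motif completeness;
#' protein properties; tandem-cluster detection and distribution summary;
#' identity matrix and paralog pairs; progressive alignment,
#' neighbor-joining tree with bootstrap supports and reference-anchored
#' subfamily assignment; and (optionally) expression summaries. A stage
#' failure halts the run naming the stage; outputs computed so far are kept
#' in the error's partial data where possible.
#'
#' @param config a list from \code{\link{pipelineConfig}}.
#' @return a \code{\link{TpsPipelineResult}}.
#' @export
runPipeline <- function(config) {
  genome <- if (is.character(config$genome)) readGenome(config$genome)
            else config$genome
  models <- if (is.character(config$models)) readGeneModels(config$models)
            else config$models
  refs <- if (is.character(config$references))
            Biostrings::readAAStringSet(config$references)
          else config$references
  refLabels <- .referenceLabels(refs, config$referenceLabels)
  if (length(refLabels) == 0L)
    stop("validation error: no reference subfamily labels available")
  names(refs) <- sub("\\s.*$", "", names(refs))
  exprIn <- config$expression
  if (is.character(exprIn)) exprIn <- readExpression(exprIn)

  # ---- extraction and translation ------------------------------------------
  prot <- .stage("extract", {
    cds <- extractCDS(models, genome)
    translateCDS(cds)
  })
  protChr <- as.character(prot)
  txGene <- stats::setNames(geneIds(models), names(models))
  txChromV <- txChrom(models)
  unplacedTx <- if (config$unplacedIsPattern)
    grepl(config$unplaced[1], txChromV) else txChromV %in% config$unplaced

  # ---- candidate gating ----------------------------------------------------
  gate <- .stage("gate", {
    do.call(rbind, lapply(seq_along(protChr), function(i) {
      p <- protChr[i]
      hits <- if (nchar(p) >= 30L)
        referenceSearch(p, refs, minIdentity = config$minRefIdentity,
                        minCoverage = config$minRefCoverage)
      else data.frame()
      data.frame(transcript_id = names(prot)[i],
                 gene_id = unname(txGene[names(prot)[i]]),
                 protein_length = nchar(p),
                 is_tps = nrow(hits) > 0L,
                 best_reference = if (nrow(hits)) hits$ref_id[1]
                                  else NA_character_,
                 best_identity = if (nrow(hits)) hits$identity[1]
                                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })

  # ---- per-gene disposition (functional / pseudogene / non-TPS / unplaced)
  genesAll <- unique(geneIds(models))
  disposition <- vapply(genesAll, function(g) {
    txs <- which(txGene == g)
    if (any(unplacedTx[txs])) return("unplaced")
    if (!any(gate$is_tps[match(names(models)[txs], gate$transcript_id)]))
      return("non_tps")
    maxLen <- max(gate$protein_length[match(names(models)[txs],
                                            gate$transcript_id)])
    if (maxLen >= config$minProteinLen) "functional" else "pseudogene"
  }, character(1))
  dispTable <- data.frame(gene_id = genesAll,
                          disposition = unname(disposition),
                          stringsAsFactors = FALSE)

  funcGenes <- genesAll[disposition == "functional"]
  funcTxIdx <- which(txGene %in% funcGenes &
                       gate$protein_length[match(names(models),
                                                 gate$transcript_id)] >=
                       config$minProteinLen)
  funcModels <- models[funcTxIdx]
  funcProt <- stats::setNames(protChr[funcTxIdx], names(models)[funcTxIdx])

  # ---- architecture --------------------------------------------------------
  archOut <- .stage("architecture", {
    arch <- geneArchitecture(funcModels)
    stats <- if (nrow(arch)) exonIntronStats(arch) else NULL
    cons <- tryCatch(spliceConsensus(funcModels, genome),
                     error = function(e) NULL)
    list(arch = arch, stats = stats, consensus = cons)
  })
  classCounts <- table(archOut$arch$tps_class)

  # ---- motifs ---------------------------------------------------------------
  motifTab <- .stage("motifs", {
    lib <- if (is.null(config$motifLibrary)) tpsMotifLibrary("generic")
           else tpsMotifLibrary("generic", path = config$motifLibrary)
    motifCompleteness(funcProt, required = lib)
  })

  # ---- protein properties ---------------------------------------------------
  propTab <- .stage("properties", {
    proteinProperties(funcProt, minLen = config$minProteinLen)
  })

  # ---- tandem clusters -------------------------------------------------------
  tpsGenes <- genesAll[disposition %in% c("functional", "pseudogene",
                                          "unplaced")]
  clustering <- .stage("clusters", {
    tpsModels <- models[which(txGene %in% tpsGenes)]
    detectClusters(tpsModels, maxGapNt = config$clusterGap,
                   unplaced = config$unplaced,
                   unplacedIsPattern = config$unplacedIsPattern)
  })
  tpsModelsAll <- models[which(txGene %in% tpsGenes)]
  distSummary <- distributionSummary(tpsModelsAll, clustering)

  # ---- homology --------------------------------------------------------------
  homol <- .stage("homology", {
    if (length(funcProt) >= 2L) {
      im <- identityMatrix(funcProt)
      spans <- .geneSpans(funcModels)
      pos <- data.frame(id = names(funcProt),
                        chrom = spans$chrom[match(unname(txGene[names(funcProt)]),
                                                  spans$gene_id)],
                        stringsAsFactors = FALSE)
      list(identity = im,
           paralogs = findParalogPairs(im, pos,
                                       threshold = config$paralogIdentity))
    } else list(identity = NULL, paralogs = NULL)
  })

  # ---- phylogeny and subfamily assignment ------------------------------------
  phylo <- .stage("phylogeny", {
    if (length(funcProt) >= 2L) {
      seqsAll <- c(funcProt, stats::setNames(as.character(refs),
                                             names(refs)))
      msa <- progressiveMSA(seqsAll)
      boot <- bootstrapSupports(msa, nReps = config$bootstrapReps,
                                seed = config$seed)
      assign <- assignSubfamily(boot$tree, refLabels)
      list(msa = msa, tree = boot$tree, supports = boot$supports,
           assignments = assign[names(funcProt)])
    } else list(msa = NULL, tree = NULL, supports = NULL,
                assignments = NULL)
  })
  subCounts <- if (!is.null(phylo$assignments)) {
    a <- phylo$assignments
    table(factor(a, levels = sort(unique(c(refLabels, "ambiguous")))))
  } else NULL

  # ---- expression -------------------------------------------------------------
  exprOut <- .stage("expression", {
    if (is.null(exprIn)) NULL else {
      cats <- apply(exprIn, 2, expressionCategory)
      rownames(cats) <- rownames(exprIn)
      spec <- tissueSpecific(exprIn,
                             detectThreshold = config$expressionBounds[2])
      hm <- heatmapMatrix(exprIn)
      list(categories = cats, tissue_specific = spec,
           heatmap = hm)
    }
  })

  summary <- list(
    n_genes = length(genesAll),
    n_functional = sum(disposition == "functional"),
    n_pseudogene = sum(disposition == "pseudogene"),
    n_non_tps = sum(disposition == "non_tps"),
    n_unplaced = sum(disposition == "unplaced"),
    class_counts = classCounts,
    n_motif_complete = sum(motifTab$complete),
    n_clusters = distSummary$n_clusters,
    n_clustered = distSummary$n_clustered,
    pct_clustered_placed = distSummary$pct_clustered_placed,
    pct_clustered_total = distSummary$pct_clustered_total,
    subfamily_counts = subCounts,
    n_paralog_pairs = if (!is.null(homol$paralogs)) nrow(homol$paralogs)
                      else 0L,
    mean_identity = if (!is.null(homol$identity))
      attr(homol$identity, "mean_identity") else NA_real_,
    n_tissue_specific = if (!is.null(exprOut))
      table(exprOut$tissue_specific[!is.na(exprOut$tissue_specific)])
      else NULL,
    seed = config$seed)

  result <- new("TpsPipelineResult",
                summary = summary,
                tables = list(dispositions = dispTable, gate = gate,
                              architecture = archOut$arch,
                              arch_stats = archOut$stats,
                              motifs = motifTab, properties = propTab,
                              clusters = clustering,
                              distribution = distSummary,
                              identity = homol$identity,
                              paralogs = homol$paralogs,
                              assignments = phylo$assignments,
                              supports = phylo$supports,
                              expression = exprOut),
                tree = phylo$tree, consensus = archOut$consensus,
                config = config)
  if (!is.null(config$outDir)) writeReport(result, config$outDir)
  result
}

#' Write the pipeline report bundle
#'
#' Emits per-stage TSV tables, the Newick tree with bootstrap supports, the
#' splice-consensus matrices, a plain-text summary, and a run log (package
#' version, seed, configuration digest) into a directory.
#'
#' @param result a \code{TpsPipelineResult}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tb <- result@tables
  wt <- function(df, name) {
    if (!is.null(df) && is.data.frame(df) && nrow(df))
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wt(tb$dispositions, "dispositions.tsv")
  wt(tb$gate, "candidate_gate.tsv")
  if (!is.null(tb$architecture) && nrow(tb$architecture)) {
    a <- tb$architecture
    utils::write.table(data.frame(
      transcript_id = a$transcript_id, gene_id = a$gene_id,
      n_introns = a$n_introns, tps_class = a$tps_class,
      exon_lengths_aa = vapply(as.list(a$exon_lengths_aa), paste,
                               character(1), collapse = ","),
      intron_lengths_nt = vapply(as.list(a$intron_lengths_nt), paste,
                                 character(1), collapse = ","),
      intron_phases = vapply(as.list(a$intron_phases), paste,
                             character(1), collapse = ",")),
      file.path(dir, "architecture.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  wt(tb$motifs, "motif_completeness.tsv")
  wt(tb$properties, "protein_properties.tsv")
  if (!is.null(tb$clusters)) {
    wt(tb$clusters$clusters, "clusters.tsv")
    wt(tb$clusters$members, "cluster_members.tsv")
    if (nrow(tb$clusters$clusters))
      writeClusters(tb$clusters, file.path(dir, "clusters.bed"),
                    file.path(dir, "cluster_members_bed.tsv"))
  }
  if (!is.null(tb$identity))
    utils::write.table(
      data.frame(id = rownames(tb$identity), tb$identity,
                 check.names = FALSE),
      file.path(dir, "identity_matrix.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  wt(tb$paralogs, "paralog_pairs.tsv")
  if (!is.null(tb$assignments))
    utils::write.table(
      data.frame(transcript_id = names(tb$assignments),
                 subfamily = unname(tb$assignments)),
      file.path(dir, "subfamily_assignments.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  if (!is.null(result@tree))
    ape::write.tree(result@tree, file.path(dir, "tree.nwk"))
  if (!is.null(result@consensus))
    writeSpliceConsensus(result@consensus,
                         file.path(dir, "splice_donor.tsv"),
                         file.path(dir, "splice_acceptor.tsv"))
  if (!is.null(tb$expression)) {
    utils::write.table(
      data.frame(gene_id = rownames(tb$expression$heatmap$matrix),
                 tb$expression$heatmap$matrix, check.names = FALSE),
      file.path(dir, "expression_log2.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ts <- tb$expression$tissue_specific
    utils::write.table(
      data.frame(gene_id = names(ts), tissue = unname(ts)),
      file.path(dir, "tissue_specific.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  s <- result@summary
  cfgDump <- utils::capture.output(utils::str(
    result@config[!vapply(result@config, is.object, logical(1))]))
  tmp <- tempfile(); writeLines(cfgDump, tmp)
  log <- c(sprintf("tpscan version: %s",
                   as.character(utils::packageVersion("tpscan"))),
           sprintf("R version: %s", R.version.string),
           sprintf("seed: %d", s$seed),
           sprintf("config md5: %s", unname(tools::md5sum(tmp))),
           sprintf("date: (run log)"))
  writeLines(log, file.path(dir, "run_log.txt"))
  unlink(tmp)
  smry <- c(
    sprintf("genes: %d", s$n_genes),
    sprintf("functional TPS: %d", s$n_functional),
    sprintf("pseudogenes: %d", s$n_pseudogene),
    sprintf("non-TPS: %d", s$n_non_tps),
    sprintf("unplaced: %d", s$n_unplaced),
    sprintf("clusters: %d (%d genes, %.2f%% of placed)", s$n_clusters,
            s$n_clustered, s$pct_clustered_placed),
    sprintf("motif-complete proteins: %d", s$n_motif_complete),
    if (!is.null(s$subfamily_counts))
      paste("subfamilies:", paste(sprintf("%s=%d",
        names(s$subfamily_counts), s$subfamily_counts), collapse = ", ")))
  writeLines(smry, file.path(dir, "summary.txt"))
  invisible(dir)
}
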