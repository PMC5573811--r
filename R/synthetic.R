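# ---- composition tables -----------------------------------------------------

# plausible globular background composition
.AA_BG <- c(A = .08, R = .05, N = .04, D = .055, C = .015, E = .065,
            Q = .04, G = .07, H = .022, I = .055, L = .09, K = .06,
            M = .022, F = .04, P = .048, S = .068, T = .055, W = .012,
            V = .066, Y = .032)

# serine/threonine-rich, positively charged composition for transit peptides
.AA_TRANSIT <- c(S = .22, T = .12, A = .12, R = .08, K = .08, L = .10,
                 V = .07, P = .06, G = .06, F = .03, I = .03, M = .03)

# amino acids whose codon set allows an A and a G at the phase-relevant
# position of an exon|intron boundary (donor context "R/GT")
.BOUNDARY_POOLS <- list(
  p0 = c("L", "V", "S", "P", "T", "A", "G", "R", "Q", "E", "K"),
  p1A = c("I", "T", "N", "K", "M"), p1G = c("V", "A", "D", "E", "G"),
  p2A = c("Y", "H", "Q", "N", "K", "D", "E"), p2G = c("W", "G", "R"))

.sampleAA <- function(n, comp = .AA_BG)
  sample(names(comp), n, replace = TRUE, prob = comp)

# ---- FamilySpec constructor -------------------------------------------------

#' Construct a synthetic-family blueprint
#'
#' Builds a \code{\link{FamilySpec}}. The defaults describe the family shape
#' the pipeline is validated against: 28 TPS-a, 18 TPS-b, 2 TPS-c, 2
#' TPS-e/f and 5 TPS-g putatively functional genes, 40 pseudogenes (24 of
#' them on unplaced scaffolds), 3 non-TPS decoy genes, and 61 genes arranged
#' in 19 tandem clusters of 2--6 members with intra-cluster gaps below and
#' inter-cluster gaps above 67 kb.
#'
#' @param seed mandatory integer seed driving every random choice.
#' @param subfamilyCounts named integer vector of functional gene counts.
#' @param nPseudogenes,nUnplacedPseudogenes,nDecoys counts of pseudogenes,
#'   unplaced pseudogenes and non-TPS decoys.
#' @param clusterSizes integer vector of tandem-cluster sizes.
#' @param nParalogPairs,paralogIdentity number of planted high-identity
#'   paralog pairs and their protein identity target (percent).
#' @param identityRange member-to-template protein identity range (percent).
#' @param intronMeanlog,intronSdlog,intronRange intron-length log-normal
#'   parameters (most lengths fall in the 81--400 nt band) and hard range.
#' @param intraClusterGap,interClusterGap inter-gene gap ranges in nt.
#' @param tissues,nTissueSpecific,nHighExpression,nLowExpression expression
#'   planting controls.
#' @return a validated \code{FamilySpec}.
#' @export
familySpec <- function(seed,
                       subfamilyCounts = c("TPS-a" = 28L, "TPS-b" = 18L,
                                           "TPS-c" = 2L, "TPS-e/f" = 2L,
                                           "TPS-g" = 5L),
                       nPseudogenes = 40L, nUnplacedPseudogenes = 24L,
                       nDecoys = 3L,
                       clusterSizes = c(6L, 5L, 4L, 4L, 4L, 4L, 3L, 3L, 3L,
                                        3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L,
                                        2L),
                       nParalogPairs = 4L, paralogIdentity = 96,
                       identityRange = c(72, 90),
                       intronMeanlog = log(160), intronSdlog = 0.45,
                       intronRange = c(62, 2335),
                       intraClusterGap = c(2000, 45000),
                       interClusterGap = c(68000, 120000),
                       tissues = c("leaf", "flower", "fruit"),
                       nTissueSpecific = c(leaf = 4L, flower = 1L,
                                           fruit = 3L),
                       nHighExpression = 5L, nLowExpression = 8L) {
  new("FamilySpec",
      subfamilyCounts = stats::setNames(as.integer(subfamilyCounts),
                                        names(subfamilyCounts)),
      nPseudogenes = as.integer(nPseudogenes),
      nUnplacedPseudogenes = as.integer(nUnplacedPseudogenes),
      nDecoys = as.integer(nDecoys),
      clusterSizes = as.integer(clusterSizes),
      nParalogPairs = as.integer(nParalogPairs),
      paralogIdentity = paralogIdentity,
      identityRange = identityRange, intronMeanlog = intronMeanlog,
      intronSdlog = intronSdlog, intronRange = intronRange,
      intraClusterGap = intraClusterGap, interClusterGap = interClusterGap,
      tissues = tissues,
      nTissueSpecific = stats::setNames(as.integer(nTissueSpecific),
                                        names(nTissueSpecific)),
      nHighExpression = as.integer(nHighExpression),
      nLowExpression = as.integer(nLowExpression),
      seed = as.integer(seed))
}

# ---- class / subfamily templates -------------------------------------------

# architecture templates: exon coding lengths in codons (stop included in
# the last exon) and the fixed intron-phase vector per class
.ARCH_TEMPLATES <- list(
  "TPS-a"  = list(class = "III", exonsAa = c(115, 85, 75, 90, 95, 44, 45),
                  phases = c(0L, 1L, 0L, 2L, 0L, 0L)),
  "TPS-b"  = list(class = "III", exonsAa = c(125, 95, 85, 100, 105, 44, 48),
                  phases = c(0L, 1L, 0L, 2L, 0L, 0L)),
  "TPS-g"  = list(class = "III", exonsAa = c(118, 88, 78, 94, 98, 44, 46),
                  phases = c(0L, 1L, 0L, 2L, 0L, 0L)),
  "TPS-c"  = list(class = "I",
                  exonsAa = c(75, 60, 55, 65, 70, 55, 60, 65, 55, 60, 58,
                              50, 58),
                  phases = c(0L, 1L, 2L, 0L, 0L, 1L, 0L, 2L, 0L, 0L, 1L,
                             0L)),
  "TPS-e/f" = list(class = "I",
                  exonsAa = c(77, 62, 56, 66, 71, 56, 61, 66, 56, 61, 60,
                              52, 58),
                  phases = c(0L, 1L, 2L, 0L, 0L, 1L, 0L, 2L, 0L, 0L, 1L,
                             0L)))

# planted motif instances (sequence, 1-based start in the protein)
.MOTIF_TEMPLATES <- list(
  "TPS-a"  = list("RRX8W" = list(seq = "RRTASFHPSIW", at = 25L),
                  "RDR" = list(seq = "RDR", at = 330L),
                  "DDXXD" = list(seq = "DDIYD", at = 352L),
                  "NSE/DTE" = list(seq = "DDIYSHKFE", at = 462L)),
  "TPS-b"  = list("RRX8W" = list(seq = "RRSANYHPSIW", at = 85L),
                  "RDR" = list(seq = "RDR", at = 385L),
                  "DDXXD" = list(seq = "DDIYD", at = 407L),
                  "NSE/DTE" = list(seq = "DDLGTSSDE", at = 517L)),
  "TPS-g"  = list("RDQ" = list(seq = "RDQ", at = 350L),
                  "DDXXD" = list(seq = "DDIFD", at = 370L),
                  "NSE/DTE" = list(seq = "DDLGSAKDE", at = 480L)),
  "TPS-c"  = list("SAYDTAW" = list(seq = "SAYDTAW", at = 120L),
                  "QXXDGSWG" = list(seq = "QIIDGSWG", at = 152L),
                  "DXDD" = list(seq = "DVDD", at = 530L)),
  "TPS-e/f" = list("SAYDTAW" = list(seq = "SAYDTAW", at = 118L),
                  "QXXDGSWG" = list(seq = "QLIDGSWG", at = 150L),
                  "DDXXD" = list(seq = "DDIYD", at = 575L)))

# residue positions covered by planted motifs
.motifSpan <- function(sub) {
  mt <- .MOTIF_TEMPLATES[[sub]]
  unlist(lapply(mt, function(m) seq(m$at, m$at + nchar(m$seq) - 1L)))
}

# aa position whose codon carries the boundary base for intron k
.boundaryAaPos <- function(cumAa, phases) {
  ifelse(phases == 0L, cumAa, cumAa + 1L)
}

# build the per-subfamily templates: ancestor protein with motifs planted,
# boundary residues drawn from phase-compatible pools, deterministic under
# the spec seed
.familyTemplates <- function(spec) {
  withSeed(spec@seed, {
    lapply(stats::setNames(nm = TPS_SUBFAMILIES), function(sub) {
      arch <- .ARCH_TEMPLATES[[sub]]
      nCodons <- sum(arch$exonsAa)      # includes the stop codon
      L <- nCodons - 1L                 # protein length
      prot <- .sampleAA(L)
      prot[1] <- "M"
      for (m in .MOTIF_TEMPLATES[[sub]]) {
        idx <- seq(m$at, m$at + nchar(m$seq) - 1L)
        prot[idx] <- strsplit(m$seq, "")[[1]]
      }
      cumAa <- cumsum(arch$exonsAa)[-length(arch$exonsAa)]
      bAa <- .boundaryAaPos(cumAa, arch$phases)
      bBase <- character(length(bAa))   # fixed base for phase 1/2 boundaries
      for (k in seq_along(bAa)) {
        ph <- arch$phases[k]
        if (ph == 0L) {
          prot[bAa[k]] <- sample(.BOUNDARY_POOLS$p0, 1L)
          bBase[k] <- ""                # sampled per member
        } else {
          b <- sample(c("A", "G"), 1L)
          pool <- .BOUNDARY_POOLS[[paste0("p", ph, b)]]
          prot[bAa[k]] <- sample(pool, 1L)
          bBase[k] <- b
        }
      }
      protected <- sort(unique(c(1L, .motifSpan(sub), bAa)))
      list(subfamily = sub, class = arch$class, protein = prot,
           exonsAa = arch$exonsAa, phases = arch$phases, cumAa = cumAa,
           boundaryAa = bAa, boundaryBase = bBase, protected = protected)
    })
  })
}

# ---- codon-level helpers ----------------------------------------------------

# reverse-translate a protein (character vector of residues), honouring the
# boundary-base constraints: for phase-0 boundaries the codon's third base is
# sampled from {A, G}; phase 1/2 bases are fixed by the template residue.
.reverseTranslate <- function(prot, tmpl) {
  codons <- vapply(prot, function(aa) {
    cs <- CODONS_BY_AA[[aa]]
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE)
  for (k in seq_along(tmpl$boundaryAa)) {
    pos <- tmpl$boundaryAa[k]; ph <- tmpl$phases[k]
    aa <- prot[pos]
    cs <- CODONS_BY_AA[[aa]]
    if (ph == 0L) {
      b <- sample(c("A", "G"), 1L)
      ok <- cs[substr(cs, 3, 3) == b]
      if (!length(ok)) ok <- cs[substr(cs, 3, 3) %in% c("A", "G")]
      codons[pos] <- ok[sample.int(length(ok), 1L)]
    }
    # phases 1 and 2: the relevant base is determined by the residue itself
  }
  codons[1] <- "ATG"
  paste(c(codons, "TGA"), collapse = "")
}

# draw one intron: GT ... Y AG with the requested length
.drawIntron <- function(len) {
  mid <- if (len > 5L) paste(sample(c("A", "C", "G", "T"), len - 5L,
                                    replace = TRUE), collapse = "") else ""
  paste0("GT", mid, sample(c("C", "T"), 1L), "AG")
}

.drawIntronLengths <- function(n, spec) {
  len <- round(stats::rlnorm(n, spec@intronMeanlog, spec@intronSdlog))
  pmin(pmax(len, spec@intronRange[1]), spec@intronRange[2])
}

#' Mutate a coding sequence to a target protein identity
#'
#' Introduces codon-level point substitutions until the encoded protein is
#' within 0.5 points of the requested identity to the input, plus a larger
#' number of synonymous substitutions (synonymous-biased divergence).
#' Positions in \code{protect} (1-based residue indices), the start codon
#' and the terminal stop are never touched, so planted motifs and
#' exon-boundary codons survive by default.
#'
#' @param cds coding sequence (character or \code{DNAString}), length
#'   divisible by 3.
#' @param targetIdentity desired protein identity in percent (50--100).
#' @param protect integer vector of protected residue positions.
#' @param synRate synonymous substitutions per nonsynonymous one.
#' @return the mutated coding sequence (character).
#' @examples
#' cds <- "ATGGCTGCTGCTGCTGCTGCTGCTGCTGCTTGA"
#' identical(mutateToIdentity(cds, 100), cds)
#' @export
mutateToIdentity <- function(cds, targetIdentity, protect = integer(0),
                             synRate = 1.5) {
  if (targetIdentity < 50 || targetIdentity > 100)
    stop("targetIdentity must be in [50, 100]")
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_DNA[codons]
  nAa <- if (!is.na(aa[n]) && aa[n] == "*") n - 1L else n
  eligible <- setdiff(2:nAa, protect)
  nSub <- round(nAa * (1 - targetIdentity / 100))
  if (nSub > length(eligible))
    stop("target identity unreachable: only ", length(eligible),
         " mutable positions for ", nSub, " substitutions")
  if (nSub > 0) {
    pos <- sample(eligible, nSub)
    for (p in pos) {
      newAa <- sample(setdiff(AA_STANDARD20, aa[p]), 1L,
                      prob = .AA_BG[setdiff(AA_STANDARD20, aa[p])])
      cs <- CODONS_BY_AA[[newAa]]
      codons[p] <- cs[sample.int(length(cs), 1L)]
    }
    nSyn <- min(round(synRate * nSub), length(eligible) - nSub)
    if (nSyn > 0) {
      sp <- sample(setdiff(eligible, pos), nSyn)
      for (p in sp) {
        cs <- CODONS_BY_AA[[aa[p]]]
        if (length(cs) > 1L)
          codons[p] <- sample(setdiff(cs, codons[p]), 1L)
      }
    }
  }
  paste(codons, collapse = "")
}

#' Truncate a coding sequence into a pseudogene product
#'
#' Plants a premature stop codon so the translated product falls below the
#' functionality threshold (default well under 400 residues). Pure function:
#' the input is not modified.
#'
#' @param cds coding sequence (character or \code{DNAString}).
#' @param stopAtCodon codon index to replace with TAA; when NULL, sampled
#'   uniformly from codons 100--350 (capped at half the coding length).
#' @return the truncated coding sequence (character).
#' @export
truncateToPseudogene <- function(cds, stopAtCodon = NULL) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  n <- nchar(s) %/% 3L
  if (is.null(stopAtCodon)) {
    hi <- min(350L, max(100L, n %/% 2L))
    stopAtCodon <- sample(100:hi, 1L)
  }
  if (stopAtCodon < 2L || stopAtCodon > n) stop("stop position out of range")
  paste0(substr(s, 1L, 3L * (stopAtCodon - 1L)), "TAA",
         substr(s, 3L * stopAtCodon + 1L, nchar(s)))
}

# generate one member: mutated protein, reverse-translated CDS, exon/intron
# pieces; everything in transcript orientation. Uses the ambient RNG.
.makeGeneCore <- function(tmpl, spec, targetIdentity = NULL,
                          transit = FALSE, pseudo = FALSE) {
  prot <- tmpl$protein
  L <- length(prot)
  if (is.null(targetIdentity))
    targetIdentity <- stats::runif(1, spec@identityRange[1],
                                   spec@identityRange[2])
  nSub <- round(L * (1 - targetIdentity / 100))
  eligible <- setdiff(seq_len(L), tmpl$protected)
  if (transit) eligible <- setdiff(eligible, seq_len(60L))
  nSub <- min(nSub, length(eligible))
  if (nSub > 0) {
    pos <- sample(eligible, nSub)
    for (p in pos)
      prot[p] <- sample(setdiff(AA_STANDARD20, prot[p]), 1L,
                        prob = .AA_BG[setdiff(AA_STANDARD20, prot[p])])
  }
  if (transit) {
    block <- .sampleAA(60L, .AA_TRANSIT)
    block[1] <- "M"
    prot[seq_len(60L)] <- block
  }
  cds <- .reverseTranslate(prot, tmpl)
  if (pseudo) cds <- truncateToPseudogene(cds)
  protein <- as.character(translateCDS(cds)[[1]])
  # split into exon pieces at the template cuts (in nt, stop included)
  cuts <- 3L * tmpl$cumAa + tmpl$phases
  bounds <- c(0L, cuts, nchar(cds))
  exonSeqs <- substring(cds, bounds[-length(bounds)] + 1L,
                        bounds[-1L])
  intronLens <- .drawIntronLengths(length(cuts), spec)
  intronSeqs <- vapply(intronLens, .drawIntron, character(1))
  list(protein = protein, cds = cds, exonSeqs = exonSeqs,
       intronSeqs = intronSeqs, targetIdentity = targetIdentity,
       class = tmpl$class, subfamily = tmpl$subfamily)
}

# same, but from a pre-made CDS (paralog partners)
.coreFromCds <- function(cds, tmpl, spec, targetIdentity) {
  protein <- as.character(translateCDS(cds)[[1]])
  cuts <- 3L * tmpl$cumAa + tmpl$phases
  bounds <- c(0L, cuts, nchar(cds))
  exonSeqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  intronLens <- .drawIntronLengths(length(cuts), spec)
  intronSeqs <- vapply(intronLens, .drawIntron, character(1))
  list(protein = protein, cds = cds, exonSeqs = exonSeqs,
       intronSeqs = intronSeqs, targetIdentity = targetIdentity,
       class = tmpl$class, subfamily = tmpl$subfamily)
}

#' Generate one synthetic terpene-synthase gene
#'
#' Draws a gene of the requested subfamily from its template: subfamily
#' motifs planted at their conserved template positions, the coding sequence
#' split into exons per the class template (6 introns for class III
#' subfamilies, 12 for class I), introns with GT...AG cores, purine donor
#' context and pyrimidine--AG acceptor context. Uses the ambient RNG; seed
#' the session (or use \code{\link{assembleGenome}}) for reproducibility.
#'
#' @param spec a \code{FamilySpec} (templates derive from its seed).
#' @param subfamily one of the TPS subfamilies.
#' @param geneId identifier for the emitted gene.
#' @param targetIdentity protein identity to the subfamily template
#'   (percent); when NULL, drawn from \code{spec}'s identity range.
#' @param flank plain flanking sequence added on both sides of the locus.
#' @return a list: \code{model} (a single-transcript \code{GeneModelSet} on
#'   a standalone locus sequence), \code{locus} (named \code{DNAStringSet}),
#'   \code{cds}, \code{protein}, and \code{truth} (subfamily, class, motif
#'   positions).
#' @export
makeGene <- function(spec, subfamily, geneId = "gene1",
                     targetIdentity = NULL, flank = 500L) {
  stopifnot(subfamily %in% TPS_SUBFAMILIES)
  tmpl <- .familyTemplates(spec)[[subfamily]]
  core <- .makeGeneCore(tmpl, spec, targetIdentity = targetIdentity)
  pieces <- character(2L * length(core$exonSeqs) - 1L)
  pieces[c(TRUE, FALSE)] <- core$exonSeqs
  if (length(core$intronSeqs))
    pieces[c(FALSE, TRUE)] <- core$intronSeqs
  body <- paste(pieces, collapse = "")
  flankL <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  flankR <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  locusSeq <- paste0(flankL, body, flankR)
  lens <- nchar(pieces)
  ends <- cumsum(lens) + flank
  starts <- ends - lens + 1L
  exIdx <- seq(1L, length(pieces), by = 2L)
  gr <- GRanges(paste0(geneId, "_locus"),
                IRanges(starts[exIdx], ends[exIdx]), strand = "+")
  grl <- GRangesList(stats::setNames(list(gr), paste0(geneId, ".1")))
  model <- GeneModelSet(grl, geneId = geneId)
  locus <- Biostrings::DNAStringSet(stats::setNames(locusSeq,
                                                    paste0(geneId, "_locus")))
  truth <- list(subfamily = subfamily, class = core$class,
                motifs = lapply(.MOTIF_TEMPLATES[[subfamily]],
                                function(m) m$at),
                target_identity = core$targetIdentity)
  list(model = model, locus = locus, cds = core$cds,
       protein = core$protein, truth = truth)
}

# ---- whole-genome assembly --------------------------------------------------

.randomDna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# genomic placement of one gene core; returns the genomic locus string and
# the exon GRanges
.placeGene <- function(core, chrom, offset, strandChar) {
  nEx <- length(core$exonSeqs)
  pieces <- character(2L * nEx - 1L)
  pieces[c(TRUE, FALSE)] <- core$exonSeqs
  if (nEx > 1L) pieces[c(FALSE, TRUE)] <- core$intronSeqs
  body <- paste(pieces, collapse = "")
  Lt <- nchar(body)
  lens <- nchar(pieces)
  txEnds <- cumsum(lens)
  txStarts <- txEnds - lens + 1L
  exIdx <- seq(1L, length(pieces), by = 2L)
  if (strandChar == "+") {
    gs <- offset + txStarts[exIdx]
    ge <- offset + txEnds[exIdx]
    seqOut <- body
  } else {
    seqOut <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(body)))
    gs <- offset + Lt - txEnds[exIdx] + 1L
    ge <- offset + Lt - txStarts[exIdx] + 1L
    ord <- order(gs); gs <- gs[ord]; ge <- ge[ord]
  }
  list(seq = seqOut, ranges = IRanges(gs, ge), length = Lt)
}

#' Assemble a synthetic genome with planted ground truth
#'
#' Generates chromosome sequences (FASTA-ready), gene models (GFF3-ready), a
#' reference protein set and a full ground-truth table from a
#' \code{\link{FamilySpec}}: functional genes per subfamily, pseudogenes
#' (premature stops), non-TPS decoys, tandem clusters with intra-cluster
#' gaps below and inter-cluster gaps above the clustering threshold,
#' paralog pairs at the requested identity placed in the same cluster, and
#' unplaced scaffolds. Fully reproducible: the same spec (same seed) yields
#' byte-identical outputs.
#'
#' @param spec a \code{FamilySpec}.
#' @param dir optional output directory; when given, writes
#'   \code{genome.fasta}, \code{models.gff3}, \code{references.fasta},
#'   \code{truth.tsv} and \code{motif_truth.tsv}.
#' @return a \code{\link{TpsSimulation}}.
#' @export
assembleGenome <- function(spec, dir = NULL) {
  tmpl <- .familyTemplates(spec)
  sim <- withSeed(spec@seed + 1000003L, {
    # ---- roster -------------------------------------------------------------
    rows <- list(); cores <- list()
    mkId <- function(sub, i) sprintf("%s_%02d",
      gsub("[^a-z]", "", tolower(sub)), i)
    for (sub in names(spec@subfamilyCounts)) {
      cnt <- spec@subfamilyCounts[[sub]]
      if (cnt == 0L) next
      # transit-peptide allocation: TPS-b members 1..12, TPS-g members 1..3
      nTransit <- if (sub == "TPS-b") min(12L, cnt)
                  else if (sub == "TPS-g") min(3L, cnt) else 0L
      i <- 1L
      while (i <= cnt) {
        id <- mkId(sub, i)
        core <- .makeGeneCore(tmpl[[sub]], spec, transit = i <= nTransit)
        cores[[id]] <- core
        rows[[id]] <- data.frame(gene_id = id, subfamily = sub,
          class = core$class, functional = TRUE, pseudogene = FALSE,
          decoy = FALSE, unplaced = FALSE,
          paralog_partner = NA_character_, target_identity = NA_real_,
          stringsAsFactors = FALSE)
        # paralog partner: derived from this member's CDS
        if (sub == "TPS-a" && i %% 2L == 1L &&
            (i + 1L) %/% 2L <= spec@nParalogPairs && i + 1L <= cnt) {
          pid <- mkId(sub, i + 1L)
          pcds <- mutateToIdentity(core$cds, spec@paralogIdentity,
                                   protect = tmpl[[sub]]$protected)
          cores[[pid]] <- .coreFromCds(pcds, tmpl[[sub]], spec,
                                       spec@paralogIdentity)
          rows[[pid]] <- data.frame(gene_id = pid, subfamily = sub,
            class = core$class, functional = TRUE, pseudogene = FALSE,
            decoy = FALSE, unplaced = FALSE, paralog_partner = id,
            target_identity = spec@paralogIdentity,
            stringsAsFactors = FALSE)
          rows[[id]]$paralog_partner <- pid
          rows[[id]]$target_identity <- spec@paralogIdentity
          i <- i + 2L
        } else i <- i + 1L
      }
    }
    # pseudogenes
    if (spec@nPseudogenes > 0L) {
      subs <- sample(names(spec@subfamilyCounts), spec@nPseudogenes,
                     replace = TRUE,
                     prob = pmax(spec@subfamilyCounts, 0.5))
      for (i in seq_len(spec@nPseudogenes)) {
        id <- sprintf("pseudo_%02d", i)
        core <- .makeGeneCore(tmpl[[subs[i]]], spec, pseudo = TRUE)
        cores[[id]] <- core
        rows[[id]] <- data.frame(gene_id = id, subfamily = subs[i],
          class = core$class, functional = FALSE, pseudogene = TRUE,
          decoy = FALSE, unplaced = i <= spec@nUnplacedPseudogenes,
          paralog_partner = NA_character_, target_identity = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    # non-TPS decoys: unrelated random proteins, two exons
    if (spec@nDecoys > 0L) {
      for (i in seq_len(spec@nDecoys)) {
        id <- sprintf("decoy_%02d", i)
        prot <- .sampleAA(450L); prot[1] <- "M"
        codons <- vapply(prot, function(aa) {
          cs <- CODONS_BY_AA[[aa]]; cs[sample.int(length(cs), 1L)]
        }, character(1), USE.NAMES = FALSE)
        cds <- paste(c(codons, "TGA"), collapse = "")
        ilen <- .drawIntronLengths(1L, spec)
        cores[[id]] <- list(protein = paste(prot, collapse = ""), cds = cds,
          exonSeqs = c(substr(cds, 1, 600), substr(cds, 601, nchar(cds))),
          intronSeqs = .drawIntron(ilen), targetIdentity = NA_real_,
          class = "unclassified", subfamily = NA_character_)
        rows[[id]] <- data.frame(gene_id = id, subfamily = NA_character_,
          class = "unclassified", functional = FALSE, pseudogene = FALSE,
          decoy = TRUE, unplaced = FALSE,
          paralog_partner = NA_character_, target_identity = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL

    # ---- layout -------------------------------------------------------------
    placedTps <- truth$gene_id[!truth$unplaced & !truth$decoy]
    # paralog pairs share a cluster: seed clusters with the pairs first
    pairs <- truth[!is.na(truth$paralog_partner) &
                     truth$gene_id < truth$paralog_partner, , drop = FALSE]
    clusterGenes <- vector("list", length(spec@clusterSizes))
    remaining <- placedTps
    pi <- 1L
    for (p in seq_len(nrow(pairs))) {
      if (pi > length(clusterGenes)) break
      g <- c(pairs$gene_id[p], pairs$paralog_partner[p])
      clusterGenes[[pi]] <- g
      remaining <- setdiff(remaining, g)
      pi <- pi + 1L
    }
    remaining <- sample(remaining)
    for (k in seq_along(clusterGenes)) {
      need <- spec@clusterSizes[k] - length(clusterGenes[[k]])
      if (need > 0L) {
        take <- utils::head(remaining, need)
        clusterGenes[[k]] <- c(clusterGenes[[k]], take)
        remaining <- setdiff(remaining, take)
      }
    }
    singles <- c(remaining, truth$gene_id[truth$decoy])
    units <- c(lapply(clusterGenes, identity), as.list(singles))
    isCluster <- c(rep(TRUE, length(clusterGenes)),
                   rep(FALSE, length(singles)))
    chroms <- c("chr2", "chr3", "chr4", "chr5", "chr7", "chr8")
    unitChrom <- sample(chroms, length(units), replace = TRUE,
                        prob = c(.22, .2, .3, .2, .06, .02))
    # ---- emit chromosomes ---------------------------------------------------
    genomeSeqs <- character(0)
    exonsList <- list(); geneIdsOut <- character(0)
    clusterOfGene <- stats::setNames(rep(NA_character_, nrow(truth)),
                                     truth$gene_id)
    chromOfGene <- clusterOfGene; strandOfGene <- clusterOfGene
    clusterCounter <- 0L
    for (ch in chroms) {
      sel <- which(unitChrom == ch)
      if (!length(sel)) { next }
      pos <- 0L
      chromParts <- character(0)
      lead <- as.integer(round(stats::runif(1, 10000, 30000)))
      chromParts <- c(chromParts, .randomDna(lead)); pos <- pos + lead
      for (u in sel) {
        genes <- units[[u]]
        cid <- NA_character_
        if (isCluster[u]) {
          clusterCounter <- clusterCounter + 1L
          cid <- sprintf("cluster_%02d", clusterCounter)
        }
        for (gi in seq_along(genes)) {
          g <- genes[gi]
          strandChar <- sample(c("+", "-"), 1L)
          placed <- .placeGene(cores[[g]], ch, pos, strandChar)
          chromParts <- c(chromParts, placed$seq)
          exonsList[[paste0(g, ".1")]] <- GRanges(ch, placed$ranges,
                                                  strand = strandChar)
          geneIdsOut <- c(geneIdsOut, g)
          clusterOfGene[g] <- cid
          chromOfGene[g] <- ch
          strandOfGene[g] <- strandChar
          pos <- pos + placed$length
          gap <- if (gi < length(genes))
            as.integer(round(stats::runif(1, spec@intraClusterGap[1],
                                          spec@intraClusterGap[2])))
          else as.integer(round(stats::runif(1, spec@interClusterGap[1],
                                             spec@interClusterGap[2])))
          chromParts <- c(chromParts, .randomDna(gap)); pos <- pos + gap
        }
      }
      genomeSeqs[ch] <- paste(chromParts, collapse = "")
    }
    # ---- unplaced scaffolds -------------------------------------------------
    unplacedIds <- truth$gene_id[truth$unplaced]
    for (i in seq_along(unplacedIds)) {
      g <- unplacedIds[i]
      sc <- sprintf("scaffold_un_%02d", i)
      strandChar <- sample(c("+", "-"), 1L)
      placed <- .placeGene(cores[[g]], sc, 1000L, strandChar)
      genomeSeqs[sc] <- paste0(.randomDna(1000L), placed$seq,
                               .randomDna(1000L))
      exonsList[[paste0(g, ".1")]] <- GRanges(sc, placed$ranges,
                                              strand = strandChar)
      geneIdsOut <- c(geneIdsOut, g)
      chromOfGene[g] <- sc
      strandOfGene[g] <- strandChar
    }
    # ---- containers ---------------------------------------------------------
    models <- GeneModelSet(GRangesList(exonsList), geneId = geneIdsOut,
      biotype = ifelse(truth$pseudogene[match(geneIdsOut, truth$gene_id)],
                       "pseudogene", "unclassified"))
    truth$transcript_id <- paste0(truth$gene_id, ".1")
    truth$cluster_id <- unname(clusterOfGene[truth$gene_id])
    truth$chrom <- unname(chromOfGene[truth$gene_id])
    truth$strand <- unname(strandOfGene[truth$gene_id])
    motifTruth <- do.call(rbind, lapply(
      truth$gene_id[truth$functional], function(g) {
        sub <- truth$subfamily[truth$gene_id == g]
        mt <- .MOTIF_TEMPLATES[[sub]]
        data.frame(gene_id = g, subfamily = sub, motif = names(mt),
                   instance = vapply(mt, `[[`, character(1), "seq"),
                   start_aa = vapply(mt, `[[`, integer(1), "at"),
                   stringsAsFactors = FALSE)
      }))
    rownames(motifTruth) <- NULL
    refs <- Biostrings::AAStringSet(vapply(tmpl, function(t)
      paste(t$protein, collapse = ""), character(1)))
    names(refs) <- sprintf("REF_%s subfamily=%s",
                           gsub("[^a-z]", "", tolower(names(tmpl))),
                           names(tmpl))
    genome <- Biostrings::DNAStringSet(genomeSeqs)
    new("TpsSimulation", genome = genome, models = models, truth = truth,
        motifTruth = motifTruth, references = refs, spec = spec)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeGenome(sim@genome, file.path(dir, "genome.fasta"))
    writeGeneModels(sim@models, file.path(dir, "models.gff3"))
    Biostrings::writeXStringSet(sim@references,
                                file.path(dir, "references.fasta"),
                                width = 70L)
    utils::write.table(sim@truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim@motifTruth, file.path(dir, "motif_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sim
}

#' Simulate an RPKM expression matrix with planted structure
#'
#' Baseline abundances follow a heavy-tailed log-normal (meanlog log 3,
#' sdlog 1.2); planted tissue-specific genes exceed the 0.5 RPKM detection
#' threshold in exactly one tissue; planted high-expression genes reach at
#' least 60 RPKM; planted low-expression genes sit inside the 0.1--0.5 band
#' everywhere. Seeded from the spec.
#'
#' @param genes character vector of gene identifiers (rows).
#' @param spec a \code{FamilySpec} (tissues, planting counts, seed).
#' @param tissues tissue labels (default from the spec).
#' @return a list: \code{matrix} (genes x tissues RPKM), \code{truth} (list
#'   with \code{specific} named gene -> tissue, \code{high}, \code{low}).
#' @export
simulateExpression <- function(genes, spec, tissues = spec@tissues) {
  if (length(tissues) < 2L) stop("need at least two tissues")
  withSeed(spec@seed + 2000003L, {
    n <- length(genes)
    mat <- matrix(stats::rlnorm(n * length(tissues), log(3), 1.2), n,
                  dimnames = list(genes, tissues))
    pool <- sample(genes)
    take <- function(k) {
      out <- utils::head(pool, k); pool <<- utils::tail(pool, -k); out
    }
    low <- take(min(spec@nLowExpression, length(pool)))
    mat[low, ] <- stats::runif(length(low) * length(tissues), 0.12, 0.45)
    specific <- character(0)
    for (t in names(spec@nTissueSpecific)) {
      k <- spec@nTissueSpecific[[t]]
      g <- take(min(k, length(pool)))
      mat[g, ] <- stats::runif(length(g) * length(tissues), 0, 0.45)
      mat[g, t] <- stats::runif(length(g), 20, 120)
      specific <- c(specific, stats::setNames(rep(t, length(g)), g))
    }
    high <- take(min(spec@nHighExpression, length(pool)))
    mat[high, sample(tissues, 1L)] <- stats::runif(length(high), 60, 150)
    list(matrix = mat,
         truth = list(specific = specific, high = high, low = low))
  })
}
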