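#' Functionality filter on protein length
#'
#' Predicted proteins of at least \code{minLen} residues (default 400) are
#' considered putatively functional; shorter products are treated as
#' pseudogene or partial-gene products.
#'
#' @param proteins an \code{AAStringSet} or character vector.
#' @param minLen length threshold in residues.
#' @return logical vector.
#' @export
isPutativeFunctional <- function(proteins, minLen = 400L) {
  len <- if (is(proteins, "XStringSet")) Biostrings::width(proteins)
         else nchar(proteins)
  len >= minLen
}

#' Protein molecular weight (average masses)
#'
#' Sum of average (isotope-abundance weighted) residue masses plus one water
#' mass, as in the usual "theoretical MW" computation. Sequences containing
#' X are rejected with the offending position; empty sequences are an error.
#'
#' @param proteins an \code{AAStringSet}, \code{AAString} or character
#'   vector.
#' @param units \code{"Da"} (default, full precision) or \code{"kDa"}
#'   (rounded half-up to 2 decimals).
#' @return numeric vector of molecular weights.
#' @examples
#' molecularWeight("G")    # 75.07 Da
#' @export
molecularWeight <- function(proteins, units = c("Da", "kDa")) {
  units <- match.arg(units)
  seqs <- asNamedChr(proteins)
  out <- vapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    if (!nzchar(s)) stop("empty protein sequence (record ", i, ")")
    ch <- strsplit(s, "")[[1]]
    bad <- which(!ch %in% names(AA_MONO_AVG))
    if (length(bad))
      stop("non-standard residue '", ch[bad[1]], "' at position ", bad[1],
           " (record ", i, ")")
    sum(AA_MONO_AVG[ch]) + WATER_AVG
  }, numeric(1))
  names(out) <- names(seqs)
  if (units == "kDa") roundHalfUp(out / 1000, 2) else out
}

#' Net charge of a protein at a given pH
#'
#' Henderson--Hasselbalch sum over the termini and the ionizable side chains
#' (D, E, C, Y, H, K, R), with the Bjellqvist pKa set by default. X residues
#' are chargeless.
#'
#' @param protein a single sequence (character or \code{AAString}).
#' @param pH pH value(s).
#' @param pKa a pKa set shaped like \code{PKA_BJELLQVIST}.
#' @return numeric vector of net charges, one per pH.
#' @export
netCharge <- function(protein, pH, pKa = PKA_BJELLQVIST) {
  s <- as.character(protein)
  if (!nzchar(s)) stop("empty protein sequence")
  ch <- strsplit(s, "")[[1]]
  counts <- table(factor(ch, levels = c(AA_STANDARD20, "X")))
  first <- ch[1]; last <- ch[length(ch)]
  pkN <- if (first %in% names(pKa$nterm)) pKa$nterm[[first]]
         else pKa$nterm_default
  pkC <- if (last %in% names(pKa$cterm)) pKa$cterm[[last]]
         else pKa$cterm_default
  posPk <- c(pkN, rep(pKa$positive["K"], counts[["K"]]),
             rep(pKa$positive["R"], counts[["R"]]),
             rep(pKa$positive["H"], counts[["H"]]))
  negPk <- c(pkC, rep(pKa$negative["D"], counts[["D"]]),
             rep(pKa$negative["E"], counts[["E"]]),
             rep(pKa$negative["C"], counts[["C"]]),
             rep(pKa$negative["Y"], counts[["Y"]]))
  vapply(pH, function(p) {
    pos <- sum(1 / (1 + 10^(p - posPk)))
    neg <- sum(1 / (1 + 10^(negPk - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the net charge crosses zero. The net charge is
#' strictly decreasing in pH, so the root is unique; bisection on [0, 14]
#' converges to the default 0.005 tolerance in at most 12 iterations.
#' Composition-only: the result is invariant under sequence permutation.
#' Poly-X stretches are chargeless, so a pI is always defined (by the
#' termini at worst).
#'
#' @param proteins an \code{AAStringSet}, \code{AAString} or character
#'   vector.
#' @param pKa pKa set (default Bjellqvist, the set behind the usual
#'   "theoretical pI" values).
#' @param tol bisection half-width tolerance in pH units.
#' @return numeric vector of pI values.
#' @examples
#' isoelectricPoint("KKKKKKKK") > 9.5
#' @export
isoelectricPoint <- function(proteins, pKa = PKA_BJELLQVIST, tol = 0.005) {
  seqs <- asNamedChr(proteins)
  out <- vapply(seqs, function(s) {
    lo <- 0; hi <- 14; iter <- 0L
    repeat {
      mid <- (lo + hi) / 2
      q <- netCharge(s, mid, pKa)
      iter <- iter + 1L
      # stop once the pH interval is inside tolerance AND the charge at
      # the midpoint is effectively zero (large proteins have steep charge
      # curves, so the pH tolerance alone does not bound the charge)
      if (((hi - lo) / 2 <= tol && abs(q) < 0.005) || iter >= 60L) break
      if (q > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
  names(out) <- names(seqs)
  out
}

#' Crude transit-peptide heuristic
#'
#' An approximate stand-in for a dedicated targeting predictor: the
#' N-terminal window (default 60 residues) is called \code{"predicted"} when
#' it is serine/threonine enriched (S+T fraction > 0.20) and carries a net
#' positive charge (K+R minus D+E > 0); \code{"unknown"} is returned for
#' proteins shorter than 100 residues. This is a composition heuristic only
#' and is always labelled approximate; user-supplied calls should be
#' preferred when available.
#'
#' @param proteins an \code{AAStringSet} or character vector.
#' @param window N-terminal window length in residues.
#' @return character vector of \code{"predicted"}, \code{"absent"} or
#'   \code{"unknown"}.
#' @export
predictTransitPeptide <- function(proteins, window = 60L) {
  seqs <- asNamedChr(proteins)
  out <- vapply(seqs, function(s) {
    if (nchar(s) < 100L) return("unknown")
    ch <- strsplit(substr(s, 1L, window), "")[[1]]
    stFrac <- mean(ch %in% c("S", "T"))
    netPos <- sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E"))
    if (stFrac > 0.20 && netPos > 0) "predicted" else "absent"
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(seqs)
  out
}

#' Mono/sesquiterpene synthase type hint
#'
#' Monoterpene synthases carry an N-terminal plastid transit peptide and run
#' 600--650 residues; sesquiterpene synthases lack the transit peptide and
#' are typically 50--70 residues shorter. The hint is \code{"mono"} when a
#' transit peptide is predicted, \code{"sesqui"} when it is absent and the
#' protein is at most 600 residues, otherwise \code{"unknown"}.
#'
#' @param lengthAa integer vector of protein lengths.
#' @param transit character vector (\code{"predicted"}, \code{"absent"},
#'   \code{"unknown"}).
#' @return character vector of type hints.
#' @export
classifyTpsType <- function(lengthAa, transit) {
  stopifnot(length(lengthAa) == length(transit))
  out <- rep("unknown", length(lengthAa))
  out[transit == "predicted"] <- "mono"
  out[transit == "absent" & lengthAa <= 600L] <- "sesqui"
  out
}

#' Protein property table
#'
#' Length, molecular weight (kDa, 2 decimals), isoelectric point,
#' putative-functionality flag, transit-peptide call and mono/sesqui type
#' hint for a set of proteins. Proteins containing X are kept but get an NA
#' molecular weight (documented exclusion); their pI treats X as chargeless.
#'
#' @param proteins a named \code{AAStringSet} or character vector.
#' @param transit optional pre-computed transit-peptide calls (named as
#'   \code{proteins}); when missing, \code{\link{predictTransitPeptide}} is
#'   used.
#' @param minLen functionality threshold in residues.
#' @return a data.frame with one row per protein.
#' @export
proteinProperties <- function(proteins, transit = NULL, minLen = 400L) {
  seqs <- asNamedChr(proteins)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("protein", seq_along(seqs))
  len <- nchar(seqs)
  hasX <- grepl("X", seqs, fixed = TRUE)
  mw <- rep(NA_real_, length(seqs))
  ok <- !hasX & len > 0
  if (any(ok)) mw[ok] <- molecularWeight(seqs[ok], units = "kDa")
  pi <- ifelse(len > 0, isoelectricPoint(seqs), NA_real_)
  if (is.null(transit)) transit <- predictTransitPeptide(seqs)
  data.frame(protein_id = ids, length_aa = len, mw_kda = mw,
             pi = roundHalfUp(pi, 2),
             putative_functional = isPutativeFunctional(seqs, minLen),
             transit_peptide = unname(transit),
             tps_type_hint = classifyTpsType(len, unname(transit)),
             stringsAsFactors = FALSE)
}
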