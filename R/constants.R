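# Frozen constants used across the package.

# the 20 standard amino acids, one-letter codes
AA_STANDARD20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

TPS_SUBFAMILIES <- c("TPS-a", "TPS-b", "TPS-c", "TPS-e/f", "TPS-g")

# Average (isotope-abundance weighted) residue masses in Da, ExPASy style,
# i.e. amino-acid mass minus one water; protein MW = sum(residues) + water.
AA_MONO_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG <- 18.01524

# Bjellqvist pKa set (the set behind ExPASy's Compute pI/MW).
# Side chains:
PKA_BJELLQVIST <- list(
  positive = c(K = 10.0, R = 12.0, H = 5.98),
  negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
  nterm_default = 7.5,
  nterm = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
            E = 7.7),
  cterm_default = 3.55,
  cterm = c(D = 4.55, E = 4.75))

# Standard genetic code keyed by DNA codon.
GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# codons per amino acid (stop excluded)
CODONS_BY_AA <- split(names(GENETIC_CODE_DNA), GENETIC_CODE_DNA)
CODONS_BY_AA[["*"]] <- NULL

# round half away from zero (printed identities, MW, percentages)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards (keeps all package randomness behind one seed)
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# character conversion that preserves names for both XStringSet and plain
# character input (base as.character drops attributes)
asNamedChr <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  names(out) <- nm
  out
}

# reverse complement of a plain DNA string (A/C/G/T/N)
revcompStr <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}
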