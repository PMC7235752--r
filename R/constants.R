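# Core constants: alphabets, the standard genetic code, recoding tables and
# property scales used across the package.

#' structphylo: structure-partitioned phylogenomic signal analysis
#'
#' Partition protein alignments by structural environment, fit reversible
#' substitution models (single-matrix and profile mixtures) on fixed
#' candidate topologies, detect decisive sites, compare fitted rate
#' matrices in model space, diagnose compositional heterogeneity, and
#' recode amino acids.
#'
#' @keywords internal
"_PACKAGE"

#' Canonical amino-acid order, recoding tables and property scales
#'
#' `AA_ORDER` is the canonical residue order ARNDCQEGHILKMFPSTWYV used for
#' every frequency and exchangeability vector; `GENETIC_CODE_1` maps codons
#' to one-letter residues under the standard genetic code; `DAYHOFF6_TABLE`
#' and `RY_TABLE` are the recoding tables; `GRANTHAM_POLARITY` the polarity
#' scale; `GARP_SET`/`FYMINK_SET` the GC-rich / AT-rich codon residue
#' groups.
#'
#' @name structphylo-constants
#' @aliases AA_ORDER GENETIC_CODE_1 DAYHOFF6_TABLE RY_TABLE
#'   GRANTHAM_POLARITY GARP_SET FYMINK_SET
#' @export AA_ORDER GENETIC_CODE_1 DAYHOFF6_TABLE RY_TABLE
#' @export GRANTHAM_POLARITY GARP_SET FYMINK_SET
NULL

# Canonical amino-acid order (PAML convention), used for every frequency
# vector, exchangeability vector and rate-matrix file in the package.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

STATE6_ORDER <- as.character(0:5)
BINARY_ORDER <- c("0", "1")

.alphabet_states <- function(alphabet) {
  switch(alphabet,
    AA20   = AA_ORDER,
    STATE6 = STATE6_ORDER,
    BINARY = BINARY_ORDER,
    stop("unknown alphabet: ", alphabet))
}

# Symbols accepted in input matrices beyond the state alphabet. All are
# treated as missing data (all-ones partial likelihoods) but preserved
# distinctly on output.
.missing_symbols <- function(alphabet) {
  if (alphabet == "AA20") c("-", "?", "X", "B", "Z") else c("-", "?")
}

# Standard genetic code (NCBI translation table 1), codon -> amino acid
# one-letter code; '*' marks stop codons.
GENETIC_CODE_1 <- c(
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

# Dayhoff six-class recoding: 0 = C; 1 = small (A,G,P,S,T); 2 = acid/amide
# (N,D,E,Q); 3 = basic (R,H,K); 4 = large aliphatic (I,L,M,V);
# 5 = aromatic (F,W,Y).
DAYHOFF6_TABLE <- c(
  C = "0",
  A = "1", G = "1", P = "1", S = "1", T = "1",
  N = "2", D = "2", E = "2", Q = "2",
  R = "3", H = "3", K = "3",
  I = "4", L = "4", M = "4", V = "4",
  F = "5", W = "5", Y = "5")

# Purine/pyrimidine back-translation: each amino acid maps to one symbol per
# codon position; 0 = purine (A/G), 1 = pyrimidine (C/T), '?' = mixed across
# the amino acid's codons under the standard genetic code. The IUPAC
# ambiguity codes B (N/D) and Z (Q/E) take the positionwise intersection of
# their members' entries. The test suite re-derives this table by brute-force
# codon enumeration.
RY_TABLE <- c(
  A = "01?", R = "?0?", N = "001", D = "001", C = "101",
  Q = "100", E = "000", G = "00?", H = "101", I = "01?",
  L = "11?", K = "000", M = "010", F = "111", P = "11?",
  S = "???", T = "01?", W = "100", Y = "101", V = "01?",
  B = "001", Z = "?00")

# Grantham (1974) amino-acid polarity scale, canonical residue order.
GRANTHAM_POLARITY <- c(
  A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
  G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
  P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9)

# GC-rich-codon and AT-rich-codon residue groups used for compositional
# diagnostics.
GARP_SET <- c("G", "A", "R", "P")
FYMINK_SET <- c("F", "Y", "M", "I", "N", "K")

# Pair order for A-state exchangeability vectors: column-wise lower triangle
# on the canonical state order, i.e. (2,1),(3,1),...,(A,1),(3,2),...
pair_index <- function(n_states) {
  idx <- which(lower.tri(matrix(0, n_states, n_states)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

# Expand an exchangeability vector into a symmetric A x A matrix with zero
# diagonal, and the reverse.
exch_vec_to_mat <- function(r, n_states) {
  stopifnot(length(r) == n_states * (n_states - 1) / 2)
  m <- matrix(0, n_states, n_states)
  m[lower.tri(m)] <- r
  m + t(m)
}

exch_mat_to_vec <- function(m) m[lower.tri(m)]
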