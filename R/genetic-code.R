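# Genetic-code tables shared by the codon machinery.
#
# The standard code and the plastid/bacterial code 11 have identical
# sense-codon tables (61 codons, stops TAA/TAG/TGA), so a single table serves
# both; `code_id` is threaded through constructors for future codes.

NUCS <- c("A", "C", "G", "T")

# All 64 codons in lexicographic ACGT order.
ALL_CODONS <- as.vector(t(outer(
  as.vector(t(outer(NUCS, NUCS, paste0))), NUCS, paste0)))

STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
N_CODON <- length(SENSE_CODONS) # 61

# Amino acids in alphabetical single-letter order; index order is used for
# deterministic argmax tie-breaking in ancestral reconstruction.
AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
AA_THREE <- c(A="Ala", C="Cys", D="Asp", E="Glu", F="Phe", G="Gly", H="His",
              I="Ile", K="Lys", L="Leu", M="Met", N="Asn", P="Pro", Q="Gln",
              R="Arg", S="Ser", T="Thr", V="Val", W="Trp", Y="Tyr")

# Standard genetic code, codon -> single-letter amino acid ("*" = stop).
GENETIC_CODE_STD <- c(
  AAA="K", AAC="N", AAG="K", AAT="N", ACA="T", ACC="T", ACG="T", ACT="T",
  AGA="R", AGC="S", AGG="R", AGT="S", ATA="I", ATC="I", ATG="M", ATT="I",
  CAA="Q", CAC="H", CAG="Q", CAT="H", CCA="P", CCC="P", CCG="P", CCT="P",
  CGA="R", CGC="R", CGG="R", CGT="R", CTA="L", CTC="L", CTG="L", CTT="L",
  GAA="E", GAC="D", GAG="E", GAT="D", GCA="A", GCC="A", GCG="A", GCT="A",
  GGA="G", GGC="G", GGG="G", GGT="G", GTA="V", GTC="V", GTG="V", GTT="V",
  TAA="*", TAC="Y", TAG="*", TAT="Y", TCA="S", TCC="S", TCG="S", TCT="S",
  TGA="*", TGC="C", TGG="W", TGT="C", TTA="L", TTC="F", TTG="L", TTT="F")

# codon string -> sense-codon index (1..61), NA for stops
CODON_INDEX <- stats::setNames(rep(NA_integer_, 64L), ALL_CODONS)
CODON_INDEX[SENSE_CODONS] <- seq_len(N_CODON)

# sense codon index -> amino-acid index (1..20)
CODON_AA <- match(GENETIC_CODE_STD[SENSE_CODONS], AA_LETTERS)

# 61 x 3 matrix of nucleotide indices (1..4 over ACGT) per codon position
CODON_NUC <- t(vapply(strsplit(SENSE_CODONS, ""),
                      function(x) match(x, NUCS), integer(3)))

.is_transition <- function(a, b) {
  purine <- c(TRUE, FALSE, TRUE, FALSE) # A, G purines over ACGT order
  purine[a] == purine[b]
}

# Pairwise structure of the 61 sense codons, computed once at build time:
# single-nucleotide neighbours, transition vs transversion, synonymous flag.
.codon_pairs <- local({
  diff_count <- matrix(0L, N_CODON, N_CODON)
  for (p in 1:3) {
    diff_count <- diff_count + outer(CODON_NUC[, p], CODON_NUC[, p], "!=")
  }
  nb <- which(diff_count == 1L, arr.ind = TRUE)
  nb <- nb[nb[, 1] != nb[, 2], , drop = FALSE]
  pos <- integer(nrow(nb)); from_nuc <- integer(nrow(nb)); to_nuc <- integer(nrow(nb))
  for (p in 1:3) {
    d <- CODON_NUC[nb[, 1], p] != CODON_NUC[nb[, 2], p]
    pos[d] <- p
    from_nuc[d] <- CODON_NUC[nb[d, 1], p]
    to_nuc[d] <- CODON_NUC[nb[d, 2], p]
  }
  list(i = nb[, 1], j = nb[, 2], pos = pos, to_nuc = to_nuc,
       transition = .is_transition(from_nuc, to_nuc),
       synonymous = CODON_AA[nb[, 1]] == CODON_AA[nb[, 2]])
})

#' Translate sense-codon indices to amino-acid indices
#'
#' @param codon_idx integer vector/matrix of sense-codon indices (1..61).
#' @return object of the same shape with amino-acid indices (1..20 over
#'   alphabetical single-letter order).
#' @keywords internal
codon_to_aa_index <- function(codon_idx) {
  out <- CODON_AA[codon_idx]
  if (is.matrix(codon_idx)) {
    out <- matrix(out, nrow(codon_idx), dimnames = dimnames(codon_idx))
  }
  out
}
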