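#' The standard genetic code over a fixed 61-codon state space
#'
#' Returns the standard (NCBI table 1) genetic code together with the ordered
#' list of 61 sense codons that defines the state space of every codon model
#' in this package. Codons are ordered lexicographically with the nucleotide
#' order A < C < G < T; this ordering is used identically by the rate matrix,
#' the likelihood engine and the simulator, so state indices are portable
#' across all of them.
#'
#' @return An object of class `genetic_code`: a list with
#'   \describe{
#'     \item{table_id}{integer, always 1 (standard code).}
#'     \item{codons}{all 64 codons in lexicographic ACGT order.}
#'     \item{aa}{named character vector mapping each of the 64 codons to its
#'       one-letter amino acid, `"*"` for stops.}
#'     \item{sense_codons}{the 61 non-stop codons, in lexicographic order;
#'       position in this vector is the model state index.}
#'     \item{stop_codons}{the 3 stop codons (TAA, TAG, TGA).}
#'     \item{codon_index}{named integer vector: codon -> state index (1..61),
#'       `NA` for stops.}
#'   }
#' @examples
#' gc <- genetic_code()
#' gc$aa[["ATG"]]        # "M"
#' length(gc$sense_codons)  # 61
#' @export
genetic_code <- function() {
  if (!is.null(.omegascan_cache$code)) return(.omegascan_cache$code)
  nt <- c("A", "C", "G", "T")
  codons <- as.vector(t(outer(
    as.vector(t(outer(nt, nt, paste0))), nt, paste0)))
  codons <- sort(codons)  # lexicographic ACGT (C locale: A<C<G<T)
  ## standard code, one letter per codon in TCAG-block notation is error
  ## prone; spell the map out by amino acid family instead.
  aa_of <- c(
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
  aa <- aa_of[codons]
  names(aa) <- codons
  sense <- codons[aa != "*"]
  idx <- rep(NA_integer_, 64L)
  names(idx) <- codons
  idx[sense] <- seq_along(sense)
  code <- structure(list(
    table_id = 1L,
    codons = codons,
    aa = aa,
    sense_codons = sense,
    stop_codons = codons[aa == "*"],
    codon_index = idx
  ), class = "genetic_code")
  .omegascan_cache$code <- code
  code
}

.omegascan_cache <- new.env(parent = emptyenv())

#' Translate codon strings to amino acids
#'
#' @param codons character vector of triplets over `{A,C,G,T,N,-}`.
#' @param code a [genetic_code()].
#' @return one-letter amino acids; `"-"` for the all-gap codon `---`,
#'   `"X"` for any other ambiguous/partially gapped codon, `"*"` for stops.
#' @export
translate_codons <- function(codons, code = genetic_code()) {
  out <- unname(code$aa[codons])
  out[codons == "---"] <- "-"
  out[is.na(out)] <- "X"
  out
}

## split a nucleotide string into consecutive triplets
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
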