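#' The standard genetic code
#'
#' Returns the standard (NCBI translation table 1) genetic code as a named
#' character vector mapping all 64 DNA codons to one-letter amino-acid codes,
#' with `"*"` for the three stop codons (TAA, TAG, TGA).
#'
#' @return Named character vector of length 64.
#' @examples
#' genetic_code()[["ATG"]]  # "M"
#' sum(genetic_code() == "*")  # 3 stops
#' @export
genetic_code <- function() {
  code <- c(
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
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  code
}

#' Translate a single DNA codon
#'
#' @param codon Length-3 string over A/C/G/T (case-insensitive).
#' @param code Genetic code, as returned by [genetic_code()].
#' @return One-letter amino acid, or `"*"` for a stop codon.
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  if (!is.character(codon) || length(codon) != 1L || is.na(codon) ||
      !grepl("^[ACGT]{3}$", codon)) {
    stop("not a legal DNA codon: ", deparse(codon))
  }
  unname(code[[codon]])
}
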