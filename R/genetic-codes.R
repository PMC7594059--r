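#' Genetic code tables
#'
#' Returns the codon-to-amino-acid map for a supported NCBI translation
#' table: 1 (standard) or 4 (protozoan/mold mitochondrial, in which TGA
#' encodes tryptophan instead of stop).
#'
#' @param code Genetic code identifier: `1`/`"standard"` or
#'   `4`/`"protozoan_mitochondrial"`.
#' @return Named character vector mapping the 64 codons to single-letter
#'   amino acids, with `"*"` for stop.
#' @export
genetic_code_table <- function(code = 1) {
  id <- normalize_code_id(code)
  Biostrings::getGeneticCode(as.character(id))
}

normalize_code_id <- function(code) {
  if (is.character(code)) {
    code <- switch(code,
      standard = 1L, "1" = 1L,
      protozoan_mitochondrial = 4L, mitochondrial = 4L, "4" = 4L,
      stop("unknown genetic code: ", code)
    )
  }
  code <- as.integer(code)
  if (!code %in% c(1L, 4L)) stop("unknown genetic code: ", code)
  code
}

#' Translate a nucleotide sequence
#'
#' Codon-wise translation starting at position 1 of `seq`. Any codon
#' containing a character other than A/C/G/T (e.g. N) translates to `X`
#' and never terminates a stop-free region. A trailing incomplete codon is
#' dropped.
#'
#' @param seq Nucleotide string (A/C/G/T/N; case-insensitive).
#' @param code Genetic code id (1 or 4), see [genetic_code_table()].
#' @return Amino-acid string, with `*` marking stop codons.
#' @export
translate_dna <- function(seq, code = 1) {
  tab <- genetic_code_table(code)
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param seq Nucleotide string.
#' @return Reverse complement (N maps to N).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# Amino-acid alphabet in the fixed order used throughout (HMMER order).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background amino-acid frequencies (Robinson & Robinson-style composition,
# normalised over the 20-letter alphabet above).
amino_background <- function() {
  bg <- c(A = 0.0787, C = 0.0151, D = 0.0535, E = 0.0668, F = 0.0397,
          G = 0.0695, H = 0.0229, I = 0.0590, K = 0.0581, L = 0.0963,
          M = 0.0238, N = 0.0429, P = 0.0484, Q = 0.0396, R = 0.0540,
          S = 0.0683, T = 0.0541, V = 0.0673, W = 0.0114, Y = 0.0306)
  bg / sum(bg)
}

# Encode an amino string as 1-based indices into AA_ALPHABET; unknown
# letters (X, B, Z, ...) come back NA and are treated as background by
# scoring code.
aa_encode <- function(aa_seq) {
  match(strsplit(toupper(aa_seq), "")[[1]], AA_ALPHABET)
}
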