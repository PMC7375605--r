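# Internal sequence utilities shared across the package.

# IUPAC ambiguity codes (excluding N, which is kept as explicit uncertainty).
IUPAC_AMBIGUITY <- list(
  R = c("A", "G"),
  Y = c("C", "T"),
  S = c("C", "G"),
  W = c("A", "T"),
  K = c("G", "T"),
  M = c("A", "C"),
  B = c("C", "G", "T"),
  D = c("A", "G", "T"),
  H = c("A", "C", "T"),
  V = c("A", "C", "G")
)

GAP_CHARS <- c("-", ".")
CONCRETE_BASES <- c("A", "C", "G", "T")
SEQ_ALPHABET <- c(CONCRETE_BASES, "N", names(IUPAC_AMBIGUITY), GAP_CHARS)

#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Normalize a sequence for identity comparison: case-insensitive,
# '.' and '-' are the same gap character.  N stays N (matches only N).
#' @noRd
normalize_seq <- function(x) chartr(".", "-", toupper(x))

#' @noRd
check_seq_alphabet <- function(x, where = "sequence") {
  ch <- unique(seq_chars(toupper(x)))
  bad <- setdiff(ch, SEQ_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid character(s) %s in %s",
                 paste(sQuote(bad), collapse = ", "), where), call. = FALSE)
  }
  invisible(TRUE)
}

# Translate one codon; returns 'X' for anything not a clean A/C/G/T triplet.
#' @noRd
aa_of_codon <- function(codon) {
  if (nchar(codon) != 3L) return("X")
  aa <- unname(Biostrings::GENETIC_CODE[toupper(codon)])
  if (is.na(aa)) "X" else aa
}

# Translate a gap-stripped nucleotide string codon by codon; trailing
# partial codons and codons with non-ACGT characters give 'X'.
#' @noRd
translate_inframe <- function(nt) {
  nt <- toupper(nt)
  n_codon <- ceiling(nchar(nt) / 3)
  if (n_codon == 0L) return(character(0))
  vapply(seq_len(n_codon), function(i) {
    aa_of_codon(substr(nt, 3L * i - 2L, 3L * i))
  }, character(1))
}

#' @noRd
strip_gaps <- function(x) gsub("[-.]", "", x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
fatal <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
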