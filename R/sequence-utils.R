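#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' The package works internally in RNA space: sequences are uppercased and
#' `T` is rewritten to `U`. Ambiguity codes other than `N` are rejected
#' because the folding model is defined over `{A, C, G, U}` only.
#'
#' @param x Character vector of nucleotide strings.
#' @param allow_n Allow `N` characters (forbidden inside hairpin candidates).
#' @param allow_gaps Keep `-` gap characters (alignment input).
#' @return Character vector in the canonical RNA alphabet.
#' @export
as_rna <- function(x, allow_n = TRUE, allow_gaps = FALSE) {
  x <- chartr("t", "u", chartr("T", "U", toupper(x)))
  ok <- c(RNA_BASES, if (allow_n) "N", if (allow_gaps) "-")
  bad <- setdiff(unique(unlist(strsplit(x, "", fixed = TRUE))), ok)
  if (length(bad) > 0) {
    stop("invalid characters in sequence: ", paste(bad, collapse = ", "),
         " (only A/C/G/U", if (allow_n) "/N", if (allow_gaps) "/-",
         " are accepted)")
  }
  x
}

# Convert back to DNA for writers.
as_dna <- function(x) chartr("U", "T", toupper(x))

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of RNA sequences (gaps and `N` pass through).
#' @return Reverse complement, 5' to 3'.
#' @export
rc_rna <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGUN", "UGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rna_complement <- function(x) chartr("ACGUN", "UGCAN", x)

# Uniform random RNA string with configurable GC content.
random_rna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# TRUE where the two RNA bases can pair (Watson-Crick or GU wobble).
can_pair <- function(a, b) {
  paste0(a, b) %in% PAIR_NAMES
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
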