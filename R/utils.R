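# Small shared helpers: alphabet handling, reverse complement, validation.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the DNA alphabet (A/C/G/T, with N
#' passed through).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Convert between DNA and RNA alphabets
#'
#' Tags are stored in the DNA alphabet throughout the pipeline; the folding
#' and duplex modules work in RNA. These helpers translate T<->U.
#'
#' @param x Character vector of sequences.
#' @return Character vector in the other alphabet.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# Assert that sequences use the given alphabet; report offending characters.
check_alphabet <- function(x, alphabet, what = "sequence") {
  bad <- regmatches(x, gregexpr(sprintf("[^%s]", paste(alphabet, collapse = "")), x))
  offending <- unique(unlist(bad))
  if (length(offending) > 0) {
    abort(sprintf("invalid characters in %s: %s", what,
                  paste(offending, collapse = ", ")))
  }
  invisible(x)
}

# Draw a random DNA sequence of length n (uses the session RNG).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Vectorised substring count of a fixed base.
base_fraction <- function(x, base) {
  n <- nchar(x)
  hits <- nchar(x) - nchar(gsub(base, "", x, fixed = TRUE))
  ifelse(n == 0, 0, hits / n)
}

# logsumexp for numerically stable tail summation.
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}
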