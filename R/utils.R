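# Small sequence helpers shared across modules. All sequences are plain
# uppercase character scalars over {A,C,G,T,N}; Biostrings does the heavy
# lifting where an indexed container exists.

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of DNA sequences (A/C/G/T/N, any case).
#' @return Character vector of uppercase reverse complements.
#' @examples
#' revcomp("AAAACCCC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

# Complement base lookup used by the alignment-style screens (vector form).
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Split a sequence into a character vector of single bases.
.bases <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Longest homopolymer run length.
longest_homopolymer <- function(seq) {
  r <- rle(.bases(seq))
  max(r$lengths)
}

# TRUE when the sequence contains only unambiguous bases.
is_unambiguous <- function(seq) {
  !grepl("[^ACGT]", seq)
}

# Uppercase and map IUPAC ambiguity codes other than N to N (with warning).
normalize_residues <- function(seq, warn = TRUE) {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    if (warn) {
      rlang::warn("ambiguity codes other than N found; mapped to N")
    }
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  seq
}
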