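# Locus-windowed in-silico PCR check on the linear genome. A
# junction-spanning pair is divergent at its own locus by construction, so
# any convergent placement producing a short linear amplicon indicates a
# repeat-mediated secondary site within the window.

#' Check a primer pair for linear-genome amplification near its locus
#'
#' Maps both primer oligos back to the genomic window
#' `record +/- max_linear_product` by exact matching on both strands, then
#' looks for any convergent placement (one oligo on the plus strand, the
#' other on the minus strand downstream of it) whose implied product is at
#' most `max_linear_product` nt. The pair passes iff no such placement
#' exists. A primer with zero exact matches in the window passes with a
#' note.
#'
#' @param pair One-row pair tibble from [pair_and_rank()].
#' @param record The circRNA record the pair was designed on (canonical
#'   columns).
#' @param genome A `genome_source`.
#' @param max_linear_product Largest linear product considered amplifiable
#'   (default 5000 nt).
#' @return A list with `pass` (logical) and `reason` (string).
#' @export
linear_specificity_check <- function(pair, record, genome,
                                     max_linear_product = 5000L) {
  chrom <- record$chrom
  if (!chrom %in% names(genome$sequences)) {
    rlang::abort(sprintf("UnknownSequence: %s", chrom))
  }
  clen <- seq_lengths(genome)[[chrom]]
  w_start <- max(0L, record$start - max_linear_product)
  w_end <- min(clen, record$end + max_linear_product)
  window <- Biostrings::DNAString(subsequence(genome, chrom, w_start, w_end, "+"))

  hits <- function(oligo) {
    # plus-strand placements of the oligo, as [start, end) in window coords
    m <- Biostrings::matchPattern(Biostrings::DNAString(oligo), window,
                                  fixed = TRUE)
    cbind(start = BiocGenerics::start(m) - 1L, end = BiocGenerics::end(m))
  }
  oligos <- c(fwd = pair$fwd_seq[[1]], rev = pair$rev_seq[[1]])
  plus <- lapply(oligos, hits)
  minus <- lapply(oligos, function(o) hits(revcomp(o)))

  if (all(vapply(plus, nrow, 1L) + vapply(minus, nrow, 1L) == 0L)) {
    return(list(pass = TRUE,
                reason = "note: no exact primer matches in linear window"))
  }
  # convergent: sense placement of one oligo upstream of an antisense
  # placement of the other, product = antisense end - sense start
  worst <- Inf
  for (combo in list(c("fwd", "rev"), c("rev", "fwd"))) {
    s <- plus[[combo[1]]]
    a <- minus[[combo[2]]]
    if (!nrow(s) || !nrow(a)) next
    for (i in seq_len(nrow(s))) {
      prod <- a[, "end"] - s[i, "start"]
      prod <- prod[prod >= nchar(oligos[[combo[1]]]) + nchar(oligos[[combo[2]]])]
      if (length(prod)) worst <- min(worst, min(prod))
    }
  }
  if (is.finite(worst) && worst <= max_linear_product) {
    return(list(pass = FALSE,
                reason = sprintf("convergent linear placement with %d nt product",
                                 as.integer(worst))))
  }
  list(pass = TRUE, reason = "divergent on linear genome")
}
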