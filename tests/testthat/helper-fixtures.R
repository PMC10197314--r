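# Shared in-code fixtures: everything is generated at test time, nothing is
# read from disk except files the tests themselves write to tempdirs.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

toy_genome <- function(seq = "AAAAAAAAAACCCCCGGGGGTTTTTTTTTT", name = "chr1") {
  f <- write_tmp(c(paste0(">", name), seq), ".fa")
  open_genome(f)
}

# one canonical record as a one-row tibble
rec1 <- function(chrom = "chr1", start = 10L, end = 20L, strand = "+",
                 circ_id = "circA") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, circ_id = circ_id)
}
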