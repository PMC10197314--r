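# Junction template construction: clamping, strand handling, FASTA output.

test_that("templates concatenate the 3' flank to the 5' flank", {
  g <- toy_genome() # AAAAAAAAAACCCCCGGGGGTTTTTTTTTT
  tpl <- build_template(rec1(start = 10, end = 20), g,
                        shift_left = 3, shift_right = 3)
  expect_identical(tpl$sequence, "GGGCCC")
  expect_identical(tpl$junction_index, 3L)
  expect_identical(tpl$left_used + tpl$right_used, nchar(tpl$sequence))
})

test_that("flanks clamp at one full circle for short circles", {
  g <- toy_genome()
  tpl <- build_template(rec1(start = 12, end = 16), g) # span 4, defaults 150
  expect_identical(tpl$left_used, 4L)
  expect_identical(tpl$right_used, 4L)
  expect_identical(nchar(tpl$sequence), 8L)
  expect_identical(tpl$junction_index, 4L)
})

test_that("templates equal a rotation of the doubled circle sequence", {
  withr::local_seed(23)
  gseq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  g <- toy_genome(gseq, "c")
  for (k in 1:40) {
    span <- sample(2:400, 1)
    start <- sample(0:(2000 - span), 1)
    strand <- sample(c("+", "-"), 1)
    sl <- sample(1:200, 1); sr <- sample(1:200, 1)
    tpl <- build_template(rec1("c", start, start + span, strand), g, sl, sr)
    expect_identical(
      tpl$sequence,
      oracle_template_from_doubled(gseq, start, start + span, strand,
                                   tpl$left_used, tpl$right_used))
    expect_lte(nchar(tpl$sequence), 2L * span)
  }
})

test_that("a mirrored minus-strand record yields the identical template", {
  withr::local_seed(31)
  gseq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  g <- toy_genome(gseq, "c")
  mirrored <- revcomp(gseq)
  gm <- toy_genome(mirrored, "c")
  for (k in 1:20) {
    span <- sample(10:300, 1)
    start <- sample(0:(1000 - span), 1)
    tpl <- build_template(rec1("c", start, start + span, "+"), g, 50, 50)
    tplm <- build_template(
      rec1("c", 1000 - (start + span), 1000 - start, "-"), gm, 50, 50)
    expect_identical(tplm$sequence, tpl$sequence)
    expect_identical(tplm$junction_index, tpl$junction_index)
  }
})

test_that("records off the genome or all-N templates are dropped with reasons", {
  g <- toy_genome("ACGTNNNNNNNNNNNNACGT", "chr1")
  recs <- dplyr::bind_rows(
    rec1("chrZ", 0, 10, circ_id = "missing_contig"),
    rec1("chr1", 10, 40, circ_id = "past_end"),
    rec1("chr1", 6, 14, circ_id = "all_n"),
    rec1("chr1", 0, 20, circ_id = "fine"))
  expect_warning(tpl <- build_templates(recs, g, 4, 4), "dropped")
  expect_identical(tpl$circ_id, "fine")
  fails <- attr(tpl, "failures")
  expect_setequal(fails$circ_id, c("missing_contig", "past_end", "all_n"))
})

test_that("template FASTA headers carry the junction and stay unique", {
  g <- toy_genome()
  recs <- dplyr::bind_rows(rec1(start = 5, end = 20),
                           rec1(start = 10, end = 25)) # same circ_id
  tpl <- build_templates(recs, g, 4, 4)
  f <- tempfile(fileext = ".fa")
  templates_to_fasta(tpl, f)
  reread <- Biostrings::readDNAStringSet(f)
  expect_identical(names(reread),
                   c("circA|junction=4|chr1:5-20(+)",
                     "circA_2|junction=4|chr1:10-25(+)"))
  expect_identical(unname(as.character(reread)), tpl$sequence)
})
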