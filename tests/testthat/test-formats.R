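# Dialect detection and canonical parsing.

test_that("detect_format recognizes dialects from content, not names", {
  expect_identical(
    detect_format("circRNA_ID\tchr\tcircRNA_start\tcircRNA_end"), "ciri2")
  expect_identical(detect_format("chr1\t100\t500\tcircA\t0\t+"), "bed")
  expect_identical(
    detect_format(c("# chrom\tstart\tend\tname\tn_reads\tstrand",
                    "chr1\t100\t500\tc\t4\t+")), "find_circ")
  expect_identical(
    detect_format("Chr\tStart\tEnd\tGene\tJunctionType\tStrand\tA\tB"), "dcc")
  expect_identical(
    detect_format("chr1~chr1\t500\t101\tFUSION_1\t7\t++\t..."), "mapsplice")
  expect_identical(
    detect_format("chr1|geneA:101|geneB:500|reg|+\t0.9\t12\t0.01"), "knife")
  ce2 <- paste(c("chr1", 100, 500, "c", 0, "+", 100, 500, "0,0,0", 1,
                 "400,", "0,", 3, "circRNA", "g", "iso", 1, "NA"),
               collapse = "\t")
  expect_identical(detect_format(ce2), "circexplorer2")
  expect_error(detect_format("just,some,prose,in,a,csv"),
               "UnrecognizedFormat")
  expect_error(detect_format(character()), "UnrecognizedFormat")
})

test_that("coordinates are converted to 0-based half-open per dialect", {
  # same circle, every convention; span must be invariant (400 nt)
  bed <- write_tmp("chr1\t100\t500\tcircA\t0\t+", ".bed")
  ciri <- write_tmp(c(
    paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
          "#junction_reads", "SM_MS_NM", "#non_junction_reads",
          "junction_reads_ratio", "circRNA_type", "gene_id", "strand",
          "junction_reads_ID", sep = "\t"),
    "chr1:101|500\tchr1\t101\t500\t5\t5_5_0\t10\t0.5\texon\tg\t+\tids"))
  dcc <- write_tmp(c("Chr\tStart\tEnd\tGene\tJunctionType\tStrand\tR\tO",
                     "chr1\t101\t500\tcircA\t1\t+\tintron\tr"))
  knife <- write_tmp("chr1|gA:101|gB:500|reg|+\t0.98\t12\t0.01")
  maps <- write_tmp("chr1~chr1\t500\t101\tcircA\t7\t++\t...")
  for (f in list(bed, ciri, dcc, knife, maps)) {
    b <- parse_records(f)
    expect_identical(b$start, 100L)
    expect_identical(b$end, 500L)
    expect_identical(b$end - b$start, 400L)
    expect_identical(b$strand, "+")
  }
  expect_identical(parse_records(bed)$circ_id, "circA")
})

test_that("dedup keeps first occurrence and preserves order", {
  f <- write_tmp(c("chr1\t10\t400\ta\t0\t+",
                   "chr1\t5\t300\tb\t0\t+",
                   "chr1\t10\t400\tdup_of_a\t0\t+",
                   "chr1\t10\t400\ta_minus\t0\t-"))
  b <- suppressWarnings(parse_records(f))
  expect_identical(b$circ_id, c("a", "b", "a_minus"))
  expect_identical(batch_counts(b), c(n_input = 4L, n_kept = 3L))
})

test_that("submission cap truncates with a warning, errors when strict", {
  lines <- sprintf("chr1\t%d\t%d\tr%d\t0\t+", 1:150 * 10L, 1:150 * 10L + 400L,
                   1:150)
  f <- write_tmp(lines)
  expect_warning(b <- parse_records(f), "truncated")
  expect_identical(nrow(b), 100L)
  expect_identical(batch_counts(b)[["n_input"]], 150L)
  expect_match(batch_warnings(b), "truncated", all = FALSE)
  expect_error(parse_records(f, strict = TRUE), "cap")
})

test_that("dot strands become '+' with a warning; missing ids are generated", {
  f <- write_tmp("chr1\t100\t500")
  expect_warning(b <- parse_records(f), "strand")
  expect_identical(b$strand, "+")
  expect_identical(b$circ_id, "chr1:100-500:+")
})

test_that("malformed rows and empty input are reported as specified", {
  f <- write_tmp(c("chr1\t100\t500\tok\t0\t+", "chr1\tnot_a_number\t500"))
  expect_error(parse_records(f), "MalformedRow\\(2\\)")
  bad_iv <- write_tmp("chr1\t500\t100\tinverted\t0\t+")
  expect_error(parse_records(bad_iv), "MalformedRow")
  empty <- write_tmp(character())
  expect_warning(b <- parse_records(empty), "EmptyInput")
  expect_identical(nrow(b), 0L)
})

test_that("write_bed round-trips records exactly, including CRLF tolerance", {
  lines <- sprintf("chr%d\t%d\t%d\tid%d\t0\t%s", 1:5, 1:5 * 7L,
                   1:5 * 7L + 200L, 1:5, c("+", "-", "+", "-", "+"))
  f <- write_tmp(lines)
  b <- parse_records(f)
  out <- tempfile(fileext = ".bed")
  write_bed(b, out)
  expect_identical(length(readLines(out)), 5L)
  b2 <- parse_records(out)
  cols <- c("chrom", "start", "end", "strand", "circ_id")
  expect_identical(b2[cols], b[cols])
  # CRLF input parses identically
  crlf <- tempfile()
  writeBin(charToRaw(paste0(paste(lines, collapse = "\r\n"), "\r\n")), crlf)
  expect_identical(parse_records(crlf)[cols], b[cols])
  # empty batch writes an empty file
  e <- suppressWarnings(parse_records(write_tmp(character())))
  out2 <- tempfile(); write_bed(e, out2)
  expect_identical(length(readLines(out2)), 0L)
})
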