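# Candidate enumeration vs an exhaustive filter oracle.

# literal re-filter of every window, using only exported scalar functions
oracle_enumerate <- function(template_seq, cfg) {
  n <- nchar(template_seq)
  out <- list()
  for (L in cfg$min_len:cfg$max_len) {
    if (n < L) next
    for (s in 0:(n - L)) {
      w <- substr(template_seq, s + 1, s + L)
      if (grepl("[^ACGT]", w)) next
      for (orient in c("forward", "reverse")) {
        oligo <- if (orient == "forward") w else revcomp(w)
        if (max(rle(strsplit(oligo, "")[[1]])$lengths) > cfg$max_homopolymer) next
        gc <- gc_content(oligo)
        if (gc < cfg$gc_min || gc > cfg$gc_max) next
        tm <- melting_temperature(oligo, cfg$primer_conc, cfg$monovalent_salt)
        if (tm < cfg$tm_min || tm > cfg$tm_max) next
        sc <- structure_screens(oligo)
        if (sc$self_dimer_score > cfg$max_dimer ||
            sc$dimer_3p_score > cfg$max_dimer_3p ||
            sc$hairpin_score > cfg$max_hairpin_stem) next
        out[[length(out) + 1]] <- data.frame(orientation = orient,
                                             sequence = oligo,
                                             template_start = s, length = L)
      }
    }
  }
  do.call(rbind, out)
}

test_that("enumeration equals the exhaustive filter oracle on a seeded template", {
  withr::local_seed(13)
  tpl_seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                   collapse = "")
  tpl <- tibble::tibble(sequence = tpl_seq, junction_index = 200L)
  cfg <- design_config()
  got <- enumerate_candidates(tpl, cfg)
  want <- oracle_enumerate(tpl_seq, cfg)
  key <- function(d) sort(paste(d$orientation, d$template_start, d$length,
                                d$sequence))
  expect_identical(key(got), key(want))
  expect_identical(nrow(got), nrow(want))
  # every survivor respects the candidate invariants
  expect_true(all(got$length >= cfg$min_len & got$length <= cfg$max_len))
  expect_true(all(got$tm >= cfg$tm_min & got$tm <= cfg$tm_max))
  expect_true(all(got$gc >= cfg$gc_min & got$gc <= cfg$gc_max))
  expect_false(any(grepl("[^ACGT]", got$sequence)))
})

test_that("penalty is the weighted length/Tm/GC distance, zero length-term at opt_len", {
  withr::local_seed(14)
  tpl <- tibble::tibble(
    sequence = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                     collapse = ""),
    junction_index = 150L)
  cfg <- design_config()
  got <- enumerate_candidates(tpl, cfg)
  expect_gt(nrow(got), 0)
  manual <- cfg$w_len * abs(got$length - cfg$opt_len) +
    cfg$w_tm * abs(got$tm - cfg$tm_opt) + cfg$w_gc * abs(got$gc - 0.5)
  expect_equal(got$penalty, manual, tolerance = 1e-12)
  at_opt <- got[got$length == cfg$opt_len, ]
  if (nrow(at_opt)) {
    expect_equal(at_opt$penalty,
                 cfg$w_tm * abs(at_opt$tm - cfg$tm_opt) +
                   cfg$w_gc * abs(at_opt$gc - 0.5),
                 tolerance = 1e-12)
  }
})

test_that("degenerate templates yield no candidates", {
  cfg <- design_config()
  allN <- tibble::tibble(sequence = strrep("N", 300), junction_index = 150L)
  expect_identical(nrow(enumerate_candidates(allN, cfg)), 0L)
  short <- tibble::tibble(sequence = "ACGTACGTAC", junction_index = 5L)
  expect_identical(nrow(enumerate_candidates(short, cfg)), 0L)
})
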