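# Deterministic synthetic fixtures: an i.i.d. random genome at a target GC
# with circRNAs planted at known coordinates, serialized in every supported
# predictor dialect plus a canonical truth table. Base composition is i.i.d.
# (no higher-order genome realism): that is all the primer engine's screens
# and pairing logic need, and it keeps every stage reproducible from one
# integer seed.

#' Specify a synthetic circRNA fixture
#'
#' @param seed Integer seed; the same spec is byte-reproducible.
#' @param n_contigs,contig_len Number and length (nt) of random contigs.
#' @param gc Target GC fraction of the genome (default 0.5).
#' @param n_circles Number of planted circRNAs (default 10, the size of a
#'   typical validation batch).
#' @param span_range Circle span bounds in nt (default 200--2000, comfortably
#'   above the 150 nt flank windows so default templates are full length).
#' @param strands Allowed strands to sample from (default `c("+", "-")`).
#' @param planted_repeats Optional integer vector of circle indices that get
#'   a convergent copy of their acceptor flank planted ~1 kb downstream of
#'   the circle, creating a linear-specificity failure.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 1L, contig_len = 10000L,
                         gc = 0.5, n_circles = 10L,
                         span_range = c(200L, 2000L),
                         strands = c("+", "-"),
                         planted_repeats = integer()) {
  stopifnot(gc > 0, gc < 1, n_circles >= 1, span_range[1] >= 1,
            span_range[1] <= span_range[2],
            all(strands %in% c("+", "-")),
            all(planted_repeats %in% seq_len(n_circles)))
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_len = as.integer(contig_len), gc = as.numeric(gc),
                 n_circles = as.integer(n_circles),
                 span_range = as.integer(span_range), strands = strands,
                 planted_repeats = as.integer(planted_repeats)),
            class = "fixture_spec")
}

# run code under a local RNG state so fixtures never disturb the caller's seed
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome with planted circRNAs in all dialects
#'
#' Writes `genome.fa`, one call file per supported dialect (each in that
#' dialect's own coordinate convention) and `truth.tsv` (the canonical
#' records) under `out_dir`. The same planted circle therefore parses to an
#' identical canonical record from every dialect file.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created).
#' @return List with `genome` (FASTA path), `calls` (named list of dialect
#'   file paths), `truth_path`, and `truth` (canonical tibble).
#' @export
make_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .with_seed(spec$seed, {
    probs <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
    contigs <- lapply(seq_len(spec$n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), spec$contig_len, replace = TRUE,
                   prob = probs), collapse = "")
    })
    names(contigs) <- sprintf("ctg%02d", seq_len(spec$n_contigs))

    max_span <- min(spec$span_range[2], spec$contig_len - 2L)
    min_span <- min(spec$span_range[1], max_span)
    truth <- dplyr::bind_rows(lapply(seq_len(spec$n_circles), function(i) {
      chrom <- sample(names(contigs), 1)
      span <- sample(min_span:max_span, 1)
      start <- sample(0:(spec$contig_len - span - 1L), 1)
      tibble::tibble(chrom = chrom, start = as.integer(start),
                     end = as.integer(start + span),
                     strand = sample(spec$strands, 1),
                     circ_id = sprintf("circ_%03d", i))
    }))
    truth <- dplyr::distinct(truth, .data$chrom, .data$start, .data$end,
                             .data$strand, .keep_all = TRUE)

    # convergent repeats: copy the acceptor flank (first 150 nt of the
    # circle, which carries the reverse primer's antisense site) to ~1 kb
    # downstream of the circle on the plus strand
    for (i in spec$planted_repeats) {
      if (i > nrow(truth)) next
      rec <- truth[i, ]
      flank_len <- min(150L, rec$end - rec$start)
      ins <- rec$end + 1000L
      ctg <- contigs[[rec$chrom]]
      if (ins + flank_len > nchar(ctg)) next
      piece <- substr(ctg, rec$start + 1L, rec$start + flank_len)
      substr(ctg, ins + 1L, ins + flank_len) <- piece
      contigs[[rec$chrom]] <- ctg
    }

    genome_path <- file.path(out_dir, "genome.fa")
    seqs <- Biostrings::DNAStringSet(unlist(contigs))
    Biostrings::writeXStringSet(seqs, genome_path, width = 70L)

    calls <- write_dialect_files(truth, out_dir)
    truth_path <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth, truth_path)
    list(genome = genome_path, calls = calls, truth_path = truth_path,
         truth = truth)
  })
}

# Serialize the truth set in every dialect's native convention.
write_dialect_files <- function(truth, out_dir) {
  s1 <- truth$start + 1L # 1-based first base
  e1 <- truth$end        # 1-based last base
  paths <- list()
  emit <- function(name, file, lines) {
    p <- file.path(out_dir, file)
    readr::write_lines(lines, p)
    paths[[name]] <<- p
  }
  emit("bed", "calls.bed",
       sprintf("%s\t%d\t%d\t%s\t0\t%s", truth$chrom, truth$start, truth$end,
               truth$circ_id, truth$strand))
  emit("ciri2", "calls.ciri",
       c(paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
               "#junction_reads", "SM_MS_NM", "#non_junction_reads",
               "junction_reads_ratio", "circRNA_type", "gene_id", "strand",
               "junction_reads_ID", sep = "\t"),
         sprintf("%s:%d|%d\t%s\t%d\t%d\t5\t5_5_0\t10\t0.5\texon\tgene1\t%s\tids",
                 truth$chrom, s1, e1, truth$chrom, s1, e1, truth$strand)))
  emit("find_circ", "calls.candidates.bed",
       c(paste("# chrom", "start", "end", "name", "n_reads", "strand",
               "n_uniq", "uniq_bridges", "best_qual_left", "best_qual_right",
               sep = "\t"),
         sprintf("%s\t%d\t%d\t%s\t4\t%s\t2\t2\t40\t40", truth$chrom,
                 truth$start, truth$end, truth$circ_id, truth$strand)))
  emit("circexplorer2", "circularRNA_known.txt",
       sprintf(paste0("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0,0,0\t1\t%d,\t0,",
                      "\t3\tcircRNA\tgene1\tiso1\t1\tNA"),
               truth$chrom, truth$start, truth$end, truth$circ_id,
               truth$strand, truth$start, truth$end,
               truth$end - truth$start))
  emit("dcc", "CircCoordinates",
       c(paste("Chr", "Start", "End", "Gene", "JunctionType", "Strand",
               "Start-End Region", "OverallRegions", sep = "\t"),
         sprintf("%s\t%d\t%d\t%s\t1\t%s\tintron-intron\tregion",
                 truth$chrom, s1, e1, truth$circ_id, truth$strand)))
  emit("circrna_finder", "filteredJunctions.bed",
       sprintf("%s\t%d\t%d\t%s\t6\t%s", truth$chrom, truth$start, truth$end,
               truth$circ_id, truth$strand))
  emit("knife", "knife_report.txt",
       sprintf("%s|gene1:%d|gene2:%d|reg|%s\t0.98\t12\t0.01",
               truth$chrom, s1, e1, truth$strand))
  emit("mapsplice", "circular_RNAs.txt",
       sprintf("%s~%s\t%d\t%d\tFUSION_%d\t7\t%s%s\t...",
               truth$chrom, truth$chrom, e1, s1, seq_len(nrow(truth)),
               truth$strand, truth$strand))
  paths
}
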