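# Junction templates: the linear sequence a circle presents around its
# back-splice junction. The donor-side flank (circle 3' end) is concatenated
# to the acceptor-side flank (circle 5' start), so a primer pair converging
# across the junction on this template is divergent on the linear genome.

#' Build the back-splice junction template for one circRNA
#'
#' Takes up to `shift_left` nt from the circle's 3' end and `shift_right` nt
#' from its 5' start and joins them; the junction sits at index `left_used`
#' (0-based, counting bases of the donor flank). Flanks are clamped at the
#' circle's own span: a circle shorter than the shift window contributes at
#' most one full copy of itself per flank, never wrapping a second turn
#' (wrapping further would duplicate the junction inside the template and
#' create artifactual primer sites). Minus-strand circles are built on the
#' transcribed strand.
#'
#' @param record One-row data frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `circ_id`.
#' @param genome A `genome_source`.
#' @param shift_left,shift_right Flank widths in nt (defaults 150).
#' @return A one-row tibble: `circ_id`, `sequence`, `junction_index`,
#'   `left_used`, `right_used`, plus the record's coordinates.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c", "AAAAAAAAAACCCCCGGGGGTTTTTTTTTT"), f)
#' g <- open_genome(f)
#' rec <- list(chrom = "c", start = 10L, end = 20L, strand = "+", circ_id = "x")
#' build_template(rec, g, shift_left = 3, shift_right = 3)
#' @export
build_template <- function(record, genome, shift_left = 150L, shift_right = 150L) {
  stopifnot(shift_left >= 1L, shift_right >= 1L)
  chrom <- record$chrom; start <- record$start; end <- record$end
  strand <- record$strand
  span <- end - start
  if (span < 1L) rlang::abort(sprintf("record %s has span < 1", record$circ_id))
  left_used <- min(as.integer(shift_left), span)
  right_used <- min(as.integer(shift_right), span)
  if (strand == "+") {
    donor <- subsequence(genome, chrom, end - left_used, end, "+")
    acceptor <- subsequence(genome, chrom, start, start + right_used, "+")
  } else {
    donor <- subsequence(genome, chrom, start, start + left_used, "-")
    acceptor <- subsequence(genome, chrom, end - right_used, end, "-")
  }
  tibble::tibble(
    circ_id = record$circ_id,
    sequence = paste0(donor, acceptor),
    junction_index = left_used,
    left_used = left_used,
    right_used = right_used,
    chrom = chrom, start = start, end = end, strand = strand)
}

#' Build junction templates for a batch of records
#'
#' Applies [build_template()] to every row; records on contigs absent from
#' the genome, records exceeding their contig, and records whose template
#' would be entirely N are dropped with a warning and reported in the
#' `failures` attribute (`circ_id`, `reason`).
#'
#' @param records Canonical record tibble (see [parse_records()]).
#' @param genome A `genome_source`.
#' @inheritParams build_template
#' @return Tibble of templates with attribute `failures`.
#' @export
build_templates <- function(records, genome, shift_left = 150L,
                            shift_right = 150L) {
  out <- vector("list", nrow(records))
  fail <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (!rec$chrom %in% names(genome$sequences)) {
      fail[[length(fail) + 1L]] <- tibble::tibble(
        circ_id = rec$circ_id,
        reason = sprintf("sequence '%s' absent from genome", rec$chrom))
      next
    }
    if (rec$end > seq_lengths(genome)[[rec$chrom]]) {
      fail[[length(fail) + 1L]] <- tibble::tibble(
        circ_id = rec$circ_id,
        reason = sprintf("record exceeds contig '%s'", rec$chrom))
      next
    }
    tpl <- build_template(rec, genome, shift_left, shift_right)
    if (!grepl("[ACGT]", tpl$sequence)) {
      fail[[length(fail) + 1L]] <- tibble::tibble(
        circ_id = rec$circ_id, reason = "template contains only N bases")
      next
    }
    out[[i]] <- tpl
  }
  failures <- if (length(fail)) dplyr::bind_rows(fail) else {
    tibble::tibble(circ_id = character(), reason = character())
  }
  if (nrow(failures)) {
    rlang::warn(sprintf("%d record(s) dropped at template stage: %s",
                        nrow(failures),
                        paste(failures$circ_id, collapse = ", ")))
  }
  res <- dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  if (!nrow(res)) {
    res <- tibble::tibble(circ_id = character(), sequence = character(),
                          junction_index = integer(), left_used = integer(),
                          right_used = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
  }
  attr(res, "failures") <- failures
  res
}

#' Write junction templates to FASTA
#'
#' Headers follow the grammar
#' `circ_id|junction=<j>|<chrom>:<start>-<end>(<strand>)`; duplicate
#' `circ_id`s get `_2`, `_3`, ... suffixes so headers stay unique.
#'
#' @param templates Template tibble from [build_templates()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
templates_to_fasta <- function(templates, path) {
  if (!nrow(templates)) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  ids <- templates$circ_id
  dup <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  ids <- ifelse(dup > 1L, paste0(ids, "_", dup), ids)
  headers <- sprintf("%s|junction=%d|%s:%d-%d(%s)",
                     ids, templates$junction_index, templates$chrom,
                     templates$start, templates$end, templates$strand)
  seqs <- Biostrings::DNAStringSet(templates$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
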