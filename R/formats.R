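# Canonical record table and the per-predictor dialect parsers.
#
# Internally every interval is 0-based half-open (BED convention): one
# conversion site per dialect, and span = end - start in every dialect.

CIRC_FORMATS <- c("bed", "ciri2", "find_circ", "circexplorer2", "dcc",
                  "circrna_finder", "knife", "mapsplice")

new_circ_batch <- function(records, n_input, warnings = character()) {
  records <- tibble::as_tibble(records)
  structure(records,
            class = c("circ_batch", class(records)),
            n_input = n_input,
            n_kept = nrow(records),
            warnings = warnings)
}

#' Warnings and input counts attached to a parsed batch
#'
#' @param batch A `circ_batch` tibble from [parse_records()].
#' @return `batch_warnings()`: character vector of warnings recorded during
#'   parsing; `batch_counts()`: named integer vector with `n_input` (rows
#'   seen) and `n_kept` (rows after dedup and the submission cap).
#' @export
batch_warnings <- function(batch) attr(batch, "warnings") %||% character()

#' @rdname batch_warnings
#' @export
batch_counts <- function(batch) {
  c(n_input = attr(batch, "n_input") %||% nrow(batch),
    n_kept = attr(batch, "n_kept") %||% nrow(batch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_text_lines <- function(path) {
  lines <- readr::read_lines(path)
  sub("\r$", "", lines)
}

.is_int_str <- function(x) grepl("^-?[0-9]+$", x)

#' Detect which predictor dialect a coordinate file is written in
#'
#' Detection inspects header tokens and column signatures of the first lines,
#' never the file name. Plain BED6-compatible tables (including
#' circRNA_finder junction files, which share BED's 0-based convention)
#' resolve to `"bed"`.
#'
#' @param first_lines Character vector of raw lines from the top of the file
#'   (a couple of lines suffice).
#' @return One of `"bed"`, `"ciri2"`, `"find_circ"`, `"circexplorer2"`,
#'   `"dcc"`, `"circrna_finder"`, `"knife"`, `"mapsplice"`.
#' @examples
#' detect_format("chr1\t100\t500\tcircA\t0\t+")
#' @export
detect_format <- function(first_lines) {
  lines <- sub("\r$", "", first_lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) rlang::abort("UnrecognizedFormat: no content lines")

  if (any(startsWith(lines, "circRNA_ID"))) return("ciri2")

  header <- lines[startsWith(lines, "#")]
  if (length(header) &&
      grepl("n_reads|n_uniq|best_qual", header[1])) {
    return("find_circ")
  }

  data <- lines[!startsWith(lines, "#")]
  if (!length(data)) rlang::abort("UnrecognizedFormat: only comment lines")
  f <- strsplit(data[1], "\t", fixed = TRUE)[[1]]

  # DCC CircCoordinates header
  if (length(f) >= 6 && tolower(f[1]) == "chr" && tolower(f[2]) == "start" &&
      tolower(f[3]) == "end") {
    return("dcc")
  }
  # mapsplice: fused chrom name and/or doubled strand symbol
  if (length(f) >= 6 &&
      (grepl("~", f[1], fixed = TRUE) || f[6] %in% c("++", "--", "+-", "-+"))) {
    return("mapsplice")
  }
  # KNIFE: junction id encodes the coordinates
  if (grepl("^[^|]+\\|[^|]+:[0-9]+\\|[^|]+:[0-9]+\\|", f[1])) {
    return("knife")
  }
  if (length(f) >= 3 && .is_int_str(f[2]) && .is_int_str(f[3])) {
    # CIRCexplorer2 BED12+: block size/offset comma lists in cols 11-12
    if (length(f) >= 14 &&
        grepl("^[0-9]+(,[0-9]+)*,?$", f[11]) &&
        grepl("^[0-9]+(,[0-9]+)*,?$", f[12])) {
      return("circexplorer2")
    }
    if (length(f) <= 3 || length(f) >= 4) {
      if (length(f) < 6 || f[6] %in% c("+", "-", ".")) return("bed")
    }
  }
  rlang::abort("UnrecognizedFormat: no known dialect matches these lines")
}

# --- per-dialect row parsers -------------------------------------------------
# Each returns a data frame chrom/start/end/strand/circ_id in canonical
# 0-based half-open coordinates, or aborts with the 1-based line number.

.malformed <- function(line_no, why) {
  rlang::abort(sprintf("MalformedRow(%d): %s", line_no, why))
}

.need <- function(ok, line_no, why) if (!ok) .malformed(line_no, why)

.parse_bed_like <- function(fields, line_no, base = 0L) {
  .need(length(fields) >= 3, line_no, "fewer than 3 columns")
  .need(.is_int_str(fields[2]) && .is_int_str(fields[3]), line_no,
        "non-integer coordinates")
  start <- as.integer(fields[2]) - base
  end <- as.integer(fields[3])
  strand <- if (length(fields) >= 6) fields[6] else "."
  name <- if (length(fields) >= 4 && nzchar(fields[4])) fields[4] else NA_character_
  list(chrom = fields[1], start = start, end = end, strand = strand,
       circ_id = name)
}

.parser_bed <- function(fields, line_no) .parse_bed_like(fields, line_no, 0L)
.parser_find_circ <- function(fields, line_no) .parse_bed_like(fields, line_no, 0L)
.parser_circrna_finder <- function(fields, line_no) .parse_bed_like(fields, line_no, 0L)

.parser_circexplorer2 <- function(fields, line_no) {
  .need(length(fields) >= 6, line_no, "CIRCexplorer2 rows need >= 6 columns")
  .parse_bed_like(fields, line_no, 0L)
}

.parser_ciri2 <- function(fields, line_no, cols) {
  .need(length(fields) >= max(cols), line_no, "short CIRI2 row")
  start1 <- fields[cols["circRNA_start"]]
  end1 <- fields[cols["circRNA_end"]]
  .need(.is_int_str(start1) && .is_int_str(end1), line_no,
        "non-integer CIRI2 coordinates")
  strand <- if (!is.na(cols["strand"]) && length(fields) >= cols["strand"]) {
    fields[cols["strand"]]
  } else "."
  list(chrom = fields[cols["chr"]],
       start = as.integer(start1) - 1L, end = as.integer(end1),
       strand = strand, circ_id = fields[cols["circRNA_ID"]])
}

.parser_dcc <- function(fields, line_no) {
  .need(length(fields) >= 6, line_no, "DCC rows need >= 6 columns")
  .need(.is_int_str(fields[2]) && .is_int_str(fields[3]), line_no,
        "non-integer DCC coordinates")
  list(chrom = fields[1], start = as.integer(fields[2]) - 1L,
       end = as.integer(fields[3]), strand = fields[6],
       circ_id = if (nzchar(fields[4])) fields[4] else NA_character_)
}

.parser_knife <- function(fields, line_no) {
  m <- stringr::str_match(
    fields[1],
    "^([^|]+)\\|[^|:]+:([0-9]+)\\|[^|:]+:([0-9]+)\\|[^|]+\\|([+-.])")
  .need(!is.na(m[1, 1]), line_no, "unparseable KNIFE junction id")
  p1 <- as.integer(m[1, 3]); p2 <- as.integer(m[1, 4])
  list(chrom = m[1, 2], start = min(p1, p2) - 1L, end = max(p1, p2),
       strand = m[1, 5], circ_id = fields[1])
}

.parser_mapsplice <- function(fields, line_no) {
  .need(length(fields) >= 6, line_no, "mapsplice rows need >= 6 columns")
  .need(.is_int_str(fields[2]) && .is_int_str(fields[3]), line_no,
        "non-integer mapsplice coordinates")
  chrom <- strsplit(fields[1], "~", fixed = TRUE)[[1]][1]
  p1 <- as.integer(fields[2]); p2 <- as.integer(fields[3])
  strand <- substr(fields[6], 1, 1)
  list(chrom = chrom, start = min(p1, p2) - 1L, end = max(p1, p2),
       strand = strand, circ_id = if (nzchar(fields[4])) fields[4] else NA_character_)
}

# --- main entry --------------------------------------------------------------

#' Parse circRNA predictor output into a canonical record table
#'
#' Reads back-splice junction calls from any supported dialect and returns a
#' canonical tibble in 0-based half-open coordinates: columns `chrom`,
#' `start`, `end`, `strand`, `circ_id`, `source_format`. Rows are
#' deduplicated on (chrom, start, end, strand) keeping the first occurrence,
#' and submissions are capped (default 100 records) with a warning --- or an
#' error under `strict = TRUE`. Strand `"."` is accepted and treated as `"+"`
#' with a warning. A missing `circ_id` is generated as
#' `"chrom:start-end:strand"`.
#'
#' @param path Path to the coordinate file.
#' @param format One of `"auto"` (default) or a dialect name; see
#'   [detect_format()].
#' @param cap Maximum records kept per submission (default 100).
#' @param strict Error instead of truncating when the cap is exceeded.
#' @return A `circ_batch` tibble; inspect [batch_warnings()] and
#'   [batch_counts()].
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t500\tcircA\t0\t+", f)
#' parse_records(f)
#' @export
parse_records <- function(path, format = "auto", cap = 100L, strict = FALSE) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- .read_text_lines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    rlang::warn("EmptyInput: no records in file")
    return(new_circ_batch(
      tibble::tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), circ_id = character(),
                     source_format = character()),
      n_input = 0L, warnings = "EmptyInput: no records in file"))
  }
  if (identical(format, "auto")) {
    format <- detect_format(utils::head(lines[keep], 5))
  }
  format <- match.arg(format, CIRC_FORMATS)

  warnings <- character()
  line_nos <- seq_along(lines)

  is_data <- keep & !startsWith(trimws(lines), "#")
  ciri_cols <- NULL
  if (format == "ciri2") {
    hdr_i <- which(startsWith(lines, "circRNA_ID"))
    if (!length(hdr_i)) rlang::abort("CIRI2 input lacks its circRNA_ID header")
    hdr <- strsplit(lines[hdr_i[1]], "\t", fixed = TRUE)[[1]]
    ciri_cols <- stats::setNames(match(c("circRNA_ID", "chr", "circRNA_start",
                                         "circRNA_end", "strand"), hdr),
                                 c("circRNA_ID", "chr", "circRNA_start",
                                   "circRNA_end", "strand"))
    if (anyNA(ciri_cols[c("circRNA_ID", "chr", "circRNA_start", "circRNA_end")])) {
      rlang::abort("CIRI2 header is missing required columns")
    }
    is_data[hdr_i] <- FALSE
  }
  if (format == "dcc") {
    first_data <- which(is_data)[1]
    f1 <- strsplit(lines[first_data], "\t", fixed = TRUE)[[1]]
    if (tolower(f1[1]) == "chr" && !.is_int_str(f1[2])) is_data[first_data] <- FALSE
  }

  idx <- which(is_data)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rows[[k]] <- switch(format,
      bed = .parser_bed(fields, i),
      find_circ = .parser_find_circ(fields, i),
      circrna_finder = .parser_circrna_finder(fields, i),
      circexplorer2 = .parser_circexplorer2(fields, i),
      ciri2 = .parser_ciri2(fields, i, ciri_cols),
      dcc = .parser_dcc(fields, i),
      knife = .parser_knife(fields, i),
      mapsplice = .parser_mapsplice(fields, i))
    r <- rows[[k]]
    .need(r$start >= 0L && r$start < r$end, i,
          sprintf("invalid interval [%d, %d)", r$start, r$end))
    .need(r$strand %in% c("+", "-", "."), i,
          sprintf("invalid strand '%s'", r$strand))
  }
  rec <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  n_input <- nrow(rec)
  if (n_input == 0L) {
    rlang::warn("EmptyInput: no records in file")
    warnings <- c(warnings, "EmptyInput: no records in file")
  }

  if (n_input > 0L && any(rec$strand == ".")) {
    msg <- sprintf("%d record(s) with strand '.'; treated as '+'",
                   sum(rec$strand == "."))
    rlang::warn(msg)
    warnings <- c(warnings, msg)
    rec$strand[rec$strand == "."] <- "+"
  }
  if (n_input > 0L) {
    rec$circ_id <- ifelse(
      is.na(rec$circ_id) | !nzchar(rec$circ_id),
      sprintf("%s:%d-%d:%s", rec$chrom, rec$start, rec$end, rec$strand),
      rec$circ_id)
    n0 <- nrow(rec)
    rec <- dplyr::distinct(rec, .data$chrom, .data$start, .data$end,
                           .data$strand, .keep_all = TRUE)
    if (nrow(rec) < n0) {
      msg <- sprintf("%d duplicate record(s) removed (first occurrence kept)",
                     n0 - nrow(rec))
      rlang::warn(msg)
      warnings <- c(warnings, msg)
    }
    if (nrow(rec) > cap) {
      if (strict) {
        rlang::abort(sprintf("submission has %d records; cap is %d (strict mode)",
                             nrow(rec), cap))
      }
      msg <- sprintf("submission truncated to the first %d of %d records",
                     cap, nrow(rec))
      rlang::warn(msg)
      warnings <- c(warnings, msg)
      rec <- rec[seq_len(cap), ]
    }
  }
  rec$source_format <- rep(format, nrow(rec))
  new_circ_batch(rec, n_input = n_input, warnings = warnings)
}

#' Write canonical circRNA records to BED6
#'
#' The canonical table round-trips: `parse_records()` on the written file
#' reproduces the records exactly.
#'
#' @param batch A `circ_batch` tibble (or any data frame with the canonical
#'   columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(batch, path) {
  lines <- if (nrow(batch)) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s",
            batch$chrom, batch$start, batch$end, batch$circ_id, batch$strand)
  } else character()
  readr::write_lines(lines, path)
  invisible(path)
}

#' @export
print.circ_batch <- function(x, ...) {
  cnt <- batch_counts(x)
  cat(sprintf("<circ_batch> %d record(s) kept of %d seen\n",
              cnt[["n_kept"]], cnt[["n_input"]]))
  w <- batch_warnings(x)
  if (length(w)) cat(paste0("  warning: ", w, "\n"), sep = "")
  NextMethod()
}
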