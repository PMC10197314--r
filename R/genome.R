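# Random-access, strand-aware genome sequence. Sequences are held as a
# Biostrings::DNAStringSet (plain or gzipped FASTA both read transparently);
# subsequence extraction goes through subseq/reverseComplement so no residue
# outside the contig can ever be returned.

#' Open a reference genome
#'
#' Local mode reads a FASTA file (plain or gzip). Accession mode resolves an
#' NCBI assembly accession (e.g. `"GCF_001858045.2"`) through the NCBI
#' datasets download endpoint, caches the FASTA under
#' `cache_dir/<accession>/<accession>.fna`, and then behaves exactly like
#' local mode; once cached, no network is touched. Sequence names are taken
#' from the first whitespace-delimited token of each FASTA header.
#'
#' @param path_or_accession FASTA path (local mode) or assembly accession
#'   (accession mode).
#' @param mode `"local"` (default) or `"accession"`.
#' @param cache_dir Cache directory for accession mode (default
#'   `tools::R_user_dir("circseam", "cache")`).
#' @return A `genome_source` object.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), f)
#' g <- open_genome(f)
#' seq_lengths(g)
#' @export
open_genome <- function(path_or_accession, mode = c("local", "accession"),
                        cache_dir = tools::R_user_dir("circseam", "cache")) {
  mode <- match.arg(mode)
  if (mode == "accession") {
    path <- fetch_assembly(path_or_accession, cache_dir)
    origin <- "ncbi_accession"
    accession <- path_or_accession
  } else {
    path <- path_or_accession
    origin <- "local_fasta"
    accession <- NA_character_
    if (!file.exists(path)) rlang::abort(sprintf("FASTA not found: %s", path))
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) rlang::abort(sprintf("cannot parse FASTA %s: %s",
                                             path, conditionMessage(e))))
  if (!length(seqs)) rlang::abort(sprintf("FASTA has no sequences: %s", path))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(sequences = seqs, origin = origin, accession = accession,
                 path = path),
            class = "genome_source")
}

#' @rdname open_genome
#' @param genome A `genome_source`.
#' @return `seq_lengths()`: named integer vector of contig lengths.
#' @export
seq_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$sequences), names(genome$sequences))
}

# Download an assembly FASTA by accession into the cache (accession mode
# only; the test suite never exercises this path).
fetch_assembly <- function(accession, cache_dir) {
  if (!grepl("^GC[AF]_[0-9]+\\.[0-9]+", accession)) {
    rlang::abort(sprintf("not a valid NCBI assembly accession: %s", accession))
  }
  acc <- sub("^(GC[AF]_[0-9]+\\.[0-9]+).*", "\\1", accession)
  dest_dir <- file.path(cache_dir, acc)
  dest <- file.path(dest_dir, paste0(acc, ".fna"))
  if (file.exists(dest)) return(dest)
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  url <- sprintf(paste0("https://api.ncbi.nlm.nih.gov/datasets/v2alpha/genome/",
                        "accession/%s/download?include_annotation_type=GENOME_FASTA"),
                 acc)
  zipfile <- file.path(dest_dir, paste0(acc, ".zip"))
  status <- tryCatch(utils::download.file(url, zipfile, mode = "wb", quiet = TRUE),
                     error = function(e) -1L)
  if (!identical(status, 0L)) {
    rlang::abort(sprintf("failed to download assembly %s from NCBI", acc))
  }
  files <- utils::unzip(zipfile, list = TRUE)$Name
  fna <- grep("\\.(fna|fa|fasta)$", files, value = TRUE)
  if (!length(fna)) rlang::abort("downloaded archive contains no FASTA")
  utils::unzip(zipfile, files = fna[1], exdir = dest_dir, junkpaths = TRUE)
  file.rename(file.path(dest_dir, basename(fna[1])), dest)
  unlink(zipfile)
  dest
}

#' Extract a strand-aware genomic subsequence
#'
#' Coordinates are 0-based half-open. Strand `"-"` returns the reverse
#' complement of the forward slice (i.e. the transcribed sequence of a minus
#' strand feature). Soft-masked (lowercase) bases are uppercased; IUPAC codes
#' other than N become N.
#'
#' @param genome A `genome_source` from [open_genome()].
#' @param chrom Sequence name.
#' @param start,end 0-based half-open interval, `0 <= start < end <= length`.
#' @param strand `"+"` or `"-"`.
#' @return Uppercase residue string over A/C/G/T/N.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "AAAACCCC"), f)
#' g <- open_genome(f)
#' subsequence(g, "chr1", 0, 8, "-")
#' @export
subsequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome$sequences)) {
    rlang::abort(sprintf("UnknownSequence: %s", chrom))
  }
  len <- length(genome$sequences[[chrom]])
  if (!(start >= 0 && start < end && end <= len)) {
    rlang::abort(sprintf("OutOfBounds: [%d, %d) on %s of length %d",
                         start, end, chrom, len))
  }
  if (!strand %in% c("+", "-")) rlang::abort("strand must be '+' or '-'")
  s <- Biostrings::subseq(genome$sequences[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  normalize_residues(as.character(s), warn = FALSE)
}

#' @export
print.genome_source <- function(x, ...) {
  cat(sprintf("<genome_source> %d sequence(s), %s origin\n",
              length(x$sequences), x$origin))
  if (!is.na(x$accession)) cat(sprintf("  accession: %s\n", x$accession))
  lens <- seq_lengths(x)
  show <- utils::head(lens, 5)
  cat(sprintf("  %s: %s nt\n", names(show), format(show, big.mark = ",")),
      sep = "")
  if (length(lens) > 5) cat(sprintf("  ... and %d more\n", length(lens) - 5))
  invisible(x)
}
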