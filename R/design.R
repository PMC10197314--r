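# End-to-end design: records -> templates -> candidates -> ranked pairs ->
# conditions (+ optional linear-genome specificity flag). The run is fully
# deterministic: identical inputs and configuration give byte-identical
# reports.

#' Design junction-spanning primer sets for a batch of circRNAs
#'
#' For each record, builds the back-splice junction template, enumerates and
#' screens candidates, pairs and ranks them, recommends PCR conditions and
#' (optionally) flags pairs with convergent linear-genome placements near
#' the locus. Records for which no valid pair exists are reported in the
#' `failures` table with a reason, mirroring how a submission batch can come
#' back partially designed.
#'
#' @param records Canonical record tibble from [parse_records()].
#' @param genome A `genome_source` from [open_genome()].
#' @param cfg A [design_config()].
#' @param specificity Run [linear_specificity_check()] on every reported
#'   pair (default TRUE).
#' @return A `circ_design` object: list with `primers` (tibble, one row per
#'   reported pair), `failures` (tibble: `circ_id`, `reason`), `templates`
#'   (tibble) and `config`.
#' @examples
#' spec <- fixture_spec(seed = 7, n_circles = 3)
#' fx <- make_fixture(spec, tempfile("fx"))
#' g <- open_genome(fx$genome)
#' d <- design_primers(parse_records(fx$calls$bed), g)
#' glance(d)
#' @export
design_primers <- function(records, genome, cfg = design_config(),
                           specificity = TRUE) {
  templates <- build_templates(records, genome, cfg$shift_left, cfg$shift_right)
  failures <- attr(templates, "failures")
  primers <- list()
  for (i in seq_len(nrow(templates))) {
    tpl <- templates[i, ]
    cands <- enumerate_candidates(tpl, cfg)
    pairs <- pair_and_rank(cands, tpl, cfg)
    if (!nrow(pairs)) {
      failures <- dplyr::bind_rows(
        failures,
        tibble::tibble(circ_id = tpl$circ_id,
                       reason = "no primers found under the configured constraints"))
      next
    }
    pairs <- recommend_conditions(pairs, cfg$ta_offset, cfg$ext_per_kb)
    if (specificity) {
      rec <- records[records$circ_id == tpl$circ_id, ][1, ]
      chk <- lapply(seq_len(nrow(pairs)), function(k) {
        linear_specificity_check(pairs[k, ], rec, genome,
                                 cfg$max_linear_product)
      })
      pairs$linear_specific <- vapply(chk, `[[`, logical(1), "pass")
      pairs$specificity_note <- vapply(chk, `[[`, character(1), "reason")
    } else {
      pairs$linear_specific <- NA
      pairs$specificity_note <- "not checked"
    }
    primers[[length(primers) + 1L]] <- dplyr::mutate(
      pairs, circ_id = tpl$circ_id, junction_index = tpl$junction_index,
      .before = 1L)
  }
  primers <- if (length(primers)) dplyr::bind_rows(primers) else {
    empty <- recommend_conditions(pair_and_rank(
      enumerate_candidates(list(sequence = "ACGT"), cfg),
      list(junction_index = 1L), cfg))
    dplyr::mutate(empty, circ_id = character(0), junction_index = integer(0),
                  linear_specific = logical(0),
                  specificity_note = character(0), .before = 1L)
  }
  structure(list(primers = primers, failures = failures,
                 templates = templates, config = cfg,
                 n_records = nrow(records)),
            class = "circ_design")
}

#' @export
print.circ_design <- function(x, ...) {
  cat(sprintf("<circ_design> %d primer set(s) across %d circRNA(s); %d failure(s)\n",
              nrow(x$primers), length(unique(x$primers$circ_id)),
              nrow(x$failures)))
  invisible(x)
}

#' Tidy a primer design into one row per reported pair
#'
#' @param x A `circ_design`.
#' @param ... Unused.
#' @return The `primers` tibble.
#' @method tidy circ_design
#' @export
tidy.circ_design <- function(x, ...) x$primers

#' One-row summary of a primer design run
#'
#' @param x A `circ_design`.
#' @param ... Unused.
#' @return Tibble with record/template/pair counts and penalty summaries.
#' @method glance circ_design
#' @export
glance.circ_design <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_templates = nrow(x$templates),
    n_designed = length(unique(x$primers$circ_id)),
    n_failed = nrow(x$failures),
    n_pairs = nrow(x$primers),
    mean_pair_penalty = if (nrow(x$primers)) mean(x$primers$pair_penalty) else NA_real_,
    mean_product_size = if (nrow(x$primers)) mean(x$primers$product_size) else NA_real_)
}

#' Plot primer placements around the back-splice junction
#'
#' Draws each reported pair as two arrows on its template axis with the
#' junction marked, one facet per circRNA.
#'
#' @param object A `circ_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circ_design
#' @export
autoplot.circ_design <- function(object, ...) {
  p <- object$primers
  if (!nrow(p)) rlang::abort("no primers to plot")
  seg <- dplyr::bind_rows(
    tibble::tibble(circ_id = p$circ_id, set_rank = p$set_rank,
                   x = p$fwd_start, xend = p$fwd_start + p$fwd_len,
                   role = "forward"),
    tibble::tibble(circ_id = p$circ_id, set_rank = p$set_rank,
                   x = p$rev_start + p$rev_len, xend = p$rev_start,
                   role = "reverse"))
  jx <- dplyr::distinct(tibble::tibble(circ_id = p$circ_id,
                                       junction = p$junction_index))
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$set_rank, yend = .data$set_rank,
                   colour = .data$role),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))) +
    ggplot2::geom_vline(data = jx,
                        ggplot2::aes(xintercept = .data$junction),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~circ_id) +
    ggplot2::scale_y_reverse(breaks = function(l) seq(1, max(l))) +
    ggplot2::labs(x = "template position (nt)", y = "primer set rank",
                  colour = NULL,
                  title = "Primer sets around the back-splice junction") +
    ggplot2::theme_minimal()
}

#' Write the user-facing result files for a design run
#'
#' Emits `primers.tsv` (one row per reported pair, stable column order),
#' `templates.fasta`, `failures.tsv` (one row per undesignable record) and
#' `run_log.txt` (configuration echo and seed). All files are written even
#' when empty, headers included; numeric columns use '.' decimals so
#' repeated runs are byte-identical.
#'
#' @param design A `circ_design` from [design_primers()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer recorded in the run log.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(design, out_dir, seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- design$primers
  primers_tbl <- tibble::tibble(
    circ_id = p$circ_id, set_rank = p$set_rank,
    forward_seq = p$fwd_seq, reverse_seq = p$rev_seq,
    forward_start = p$fwd_start, reverse_start = p$rev_start,
    forward_len = p$fwd_len, reverse_len = p$rev_len,
    forward_tm = round(p$fwd_tm, 2), reverse_tm = round(p$rev_tm, 2),
    forward_gc = round(p$fwd_gc, 3), reverse_gc = round(p$rev_gc, 3),
    product_size = p$product_size, junction_index = p$junction_index,
    pair_penalty = round(p$pair_penalty, 4),
    annealing_temp = p$annealing_temp, extension_time = p$extension_time,
    cycles = p$cycles, denaturation_temp = p$denaturation_temp,
    linear_specific = p$linear_specific)
  paths <- c(primers = file.path(out_dir, "primers.tsv"),
             templates = file.path(out_dir, "templates.fasta"),
             failures = file.path(out_dir, "failures.tsv"),
             log = file.path(out_dir, "run_log.txt"))
  readr::write_tsv(primers_tbl, paths[["primers"]])
  templates_to_fasta(design$templates, paths[["templates"]])
  readr::write_tsv(design$failures, paths[["failures"]])
  cfg <- design$config
  log_lines <- c(
    "circseam design run",
    sprintf("seed: %s", ifelse(is.na(seed), "none", as.character(seed))),
    "config:",
    vapply(names(unclass(cfg)), function(k) {
      sprintf("  %s: %s", k, format(cfg[[k]], scientific = FALSE))
    }, character(1)),
    sprintf("records designed: %d", length(unique(p$circ_id))),
    sprintf("records failed: %d", nrow(design$failures)))
  readr::write_lines(log_lines, paths[["log"]])
  invisible(paths)
}
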