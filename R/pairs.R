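# Pairing and ranking. A pair's product runs from the forward primer's
# 5' end to the reverse primer's 5' end (binding-site end) on the template;
# only products strictly containing the back-splice junction are kept, which
# is what makes the reported pairs circle-specific (divergent on the linear
# genome).

#' Pair candidates and return the top ranked primer sets
#'
#' Forms every (forward, reverse) combination whose product interval
#' `[f$template_start, r$template_start + r$length)` has size inside
#' `[cfg$product_min, cfg$product_max]`, whose Tm difference is at most
#' `cfg$max_tm_diff`, and whose product strictly contains the junction
#' (`product_start < junction_index < product_end`). Pairs are ranked by
#' `pair_penalty = f$penalty + r$penalty + w_diff * tm_diff`, ties broken by
#' `(pair_penalty, product_start, forward sequence)`, and the top
#' `cfg$n_sets` are returned.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param template The template the candidates were enumerated on.
#' @param cfg A [design_config()].
#' @param all_pairs Return every surviving pair unranked-capped (for
#'   diagnostics) instead of the top `n_sets`.
#' @return Tibble of pairs: `set_rank`, forward/reverse columns (prefixed
#'   `fwd_` / `rev_`), `product_start`, `product_end`, `product_size`,
#'   `spans_junction`, `tm_diff`, `pair_penalty`. Zero rows when no valid
#'   pair exists.
#' @export
pair_and_rank <- function(candidates, template, cfg = design_config(),
                          all_pairs = FALSE) {
  j <- template$junction_index[[1]]
  fwd <- candidates[candidates$orientation == "forward", , drop = FALSE]
  rev <- candidates[candidates$orientation == "reverse", , drop = FALSE]
  empty <- tibble::tibble(
    set_rank = integer(), fwd_seq = character(), rev_seq = character(),
    fwd_start = integer(), rev_start = integer(),
    fwd_len = integer(), rev_len = integer(),
    fwd_tm = numeric(), rev_tm = numeric(),
    fwd_gc = numeric(), rev_gc = numeric(),
    fwd_penalty = numeric(), rev_penalty = numeric(),
    product_start = integer(), product_end = integer(),
    product_size = integer(), spans_junction = logical(),
    tm_diff = numeric(), pair_penalty = numeric())
  if (!nrow(fwd) || !nrow(rev)) return(empty)

  idx <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  p_start <- fwd$template_start[idx$f]
  p_end <- rev$template_start[idx$r] + rev$length[idx$r]
  size <- p_end - p_start
  tm_diff <- abs(fwd$tm[idx$f] - rev$tm[idx$r])
  keep <- size >= cfg$product_min & size <= cfg$product_max &
    tm_diff <= cfg$max_tm_diff & p_start < j & j < p_end
  if (!any(keep)) return(empty)
  idx <- idx[keep, , drop = FALSE]
  tmd <- tm_diff[keep]
  pen <- fwd$penalty[idx$f] + rev$penalty[idx$r] + cfg$w_diff * tmd
  pairs <- tibble::tibble(
    fwd_seq = fwd$sequence[idx$f], rev_seq = rev$sequence[idx$r],
    fwd_start = fwd$template_start[idx$f], rev_start = rev$template_start[idx$r],
    fwd_len = fwd$length[idx$f], rev_len = rev$length[idx$r],
    fwd_tm = fwd$tm[idx$f], rev_tm = rev$tm[idx$r],
    fwd_gc = fwd$gc[idx$f], rev_gc = rev$gc[idx$r],
    fwd_penalty = fwd$penalty[idx$f], rev_penalty = rev$penalty[idx$r],
    product_start = p_start[keep], product_end = p_end[keep],
    product_size = size[keep], spans_junction = TRUE,
    tm_diff = tmd,
    pair_penalty = pen)
  pairs <- dplyr::arrange(pairs, .data$pair_penalty, .data$product_start,
                          .data$fwd_seq)
  if (!all_pairs) pairs <- utils::head(pairs, cfg$n_sets)
  dplyr::mutate(pairs, set_rank = dplyr::row_number(), .before = 1L)
}
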