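# Exhaustive primer-candidate enumeration on a junction template. Every
# window with length in [min_len, max_len] is scored; filters run in
# increasing cost order (alphabet / homopolymer / GC -> Tm -> structure
# screens) over vectorized matrices, so nothing is sampled or pruned
# heuristically: the surviving set is exactly the set passing all screens.

#' Enumerate primer candidates on a junction template
#'
#' Considers every substring of the template with length in
#' `[cfg$min_len, cfg$max_len]`. Forward candidates read the template strand;
#' reverse candidates are the reverse complement of their binding site, with
#' `template_start` always the 0-based start of the binding site in template
#' coordinates. A window survives if it contains no N, its longest
#' homopolymer, GC fraction and nearest-neighbor Tm fall inside the
#' configured windows, and the self-dimer / hairpin screens pass. Each
#' candidate carries the penalty
#' `w_len |len - opt_len| + w_tm |Tm - tm_opt| + w_gc |GC - 0.5|`.
#'
#' @param template One-row template tibble from [build_template()] (or a list
#'   with `sequence` and `junction_index`).
#' @param cfg A [design_config()].
#' @return Tibble of candidates: `orientation`, `sequence`, `template_start`,
#'   `length`, `tm`, `gc`, `self_dimer_score`, `dimer_3p_score`,
#'   `hairpin_score`, `penalty`. Zero rows when nothing passes.
#' @export
enumerate_candidates <- function(template, cfg = design_config()) {
  seq <- template$sequence[[1]]
  tlen <- nchar(seq)
  enc <- match(.bases(seq), c("A", "C", "G", "T")) # NA for N
  out <- list()
  for (L in cfg$min_len:cfg$max_len) {
    if (tlen < L) next
    starts <- 0:(tlen - L) # 0-based
    X <- matrix(enc[outer(starts, 1:L, `+`)], nrow = length(starts))
    ok <- rowSums(is.na(X)) == 0L
    if (!any(ok)) next
    X <- X[ok, , drop = FALSE]
    starts <- starts[ok]

    keep <- homopolymer_matrix(X) <= cfg$max_homopolymer
    gc <- rowSums(X == 2L | X == 3L) / L
    keep <- keep & gc >= cfg$gc_min & gc <= cfg$gc_max
    if (!any(keep)) next
    X <- X[keep, , drop = FALSE]; starts <- starts[keep]; gc <- gc[keep]

    tm <- tm_matrix(X, cfg$primer_conc, cfg$monovalent_salt)
    keep <- tm >= cfg$tm_min & tm <= cfg$tm_max
    if (!any(keep)) next
    X <- X[keep, , drop = FALSE]; starts <- starts[keep]
    gc <- gc[keep]; tm <- tm[keep]

    for (orient in c("forward", "reverse")) {
      M <- if (orient == "forward") X else (5L - X)[, L:1, drop = FALSE]
      d <- dimer_matrix(M)
      hp <- hairpin_matrix(M)
      pass <- d[, "dimer"] <= cfg$max_dimer &
        d[, "dimer_3p"] <= cfg$max_dimer_3p &
        hp <= cfg$max_hairpin_stem
      if (!any(pass)) next
      seqs <- apply(M[pass, , drop = FALSE], 1L, function(r) {
        paste(c("A", "C", "G", "T")[r], collapse = "")
      })
      pen <- cfg$w_len * abs(L - cfg$opt_len) +
        cfg$w_tm * abs(tm[pass] - cfg$tm_opt) +
        cfg$w_gc * abs(gc[pass] - 0.5)
      out[[length(out) + 1L]] <- tibble::tibble(
        orientation = orient,
        sequence = seqs,
        template_start = starts[pass],
        length = L,
        tm = tm[pass],
        gc = gc[pass],
        self_dimer_score = as.integer(d[pass, "dimer"]),
        dimer_3p_score = as.integer(d[pass, "dimer_3p"]),
        hairpin_score = as.integer(hp[pass]),
        penalty = pen)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      orientation = character(), sequence = character(),
      template_start = integer(), length = integer(), tm = numeric(),
      gc = numeric(), self_dimer_score = integer(),
      dimer_3p_score = integer(), hairpin_score = integer(),
      penalty = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$orientation,
                 .data$template_start, .data$length)
}
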