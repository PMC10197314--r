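# Thermocycling recommendations. These are the standard bench heuristics
# (annealing a fixed offset below the cooler primer's Tm; 30 s extension per
# kb with a 30 s floor); both knobs are configurable.

#' Recommend PCR conditions for ranked primer pairs
#'
#' Appends per-pair thermocycling columns: `annealing_temp`
#' (`min(Tm_f, Tm_r) - ta_offset`, rounded to 0.1 degrees C),
#' `extension_time` (`max(30, ceiling(product_size / 1000) * ext_per_kb)`
#' seconds), `cycles` (35) and `denaturation_temp` (95 C).
#'
#' @param pairs Pair tibble from [pair_and_rank()].
#' @param ta_offset Degrees below the lower primer Tm (default 3).
#' @param ext_per_kb Extension seconds per kb (default 30).
#' @return `pairs` with the four condition columns appended.
#' @export
recommend_conditions <- function(pairs, ta_offset = 3.0, ext_per_kb = 30L) {
  if (!nrow(pairs)) {
    return(dplyr::mutate(pairs, annealing_temp = numeric(0),
                         extension_time = integer(0), cycles = integer(0),
                         denaturation_temp = numeric(0)))
  }
  dplyr::mutate(
    pairs,
    annealing_temp = round(pmin(.data$fwd_tm, .data$rev_tm) - ta_offset, 1),
    extension_time = pmax(30L,
                          as.integer(ceiling(.data$product_size / 1000) *
                                       ext_per_kb)),
    cycles = 35L,
    denaturation_temp = 95)
}
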