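#' Design configuration
#'
#' Bundles every tunable of the design pipeline. Defaults follow the
#' conventional single-submission design form for circRNA junction primers:
#' 150 nt taken from each side of the back-splice junction, primers of
#' 15--20 nt (optimum 19), amplicons of 150--200 nt and up to 4 ranked
#' primer sets per circle. Thermodynamic conditions (50 nM primer,
#' 50 mM monovalent salt) and the 57/60/63 degree Tm window are standard
#' bench defaults; adjust them to your PCR chemistry.
#'
#' @param shift_left,shift_right Nucleotides taken upstream/downstream of the
#'   junction when building the template (default 150 each; clamped to the
#'   circle span for short circles).
#' @param opt_len,min_len,max_len Primer length optimum and bounds in nt
#'   (defaults 19, 15, 20).
#' @param product_min,product_max Amplicon size window in nt (defaults 150, 200).
#' @param tm_opt,tm_min,tm_max Primer melting temperature optimum and bounds
#'   in degrees Celsius (defaults 60, 57, 63).
#' @param max_tm_diff Maximum |Tm(forward) - Tm(reverse)| in degrees C (default 3).
#' @param n_sets Maximum ranked primer pairs reported per circRNA (default 4).
#' @param primer_conc Total primer strand concentration in mol/L (default 50e-9).
#' @param monovalent_salt Monovalent cation concentration in mol/L (default 0.05).
#' @param gc_min,gc_max Allowed primer GC fraction (defaults 0.20, 0.80).
#' @param max_homopolymer Longest tolerated single-base run (default 4).
#' @param max_dimer,max_dimer_3p,max_hairpin_stem Structure-screen rejection
#'   thresholds: overall self-dimer Watson-Crick matches (default 8), matches in
#'   a run anchored at the 3' terminus (default 4), hairpin stem length
#'   (default 4).
#' @param w_len,w_tm,w_gc,w_diff Penalty weights: per nt away from `opt_len`,
#'   per degree away from `tm_opt`, per unit GC-fraction away from 0.5, and per
#'   degree of pair Tm difference (defaults 1, 1, 10, 0.5).
#' @param max_linear_product Window (nt) for the linear-genome specificity
#'   check (default 5000).
#' @param cap Maximum records processed per submission (default 100).
#' @param ta_offset Annealing temperature offset below the lower primer Tm in
#'   degrees C (default 3).
#' @param ext_per_kb Extension seconds per kb of product, floor 30 s (default 30).
#'
#' @return A `design_config` list.
#' @examples
#' cfg <- design_config(tm_opt = 62, tm_min = 59, tm_max = 65)
#' cfg$tm_opt
#' @export
design_config <- function(shift_left = 150L, shift_right = 150L,
                          opt_len = 19L, min_len = 15L, max_len = 20L,
                          product_min = 150L, product_max = 200L,
                          tm_opt = 60, tm_min = 57, tm_max = 63,
                          max_tm_diff = 3,
                          n_sets = 4L,
                          primer_conc = 50e-9, monovalent_salt = 0.05,
                          gc_min = 0.20, gc_max = 0.80,
                          max_homopolymer = 4L,
                          max_dimer = 8L, max_dimer_3p = 4L, max_hairpin_stem = 4L,
                          w_len = 1.0, w_tm = 1.0, w_gc = 10.0, w_diff = 0.5,
                          max_linear_product = 5000L,
                          cap = 100L,
                          ta_offset = 3.0, ext_per_kb = 30L) {
  cfg <- list(
    shift_left = as.integer(shift_left), shift_right = as.integer(shift_right),
    opt_len = as.integer(opt_len), min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    product_min = as.integer(product_min), product_max = as.integer(product_max),
    tm_opt = as.numeric(tm_opt), tm_min = as.numeric(tm_min),
    tm_max = as.numeric(tm_max), max_tm_diff = as.numeric(max_tm_diff),
    n_sets = as.integer(n_sets),
    primer_conc = as.numeric(primer_conc),
    monovalent_salt = as.numeric(monovalent_salt),
    gc_min = as.numeric(gc_min), gc_max = as.numeric(gc_max),
    max_homopolymer = as.integer(max_homopolymer),
    max_dimer = as.integer(max_dimer), max_dimer_3p = as.integer(max_dimer_3p),
    max_hairpin_stem = as.integer(max_hairpin_stem),
    w_len = as.numeric(w_len), w_tm = as.numeric(w_tm),
    w_gc = as.numeric(w_gc), w_diff = as.numeric(w_diff),
    max_linear_product = as.integer(max_linear_product),
    cap = as.integer(cap),
    ta_offset = as.numeric(ta_offset), ext_per_kb = as.integer(ext_per_kb)
  )
  if (cfg$shift_left < 1L || cfg$shift_right < 1L) {
    rlang::abort("shift_left and shift_right must be >= 1")
  }
  if (!(cfg$min_len <= cfg$opt_len && cfg$opt_len <= cfg$max_len)) {
    rlang::abort("need min_len <= opt_len <= max_len")
  }
  if (cfg$product_min > cfg$product_max) {
    rlang::abort("need product_min <= product_max")
  }
  if (!(cfg$tm_min <= cfg$tm_opt && cfg$tm_opt <= cfg$tm_max)) {
    rlang::abort("need tm_min <= tm_opt <= tm_max")
  }
  if (cfg$n_sets < 1L) rlang::abort("n_sets must be >= 1")
  if (cfg$primer_conc <= 0 || cfg$monovalent_salt <= 0) {
    rlang::abort("concentrations must be positive")
  }
  structure(cfg, class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  template shifts : %d / %d nt\n", x$shift_left, x$shift_right))
  cat(sprintf("  primer length   : %d-%d nt (opt %d)\n",
              x$min_len, x$max_len, x$opt_len))
  cat(sprintf("  product size    : %d-%d nt\n", x$product_min, x$product_max))
  cat(sprintf("  Tm window       : %.1f-%.1f C (opt %.1f), pair diff <= %.1f\n",
              x$tm_min, x$tm_max, x$tm_opt, x$max_tm_diff))
  cat(sprintf("  sets per circle : %d\n", x$n_sets))
  cat(sprintf("  conditions      : %.0f nM primer, %.0f mM monovalent salt\n",
              x$primer_conc * 1e9, x$monovalent_salt * 1e3))
  invisible(x)
}

#' Read a design configuration from a YAML-style key-value file
#'
#' Accepts a flat `key: value` file whose keys match the arguments of
#' [design_config()]. Unknown keys raise an error; missing keys keep their
#' defaults. Intended for the command-line wrapper (flags override the file).
#'
#' @param path Path to the configuration file.
#' @return A `design_config` list.
#' @export
read_design_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- stringr::str_match(lines, "^\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(\\S+)\\s*$")
  if (any(is.na(kv[, 1]))) {
    rlang::abort(sprintf("unparseable config line: %s",
                         lines[which(is.na(kv[, 1]))[1]]))
  }
  args <- as.list(as.numeric(kv[, 3]))
  names(args) <- kv[, 2]
  unknown <- setdiff(names(args), names(formals(design_config)))
  if (length(unknown)) {
    rlang::abort(sprintf("unknown config keys: %s",
                         paste(unknown, collapse = ", ")))
  }
  do.call(design_config, args)
}
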