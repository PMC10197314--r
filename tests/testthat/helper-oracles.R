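# Independent brute-force oracles. These re-derive each quantity by the
# most literal method available (per-step summation, all-offsets string
# scanning, exhaustive double loops) and share no code with the package
# internals they check.

# --- nearest-neighbor Tm by literal per-step summation ----------------------
# Only the ten unique duplex steps are tabulated; a step absent from the
# table is looked up by its reverse complement, exactly as printed tables
# are used by hand.
oracle_tm <- function(seq, primer_conc = 50e-9, na = 0.05) {
  dh10 <- c("AA" = -7.9, "AT" = -7.2, "TA" = -7.2, "CA" = -8.5,
            "GT" = -8.4, "CT" = -7.8, "GA" = -8.2, "CG" = -10.6,
            "GC" = -9.8, "GG" = -8.0)
  ds10 <- c("AA" = -22.2, "AT" = -20.4, "TA" = -21.3, "CA" = -22.7,
            "GT" = -22.4, "CT" = -21.0, "GA" = -22.2, "CG" = -27.2,
            "GC" = -24.4, "GG" = -19.9)
  rc1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
  rc <- function(s) paste(rev(vapply(strsplit(s, "")[[1]], rc1, "")),
                          collapse = "")
  n <- nchar(seq)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1)) {
    step <- substr(seq, i, i + 1)
    if (!step %in% names(dh10)) step <- rc(step)
    dh <- dh + dh10[[step]]
    ds <- ds + ds10[[step]]
  }
  for (b in c(substr(seq, 1, 1), substr(seq, n, n))) {
    if (b %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  if (identical(seq, rc(seq))) {
    ds <- ds - 1.4
    k <- primer_conc / 2
  } else {
    k <- primer_conc / 4
  }
  ds <- ds + 0.368 * (n - 1) * log(na)
  dh * 1000 / (ds + 1.987 * log(k)) - 273.15
}

# --- structure screens by all-offsets string scanning -----------------------
oracle_dimer <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  pair <- function(x, y) {
    (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "C" & y == "G") | (x == "G" & y == "C")
  }
  best <- 0L; best3p <- 0L
  for (off in -(n - 1):(n - 1)) {
    total <- 0L
    run_at_3p <- 0L
    for (i in 1:n) {
      k <- n + 1 - (i - off) # partner index: antiparallel alignment
      hit <- k >= 1 && k <= n && pair(b[i], b[k])
      if (hit) total <- total + 1L
    }
    best <- max(best, total)
    # run of consecutive pairs ending at the 3' terminus
    run <- 0L
    for (i in n:1) {
      k <- n + 1 - (i - off)
      if (k >= 1 && k <= n && pair(b[i], b[k])) run <- run + 1L else break
    }
    best3p <- max(best3p, run)
  }
  c(dimer = best, dimer_3p = best3p)
}

oracle_hairpin <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  pair <- function(x, y) {
    (x == "A" && y == "T") || (x == "T" && y == "A") ||
      (x == "C" && y == "G") || (x == "G" && y == "C")
  }
  best <- 0L
  for (i in 1:n) for (j in 1:n) {
    if (j - i - 1 < min_loop) next # innermost pair needs the loop
    k <- 0L
    while (i - k >= 1 && j + k <= n && pair(b[i - k], b[j + k])) k <- k + 1L
    best <- max(best, k)
  }
  best
}

# --- exhaustive pair enumeration (double loop) ------------------------------
oracle_pairs <- function(candidates, junction_index, cfg) {
  fwd <- candidates[candidates$orientation == "forward", ]
  rev <- candidates[candidates$orientation == "reverse", ]
  out <- list()
  for (i in seq_len(nrow(fwd))) for (k in seq_len(nrow(rev))) {
    ps <- fwd$template_start[i]
    pe <- rev$template_start[k] + rev$length[k]
    size <- pe - ps
    if (size < cfg$product_min || size > cfg$product_max) next
    if (abs(fwd$tm[i] - rev$tm[k]) > cfg$max_tm_diff) next
    if (!(ps < junction_index && junction_index < pe)) next
    out[[length(out) + 1]] <- data.frame(
      fwd_seq = fwd$sequence[i], rev_seq = rev$sequence[k],
      fwd_start = ps, rev_start = rev$template_start[k],
      product_size = size)
  }
  if (!length(out)) {
    return(data.frame(fwd_seq = character(), rev_seq = character(),
                      fwd_start = integer(), rev_start = integer(),
                      product_size = integer()))
  }
  do.call(rbind, out)
}

# --- rotation oracle for junction templates ---------------------------------
# The template must be a substring of the doubled circle read on the
# circle's own strand, ending left_used bases after the (second) junction.
oracle_template_from_doubled <- function(genome_str, start, end, strand,
                                         left_used, right_used) {
  circle <- substr(genome_str, start + 1, end)
  if (strand == "-") {
    comp <- chartr("ACGT", "TGCA", circle)
    circle <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  doubled <- paste0(circle, circle)
  span <- nchar(circle)
  substr(doubled, span - left_used + 1, span + right_used)
}

# random primer generator for oracle sweeps
random_primer <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
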