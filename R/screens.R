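# Primer secondary-structure screens. With bases encoded A=1, C=2, G=3,
# T=4, two bases form a Watson-Crick pair iff their codes sum to 5; scores
# are plain pair counts (dimensionless), not free energies. All screens run
# as column-vectorized operations over an integer matrix of equal-length
# sequences so whole candidate batches are scored at once.

# Longest single-base run per row.
homopolymer_matrix <- function(X) {
  L <- ncol(X)
  run <- rep(1L, nrow(X))
  best <- run
  if (L >= 2) {
    for (cc in 2:L) {
      run <- ifelse(X[, cc] == X[, cc - 1L], run + 1L, 1L)
      best <- pmax(best, run)
    }
  }
  best
}

# Self-dimer: maximum WC pair count over all ungapped antiparallel
# alignments of each sequence with itself, and the longest complementary
# run containing the 3'-terminal base in any alignment.
dimer_matrix <- function(X) {
  L <- ncol(X)
  Y <- (5L - X)[, L:1, drop = FALSE] # partner strand read 3'->5'
  m <- nrow(X)
  best <- integer(m)
  best3p <- integer(m)
  for (off in (-(L - 1L)):(L - 1L)) {
    i <- max(1L, 1L + off):min(L, L + off)
    j <- i - off
    # x[i] faces rev(x)[j]; a pair forms when x[i] complements x[L+1-j],
    # i.e. when x[i] + Y-code at j sums consistently -> compare to partner
    hit <- X[, i, drop = FALSE] == Y[, j, drop = FALSE]
    best <- pmax(best, as.integer(rowSums(hit)))
    if (off >= 0L) { # overlap includes the 3'-terminal base (i = L)
      alive <- rep(TRUE, m)
      run <- integer(m)
      for (cc in ncol(hit):1L) {
        alive <- alive & hit[, cc]
        run <- run + alive
        if (!any(alive)) break
      }
      best3p <- pmax(best3p, run)
    }
  }
  cbind(dimer = best, dimer_3p = best3p)
}

# Longest intramolecular stem closable with a loop of >= min_loop nt.
# run(i, j) = consecutive pairs ending at (i, j) extends run(i-1, j+1):
# constant anti-diagonal s = i + j, i ascending.
hairpin_matrix <- function(X, min_loop = 3L) {
  L <- ncol(X)
  m <- nrow(X)
  best <- integer(m)
  if (L < min_loop + 2L) return(best)
  comp <- function(i, j) (X[, i] + X[, j]) == 5L
  for (s in 3L:(2L * L - min_loop - 1L)) {
    run <- integer(m)
    i_lo <- max(1L, s - L)
    i_hi <- (s - 1L) %/% 2L
    if (i_lo > i_hi) next
    for (i in i_lo:i_hi) {
      j <- s - i
      run <- ifelse(comp(i, j), run + 1L, 0L)
      if (j - i - 1L >= min_loop) best <- pmax(best, run)
    }
  }
  best
}

#' Screen a primer for self-dimers and hairpins
#'
#' The self-dimer score is the maximum count of Watson-Crick pairs over all
#' ungapped antiparallel alignments of the primer against itself (equivalently,
#' of the primer against its own reverse complement); `dimer_3p_score` is the
#' longest complementary run containing the primer's 3'-terminal base in any
#' such alignment. The hairpin score is the longest intramolecular stem
#' closable with a loop of at least 3 nt. Default rejection thresholds
#' (overall dimer > 8, 3' dimer run > 4, stem > 4) live in [design_config()].
#'
#' @param seq Character vector of primer sequences (A/C/G/T).
#' @return Tibble with `sequence`, `self_dimer_score`, `dimer_3p_score`,
#'   `hairpin_score`.
#' @examples
#' structure_screens("AAAAAAAAAAAAAAA")
#' @export
structure_screens <- function(seq) {
  if (!length(seq)) rlang::abort("empty input")
  if (any(grepl("[^ACGT]", seq))) rlang::abort("ambiguous bases in sequence")
  n <- nchar(seq)
  dimer <- integer(length(seq)); dimer3 <- integer(length(seq))
  hp <- integer(length(seq))
  for (L in unique(n)) {
    idx <- which(n == L)
    X <- encode_matrix(seq[idx])
    d <- dimer_matrix(X)
    dimer[idx] <- d[, "dimer"]
    dimer3[idx] <- d[, "dimer_3p"]
    hp[idx] <- hairpin_matrix(X)
  }
  tibble::tibble(sequence = seq,
                 self_dimer_score = dimer,
                 dimer_3p_score = dimer3,
                 hairpin_score = hp)
}
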