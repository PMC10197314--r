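# Pairing, ranking, determinism and monotone relaxation.

make_template <- function(n = 400, seed = 17, gc = 0.5) {
  withr::local_seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  tibble::tibble(
    sequence = paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                            prob = probs), collapse = ""),
    junction_index = as.integer(n / 2))
}

test_that("surviving pairs equal the exhaustive double-loop oracle", {
  for (seed in c(17, 18, 19)) {
    tpl <- make_template(n = 300 + 100 * (seed - 17), seed = seed, gc = 0.55)
    cfg <- design_config()
    cands <- enumerate_candidates(tpl, cfg)
    got <- pair_and_rank(cands, tpl, cfg, all_pairs = TRUE)
    want <- oracle_pairs(cands, tpl$junction_index, cfg)
    key <- function(d) sort(paste(d$fwd_seq, d$fwd_start, d$rev_seq,
                                  d$rev_start, d$product_size))
    expect_identical(key(got), key(want))
  }
})

test_that("reported pairs satisfy every pair invariant", {
  tpl <- make_template(400, seed = 21, gc = 0.6)
  cfg <- design_config()
  pairs <- pair_and_rank(enumerate_candidates(tpl, cfg), tpl, cfg,
                         all_pairs = TRUE)
  expect_gt(nrow(pairs), 0)
  j <- tpl$junction_index
  expect_true(all(pairs$product_size ==
                    pairs$product_end - pairs$product_start))
  expect_true(all(pairs$product_size >= cfg$product_min &
                    pairs$product_size <= cfg$product_max))
  expect_true(all(pairs$product_start < j & j < pairs$product_end))
  expect_true(all(pairs$spans_junction))
  expect_true(all(pairs$tm_diff <= cfg$max_tm_diff))
  # interval arithmetic: junction containment bounds the forward start
  expect_true(all(pairs$product_start >= j - cfg$product_max + 1))
})

test_that("top sets are capped, deterministically ordered and distinct", {
  tpl <- make_template(400, seed = 22, gc = 0.6)
  cfg <- design_config()
  cands <- enumerate_candidates(tpl, cfg)
  all_p <- pair_and_rank(cands, tpl, cfg, all_pairs = TRUE)
  expect_gte(nrow(all_p), 20) # permissive template
  top <- pair_and_rank(cands, tpl, cfg)
  expect_identical(nrow(top), cfg$n_sets)
  expect_identical(top$set_rank, 1:4)
  expect_true(!is.unsorted(top$pair_penalty))
  expect_identical(top, pair_and_rank(cands, tpl, cfg)) # byte-identical rerun
  expect_identical(nrow(dplyr::distinct(
    top, .data$fwd_seq, .data$fwd_start, .data$rev_seq, .data$rev_start)),
    nrow(top))
  # ranked list is the head of the penalty-sorted full list
  expect_equal(top$pair_penalty, utils::head(all_p$pair_penalty, 4),
               tolerance = 1e-12)
})

test_that("a product entirely on one side of the junction is excluded", {
  # synthetic candidates straddling nothing: place both primers left of j
  tpl <- make_template(400, seed = 23, gc = 0.6)
  cfg <- design_config(product_min = 40L, product_max = 60L)
  cands <- enumerate_candidates(tpl, cfg)
  left <- cands[cands$template_start + cands$length <= tpl$junction_index, ]
  pairs <- pair_and_rank(left, tpl, cfg, all_pairs = TRUE)
  expect_identical(nrow(pairs), 0L)
})

test_that("widening Tm or product windows never loses pairs", {
  tpl <- make_template(450, seed = 24)
  base <- design_config()
  n_base <- nrow(pair_and_rank(enumerate_candidates(tpl, base), tpl, base,
                               all_pairs = TRUE))
  wider_tm <- design_config(tm_min = 55, tm_max = 65)
  n_tm <- nrow(pair_and_rank(enumerate_candidates(tpl, wider_tm), tpl,
                             wider_tm, all_pairs = TRUE))
  wider_prod <- design_config(product_min = 120L, product_max = 230L)
  n_prod <- nrow(pair_and_rank(enumerate_candidates(tpl, wider_prod), tpl,
                               wider_prod, all_pairs = TRUE))
  expect_gte(n_tm, n_base)
  expect_gte(n_prod, n_base)
})
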