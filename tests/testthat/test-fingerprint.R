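toy_products <- function(df, enzyme = "chitinosanase") {
  product_table(df, enzyme = enzyme)
}

test_that("normalize_window rescales in-window fractions and flags the rest", {
  df <- data.frame(dp = c(2L, 3L, 12L), n_acetyl = c(2L, 1L, 4L),
                   n_deacetyl = c(0L, 2L, 8L),
                   end_flag = "interior", abundance = c(3, 1, 5))
  p <- normalize_window(toy_products(df))
  expect_equal(p$fraction, c(0.75, 0.25, NA))
  expect_equal(p$in_window, c(TRUE, TRUE, FALSE))
  one <- normalize_window(toy_products(df[1, ]))
  expect_equal(one$fraction, 1)
  expect_error(normalize_window(toy_products(df[3, ])), "no products in DP window")
})

test_that("estimate_fa is monomer-weighted and exact without a window", {
  allA <- toy_products(data.frame(dp = c(2L, 4L), n_acetyl = c(2L, 4L),
                                  n_deacetyl = 0L, end_flag = "interior",
                                  abundance = 1))
  expect_equal(estimate_fa(allA), 1)

  e <- generate_bernoulli(0.42, rep(80, 25), seed = 41)
  p <- digest(e, preset_hydrolases()$chitinosanase, seed = 42)
  expect_equal(estimate_fa(p, 1, Inf), compute_fa(e))
})

test_that("windowed F_A error is bounded by the excluded mass fraction", {
  e <- generate_bernoulli(0.34, rep(700, 60), seed = 43)
  p <- digest(e, preset_hydrolases()$chitinosanase, seed = 44)
  inw <- p$dp >= 2 & p$dp <= 10
  excluded <- 1 - sum(p$abundance[inw] * p$dp[inw]) / sum(p$abundance * p$dp)
  expect_lt(excluded, 0.10)
  expect_lt(abs(estimate_fa(p) - compute_fa(e)), excluded)
})

test_that("infer_block_profile applies the DA/XX lemma on the toy sequence", {
  e <- chain_ensemble("AADDDAADDA")
  p <- digest(e, preset_hydrolases()$chitinosanase, seed = 1)
  prof <- infer_block_profile(p)
  expect_same_profile(prof, block_profile_from_sequences(e))
  # reducing-terminal product (a=2, d=2) contributed A-block 2 and D-block 2
  expect_true(any(prof$type == "A" & prof$size == 2 & !prof$terminal))
})

test_that("infer_block_profile equals the run-length oracle on complete digests", {
  for (seed in c(51, 52, 53)) {
    e <- random_small_ensemble(40, 50, 0.35, seed)
    p <- digest(e, preset_hydrolases()$chitinosanase, seed = seed + 100)
    expect_same_profile(infer_block_profile(p),
                        block_profile_from_sequences(e))
  }
  # composition alone determines the form of interior and non-reducing
  # products (they always end with the donated A); strip their sequences
  # and the inference must still be exact
  e <- generate_bernoulli(0.4, rep(60, 30), seed = 54)
  p <- digest(e, preset_hydrolases()$chitinosanase, seed = 55)
  determined <- p$end_flag %in% c("interior", "non_reducing")
  p$sequence[determined] <- NA_character_
  expect_same_profile(infer_block_profile(p),
                      block_profile_from_sequences(e))
})

test_that("inferred D-block average matches geometric theory on random PA", {
  e <- generate_bernoulli(0.33, rep(500, 100), seed = 56)
  p <- digest(e, preset_hydrolases()$chitinosanase, seed = 57)
  prof <- infer_block_profile(p)
  expect_equal(average_block_sizes(prof, "number")[["D"]], 3.0,
               tolerance = 0.1 / 3)
})

test_that("infer_block_profile provenance and consistency guards", {
  e <- chain_ensemble("AAAA")
  p <- digest(e, preset_hydrolases()$ChiB, seed = 1)
  expect_error(infer_block_profile(p), "not chitinosanase")
  bad <- toy_products(data.frame(dp = 2L, n_acetyl = 0L, n_deacetyl = 2L,
                                 end_flag = "interior", abundance = 1))
  expect_error(infer_block_profile(bad), "inconsistent with DA/XX")
})

test_that("average_block_sizes: hand values and Cauchy-Schwarz property", {
  p <- block_profile(data.frame(type = "A", size = 2L, terminal = FALSE,
                                count = 5))
  expect_equal(unname(average_block_sizes(p, "number")), 2)
  expect_equal(unname(average_block_sizes(p, "weight")), 2)
  p2 <- block_profile(data.frame(type = "A", size = c(1L, 3L),
                                 terminal = FALSE, count = 1))
  expect_equal(unname(average_block_sizes(p2, "number")), 2)
  expect_equal(unname(average_block_sizes(p2, "weight")), 2.5)
  for (seed in c(61, 62)) {
    e <- random_small_ensemble(30, 40, 0.3, seed)
    prof <- block_profile_from_sequences(e)
    w <- average_block_sizes(prof, "weight")
    n <- average_block_sizes(prof, "number")
    expect_true(all(w >= n - 1e-12))
  }
})

test_that("compare_profiles detects block enrichment and regular depletion", {
  bern <- block_profile_from_sequences(
    generate_bernoulli(0.33, rep(600, 60), seed = 63))
  blocky <- block_profile_from_sequences(
    generate_markov(markov_pa_spec(0.33, 0.3), rep(600, 60), seed = 64))
  reg <- block_profile_from_sequences(generate_regular(0.33, rep(600, 60)))

  same <- compare_profiles(bern, bern)
  expect_true(all(same$delta$delta == 0))
  expect_equal(unname(same$tv), c(0, 0))

  db <- compare_profiles(blocky, bern)$delta
  expect_gt(sum(db$delta[db$type == "A" & db$size >= 3]), 0)
  dr <- compare_profiles(reg, bern)$delta
  expect_lt(sum(dr$delta[dr$type == "A" & dr$size >= 2]), 0)
})

test_that("add_ms_noise: identity at cv 0, determinism, low estimator bias", {
  e <- generate_bernoulli(0.34, rep(200, 50), seed = 65)
  p <- digest(e, preset_hydrolases()$chitinosanase, seed = 66)
  expect_identical(add_ms_noise(p, 0), p)
  n1 <- add_ms_noise(p, 0.1, seed = 5)
  n2 <- add_ms_noise(p, 0.1, seed = 5)
  expect_identical(n1$abundance, n2$abundance)
  expect_false(identical(n1$abundance, p$abundance))
  expect_equal(sum(n1$abundance), sum(p$abundance))

  base <- estimate_fa(p)
  reps <- vapply(1:100, function(k)
    estimate_fa(add_ms_noise(p, 0.1, seed = 700 + k)), numeric(1))
  expect_lt(abs(mean(reps) - base), 0.01)
})
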