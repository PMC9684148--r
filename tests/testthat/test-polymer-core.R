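test_that("compute_fa counts acetyl units, abundance-weighted", {
  expect_equal(compute_fa(chain_ensemble("AADDA")), 0.6)
  expect_equal(compute_fa(chain_ensemble(c("DDDD", "DD"))), 0)
  # abundance weighting: 2 x "AA" + 1 x "DD" -> 4 A of 6
  e <- chain_ensemble(c("AA", "DD"), abundances = c(2, 1))
  expect_equal(compute_fa(e), 2 / 3)
  expect_error(chain_ensemble(character(0)), "empty ensemble")
  # 1e5 Bernoulli(0.34) monomers recover fa within 3 binomial SE
  e <- generate_bernoulli(0.34, rep(1000, 100), seed = 7)
  se <- sqrt(0.34 * 0.66 / 1e5)
  expect_lt(abs(compute_fa(e) - 0.34), 3 * se)
})

test_that("dyad_fractions handles limits and pools by abundance", {
  d <- dyad_fractions(chain_ensemble("ADAD"))
  expect_equal(unname(d$fractions[c("AD", "DA", "AA", "DD")]),
               c(2 / 3, 1 / 3, 0, 0))
  expect_equal(d$P_sigma, 2)

  expect_warning(dh <- dyad_fractions(chain_ensemble("AAAA")),
                 "P_DA set to 0")
  expect_equal(dh$fractions[["AA"]], 1)
  expect_equal(dh$P_sigma, 0)

  expect_error(dyad_fractions(chain_ensemble(c("A", "D"))), "no dyads")

  # abundance weighting and no cross-chain dyads
  e <- chain_ensemble(c("AA", "AD"), abundances = c(2, 1))
  expect_warning(dyad_fractions(e), "P_DA set to 0")
  de <- suppressWarnings(dyad_fractions(e))
  expect_equal(unname(de$counts[c("AA", "AD")]), c(2, 1))
})

test_that("dyad fractions of a stationary Markov ensemble match the closed form", {
  # oracle: stationary two-state chain with P_AD, P_DA gives
  # F_AA = fa (1 - P_AD), F_AD = F_DA = fa P_AD, F_DD = (1 - fa)(1 - P_DA)
  fa <- 0.33; p_ad <- 0.201; p_da <- 0.099
  expected <- c(AA = fa * (1 - p_ad), AD = fa * p_ad,
                DA = (1 - fa) * p_da, DD = (1 - fa) * (1 - p_da))
  expect_equal(unname(round(expected, 4)), c(0.2637, 0.0663, 0.0663, 0.6037))
  e <- generate_markov(markov_pa_spec(fa, 0.3), rep(800, 300), seed = 3)
  d <- dyad_fractions(e)
  expect_equal(unname(d$fractions[names(expected)]), unname(expected),
               tolerance = 0.02)
})

test_that("p_sigma reproduces the random, block and alternating landmarks", {
  # product-form (random) dyads give exactly 1 at any composition
  for (fa in c(0.05, 0.2, 0.33, 0.5, 0.7, 0.95)) {
    d <- dyad_stats(fa^2, fa * (1 - fa), (1 - fa) * fa, (1 - fa)^2)
    expect_equal(p_sigma(d), 1)
  }
  # the block-PA quadruple prints as 0.30
  d <- dyad_stats(0.2637, 0.0663, 0.0663, 0.6037)
  expect_equal(p_sigma(d), 0.30, tolerance = 0.005)
  expect_equal(p_sigma(dyad_stats(0, 0.5, 0.5, 0)), 2)
  degenerate <- structure(list(fractions = c(AA = 0, AD = 0, DA = 0, DD = 0),
                               P_sigma = 0),
                          class = "dyad_stats")
  expect_error(p_sigma(degenerate), "degenerate composition")
})

test_that("block_profile_from_sequences decomposes runs and conserves monomers", {
  p <- block_profile_from_sequences(chain_ensemble("AADDDA"))
  expect_equal(as.data.frame(p),
               data.frame(type = c("A", "A", "D"), size = c(1L, 2L, 3L),
                          terminal = c(TRUE, TRUE, FALSE),
                          count = c(1, 1, 1), stringsAsFactors = FALSE))
  pd <- block_profile_from_sequences(chain_ensemble("DDDD"))
  expect_equal(pd$type, "D")
  expect_equal(pd$size, 4L)

  # conservation, property-style over random ensembles
  for (seed in c(11, 12, 13)) {
    e <- random_small_ensemble(40, 60, 0.4, seed)
    p <- block_profile_from_sequences(e)
    expect_identical(sum(p$size * p$count),
                     sum(e$abundances * nchar(e$sequences)))
  }

  # Bernoulli run lengths are geometric: empirical D-block mean near 1/fa
  e <- generate_bernoulli(0.33, rep(700, 150), seed = 17)
  p <- block_profile_from_sequences(e)
  avg <- average_block_sizes(p, "number")
  expect_equal(avg[["D"]], 1 / 0.33, tolerance = 0.04)
})

test_that("dp_moments and dispersity", {
  m <- dp_moments(chain_ensemble(strrep("D", 100)))
  expect_equal(c(m$DPn, m$DPw, m$dispersity), c(100, 100, 1))
  m2 <- dp_moments(c(100, 300))
  expect_equal(c(m2$DPn, m2$DPw, m2$dispersity), c(200, 250, 1.25))
  # abundance-weighted: 3 x DP100 + 1 x DP300
  m3 <- dp_moments(c(100, 300), abundances = c(3, 1))
  expect_equal(m3$DPn, 150)
})

test_that("bernoulli_theory: geometric blocks, dyads and block frequencies", {
  th <- bernoulli_theory(0.33)
  expect_equal(th$mean_block[["D"]], 1 / 0.33)
  expect_equal(round(th$mean_block[["D"]]), 3)
  expect_equal(th$mean_block[["A"]], 1 / 0.67)

  th1 <- bernoulli_theory(0.1)
  expect_equal(th1$block_frequency(7), 1e-7)
  expect_equal(th1$expected_blocks_per_polymer(7, 1000), 1e-4)

  th5 <- bernoulli_theory(0.5)
  expect_equal(unname(th5$dyads$fractions), rep(0.25, 4))
  expect_equal(p_sigma(th5$dyads), 1)

  # run pmf is a proper geometric distribution
  expect_equal(sum(th$run_pmf(1:500, "A")), 1, tolerance = 1e-10)
  expect_equal(sum((1:500) * th$run_pmf(1:500, "D")), th$mean_block[["D"]],
               tolerance = 1e-6)
  # exact interior block-start probability is (1-p)^2 p^k
  expect_equal(th1$block_frequency(7, method = "interior"), 0.9^2 * 1e-7)

  expect_error(bernoulli_theory(0), "strictly in")
  expect_error(bernoulli_theory(1.2), "strictly in")
})

test_that("p_sigma(bernoulli dyads) is exactly 1 across a fine fa sweep", {
  for (fa in seq(0.02, 0.98, by = 0.04))
    expect_equal(p_sigma(bernoulli_theory(fa)$dyads), 1, tolerance = 1e-12)
})

test_that("dyad-based F_A matches monomer F_A within the end-effect bound", {
  for (seed in c(21, 22)) {
    e <- random_small_ensemble(50, 80, 0.35, seed)
    d <- dyad_fractions(e)
    dpn <- dp_moments(e)$DPn
    expect_lt(abs(d$F_A - compute_fa(e)), 2 / dpn + 1e-12)
  }
})
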