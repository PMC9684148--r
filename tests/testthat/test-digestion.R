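test_that("cleavable_bonds applies subsite rules and occupancy windows", {
  h <- preset_hydrolases()
  # DA/XX: only D5-A6 precedes a bond; the DA at the reducing end has no +1
  expect_equal(cleavable_bonds("AADDDAADDA", h$chitinosanase), 6L)
  expect_equal(cleavable_bonds("DDDDDD", h$chitinosanase), integer(0))
  # lysozyme occupancy bounds: 3 <= j <= DP - 2 on an all-A heptamer
  expect_equal(cleavable_bonds("AAAAAAA", h$lysozyme), c(3L, 4L, 5L))
  # ChiB: cut after any A with an occupied {-2}
  expect_equal(cleavable_bonds("DADAD", h$ChiB), c(2L, 4L))
  expect_equal(cleavable_bonds("AD", h$ChiB), integer(0))
  expect_error(hydrolase_spec("x", allowed = list(), required = character()),
               "at least one subsite")
})

test_that("digest reproduces the toy chitinosanase example exactly", {
  e <- chain_ensemble("AADDDAADDA")
  for (seed in 1:3) {
    p <- digest(e, preset_hydrolases()$chitinosanase, seed = seed)
    expect_equal(p$sequence, c("ADDA", "AADDDA"))
    expect_equal(p$end_flag, c("reducing", "non_reducing"))
    expect_equal(p$n_acetyl, c(2L, 3L))
    expect_equal(p$n_deacetyl, c(2L, 3L))
  }
})

test_that("digestion conserves monomers and acetyl counts exactly", {
  h <- preset_hydrolases()
  ensembles <- list(
    generate_bernoulli(0.3, rep(150, 15), seed = 21),
    generate_markov(markov_pa_spec(0.33, 0.3), rep(150, 15), seed = 22))
  for (e in ensembles) {
    tm <- sum(e$abundances * nchar(e$sequences))
    ta <- sum(e$abundances *
                vapply(gregexpr("A", e$sequences), function(m) sum(m > 0),
                       integer(1)))
    for (nm in names(h)) for (seed in c(1, 99)) {
      p <- digest(e, h[[nm]], seed = seed)
      expect_identical(sum(p$abundance * p$dp), as.numeric(tm))
      expect_identical(sum(p$abundance * p$n_acetyl), as.numeric(ta))
    }
  }
})

test_that("chitinosanase digestion is order-robust (seed-independent)", {
  e <- generate_bernoulli(0.35, rep(120, 20), seed = 30)
  h <- preset_hydrolases()$chitinosanase
  p1 <- digest(e, h, seed = 1)
  p2 <- digest(e, h, seed = 2)
  cols <- c("sequence", "end_flag", "dp", "n_acetyl", "n_deacetyl", "abundance")
  strip <- function(p) {
    a <- data.frame(p[cols])[order(p$sequence, p$end_flag), ]
    rownames(a) <- NULL
    a
  }
  expect_equal(strip(p1), strip(p2))
})

test_that("interior chitinosanase products have the A^(a-1) D^d A form", {
  e <- generate_markov(markov_pa_spec(0.4, 0.7), rep(200, 20), seed = 31)
  p <- digest(e, preset_hydrolases()$chitinosanase, seed = 32)
  interior <- p$sequence[p$end_flag == "interior"]
  expect_gt(length(interior), 0)
  expect_true(all(grepl("^A*D+A$", interior)))
})

test_that("occupancy constraints bound the minimum product size", {
  h <- preset_hydrolases()
  e <- generate_bernoulli(0.5, rep(100, 20), seed = 33)
  for (nm in c("Csn174", "lysozyme")) {
    p <- digest(e, h[[nm]], seed = 34)
    expect_gte(min(p$dp), 2L)
  }
})

test_that("Csn174 reduces long GlcN blocks to dimers and trimers only", {
  e <- generate_bernoulli(0, rep(300, 10))
  p <- digest(e, preset_hydrolases()$Csn174, seed = 35)
  expect_true(all(p$dp %in% 2:3))
  expect_true(all(p$n_acetyl == 0L))
})

test_that("lysozyme leaves only fully-acetylated DP 2-4 from an A-heptamer", {
  e <- chain_ensemble("AAAAAAA")
  for (seed in 1:5) {
    p <- digest(e, preset_hydrolases()$lysozyme, seed = seed)
    expect_true(all(p$n_deacetyl == 0L))
    expect_true(all(p$dp %in% 2:4))
  }
})

test_that("weighted mode only biases order: same limit products as absolute", {
  abs_spec <- preset_hydrolases()$chitinosanase
  soft <- hydrolase_spec("soft", allowed = list(`-2` = "D", `-1` = "A"),
                         required = c("-2", "-1", "+1"),
                         mode = "weighted",
                         weights = list(`+1` = c(A = 5, D = 1)))
  e <- generate_bernoulli(0.35, rep(120, 10), seed = 36)
  p1 <- digest(e, abs_spec, seed = 37)
  p2 <- digest(e, soft, seed = 38)
  k1 <- as.data.frame(p1)[order(p1$sequence, p1$end_flag),
                          c("sequence", "end_flag", "abundance")]
  k2 <- as.data.frame(p2)[order(p2$sequence, p2$end_flag),
                          c("sequence", "end_flag", "abundance")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})
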