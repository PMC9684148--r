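# Shared helpers: ensembles are always built in code, never stored.

# delta-method-ish standard error of a pooled-dyad P_sigma estimate,
# treating the two transition frequencies as independent binomials
p_sigma_se <- function(d) {
  nA <- d$counts[["AA"]] + d$counts[["AD"]]
  nD <- d$counts[["DD"]] + d$counts[["DA"]]
  sqrt(d$P_AD * (1 - d$P_AD) / max(nA, 1)) +
    sqrt(d$P_DA * (1 - d$P_DA) / max(nD, 1))
}

# random mixed-length test ensemble (small chains, both letters guaranteed)
random_small_ensemble <- function(n_chains, max_dp, fa, seed) {
  lens <- with_test_seed(seed, sample(2:max_dp, n_chains, replace = TRUE))
  generate_bernoulli(fa, lens, seed = seed + 1L)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

expect_same_profile <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
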