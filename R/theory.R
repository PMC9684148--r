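#' Closed-form theory for Bernoullian (random) acetylation
#'
#' For an i.i.d. (random-PA) chain with per-residue acetylation probability
#' `fa`, returns the standard copolymer results:
#'
#' * dyad fractions are product-form, `F_XY = F_X * F_Y`, so
#'   `P_sigma = 1` identically;
#' * run (block) lengths are geometric: an A-run continues with probability
#'   `fa` (mean `1 / (1 - fa)`), a D-run with probability `1 - fa`
#'   (mean `1 / fa`) -- e.g. at `fa = 0.33` the mean GlcN block size is
#'   `1/0.33 = 3.03`, rounding to 3;
#' * the simple per-monomer frequency of an A-block of length >= `k`
#'   starting at a given monomer is `fa^k` (e.g. `0.1^7 = 1e-7`: one
#'   heptameric GlcNAc block per 10^7 monomers, or one per 10^4 polymers of
#'   DP 1000). The exact interior-block-start probability
#'   `(1 - fa)^2 * fa^k` is also exposed, clearly labelled.
#'
#' @param fa fraction of acetylation, strictly in `(0, 1)`.
#' @return object of class `bernoulli_theory`: list with
#'   `fa`; `dyads` (a [dyad_stats()]); `mean_block` (named c(A=, D=));
#'   `run_pmf(size, type)` geometric block-length pmf;
#'   `block_frequency(k, type, method)` with `method = "simple"` (`p^k`,
#'   the estimate used for order-of-magnitude block frequencies) or
#'   `"interior"` (`(1-p)^2 p^k`, exact probability that an interior block
#'   of exactly size `k` starts at a given position);
#'   `expected_blocks_per_polymer(k, dp, type, method)`.
#' @examples
#' th <- bernoulli_theory(0.33)
#' th$mean_block[["D"]]                       # 3.03
#' bernoulli_theory(0.1)$block_frequency(7)   # 1e-7
#' @export
bernoulli_theory <- function(fa) {
  if (!is.numeric(fa) || length(fa) != 1L || is.na(fa) || fa <= 0 || fa >= 1)
    stop("fa must lie strictly in (0, 1)", call. = FALSE)
  cont <- function(type) {
    type <- match.arg(type, c("A", "D"))
    if (type == "A") fa else 1 - fa
  }
  block_frequency <- function(k, type = "A", method = c("simple", "interior")) {
    method <- match.arg(method)
    p <- cont(type)
    if (any(k < 1)) stop("block size k must be >= 1", call. = FALSE)
    if (method == "simple") p^k else (1 - p)^2 * p^k
  }
  structure(list(
    fa = fa,
    dyads = dyad_stats(fa^2, fa * (1 - fa), (1 - fa) * fa, (1 - fa)^2),
    mean_block = c(A = 1 / (1 - fa), D = 1 / fa),
    run_pmf = function(size, type = "A") {
      p <- cont(type)
      stats::dgeom(size - 1, prob = 1 - p)
    },
    block_frequency = block_frequency,
    expected_blocks_per_polymer = function(k, dp, type = "A",
                                           method = "simple") {
      dp * block_frequency(k, type, method)
    }
  ), class = "bernoulli_theory")
}

#' @export
print.bernoulli_theory <- function(x, ...) {
  cat(sprintf("Bernoulli (random-PA) theory at F_A = %.3f\n", x$fa))
  cat(sprintf("mean block sizes: A %.2f, D %.2f; P_sigma = 1\n",
              x$mean_block[["A"]], x$mean_block[["D"]]))
  invisible(x)
}
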