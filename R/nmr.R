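#' Simulated 13C-NMR dyad intensities
#'
#' In 13C-NMR dyad analysis the four C-5 resonance peak areas `I_AA, I_AD,
#' I_DA, I_DD` are proportional to the pooled dyad counts of the sample.
#' `simulate_intensities` computes the pooled dyad counts of an ensemble
#' and perturbs each by an independent multiplicative log-normal factor
#' (median 1, coefficient of variation `noise_cv`). The I_AD/I_DA symmetry
#' is not enforced: real integrals differ and the estimator uses them as
#' measured.
#'
#' @param ensemble a [chain_ensemble()] with at least one dyad.
#' @param noise_cv coefficient of variation of the intensity noise
#'   (default 0: intensities exactly proportional to dyad counts).
#' @param seed optional integer seed.
#' @return object of class `dyad_intensities`: named numeric
#'   `c(I_AA, I_AD, I_DA, I_DD)`.
#' @export
simulate_intensities <- function(ensemble, noise_cv = 0, seed = NULL) {
  stopifnot(noise_cv >= 0)
  d <- dyad_fractions(ensemble)
  counts <- d$counts
  with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      counts <- counts * exp(stats::rnorm(4L, mean = 0, sd = sdlog))
    }
    structure(c(I_AA = counts[["AA"]], I_AD = counts[["AD"]],
                I_DA = counts[["DA"]], I_DD = counts[["DD"]]),
              class = "dyad_intensities")
  })
}

#' @export
print.dyad_intensities <- function(x, ...) {
  cat("dyad intensities (a.u.):\n")
  print(unclass(x))
  invisible(x)
}

#' P_sigma and F_A from dyad intensity quadruples
#'
#' Normalises the four peak areas to dyad fractions and computes
#' `P_sigma = I_AD/(I_AA + I_AD) + I_DA/(I_DD + I_DA)` and
#' `F_A = (I_AA + I_AD) / sum(I)`. A degenerate (all-zero) transition
#' denominator contributes 0 with a warning, consistent with
#' [dyad_stats()].
#'
#' @param intensities a `dyad_intensities` object or any numeric vector of
#'   four non-negative areas in the order `I_AA, I_AD, I_DA, I_DD`.
#' @return named numeric `c(P_sigma = , F_A = )`.
#' @examples
#' p_sigma_from_intensities(c(0.2637, 0.0663, 0.0663, 0.6037))
#' @export
p_sigma_from_intensities <- function(intensities) {
  x <- as.numeric(intensities)
  if (length(x) != 4L || any(!is.finite(x)) || any(x < 0))
    stop("need four finite non-negative intensities (I_AA, I_AD, I_DA, I_DD)",
         call. = FALSE)
  if (sum(x) == 0) stop("all-zero intensities", call. = FALSE)
  d <- dyad_stats(x[1], x[2], x[3], x[4])
  c(P_sigma = d$P_sigma, F_A = d$F_A)
}
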