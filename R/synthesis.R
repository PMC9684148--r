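#' Chain-length (DP) distribution specification
#'
#' Chitosan samples are polydisperse; the Schulz--Zimm family (a gamma
#' distribution with shape `z = 1/(dispersity - 1)` and mean `dpn`) is the
#' standard two-moment polymer length model and reproduces a target
#' dispersity `DPw/DPn = (z + 1)/z`.
#'
#' @param family `"fixed"`, `"schulz_zimm"` or `"empirical"`.
#' @param dpn target number-average DP (required for fixed/schulz_zimm).
#' @param dispersity target dispersity `>= 1` (schulz_zimm only).
#' @param min_dp minimum DP after rounding (default 2).
#' @param values DP pool for `family = "empirical"`.
#' @return object of class `dp_spec`.
#' @export
dp_spec <- function(family = c("fixed", "schulz_zimm", "empirical"),
                    dpn = NULL, dispersity = NULL, min_dp = 2,
                    values = NULL) {
  family <- match.arg(family)
  if (family %in% c("fixed", "schulz_zimm")) {
    if (is.null(dpn) || dpn < min_dp)
      stop("dpn must be >= min_dp", call. = FALSE)
  }
  if (family == "schulz_zimm") {
    if (is.null(dispersity) || dispersity < 1)
      stop("dispersity must be >= 1", call. = FALSE)
  }
  if (family == "empirical" && (is.null(values) || length(values) == 0L))
    stop("empirical family needs a non-empty values pool", call. = FALSE)
  structure(list(family = family, dpn = dpn, dispersity = dispersity,
                 min_dp = as.integer(min_dp), values = values),
            class = "dp_spec")
}

#' Sample chain lengths
#'
#' Draws `n` integer DP values from a [dp_spec()]. Schulz--Zimm draws come
#' from a gamma distribution with shape `z = 1/(dispersity - 1)` and mean
#' `dpn`, rounded to the nearest integer and clamped at `min_dp` (rounding
#' bias is negligible at `dpn >= 200`). `dispersity = 1` degenerates to the
#' fixed family.
#'
#' @param spec a [dp_spec()].
#' @param n number of chains, `>= 1`.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of length `n`.
#' @examples
#' sample_lengths(dp_spec("fixed", dpn = 700), 3)
#' @export
sample_lengths <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dp_spec"), n >= 1)
  n <- as.integer(n)
  with_seed(seed, {
    raw <- switch(spec$family,
      fixed = rep(spec$dpn, n),
      schulz_zimm = {
        if (spec$dispersity == 1) rep(spec$dpn, n)
        else {
          z <- 1 / (spec$dispersity - 1)
          stats::rgamma(n, shape = z, scale = spec$dpn / z)
        }
      },
      empirical = sample(spec$values, n, replace = TRUE))
    pmax(as.integer(round(raw)), spec$min_dp)
  })
}

#' Generate a random-PA (Bernoulli) ensemble
#'
#' Residues are i.i.d. with `Pr(A) = fa`: the model of chemically
#' N-acetylated (conventional, random-PA) chitosans.
#'
#' @param fa fraction of acetylation in `[0, 1]`.
#' @param lengths integer vector of chain lengths (one chain each).
#' @param seed optional integer seed.
#' @param id_prefix prefix for chain ids.
#' @return a [chain_ensemble()].
#' @examples
#' e <- generate_bernoulli(0.34, rep(700, 10), seed = 1)
#' compute_fa(e)
#' @export
generate_bernoulli <- function(fa, lengths, seed = NULL,
                               id_prefix = "bernoulli") {
  if (fa < 0 || fa > 1) stop("fa must lie in [0, 1]", call. = FALSE)
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) >= 1L, all(lengths >= 1L))
  with_seed(seed, {
    draws <- stats::runif(sum(lengths)) < fa
    idx <- rep.int(seq_along(lengths), lengths)
    seqs <- vapply(split(draws, idx), .bits_to_string, character(1))
    chain_ensemble(seqs, ids = paste0(id_prefix, "_", seq_along(lengths)))
  })
}

#' First-order Markov PA specification
#'
#' Parameterises a two-state stationary Markov chain by its targets `fa`
#' (stationary fraction of A) and `p_sigma`, via
#' `P_AD = (1 - fa) * p_sigma` and `P_DA = fa * p_sigma`. The feasible
#' range is `0 < p_sigma <= min(1/fa, 1/(1 - fa), 2)`; `p_sigma = 1`
#' recovers the Bernoulli model exactly.
#'
#' @param fa target fraction of acetylation, strictly in `(0, 1)`.
#' @param p_sigma target deviation-from-randomness statistic.
#' @return object of class `markov_pa_spec` with `fa`, `p_sigma`, `P_AD`,
#'   `P_DA`.
#' @export
markov_pa_spec <- function(fa, p_sigma) {
  if (fa <= 0 || fa >= 1) stop("fa must lie strictly in (0, 1)", call. = FALSE)
  bound <- min(1 / fa, 1 / (1 - fa), 2)
  if (p_sigma <= 0 || p_sigma > bound)
    stop(sprintf("p_sigma must lie in (0, %.4f] at fa = %.3f", bound, fa),
         call. = FALSE)
  structure(list(fa = fa, p_sigma = p_sigma,
                 P_AD = (1 - fa) * p_sigma, P_DA = fa * p_sigma),
            class = "markov_pa_spec")
}

#' Generate a Markov (block-wise or regular-leaning) ensemble
#'
#' The first residue of each chain is drawn from the stationary
#' distribution (`Pr(A) = fa`); subsequent residues follow the two-state
#' chain of the [markov_pa_spec()]. Empirical `F_A` and `P_sigma` converge
#' to the targets as the pooled dyad count grows.
#'
#' @param spec a [markov_pa_spec()].
#' @param lengths integer vector of chain lengths.
#' @param seed optional integer seed.
#' @param id_prefix prefix for chain ids.
#' @return a [chain_ensemble()].
#' @examples
#' e <- generate_markov(markov_pa_spec(0.33, 0.3), rep(800, 20), seed = 1)
#' p_sigma(dyad_fractions(e))
#' @export
generate_markov <- function(spec, lengths, seed = NULL,
                            id_prefix = "markov") {
  stopifnot(inherits(spec, "markov_pa_spec"))
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) >= 1L, all(lengths >= 1L))
  n <- length(lengths)
  m <- max(lengths)
  with_seed(seed, {
    state <- matrix(FALSE, nrow = n, ncol = m)
    state[, 1L] <- stats::runif(n) < spec$fa
    if (m >= 2L) for (j in 2:m) {
      pA <- ifelse(state[, j - 1L], 1 - spec$P_AD, spec$P_DA)
      state[, j] <- stats::runif(n) < pA
    }
    seqs <- vapply(seq_len(n), function(i)
      .bits_to_string(state[i, seq_len(lengths[i])]), character(1))
    chain_ensemble(seqs, ids = paste0(id_prefix, "_", seq_len(n)))
  })
}

#' Generate a regular (maximally even) PA ensemble
#'
#' Deterministically places A residues at maximally even spacing: residue
#' `i` is A iff `ceiling(i * fa)` increments at `i`. The achieved `F_A` is
#' within `1/DP` of the target; for `fa <= 0.5` no AA dyad occurs and the
#' resulting `P_sigma` exceeds 1 (regular, anti-block PA). For `fa > 0.5`
#' the symmetric rule is applied with the roles of A and D swapped. No seed
#' is involved: the construction is an exactly reproducible `P_sigma > 1`
#' reference.
#'
#' @param fa target fraction of acetylation, strictly in `(0, 1)`.
#' @param lengths integer vector of chain lengths.
#' @param id_prefix prefix for chain ids.
#' @return a [chain_ensemble()].
#' @examples
#' generate_regular(0.5, 8)$sequences  # "ADADADAD"
#' @export
generate_regular <- function(fa, lengths, id_prefix = "regular") {
  if (fa <= 0 || fa >= 1) stop("fa must lie strictly in (0, 1)", call. = FALSE)
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) >= 1L, all(lengths >= 1L))
  p <- if (fa > 0.5) 1 - fa else fa
  seqs <- vapply(lengths, function(n) {
    i <- seq_len(n)
    hits <- ceiling(i * p) > ceiling((i - 1) * p)
    if (fa > 0.5) hits <- !hits
    .bits_to_string(hits)
  }, character(1))
  chain_ensemble(seqs, ids = paste0(id_prefix, "_", seq_along(lengths)))
}
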