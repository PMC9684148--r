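#' Dyad statistics
#'
#' A dyad is an ordered nearest-neighbour residue pair read along the
#' non-reducing -> reducing direction. `dyad_stats` holds the four dyad
#' fractions `F_AA, F_AD, F_DA, F_DD` together with the derived conditional
#' transition frequencies `P_AD = F_AD / (F_AA + F_AD)`,
#' `P_DA = F_DA / (F_DD + F_DA)`, the deviation-from-randomness statistic
#' `P_sigma = P_AD + P_DA`, and the dyad-based `F_A = F_AA + F_AD`.
#' `P_sigma` is 1 for a Bernoullian (random) PA, below 1 for block-wise PA
#' and approaches 2 for an alternating (regular) PA.
#'
#' When a transition denominator is zero (homopolymer limit) that term is
#' defined as 0 and a warning is issued, keeping the statistic total on
#' degenerate inputs.
#'
#' @param F_AA,F_AD,F_DA,F_DD non-negative dyad counts or fractions;
#'   normalised internally.
#' @return an object of class `dyad_stats`: list with `fractions` (named
#'   numeric of length 4), `P_AD`, `P_DA`, `P_sigma`, `F_A`, and `counts`
#'   (the unnormalised input).
#' @examples
#' d <- dyad_stats(0.2637, 0.0663, 0.0663, 0.6037)
#' d$P_sigma  # ~0.30, a strongly block-wise PA
#' @export
dyad_stats <- function(F_AA, F_AD, F_DA, F_DD) {
  counts <- c(AA = F_AA, AD = F_AD, DA = F_DA, DD = F_DD)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("dyad counts/fractions must be finite and >= 0", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("no dyads", call. = FALSE)
  f <- counts / tot
  denA <- f[["AA"]] + f[["AD"]]
  denD <- f[["DD"]] + f[["DA"]]
  p_ad <- if (denA > 0) f[["AD"]] / denA else {
    warning("no A-initial dyads; P_AD set to 0", call. = FALSE); 0
  }
  p_da <- if (denD > 0) f[["DA"]] / denD else {
    warning("no D-initial dyads; P_DA set to 0", call. = FALSE); 0
  }
  structure(list(fractions = f, counts = counts,
                 P_AD = p_ad, P_DA = p_da,
                 P_sigma = p_ad + p_da, F_A = denA),
            class = "dyad_stats")
}

#' @export
print.dyad_stats <- function(x, ...) {
  cat(sprintf("dyad fractions: AA %.4f  AD %.4f  DA %.4f  DD %.4f\n",
              x$fractions[["AA"]], x$fractions[["AD"]],
              x$fractions[["DA"]], x$fractions[["DD"]]))
  cat(sprintf("P_AD = %.4f, P_DA = %.4f, P_sigma = %.4f, F_A(dyad) = %.4f\n",
              x$P_AD, x$P_DA, x$P_sigma, x$F_A))
  invisible(x)
}

#' Pooled dyad fractions of an ensemble
#'
#' Counts dyads within each chain (a chain of DP `n` contributes `n - 1`
#' dyads; dyads never span chains), pools them across the ensemble weighted
#' by chain abundance, and returns the normalised [dyad_stats()]. This
#' mirrors NMR dyad integration, which averages over molecules.
#'
#' @param ensemble a [chain_ensemble()]; at least one chain must have
#'   DP >= 2.
#' @return a [dyad_stats()] object.
#' @examples
#' dyad_fractions(chain_ensemble("ADAD"))$P_sigma  # 2 (alternating limit)
#' @export
dyad_fractions <- function(ensemble) {
  .assert_ensemble(ensemble)
  counts <- c(AA = 0, AD = 0, DA = 0, DD = 0)
  bits <- .chain_bits(ensemble$sequences)
  for (i in seq_along(bits)) {
    b <- bits[[i]]
    n <- length(b)
    if (n < 2L) next
    x <- b[-n]; y <- b[-1L]
    w <- ensemble$abundances[i]
    counts[["AA"]] <- counts[["AA"]] + w * sum(x & y)
    counts[["AD"]] <- counts[["AD"]] + w * sum(x & !y)
    counts[["DA"]] <- counts[["DA"]] + w * sum(!x & y)
    counts[["DD"]] <- counts[["DD"]] + w * sum(!x & !y)
  }
  if (sum(counts) == 0) stop("no dyads", call. = FALSE)
  dyad_stats(counts[["AA"]], counts[["AD"]], counts[["DA"]], counts[["DD"]])
}

#' P_sigma deviation-from-randomness statistic
#'
#' `P_sigma = F_AD/(F_AA + F_AD) + F_DA/(F_DD + F_DA)`. Equals 1 for a
#' random (Bernoullian) PA, < 1 for block-wise PA, and 2 in the alternating
#' limit.
#'
#' @param dyads a [dyad_stats()] object, or a [chain_ensemble()] (dyads are
#'   then pooled first).
#' @return numeric `P_sigma` in `[0, 2]`.
#' @export
p_sigma <- function(dyads) {
  if (inherits(dyads, "chain_ensemble")) dyads <- dyad_fractions(dyads)
  if (!inherits(dyads, "dyad_stats"))
    stop("expected dyad_stats or chain_ensemble", call. = FALSE)
  denA <- dyads$fractions[["AA"]] + dyads$fractions[["AD"]]
  denD <- dyads$fractions[["DD"]] + dyads$fractions[["DA"]]
  if (denA == 0 && denD == 0) stop("degenerate composition", call. = FALSE)
  dyads$P_sigma
}
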