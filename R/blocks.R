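#' Block-size profiles
#'
#' A block is a maximal run of identical residues (an A-block of GlcNAc or a
#' D-block of GlcN). A `block_profile` stores abundance-weighted molar
#' counts of blocks per (type, size), with blocks touching a chain end
#' tracked separately via a `terminal` flag: end blocks are censored by the
#' chain terminus and are excluded from averages by default.
#'
#' @param df data frame with columns `type` ("A"/"D"), `size` (>= 1),
#'   `terminal` (logical), `count` (>= 0).
#' @return object of class `block_profile` (a data frame, aggregated and
#'   ordered by type, size, terminal).
#' @export
block_profile <- function(df) {
  stopifnot(all(c("type", "size", "terminal", "count") %in% names(df)))
  if (nrow(df) == 0L) stop("empty block profile", call. = FALSE)
  if (any(df$size < 1L)) stop("block sizes must be >= 1", call. = FALSE)
  if (any(df$count < 0)) stop("block counts must be >= 0", call. = FALSE)
  key <- paste(df$type, df$size, df$terminal, sep = "\r")
  agg <- rowsum(df$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(type = vapply(parts, `[`, "", 1L),
                    size = as.integer(vapply(parts, `[`, "", 2L)),
                    terminal = as.logical(vapply(parts, `[`, "", 3L)),
                    count = agg[, 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$type, out$size, out$terminal), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("block_profile", "data.frame")
  out
}

#' @export
print.block_profile <- function(x, ...) {
  cat("block_profile:\n")
  print.data.frame(x)
  invisible(x)
}

#' Block profile by direct run-length decomposition
#'
#' Decomposes every chain into maximal runs of identical residues and counts
#' them abundance-weighted. Runs touching a chain end (the first and last
#' run of each chain) are flagged `terminal`. Monomers are conserved
#' exactly: `sum(size * count)` over the full profile equals the ensemble's
#' total monomer count. Serves as the brute-force oracle for
#' [infer_block_profile()].
#'
#' @param ensemble a [chain_ensemble()].
#' @return a [block_profile()].
#' @examples
#' block_profile_from_sequences(chain_ensemble("AADDDA"))
#' @export
block_profile_from_sequences <- function(ensemble) {
  .assert_ensemble(ensemble)
  pieces <- vector("list", length(ensemble$sequences))
  for (i in seq_along(ensemble$sequences)) {
    r <- rle(strsplit(ensemble$sequences[i], "", fixed = TRUE)[[1]])
    k <- length(r$lengths)
    term <- rep(FALSE, k); term[1L] <- TRUE; term[k] <- TRUE
    pieces[[i]] <- data.frame(type = r$values, size = r$lengths,
                              terminal = term,
                              count = ensemble$abundances[i],
                              stringsAsFactors = FALSE)
  }
  block_profile(do.call(rbind, pieces))
}

#' Number- and weight-average block sizes
#'
#' Number average `sum(s * n_s) / sum(n_s)`; weight average
#' `sum(s^2 * n_s) / sum(s * n_s)` (the default, matching weight-average
#' block sizes as reported by EMS fingerprinting). Terminal (censored)
#' blocks are excluded unless `include_terminal = TRUE`.
#'
#' @param profile a [block_profile()].
#' @param kind `"weight"` (default) or `"number"`.
#' @param include_terminal include end blocks in the averages?
#' @return named numeric: average size for each block type present.
#' @examples
#' p <- block_profile(data.frame(type = "A", size = c(1, 3),
#'                               terminal = FALSE, count = 1))
#' average_block_sizes(p, "number")  # 2
#' average_block_sizes(p, "weight")  # 2.5
#' @export
average_block_sizes <- function(profile, kind = c("weight", "number"),
                                include_terminal = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(profile, "block_profile"))
  p <- if (include_terminal) profile else profile[!profile$terminal, , drop = FALSE]
  if (nrow(p) == 0L || sum(p$count) == 0) stop("empty block profile", call. = FALSE)
  out <- vapply(sort(unique(p$type)), function(ty) {
    q <- p[p$type == ty, , drop = FALSE]
    if (sum(q$count) == 0) return(NA_real_)
    if (kind == "number") sum(q$size * q$count) / sum(q$count)
    else sum(q$size^2 * q$count) / sum(q$size * q$count)
  }, numeric(1))
  out
}

#' Compare two block-size profiles
#'
#' Normalises each profile to per-type block-size frequencies and returns
#' per-size frequency differences `delta = f_sample - f_reference` together
#' with the total-variation distance per block type.
#'
#' @param sample,reference [block_profile()] objects.
#' @param include_terminal include end blocks? default `FALSE`.
#' @return list with `delta` (data frame: type, size, f_sample,
#'   f_reference, delta) and `tv` (named numeric, total-variation distance
#'   per type).
#' @export
compare_profiles <- function(sample, reference, include_terminal = FALSE) {
  freq <- function(p) {
    q <- if (include_terminal) p else p[!p$terminal, , drop = FALSE]
    q <- stats::aggregate(count ~ type + size, data = q, FUN = sum)
    tot <- stats::ave(q$count, q$type, FUN = sum)
    q$f <- q$count / tot
    q[, c("type", "size", "f")]
  }
  fs <- freq(sample); fr <- freq(reference)
  m <- merge(fs, fr, by = c("type", "size"), all = TRUE,
             suffixes = c("_sample", "_reference"))
  m$f_sample[is.na(m$f_sample)] <- 0
  m$f_reference[is.na(m$f_reference)] <- 0
  m$delta <- m$f_sample - m$f_reference
  m <- m[order(m$type, m$size), , drop = FALSE]
  rownames(m) <- NULL
  tv <- vapply(sort(unique(m$type)), function(ty)
    0.5 * sum(abs(m$delta[m$type == ty])), numeric(1))
  list(delta = m, tv = tv)
}
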