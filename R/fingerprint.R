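#' Normalise product abundances over a DP window
#'
#' EMS fingerprinting quantifies hydrolysis products of DP 2--10;
#' `normalize_window` rescales the molar abundances of products within
#' `[dp_min, dp_max]` to sum to 1 (column `fraction`) and flags products
#' outside the window as excluded (`in_window = FALSE`, `fraction = NA`)
#' while retaining them.
#'
#' @param products a [product_table()].
#' @param dp_min,dp_max DP window bounds (defaults 2 and 10).
#' @return the product table with added `in_window` and `fraction` columns
#'   and a `window` attribute.
#' @export
normalize_window <- function(products, dp_min = 2, dp_max = 10) {
  stopifnot(inherits(products, "product_table"))
  inw <- products$dp >= dp_min & products$dp <= dp_max
  if (!any(inw)) stop("no products in DP window", call. = FALSE)
  tot <- sum(products$abundance[inw])
  products$in_window <- inw
  products$fraction <- ifelse(inw, products$abundance / tot, NA_real_)
  attr(products, "window") <- c(dp_min = dp_min, dp_max = dp_max)
  products
}

#' EMS-fingerprint estimate of the substrate F_A
#'
#' Monomer-weighted estimate over the DP window:
#' `sum(x_p * nA_p) / sum(x_p * dp_p)` with `x_p` the windowed mole
#' fractions. Monomer weighting (rather than per-product averaging)
#' reduces small-DP composition bias. With `dp_min = 1, dp_max = Inf`
#' (no window) the estimate equals the substrate [compute_fa()] exactly,
#' by conservation.
#'
#' @param products a [product_table()].
#' @param dp_min,dp_max DP window (defaults 2 and 10; use `1` and `Inf`
#'   for the unrestricted conservation identity).
#' @return estimated `F_A` in `[0, 1]`.
#' @export
estimate_fa <- function(products, dp_min = 2, dp_max = 10) {
  stopifnot(inherits(products, "product_table"))
  inw <- products$dp >= dp_min & products$dp <= dp_max
  if (!any(inw)) stop("no products in DP window", call. = FALSE)
  ab <- products$abundance[inw]
  sum(ab * products$n_acetyl[inw]) / sum(ab * products$dp[inw])
}

#' Infer the substrate block-size profile from chitinosanase products
#'
#' The chitinosanase DA/XX rule (cleave after every A preceded by a D)
#' implies the structural lemma: every interior product has the form
#' `A^(a-1) D^d A` with `a = n_acetyl`, `d = n_deacetyl`, where the leading
#' `A^(a-1)` run together with the trailing A donated by the preceding
#' product reconstitutes an A-block of size exactly `a`, and the D-run of
#' size `d` is an intact D-block. Each interior product therefore
#' contributes one A-block of size `a` and one D-block of size `d`.
#'
#' End handling: the non-reducing-terminal product's leading run is a
#' complete but end-censored block (flagged terminal); the
#' reducing-terminal product's trailing run after its last D-run is flagged
#' terminal likewise. Terminal blocks are excluded from averages by default
#' (see [average_block_sizes()]).
#'
#' When explicit product sequences are available (the default for tables
#' produced by [digest()]) the reconstruction is exact: for a complete,
#' unwindowed chitinosanase digest the inferred profile equals
#' [block_profile_from_sequences()] of the substrate, block for block.
#' Without sequences, products are reconstructed from composition via the
#' lemma's canonical form (`A^(a-1) D^d A`; intact chains as `A^a D^d`,
#' with a warning).
#'
#' @param products a [product_table()] generated under the chitinosanase
#'   rule (checked via provenance unless `check_provenance = FALSE`).
#' @param check_provenance error when the recorded enzyme is not the
#'   chitinosanase preset? Default `TRUE`.
#' @return a [block_profile()].
#' @export
infer_block_profile <- function(products, check_provenance = TRUE) {
  stopifnot(inherits(products, "product_table"))
  enz <- attr(products, "enzyme")
  if (check_provenance && (is.na(enz) || enz != "chitinosanase"))
    stop(sprintf("products were generated by '%s', not chitinosanase; use check_provenance = FALSE to override",
                 enz), call. = FALSE)
  pieces <- vector("list", nrow(products))
  for (i in seq_len(nrow(products))) {
    flag <- products$end_flag[i]
    a <- products$n_acetyl[i]; d <- products$n_deacetyl[i]
    if (check_provenance && flag == "interior" && (a == 0L || d == 0L))
      stop("inconsistent with DA/XX provenance: interior product lacks A or D",
           call. = FALSE)
    s <- products$sequence[i]
    if (is.na(s)) {
      if (flag == "intact") {
        warning("intact product without sequence: assuming form A^a D^d",
                call. = FALSE)
        s <- paste0(strrep("A", a), strrep("D", d))
      } else {
        s <- paste0(strrep("A", max(a - 1L, 0L)), strrep("D", d),
                    if (a >= 1L) "A" else "")
      }
    }
    # stitch across cleavage sites: a preceding cut donates its trailing A
    # to this product; a following cut borrows this product's trailing A
    if (flag %in% c("interior", "reducing")) s <- paste0("A", s)
    if (flag %in% c("interior", "non_reducing"))
      s <- substr(s, 1L, nchar(s) - 1L)
    if (nchar(s) == 0L) next
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    k <- length(r$lengths)
    term <- rep(FALSE, k)
    if (flag %in% c("non_reducing", "intact")) term[1L] <- TRUE
    if (flag %in% c("reducing", "intact")) term[k] <- TRUE
    pieces[[i]] <- data.frame(type = r$values, size = r$lengths,
                              terminal = term, count = products$abundance[i],
                              stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) stop("no blocks inferable", call. = FALSE)
  block_profile(do.call(rbind, pieces))
}

#' Apply multiplicative measurement noise to product abundances
#'
#' Emulates semi-quantitative MS abundances: each abundance is multiplied
#' by an independent log-normal factor with median 1 and coefficient of
#' variation `cv`, then the table is re-normalised to its original total.
#' The result is flagged `noisy` so conservation checks are skipped.
#'
#' @param products a [product_table()].
#' @param cv coefficient of variation of the noise factors (`>= 0`;
#'   `cv = 0` is the identity).
#' @param seed optional integer seed.
#' @return a noisy [product_table()].
#' @export
add_ms_noise <- function(products, cv, seed = NULL) {
  stopifnot(inherits(products, "product_table"), cv >= 0)
  if (cv == 0) return(products)
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    fac <- exp(stats::rnorm(nrow(products), mean = 0, sd = sdlog))
    tot <- sum(products$abundance)
    products$abundance <- products$abundance * fac
    products$abundance <- products$abundance * tot / sum(products$abundance)
  })
  attr(products, "noisy") <- TRUE
  products
}
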