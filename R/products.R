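#' Oligomer product tables
#'
#' A `product_table` is the in-silico analogue of a semi-quantitative MS
#' oligomer fingerprint: one row per distinct product species with its DP,
#' acetyl (`n_acetyl` = GlcNAc) and deacetyl (`n_deacetyl` = GlcN) counts,
#' end flag (`non_reducing`, `interior`, `reducing`, or `intact`), molar
#' abundance and, optionally, its explicit sequence. Provenance (substrate
#' id, enzyme, seed, substrate totals, number of cleavage events) is
#' carried in attributes and used to re-validate monomer conservation.
#'
#' @param df data frame with columns `dp`, `n_acetyl`, `n_deacetyl`,
#'   `end_flag`, `abundance` and optionally `sequence`.
#' @param substrate_id,enzyme,seed provenance fields (may be `NA`).
#' @param total_monomers,total_acetyl substrate totals for conservation
#'   checks (may be `NA`).
#' @param n_cuts number of cleavage events that produced the table.
#' @param noisy logical; `TRUE` after measurement noise has been applied
#'   (conservation checks are then skipped).
#' @return object of class `product_table` (a data frame).
#' @export
product_table <- function(df, substrate_id = NA_character_,
                          enzyme = NA_character_, seed = NA_integer_,
                          total_monomers = NA_real_, total_acetyl = NA_real_,
                          n_cuts = NA_integer_, noisy = FALSE) {
  req <- c("dp", "n_acetyl", "n_deacetyl", "end_flag", "abundance")
  if (!all(req %in% names(df)))
    stop("product table needs columns dp, n_acetyl, n_deacetyl, end_flag, abundance",
         call. = FALSE)
  if (!"sequence" %in% names(df)) df$sequence <- NA_character_
  df <- df[, c(req, "sequence"), drop = FALSE]
  for (i in seq_len(nrow(df))) {
    if (df$dp[i] != df$n_acetyl[i] + df$n_deacetyl[i])
      stop(sprintf("row %d: dp (%d) != n_acetyl + n_deacetyl (%d)",
                   i, df$dp[i], df$n_acetyl[i] + df$n_deacetyl[i]),
           call. = FALSE)
    if (!is.finite(df$abundance[i]) || df$abundance[i] <= 0)
      stop(sprintf("row %d: abundance must be > 0", i), call. = FALSE)
  }
  ok_flags <- c("non_reducing", "interior", "reducing", "intact")
  if (!all(df$end_flag %in% ok_flags))
    stop("end_flag must be one of non_reducing, interior, reducing, intact",
         call. = FALSE)
  rownames(df) <- NULL
  structure(df,
            substrate_id = substrate_id, enzyme = enzyme, seed = seed,
            total_monomers = total_monomers, total_acetyl = total_acetyl,
            n_cuts = n_cuts, noisy = noisy,
            class = c("product_table", "data.frame"))
}

#' @export
print.product_table <- function(x, ...) {
  cat(sprintf("product_table: %d species, enzyme = %s, %s cleavage events\n",
              nrow(x), attr(x, "enzyme"),
              ifelse(is.na(attr(x, "n_cuts")), "?", attr(x, "n_cuts"))))
  print.data.frame(x)
  invisible(x)
}

# validate monomer and acetyl conservation against recorded substrate totals
.check_conservation <- function(products, tol = 1e-8) {
  if (isTRUE(attr(products, "noisy"))) return(invisible(TRUE))
  tm <- attr(products, "total_monomers")
  ta <- attr(products, "total_acetyl")
  if (!is.na(tm)) {
    got <- sum(products$abundance * products$dp)
    if (abs(got - tm) > tol * max(1, tm))
      stop(sprintf("monomer conservation violated: products carry %.6g of %.6g monomers",
                   got, tm), call. = FALSE)
  }
  if (!is.na(ta)) {
    got <- sum(products$abundance * products$n_acetyl)
    if (abs(got - ta) > tol * max(1, ta))
      stop(sprintf("acetyl conservation violated: products carry %.6g of %.6g A units",
                   got, ta), call. = FALSE)
  }
  invisible(TRUE)
}
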