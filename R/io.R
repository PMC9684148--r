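#' Read and write chain ensembles as FASTA
#'
#' FASTA records over the alphabet `{A, D}` (case-insensitive on read,
#' upper-case on write). The header carries the chain id followed by
#' optional whitespace-separated `key=value` metadata; a non-unit abundance
#' is round-tripped via an `ab=` key, and [write_sequences()] can embed
#' further provenance keys (e.g. `fa=`, `pa=`, `seed=`).
#'
#' @param path file path.
#' @return `read_sequences`: a [chain_ensemble()] (header metadata in the
#'   `metadata` attribute); `write_sequences`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_sequences(chain_ensemble(c("AADDA", "DDD")), f)
#' read_sequences(f)
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty ensemble", call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^AD]", seqs[[i]])
    if (bad > 0L)
      stop(sprintf("invalid character '%s' in record '%s' at position %d",
                   substr(seqs[[i]], bad, bad),
                   sub("\\s.*", "", names(set)[i]), bad), call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*", "", headers)
  meta <- lapply(headers, .parse_header_meta)
  ab <- vapply(meta, function(m) {
    if (!is.null(m[["ab"]])) as.numeric(m[["ab"]]) else 1
  }, numeric(1))
  e <- chain_ensemble(seqs, ids = ids, abundances = ab)
  attr(e, "metadata") <- meta
  e
}

.parse_header_meta <- function(header) {
  toks <- strsplit(header, "\\s+")[[1]][-1]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  if (length(toks) == 0L) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                  vapply(kv, `[`, "", 1L))
}

#' @param ensemble a [chain_ensemble()].
#' @param metadata optional named list (or list of named lists, one per
#'   chain) of `key=value` pairs to embed in headers.
#' @rdname read_sequences
#' @export
write_sequences <- function(ensemble, path, metadata = NULL) {
  .assert_ensemble(ensemble)
  headers <- ensemble$ids
  for (i in seq_along(headers)) {
    kv <- character(0)
    if (ensemble$abundances[i] != 1)
      kv <- c(kv, paste0("ab=", format(ensemble$abundances[i], digits = 15)))
    m <- if (is.null(metadata)) NULL
         else if (!is.null(names(metadata))) metadata else metadata[[i]]
    if (length(m))
      kv <- c(kv, paste0(names(m), "=", vapply(m, as.character, "")))
    if (length(kv)) headers[i] <- paste(headers[i], paste(kv, collapse = " "))
  }
  set <- Biostrings::BStringSet(ensemble$sequences)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write product tables as CSV
#'
#' Columns `dp, n_acetyl, n_deacetyl, end_flag, abundance, sequence`
#' (sequence optional). Provenance is written as `# key: value` comment
#' lines and restored on read; when substrate totals are present and the
#' table is not flagged noisy, monomer and acetyl conservation are
#' re-validated.
#'
#' @param path file path.
#' @return `read_products`: a [product_table()]; `write_products`: `path`,
#'   invisibly.
#' @export
read_products <- function(path) {
  all_lines <- readLines(path)
  is_comment <- grepl("^#", all_lines)
  meta <- list()
  for (ln in all_lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.csv(text = paste(all_lines[!is_comment], collapse = "\n"),
                        stringsAsFactors = FALSE)
  req <- c("dp", "n_acetyl", "n_deacetyl", "end_flag", "abundance")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  tab <- product_table(df,
    substrate_id = meta[["substrate_id"]] %||% NA_character_,
    enzyme = meta[["enzyme"]] %||% NA_character_,
    seed = as.integer(num_or_na(meta[["seed"]])),
    total_monomers = num_or_na(meta[["total_monomers"]]),
    total_acetyl = num_or_na(meta[["total_acetyl"]]),
    n_cuts = as.integer(num_or_na(meta[["n_cuts"]])),
    noisy = identical(meta[["noisy"]], "TRUE"))
  .check_conservation(tab)
  tab
}

#' @param products a [product_table()].
#' @rdname read_products
#' @export
write_products <- function(products, path) {
  stopifnot(inherits(products, "product_table"))
  meta <- c(tool = paste0("chitopa ",
                          as.character(utils::packageVersion("chitopa"))),
            substrate_id = attr(products, "substrate_id"),
            enzyme = attr(products, "enzyme"),
            seed = attr(products, "seed"),
            total_monomers = attr(products, "total_monomers"),
            total_acetyl = attr(products, "total_acetyl"),
            n_cuts = attr(products, "n_cuts"),
            noisy = attr(products, "noisy"))
  meta <- meta[!is.na(meta)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", meta), con)
  cols <- intersect(c("dp", "n_acetyl", "n_deacetyl", "end_flag",
                      "abundance", "sequence", "in_window", "fraction"),
                    names(products))
  utils::write.csv(as.data.frame(products)[, cols, drop = FALSE],
                   con, row.names = FALSE)
  invisible(path)
}

#' Read an enzyme definition config
#'
#' Reads a JSON enzyme definition (single spec with a `type` field of
#' `"deacetylase"` or `"hydrolase"`, or a named collection of such specs;
#' see the shipped presets under
#' `system.file("extdata/enzymes", package = "chitopa")` for the format).
#'
#' @param path JSON file path.
#' @return a [deacetylase_spec()]/[hydrolase_spec()], or a named list of
#'   them for collection files.
#' @export
read_enzyme_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  build <- function(name, entry) {
    switch(entry$type %||% stop("enzyme entry lacks a type field", call. = FALSE),
           deacetylase = .deacetylase_from_config(name, entry),
           hydrolase = .hydrolase_from_config(name, entry),
           stop(sprintf("unknown enzyme type '%s'", entry$type), call. = FALSE))
  }
  if (!is.null(cfg$type))
    return(build(cfg$name %||% sub("\\.json$", "", basename(path)), cfg))
  out <- lapply(names(cfg), function(nm) build(nm, cfg[[nm]]))
  names(out) <- names(cfg)
  out
}

# resolve an enzyme by preset name or config path
.resolve_enzyme <- function(x, kind = c("hydrolase", "deacetylase")) {
  kind <- match.arg(kind)
  if (inherits(x, paste0(kind, "_spec"))) return(x)
  presets <- if (kind == "hydrolase") preset_hydrolases() else preset_deacetylases()
  if (is.character(x) && length(x) == 1L) {
    if (x %in% names(presets)) return(presets[[x]])
    if (file.exists(x)) return(read_enzyme_config(x))
  }
  stop(sprintf("cannot resolve %s '%s' (not a preset name or config path)",
               kind, as.character(x)), call. = FALSE)
}
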