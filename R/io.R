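#' Read and write count tables as TSV
#'
#' The on-disk dialect has features as rows and samples as columns, with the
#' first column `feature_id`; in memory tables are samples x features tibbles
#' with a `sample_id` first column.
#'
#' @param counts Samples x features tibble.
#' @param path File path.
#' @return `read_counts_tsv()` returns the samples x features tibble;
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  m <- t(counts_matrix(counts))
  df <- dplyr::bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- t(as.matrix(df[-1]))
  colnames(m) <- df[[1]]
  matrix_to_tibble(m)
}

#' Read and write a strain panel as FASTA
#'
#' One record per strain; headers are `strain_id|host_of_origin|family`.
#'
#' @param panel Strain panel tibble.
#' @param path FASTA file path.
#' @return `read_panel_fasta()` returns a panel tibble (the `species` column
#'   is not stored in FASTA and comes back as `NA`).
#' @export
write_panel_fasta <- function(panel, path) {
  validate_panel(panel)
  dna <- Biostrings::DNAStringSet(stats::setNames(
    panel$ref_seq,
    paste(panel$strain_id, panel$host_of_origin, panel$family, sep = "|")))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(dna), stringr::fixed("|"), 3)
  panel <- tibble(strain_id = parts[, 1], host_of_origin = parts[, 2],
                  family = parts[, 3], species = NA_character_,
                  ref_seq = unname(as.character(dna)))
  validate_panel(panel)
  panel
}

#' Read and write sample metadata as TSV
#' @param metadata Metadata tibble (one row per sample).
#' @param path File path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write and read flat key-value text files
#'
#' Serializes a flat named list (e.g. a simulation's ground-truth parameters)
#' as `key: value` lines; values round-trip with full double precision.
#'
#' @param x Named list of scalars (numeric, logical or character).
#' @param path File path.
#' @return `read_truth()` returns the named list with numeric/logical values
#'   restored.
#' @export
write_truth <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, "")
  writeLines(paste0(names(x), ": ", vals), path)
  invisible(path)
}

parse_kv_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  parse_one <- function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  stats::setNames(lapply(vals, parse_one), keys)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  parse_kv_lines(readLines(path))
}

#' Read a plain-text configuration file
#'
#' `key: value` lines naming a simulation design and effect sizes (depth,
#' seed, phi_root, pi_priority, ...). Comments (`#`) and blank lines are
#' ignored.
#'
#' @param path File path.
#' @return Named list with numeric values parsed.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  parse_kv_lines(lines[!grepl("^\\s*#", lines)])
}

#' Read and write a culture-plate well table as TSV
#'
#' On disk: rows are OTUs, columns are `plate:well` identifiers, first
#' column `otu_id`. In memory: wells x OTUs tibble with `well_id` first.
#'
#' @param wells Well table tibble.
#' @param path File path.
#' @export
write_well_tsv <- function(wells, path) {
  m <- t(counts_matrix(wells, id_col = "well_id"))
  df <- dplyr::bind_cols(tibble(otu_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_well_tsv
#' @export
read_well_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- t(as.matrix(df[-1]))
  colnames(m) <- df[[1]]
  matrix_to_tibble(m, id_col = "well_id")
}
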