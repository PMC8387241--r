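#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Derive a child seed from a top-level seed and a sub-stream index, so each
# module draws from an independently reproducible stream. Kept < 2^31 - 1.
child_seed <- function(seed, index) {
  (as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x %% 1 != 0 || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must be a fraction in %s%g, %g%s.",
                         name, if (open_lo) "(" else "[", lo, hi,
                         if (open_hi) ")" else "]"))
  as.double(x)
}

# Draw one Dirichlet-multinomial sample: a multinomial of size `depth` whose
# probabilities are Dirichlet with mean `p` and concentration `conc`.
# conc = Inf collapses to a plain multinomial.
rdirmultinom <- function(depth, p, conc) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  if (is.finite(conc)) {
    g <- stats::rgamma(length(p), shape = conc * p, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1
    p <- g / sum(g)
  }
  as.integer(stats::rmultinom(1, size = depth, prob = p))
}

# samples-by-features tibble (first column sample_id) -> integer/double matrix
counts_matrix <- function(tbl, id_col = "sample_id") {
  stopifnot(is.data.frame(tbl), id_col %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- as.character(tbl[[id_col]])
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m, id_col = "sample_id") {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

validate_count_table <- function(tbl, id_col = "sample_id") {
  m <- counts_matrix(tbl, id_col)
  if (anyDuplicated(rownames(m))) abort("Duplicate sample ids in count table.")
  if (anyDuplicated(colnames(m))) abort("Duplicate feature ids in count table.")
  if (any(m < 0) || any(m %% 1 != 0)) abort("Counts must be non-negative integers.")
  invisible(tbl)
}

validate_panel <- function(panel) {
  need <- c("strain_id", "host_of_origin", "family", "ref_seq")
  if (!is.data.frame(panel) || !all(need %in% names(panel))) {
    abort("`panel` must be a data frame with columns strain_id, host_of_origin, family, ref_seq.")
  }
  if (anyDuplicated(panel$strain_id)) abort("Strain ids must be unique.")
  if (nrow(panel) > 0) {
    if (any(!nzchar(panel$ref_seq)) ||
        any(grepl("[^ACGT]", panel$ref_seq))) {
      abort("Every strain needs a non-empty reference sequence over {A,C,G,T}.")
    }
    if (!all(panel$host_of_origin %in% c("Lj", "At"))) {
      abort("`host_of_origin` must be 'Lj' or 'At'.")
    }
  }
  invisible(panel)
}
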