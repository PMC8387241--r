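#' Extract a primer-delimited amplicon from a template sequence
#'
#' In-silico PCR with degenerate primers: finds the leftmost exact
#' (zero-mismatch, IUPAC-aware) match of the forward primer, then the
#' leftmost match of the reverse-complemented reverse primer downstream of
#' it, and returns the template region spanning both primer binding sites.
#' The defaults are the v5-v7 16S primers 799F/1192R.
#'
#' @param template Template nucleotide string over `{A,C,G,T,N}` (a genome
#'   contig or full-length 16S sequence).
#' @param forward,reverse Primer sequences 5'->3' (the reverse primer as read
#'   on the opposite strand), IUPAC degenerate codes allowed.
#' @param max_len Maximum amplicon length accepted (error beyond it).
#'
#' @return The amplicon substring, primers included.
#' @examples
#' tpl <- paste0("GGGG", "AACAGGATTAGATACCCTG", strrep("ACGT", 75),
#'               as.character(Biostrings::reverseComplement(
#'                 Biostrings::DNAString("ACGTCATCCCCACCTTCC"))), "TTTT")
#' nchar(extract_amplicon(tpl))
#' @export
extract_amplicon <- function(template,
                             forward = "AACMGGATTAGATACCCKG",
                             reverse = "ACGTCATCCCCACCTTCC",
                             max_len = 2000) {
  if (!is.character(template) || length(template) != 1 || !nzchar(template)) {
    abort("`template` must be a single non-empty nucleotide string.")
  }
  if (grepl("[^ACGTN]", template)) {
    abort("`template` must be over {A,C,G,T,N}.")
  }
  tpl <- Biostrings::DNAString(template)
  fwd_hits <- Biostrings::matchPattern(Biostrings::DNAString(forward), tpl,
                                       fixed = FALSE)
  if (length(fwd_hits) == 0) {
    abort("No amplicon: forward primer has no match in the template.",
          class = "syncomstats_no_amplicon")
  }
  f_start <- min(Biostrings::start(fwd_hits))
  rc_rev <- Biostrings::reverseComplement(Biostrings::DNAString(reverse))
  rev_hits <- Biostrings::matchPattern(rc_rev, tpl, fixed = FALSE)
  f_idx <- which(Biostrings::start(fwd_hits) == f_start)
  f_end <- Biostrings::end(fwd_hits)[f_idx[1]]
  down <- Biostrings::start(rev_hits) > f_end
  if (!any(down)) {
    abort("No amplicon: reverse primer has no match downstream of the forward primer.",
          class = "syncomstats_no_amplicon")
  }
  r_end <- min(Biostrings::end(rev_hits)[down])
  if (r_end - f_start + 1 > max_len) {
    abort(sprintf("No amplicon: span %d exceeds `max_len` = %d.",
                  r_end - f_start + 1, max_len),
          class = "syncomstats_no_amplicon")
  }
  substr(template, f_start, r_end)
}

read_sample_reads <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("sample_id", "fastq") %in% names(reads)))
    paths <- stats::setNames(reads$fastq, reads$sample_id)
  } else if (is.character(reads) && length(reads) == 1 && dir.exists(reads)) {
    files <- list.files(reads, pattern = "\\.(fastq|fq)$", full.names = TRUE)
    paths <- stats::setNames(files, sub("\\.(fastq|fq)$", "", basename(files)))
  } else if (is.character(reads) && !is.null(names(reads))) {
    paths <- reads
  } else {
    abort("`reads` must be a tibble from simulate_reads(), a directory, or a named vector of FASTQ paths.")
  }
  lapply(paths, function(p) {
    if (file.size(p) == 0) return(character(0))
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  })
}

#' Quantify strains by perfect-match read assignment
#'
#' Assigns each merged amplicon read to a strain if and only if the read is
#' byte-identical to that strain's reference fragment (optionally after
#' trimming a constant-length prefix/suffix). Reads identical to two or more
#' references are tallied as ambiguous and excluded from the counts; all
#' other reads are unmapped. Mismatching reads are never assigned.
#'
#' @param reads Output tibble of [simulate_reads()], a directory of
#'   per-sample FASTQ files, or a named character vector of FASTQ paths
#'   (names = sample ids).
#' @param panel Strain panel with unique `ref_seq` per strain (duplicate
#'   references trigger a warning; their reads are inherently ambiguous).
#' @param revcomp Also accept reads matching the reverse complement of a
#'   reference (for unoriented inputs; default off).
#' @param trim Constant number of bases trimmed from both read ends before
#'   comparison (default 0).
#'
#' @return An object of class `mapping_result`: list with `counts` (samples x
#'   strains tibble) and `summary` (per-sample `mapped`, `unmapped`,
#'   `ambiguous`, `total`).
#' @export
map_reads_exact <- function(reads, panel, revcomp = FALSE, trim = 0) {
  validate_panel(panel)
  if (nrow(panel) == 0) abort("`panel` must be non-empty.")
  trim <- assert_count(trim, "trim")
  per_sample <- read_sample_reads(reads)

  refs <- panel$ref_seq
  if (anyDuplicated(refs)) {
    warn("Duplicate reference sequences: reads from these strains are inherently ambiguous.")
  }
  seq_map <- split(panel$strain_id, refs)  # ref seq -> strain id(s)
  uniq_refs <- names(seq_map)
  rc_refs <- if (revcomp) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(uniq_refs)))
  }

  count_rows <- vector("list", length(per_sample))
  sum_rows <- vector("list", length(per_sample))
  for (i in seq_along(per_sample)) {
    sid <- names(per_sample)[i]
    rd <- per_sample[[i]]
    if (trim > 0 && length(rd) > 0) {
      rd <- substr(rd, trim + 1L, nchar(rd) - trim)
    }
    idx <- match(rd, uniq_refs)
    if (revcomp) {
      idx2 <- match(rd, rc_refs)
      # per-read strain set: forward hits union reverse-orientation hits
      hit_sets <- mapply(function(a, b) {
        unique(c(if (!is.na(a)) seq_map[[a]], if (!is.na(b)) seq_map[[b]]))
      }, idx, idx2, SIMPLIFY = FALSE)
      hits_n <- lengths(hit_sets)
      hit_strain <- ifelse(hits_n >= 1L,
                           vapply(hit_sets, function(s) c(s, "")[1L], ""), "")
    } else {
      hits_n <- integer(length(rd))
      hit_strain <- character(length(rd))
      found <- !is.na(idx)
      hits_n[found] <- lengths(seq_map)[idx[found]]
      hit_strain[found] <- vapply(seq_map[idx[found]], `[`, "", 1L)
    }
    mapped <- hits_n == 1L
    ambiguous <- hits_n > 1L
    cnt <- table(factor(hit_strain[mapped], levels = panel$strain_id))
    count_rows[[i]] <- dplyr::bind_cols(tibble(sample_id = sid),
                                        as_tibble(as.list(as.integer(cnt)) |>
                                                    stats::setNames(panel$strain_id)))
    n_mapped <- sum(mapped)
    n_ambiguous <- sum(ambiguous)
    sum_rows[[i]] <- tibble(sample_id = sid,
                            mapped = n_mapped,
                            unmapped = length(rd) - n_mapped - n_ambiguous,
                            ambiguous = n_ambiguous,
                            total = length(rd))
  }
  structure(list(counts = dplyr::bind_rows(count_rows),
                 summary = dplyr::bind_rows(sum_rows)),
            class = "mapping_result")
}

#' Summarize unmapped and ambiguous read fractions by design factors
#'
#' Computes per-sample unmapped/ambiguous fractions, joins the sample
#' metadata, and reports group means plus a Kruskal-Wallis p-value of the
#' unmapped fraction for each grouping factor (compartment, host species,
#' experiment), mirroring the sanity check that unmapped fractions do not
#' differ across design cells. Samples with zero reads get missing (NA)
#' fractions and are excluded from the tests.
#'
#' @param result A `mapping_result` from [map_reads_exact()].
#' @param metadata Sample metadata covering all samples of `result`.
#' @param factors Metadata columns to group by.
#'
#' @return A list with `per_sample` (fractions), `by_group` (group means) and
#'   `tests` (factor, Kruskal-Wallis statistic and p-value).
#' @export
unmapped_summary <- function(result, metadata,
                             factors = c("compartment", "host_species", "experiment")) {
  stopifnot(inherits(result, "mapping_result"))
  missing <- setdiff(result$summary$sample_id, metadata$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Metadata missing for samples: ", paste(missing, collapse = ", ")))
  }
  per_sample <- result$summary |>
    dplyr::mutate(unmapped_frac = ifelse(.data$total > 0, .data$unmapped / .data$total, NA_real_),
                  ambiguous_frac = ifelse(.data$total > 0, .data$ambiguous / .data$total, NA_real_)) |>
    dplyr::left_join(metadata, by = "sample_id")
  factors <- intersect(factors, names(per_sample))
  by_group <- lapply(factors, function(f) {
    per_sample |>
      dplyr::group_by(.data[[f]]) |>
      dplyr::summarise(mean_unmapped = mean(.data$unmapped_frac, na.rm = TRUE),
                       mean_ambiguous = mean(.data$ambiguous_frac, na.rm = TRUE),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(factor = f, .before = 1) |>
      dplyr::rename(level = 2)
  }) |> dplyr::bind_rows()
  tests <- lapply(factors, function(f) {
    ok <- !is.na(per_sample$unmapped_frac) & !is.na(per_sample[[f]])
    g <- factor(per_sample[[f]][ok])
    if (nlevels(g) < 2 || stats::var(per_sample$unmapped_frac[ok]) == 0) {
      return(tibble(factor = f, statistic = NA_real_, p_value = NA_real_))
    }
    kw <- stats::kruskal.test(per_sample$unmapped_frac[ok], g)
    tibble(factor = f, statistic = unname(kw$statistic), p_value = kw$p.value)
  }) |> dplyr::bind_rows()
  list(per_sample = per_sample, by_group = by_group, tests = tests)
}
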