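#' Simulate merged amplicon reads from a strain count table
#'
#' Writes one FASTQ file per sample: exactly `count[s, f]` copies of strain
#' `f`'s reference fragment for sample `s`, with each position independently
#' substituted at `sub_error_rate` (no indels; read length equals reference
#' length, emulating quality-merged paired-end amplicons). Qualities are a
#' constant placeholder.
#'
#' @param counts Samples x strains count tibble (first column `sample_id`),
#'   e.g. `simulate_competition(...)$counts`.
#' @param panel Strain panel providing `ref_seq` per strain.
#' @param dir Output directory (created if missing).
#' @param sub_error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return A tibble with `sample_id`, `fastq` (file path) and `n_reads`,
#'   invisibly usable as the `reads` argument of [map_reads_exact()].
#' @export
simulate_reads <- function(counts, panel, dir = tempfile("reads"),
                           sub_error_rate = 0, seed = 1) {
  validate_count_table(counts)
  validate_panel(panel)
  sub_error_rate <- assert_fraction(sub_error_rate, "sub_error_rate",
                                    hi = 1, open_hi = TRUE)
  m <- counts_matrix(counts)
  unknown <- setdiff(colnames(m), panel$strain_id)
  if (length(unknown) > 0) {
    abort(paste0("Count table features missing from panel: ",
                 paste(unknown, collapse = ", ")))
  }
  refs <- stats::setNames(panel$ref_seq, panel$strain_id)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  withr::local_seed(child_seed(seed, 4L))
  bases <- c("A", "C", "G", "T")

  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    sid <- rownames(m)[i]
    reads <- character(0)
    ids <- character(0)
    for (f in colnames(m)) {
      n <- m[i, f]
      if (n == 0) next
      rs <- rep(refs[[f]], n)
      if (sub_error_rate > 0) {
        len <- nchar(refs[[f]])
        n_events <- stats::rbinom(1L, size = as.integer(n) * len,
                                  prob = sub_error_rate)
        if (n_events > 0) {
          ev <- sample.int(as.integer(n) * len, n_events)
          ri <- (ev - 1L) %/% len + 1L
          pj <- (ev - 1L) %% len + 1L
          for (k in seq_len(n_events)) {
            old <- substr(rs[ri[k]], pj[k], pj[k])
            substr(rs[ri[k]], pj[k], pj[k]) <- sample(setdiff(bases, old), 1L)
          }
        }
      }
      reads <- c(reads, rs)
      ids <- c(ids, sprintf("%s|%s|read%06d", sid, f, seq_len(n)))
    }
    path <- file.path(dir, paste0(sid, ".fastq"))
    if (length(reads) > 0) {
      dna <- Biostrings::DNAStringSet(stats::setNames(reads, ids))
      qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
      Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
    } else {
      file.create(path)
    }
    out[[i]] <- tibble(sample_id = sid, fastq = path, n_reads = sum(m[i, ]))
  }
  dplyr::bind_rows(out)
}
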