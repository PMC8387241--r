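fwd <- "AACMGGATTAGATACCCKG"
rev <- "ACGTCATCCCCACCTTCC"
rc_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))

test_that("extract_amplicon returns the primer-delimited construction", {
  f_concrete <- "AACAGGATTAGATACCCTG"  # M -> A, K -> T resolution
  filler <- strrep("ACGTTGCA", 40)
  amplicon <- paste0(f_concrete, filler, rc_rev)
  template <- paste0("GGNN", amplicon, "NNTT")
  expect_identical(extract_amplicon(template, fwd, rev), amplicon)
  # degenerate codes resolve: M = {A,C}, K = {G,T}
  f_other <- "AACCGGATTAGATACCCGG"
  expect_identical(extract_amplicon(paste0(f_other, filler, rc_rev), fwd, rev),
                   paste0(f_other, filler, rc_rev))
})

test_that("extract_amplicon applies the leftmost-match rule and errors cleanly", {
  f <- "AACAGGATTAGATACCCTG"
  filler <- strrep("TTGGCCAA", 20)
  two_sites <- paste0(f, filler, f, filler, rc_rev)
  amp <- extract_amplicon(two_sites, fwd, rev)
  expect_identical(amp, two_sites)  # starts at the first forward site
  expect_error(extract_amplicon(strrep("ACGT", 100), fwd, rev),
               class = "syncomstats_no_amplicon")
  expect_error(extract_amplicon(paste0(f, filler), fwd, rev),
               class = "syncomstats_no_amplicon")
  long <- paste0(f, strrep("ACGTTGCA", 300), rc_rev)
  expect_error(extract_amplicon(long, fwd, rev, max_len = 2000),
               class = "syncomstats_no_amplicon")
  expect_error(extract_amplicon("ACGU", fwd, rev), "A,C,G,T,N")
})

write_fastq <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(seqs, paste0("r", seq_along(seqs))))
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  path
}

test_that("perfect-match assignment counts exact reads and discards mismatches", {
  panel <- manual_panel()
  r1 <- panel$ref_seq[1]
  mism <- r1
  substr(mism, 5, 5) <- ifelse(substr(mism, 5, 5) == "A", "C", "A")
  path <- write_fastq(c(r1, r1, mism, strrep("T", 100)), tempfile(fileext = ".fastq"))
  mr <- map_reads_exact(c(s1 = path), panel)
  cm <- count_mat(mr$counts)
  expect_equal(unname(cm["s1", "LjA"]), 2)
  expect_equal(sum(cm), 2)
  expect_equal(mr$summary$unmapped, 2)
  expect_equal(mr$summary$ambiguous, 0)
})

test_that("reads matching multiple references are ambiguous, with a warning for duplicates", {
  panel <- manual_panel()
  panel$ref_seq[3] <- panel$ref_seq[1]  # LjB duplicates LjA
  path <- write_fastq(c(panel$ref_seq[1], panel$ref_seq[2]),
                      tempfile(fileext = ".fastq"))
  expect_warning(mr <- map_reads_exact(c(s1 = path), panel), "ambiguous")
  expect_equal(mr$summary$ambiguous, 1)
  expect_equal(mr$summary$mapped, 1)
  expect_equal(sum(count_mat(mr$counts)), 1)
})

test_that("mapping equals a brute-force all-pairs equality oracle", {
  set.seed(42)
  panel <- tiny_panel(n = 8, seq_len = 80)
  refs <- panel$ref_seq
  mutate1 <- function(s) {
    i <- sample(nchar(s), 1)
    substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, i, i)), 1)
    s
  }
  reads <- c(sample(refs, 120, replace = TRUE),
             vapply(sample(refs, 40, replace = TRUE), mutate1, ""),
             replicate(10, paste(sample(c("A", "C", "G", "T"), 80,
                                        replace = TRUE), collapse = "")))
  names(reads) <- NULL
  path <- write_fastq(reads, tempfile(fileext = ".fastq"))
  mr <- map_reads_exact(c(s1 = path), panel)
  # oracle: nested-loop string equality
  oracle_counts <- stats::setNames(integer(length(refs)), panel$strain_id)
  oracle_unmapped <- 0L; oracle_amb <- 0L
  for (r in reads) {
    hits <- panel$strain_id[refs == r]
    if (length(hits) == 1) oracle_counts[hits] <- oracle_counts[hits] + 1L
    else if (length(hits) == 0) oracle_unmapped <- oracle_unmapped + 1L
    else oracle_amb <- oracle_amb + 1L
  }
  cm <- count_mat(mr$counts)
  expect_equal(cm["s1", names(oracle_counts)], oracle_counts,
               ignore_attr = TRUE)
  expect_equal(mr$summary$unmapped, oracle_unmapped)
  expect_equal(mr$summary$ambiguous, oracle_amb)
  # read conservation
  expect_equal(mr$summary$mapped + mr$summary$unmapped + mr$summary$ambiguous,
               length(reads))
  # monotonicity: adding a reference never decreases mapped + ambiguous
  mr_small <- map_reads_exact(c(s1 = path), panel[1:6, ])
  expect_lte(mr_small$summary$mapped + mr_small$summary$ambiguous,
             mr$summary$mapped + mr$summary$ambiguous)
})

test_that("reverse-complement matching and trimming are opt-in", {
  panel <- manual_panel()
  # AtA ends in ACGA, so its reverse complement differs from the forward strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(panel$ref_seq[2])))
  path <- write_fastq(c(rc), tempfile(fileext = ".fastq"))
  expect_equal(map_reads_exact(c(s1 = path), panel)$summary$mapped, 0)
  expect_equal(map_reads_exact(c(s1 = path), panel,
                               revcomp = TRUE)$summary$mapped, 1)
  padded <- paste0("GG", panel$ref_seq[2], "CC")
  path2 <- write_fastq(c(padded), tempfile(fileext = ".fastq"))
  expect_equal(map_reads_exact(c(s1 = path2), panel)$summary$mapped, 0)
  mr2 <- map_reads_exact(c(s1 = path2), panel, trim = 2)
  expect_equal(unname(count_mat(mr2$counts)["s1", "AtA"]), 1)
})

test_that("round trip: error-free simulated reads map back to the exact table", {
  panel <- tiny_panel(n = 6, seq_len = 100)
  sim <- simulate_competition(panel, design_spec(replicates = 2),
                              effect_spec(depth = 400), seed = 3)
  rd <- simulate_reads(sim$counts, panel, sub_error_rate = 0, seed = 8)
  expect_equal(rd$n_reads, rep(400, nrow(rd)))
  mr <- map_reads_exact(rd, panel)
  a <- count_mat(mr$counts); b <- count_mat(sim$counts)
  expect_equal(a[rownames(b), colnames(b)], b, ignore_attr = TRUE)
  us <- unmapped_summary(mr, sim$metadata)
  expect_true(all(us$per_sample$unmapped_frac == 0))
  expect_true(all(us$per_sample$ambiguous_frac == 0))
})

test_that("substitution errors make reads unmapped at the expected rate", {
  panel <- tiny_panel(n = 4, seq_len = 100)
  counts <- manual_ab(list(s1 = rep(250, 8)), panel$strain_id)
  rd <- simulate_reads(counts, panel, sub_error_rate = 0.01, seed = 5)
  mr <- map_reads_exact(rd, panel)
  # P(read error-free) = 0.99^100 ~ 0.366; mapped fraction should be near it
  frac <- mr$summary$mapped / mr$summary$total
  expect_gt(frac, 0.30); expect_lt(frac, 0.44)
  expect_equal(mr$summary$mapped + mr$summary$unmapped + mr$summary$ambiguous,
               2000)
})

test_that("zero-read samples get missing fractions, not zeros", {
  panel <- manual_panel()
  empty <- tempfile(fileext = ".fastq"); file.create(empty)
  full <- write_fastq(panel$ref_seq[1], tempfile(fileext = ".fastq"))
  mr <- map_reads_exact(c(s0 = empty, s1 = full), panel)
  meta <- manual_meta(c("s0", "s1"), c("Lj", "At"))
  us <- unmapped_summary(mr, meta)
  expect_true(is.na(us$per_sample$unmapped_frac[us$per_sample$sample_id == "s0"]))
  expect_equal(us$per_sample$unmapped_frac[us$per_sample$sample_id == "s1"], 0)
})
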