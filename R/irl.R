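#' Greedy centroid clustering of sequences into OTUs
#'
#' Abundance-sorted greedy clustering at a global-identity threshold (the
#' classic 97% OTU definition): sequences are visited in decreasing
#' abundance (ties broken lexicographically by id), each joining the first
#' existing centroid whose global pairwise identity is at or above the
#' threshold, otherwise founding a new centroid. Identity is
#' `matches / alignment length` of a Needleman-Wunsch global alignment
#' (match +1, mismatch -1, gap opening 4, gap extension 1).
#'
#' @param sequences Data frame with columns `seq_id`, `sequence` and
#'   `abundance` (or a named character vector, abundance 1 each).
#' @param identity Identity threshold in (0, 1]; default 0.97.
#'
#' @return A tibble `seq_id`, `otu_id`, `is_centroid`; OTU ids are
#'   `OTU_<k>` in centroid founding order.
#' @export
greedy_cluster_otus <- function(sequences, identity = 0.97) {
  if (is.character(sequences)) {
    sequences <- tibble(seq_id = names(sequences) %||% paste0("seq", seq_along(sequences)),
                        sequence = unname(sequences), abundance = 1)
  }
  stopifnot(all(c("seq_id", "sequence") %in% names(sequences)))
  if (!"abundance" %in% names(sequences)) sequences$abundance <- 1
  if (nrow(sequences) == 0) abort("`sequences` must be non-empty.")
  identity <- assert_fraction(identity, "identity", open_lo = TRUE)

  ord <- order(-sequences$abundance, sequences$seq_id)
  sq <- sequences[ord, ]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  centroids <- character(0)
  assign <- integer(nrow(sq))
  for (i in seq_len(nrow(sq))) {
    hit <- 0L
    for (k in seq_along(centroids)) {
      aln <- Biostrings::pairwiseAlignment(sq$sequence[i], centroids[k],
                                           type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 4, gapExtension = 1)
      aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (Biostrings::nmatch(aln) / aln_len >= identity) { hit <- k; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, sq$sequence[i])
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  tibble(seq_id = sq$seq_id,
         otu_id = sprintf("OTU_%d", assign),
         is_centroid = !duplicated(assign))
}

#' Simulate limiting-dilution culture plates
#'
#' Emulates isolation of community members in microtitre wells: each well is
#' seeded with a Poisson number of founder cells drawn from the community's
#' relative abundances, and the well's amplicon reads are multinomial over
#' the founders' OTUs (proportional to founder cell numbers). Low seeding
#' densities give mostly pure (single-OTU) wells.
#'
#' @param community_ra Named non-negative vector of OTU relative abundances
#'   summing to 1.
#' @param n_wells Number of wells to plate.
#' @param cells_per_well_mean Mean founder cells per well (Poisson).
#' @param reads_per_well Sequencing reads per non-empty well.
#' @param seed Integer seed.
#'
#' @return A well table: tibble with `well_id` and one count column per OTU.
#' @export
simulate_irl_plates <- function(community_ra, n_wells, cells_per_well_mean = 0.3,
                                reads_per_well = 1000, seed = 1) {
  if (is.null(names(community_ra))) {
    names(community_ra) <- sprintf("OTU_%d", seq_along(community_ra))
  }
  if (any(community_ra < 0) || abs(sum(community_ra) - 1) > 1e-8) {
    abort("`community_ra` must be non-negative and sum to 1.")
  }
  n_wells <- assert_count(n_wells, "n_wells")
  if (cells_per_well_mean <= 0) abort("`cells_per_well_mean` must be positive.")
  reads_per_well <- assert_count(reads_per_well, "reads_per_well", min = 1L)
  withr::local_seed(child_seed(seed, 5L))

  otus <- names(community_ra)
  m <- matrix(0L, nrow = n_wells, ncol = length(otus),
              dimnames = list(sprintf("P1:%03d", seq_len(n_wells)), otus))
  if (n_wells > 0) {
    founders <- stats::rpois(n_wells, cells_per_well_mean)
    for (i in seq_len(n_wells)) {
      if (founders[i] == 0) next
      cells <- as.integer(stats::rmultinom(1, founders[i], community_ra))
      m[i, ] <- as.integer(stats::rmultinom(1, reads_per_well, cells / sum(cells)))
    }
  }
  matrix_to_tibble(m, id_col = "well_id")
}

#' Filter a culture-plate well table
#'
#' Drops low-coverage wells, then sparse OTUs: wells with fewer than
#' `min_well_reads` total reads are removed (a well with exactly the
#' threshold is kept), and OTUs never reaching `min_otu_well_reads` in any
#' remaining well are removed (an OTU with a per-well maximum exactly at the
#' threshold is kept).
#'
#' @param wells Well table (tibble, first column `well_id`).
#' @param min_well_reads Minimum total reads for a well to be kept.
#' @param min_otu_well_reads Minimum per-well count an OTU must reach.
#'
#' @return The filtered well table.
#' @export
filter_well_table <- function(wells, min_well_reads = 100, min_otu_well_reads = 10) {
  min_well_reads <- assert_count(min_well_reads, "min_well_reads")
  min_otu_well_reads <- assert_count(min_otu_well_reads, "min_otu_well_reads")
  m <- counts_matrix(wells, id_col = "well_id")
  if (nrow(m) > 0) m <- m[rowSums(m) >= min_well_reads, , drop = FALSE]
  if (ncol(m) > 0 && nrow(m) > 0) {
    m <- m[, apply(m, 2, max) >= min_otu_well_reads, drop = FALSE]
  } else if (nrow(m) == 0) {
    m <- m[, integer(0), drop = FALSE]
  }
  matrix_to_tibble(m, id_col = "well_id")
}

#' Identify recoverable OTUs from well purities
#'
#' A well's purity is the fraction of its reads belonging to its most
#' abundant OTU. An OTU is recoverable if it is the top member of at least
#' one well whose purity is at or above `purity_threshold` (an OTU can be
#' picked as a pure culture from that well).
#'
#' @param wells A filtered well table (see [filter_well_table()]).
#' @param purity_threshold Purity cut-off in (0, 1]; default 0.90.
#'
#' @return Tibble `otu_id`, `best_purity` (highest purity among wells where
#'   the OTU is top; NA if never top), `recoverable`.
#' @export
recoverable_otus <- function(wells, purity_threshold = 0.90) {
  purity_threshold <- assert_fraction(purity_threshold, "purity_threshold",
                                      open_lo = TRUE)
  m <- counts_matrix(wells, id_col = "well_id")
  best <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  for (i in seq_len(nrow(m))) {
    tot <- sum(m[i, ])
    if (tot == 0) next
    mx <- max(m[i, ])
    purity <- mx / tot
    for (o in colnames(m)[m[i, ] == mx]) {
      if (is.na(best[o]) || purity > best[o]) best[o] <- purity
    }
  }
  tibble(otu_id = colnames(m), best_purity = unname(best),
         recoverable = !is.na(best) & best >= purity_threshold)
}

#' Recovery statistics of a culture collection against a natural community
#'
#' Cross-references the set of recoverable OTUs with a culture-independent
#' community profile: reports which abundant OTUs (relative abundance at or
#' above `abundance_threshold`, default 0.1%) are represented in the
#' collection, the percentage of abundant OTUs recovered, and the accumulated
#' natural relative abundance of all recovered OTUs. Supports
#' cross-collection use (profile from one host, recoverable set from the
#' other host's collection).
#'
#' @param natural_profile Named vector of OTU relative abundances in the
#'   natural community (sum <= 1; unassigned mass allowed), or a data frame
#'   with columns `otu_id`, `ra`.
#' @param recoverable Character vector of recoverable OTU ids, or the tibble
#'   returned by [recoverable_otus()].
#' @param abundance_threshold Abundant-OTU cut-off on relative abundance.
#' @param abundant_only If TRUE, accumulate recovered relative abundance over
#'   abundant OTUs only (default: over all recovered OTUs).
#'
#' @return An object of class `recovery_report`: list with `per_otu` (the
#'   rank-abundance table: OTUs by decreasing RA with abundant/recovered
#'   flags) and `summary` (`n_abundant`, `pct_abundant_recovered` — NA when
#'   no OTU is abundant — and `accumulated_ra_recovered`).
#' @examples
#' recovery_report(c(OTU1 = 0.5, OTU2 = 0.3, OTU3 = 0.15, OTU4 = 0.05),
#'                 c("OTU1", "OTU3"))
#' @export
recovery_report <- function(natural_profile, recoverable,
                            abundance_threshold = 0.001,
                            abundant_only = FALSE) {
  if (is.data.frame(natural_profile)) {
    stopifnot(all(c("otu_id", "ra") %in% names(natural_profile)))
    natural_profile <- stats::setNames(natural_profile$ra, natural_profile$otu_id)
  }
  if (any(natural_profile < 0) || sum(natural_profile) > 1 + 1e-8) {
    abort("`natural_profile` must be non-negative with total <= 1.")
  }
  if (is.data.frame(recoverable)) {
    recoverable <- recoverable$otu_id[recoverable$recoverable]
  }
  abundance_threshold <- assert_fraction(abundance_threshold, "abundance_threshold")

  per_otu <- tibble(otu_id = names(natural_profile),
                    ra = unname(natural_profile)) |>
    dplyr::arrange(dplyr::desc(.data$ra), .data$otu_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  abundant = .data$ra >= abundance_threshold,
                  recovered = .data$otu_id %in% recoverable)
  n_abundant <- sum(per_otu$abundant)
  pct <- if (n_abundant == 0) NA_real_ else {
    100 * sum(per_otu$abundant & per_otu$recovered) / n_abundant
  }
  acc_pool <- if (abundant_only) per_otu$recovered & per_otu$abundant else per_otu$recovered
  structure(list(per_otu = per_otu,
                 summary = tibble(n_otus = nrow(per_otu),
                                  n_abundant = n_abundant,
                                  pct_abundant_recovered = pct,
                                  accumulated_ra_recovered = sum(per_otu$ra[acc_pool]))),
            class = "recovery_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
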