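# Samples that constitute a "competition" context: either a competition
# experiment or the simultaneously inoculated (mixed) control arm of a
# sequential experiment.
competition_samples <- function(meta) {
  tr <- meta$treatment %||% rep("competition", nrow(meta))
  fi <- meta$first_inoculum %||% rep("mixed", nrow(meta))
  tr == "competition" | (tr == "sequential" & fi == "mixed")
}

# Long per-sample strain RA joined with metadata, restricted to a compartment.
strain_ra_long <- function(ab, meta, panel, compartment) {
  m <- counts_matrix(ab)
  missing <- setdiff(colnames(m), panel$strain_id)
  if (length(missing) > 0) {
    abort(paste0("Features missing from panel: ", paste(missing, collapse = ", ")))
  }
  long <- matrix_to_tibble(m) |>
    tidyr::pivot_longer(-"sample_id", names_to = "strain_id", values_to = "ra") |>
    dplyr::inner_join(meta, by = "sample_id") |>
    dplyr::filter(.data$compartment == !!compartment) |>
    dplyr::left_join(panel[c("strain_id", "host_of_origin", "family")],
                     by = "strain_id") |>
    dplyr::mutate(cognate = .data$host_species == .data$host_of_origin)
  if (!all(c("Lj", "At") %in% unique(long$host_species))) {
    abort(sprintf("No %s samples for one of the two hosts.", compartment))
  }
  long
}

index_from_means <- function(means, min_mean_ra) {
  means |>
    dplyr::mutate(
      filtered = .data$mean_ra_cognate < min_mean_ra |
        .data$mean_ra_other < min_mean_ra,
      index = ifelse(.data$filtered, NA_real_,
                     .data$mean_ra_cognate / .data$mean_ra_other))
}

#' Per-strain host-preference index
#'
#' For every strain and experiment, the ratio between its mean relative
#' abundance in root samples of its cognate host (the species it was
#' isolated from) and in root samples of the other host. Values above 1
#' indicate preference for the cognate host. To avoid inflated ratios from
#' tiny denominators, strains whose mean relative abundance falls below
#' `min_mean_ra` (default 0.1%) in either host are excluded (flagged
#' `filtered`, index absent); a mean exactly at the threshold is retained.
#' Computed independently for each experiment, over competition samples
#' (mixed-inoculum arms of sequential experiments included).
#'
#' @param ab Abundance tibble (samples x strains, first column `sample_id`).
#' @param meta Sample metadata (see [simulate_competition()]).
#' @param panel Strain panel.
#' @param compartment Compartment to analyse (default `"root"`).
#' @param min_mean_ra Mean-relative-abundance exclusion threshold.
#'
#' @return Tibble per strain x experiment: `mean_ra_cognate`,
#'   `mean_ra_other`, `filtered`, `hpi`.
#' @export
host_preference_index <- function(ab, meta, panel, compartment = "root",
                                  min_mean_ra = 0.001) {
  validate_panel(panel)
  min_mean_ra <- assert_fraction(min_mean_ra, "min_mean_ra")
  long <- strain_ra_long(ab, meta, panel, compartment)
  long <- long[competition_samples(long), ]
  means <- long |>
    dplyr::group_by(.data$experiment, .data$strain_id, .data$host_of_origin,
                    .data$family, .data$cognate) |>
    dplyr::summarise(mean_ra = mean(.data$ra), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cognate", values_from = "mean_ra") |>
    dplyr::rename(mean_ra_cognate = "TRUE", mean_ra_other = "FALSE")
  index_from_means(means, min_mean_ra) |>
    dplyr::rename(hpi = "index") |>
    dplyr::arrange(.data$experiment, .data$strain_id)
}

mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) return(tibble(U = NA_real_, p_value = NA_real_))
  if (stats::var(c(x, y)) == 0) {
    # all observations tied (e.g. all-zero abundances): no evidence either way
    return(tibble(U = n1 * n2 / 2, p_value = 1))
  }
  exact <- max(n1, n2) <= 8
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  tibble(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Test per-strain host preference (Mann-Whitney, FDR-corrected)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per strain comparing its
#' per-sample relative abundances on the cognate versus the other host, with
#' Benjamini-Hochberg correction across strains within each experiment.
#' Strains whose abundances are all tied (e.g. absent everywhere) get
#' `p = 1` by convention. Exact p-values are used for group sizes up to 8
#' per group; the tie-corrected normal approximation above that.
#'
#' @inheritParams host_preference_index
#' @param alpha Significance level on the BH-adjusted p-values.
#'
#' @return Tibble per strain x experiment: `U`, `p_value`, `q_value`,
#'   `significant`, plus the group sizes.
#' @export
test_preference <- function(ab, meta, panel, compartment = "root",
                            alpha = 0.05) {
  validate_panel(panel)
  long <- strain_ra_long(ab, meta, panel, compartment)
  long <- long[competition_samples(long), ]
  n_per <- long |>
    dplyr::distinct(.data$experiment, .data$sample_id, .data$host_species) |>
    dplyr::count(.data$experiment, .data$host_species)
  if (any(n_per$n < 2)) abort("Need >= 2 root samples per host.")
  long |>
    dplyr::group_by(.data$experiment, .data$strain_id, .data$host_of_origin) |>
    dplyr::summarise(mann_whitney(.data$ra[.data$cognate],
                                  .data$ra[!.data$cognate]),
                     n_cognate = sum(.data$cognate),
                     n_other = sum(!.data$cognate), .groups = "drop") |>
    dplyr::group_by(.data$experiment) |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, method = "BH"),
                  significant = !is.na(.data$q_value) & .data$q_value <= alpha) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$experiment, .data$strain_id)
}

#' Per-strain invasiveness index
#'
#' The host-preference ratio computed only from invasion samples: for each
#' strain, the ratio between its mean relative abundance when invading a
#' standing (resident) community on roots of its cognate host and when
#' invading on roots of the other host. Only samples of sequential
#' experiments in which the strain's SynCom was the second (invading)
#' inoculum enter the means. The same `min_mean_ra` exclusion applies.
#' Strains never observed in an invading role are absent from the table.
#'
#' @inheritParams host_preference_index
#' @param compartment Compartment to analyse; `"root"` for the headline
#'   index, `"rhizosphere"` for the contrast where the correlation with host
#'   preference is expected to vanish.
#'
#' @return Tibble per strain x experiment: `mean_ra_invading_cognate`,
#'   `mean_ra_invading_other`, `filtered`, `inv_index`.
#' @export
invasiveness_index <- function(ab, meta, panel, compartment = "root",
                               min_mean_ra = 0.001) {
  validate_panel(panel)
  min_mean_ra <- assert_fraction(min_mean_ra, "min_mean_ra")
  long <- strain_ra_long(ab, meta, panel, compartment) |>
    dplyr::filter(.data$treatment == "sequential",
                  .data$second_inoculum == .data$host_of_origin)
  if (nrow(long) == 0) {
    abort("No invasion samples: no sequential samples where a strain's SynCom was second.")
  }
  means <- long |>
    dplyr::group_by(.data$experiment, .data$strain_id, .data$host_of_origin,
                    .data$family, .data$cognate) |>
    dplyr::summarise(mean_ra = mean(.data$ra), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cognate", values_from = "mean_ra") |>
    dplyr::rename(mean_ra_invading_cognate = "TRUE",
                  mean_ra_invading_other = "FALSE") |>
    dplyr::filter(!is.na(.data$mean_ra_invading_cognate),
                  !is.na(.data$mean_ra_invading_other))
  means |>
    dplyr::rename(mean_ra_cognate = "mean_ra_invading_cognate",
                  mean_ra_other = "mean_ra_invading_other") |>
    index_from_means(min_mean_ra) |>
    dplyr::rename(mean_ra_invading_cognate = "mean_ra_cognate",
                  mean_ra_invading_other = "mean_ra_other",
                  inv_index = "index") |>
    dplyr::arrange(.data$experiment, .data$strain_id)
}

#' Correlate host-preference and invasiveness indices
#'
#' Pearson correlation (default) between `log2(hpi)` and `log2(inv_index)`
#' across strains present and unfiltered in both tables, with a partial
#' correlation controlling for `log2` mean relative abundance — the check
#' that the preference-invasiveness link is not a mere abundance artefact.
#'
#' @param pref Output of [host_preference_index()] (one experiment).
#' @param inv Output of [invasiveness_index()] (one experiment).
#' @param method `"pearson"` (on log2 indices) or `"spearman"`.
#'
#' @return One-row tibble: `r`, `p_value`, `partial_r_given_mean_ra`, `n`,
#'   `method`.
#' @export
correlate_indices <- function(pref, inv, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (anyDuplicated(pref$strain_id) || anyDuplicated(inv$strain_id)) {
    abort("One row per strain required; filter to a single experiment first.")
  }
  both <- dplyr::inner_join(
    dplyr::filter(pref, !.data$filtered)[c("strain_id", "hpi",
                                           "mean_ra_cognate", "mean_ra_other")],
    dplyr::filter(inv, !.data$filtered)[c("strain_id", "inv_index")],
    by = "strain_id")
  if (nrow(both) < 3) abort("Fewer than 3 strains pass both filters.")
  x <- log2(both$hpi); y <- log2(both$inv_index)
  z <- log2((both$mean_ra_cognate + both$mean_ra_other) / 2)
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  r_xy <- unname(ct$estimate)
  r_xz <- stats::cor(x, z, method = method)
  r_yz <- stats::cor(y, z, method = method)
  partial <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  tibble(r = r_xy, p_value = ct$p.value,
         partial_r_given_mean_ra = partial, n = nrow(both), method = method)
}

#' Family-removal robustness of community-level host preference
#'
#' Sequential in-silico removal of individual bacterial families: for each
#' family, its strains are removed, every sample is renormalized to sum 1,
#' aggregated relative abundances by host-of-origin are recomputed, and a
#' two-sided Mann-Whitney test compares native versus non-native aggregated
#' RA within each host's root samples. A robust community-level host
#' preference keeps its direction (native > non-native) under every removal.
#'
#' @inheritParams host_preference_index
#'
#' @return Tibble per family removed (including `"none"` = baseline) x host:
#'   `mean_native_ra`, `mean_nonnative_ra`, `direction`, `p_value`.
#' @export
family_knockout <- function(ab, meta, panel, compartment = "root") {
  validate_panel(panel)
  m <- counts_matrix(ab)
  missing <- setdiff(colnames(m), panel$strain_id)
  if (length(missing) > 0) {
    abort(paste0("Features missing from panel: ", paste(missing, collapse = ", ")))
  }
  keep_meta <- meta[meta$compartment == compartment &
                      competition_samples(meta), ]
  m <- m[rownames(m) %in% keep_meta$sample_id, , drop = FALSE]

  one_removal <- function(fam) {
    drop_ids <- panel$strain_id[panel$family == fam]
    mm <- m[, !(colnames(m) %in% drop_ids), drop = FALSE]
    if (ncol(mm) == 0) {
      warn(sprintf("Removing family %s leaves no features; skipped.", fam))
      return(NULL)
    }
    tot <- rowSums(mm)
    ok <- tot > 0
    mm <- mm[ok, , drop = FALSE] / tot[ok]
    agg <- aggregate_by_origin(matrix_to_tibble(mm), panel) |>
      dplyr::inner_join(keep_meta[c("sample_id", "host_species")], by = "sample_id") |>
      dplyr::mutate(native_ra = ifelse(.data$host_species == "Lj",
                                       .data$Lj_derived_RA, .data$At_derived_RA),
                    nonnative_ra = ifelse(.data$host_species == "Lj",
                                          .data$At_derived_RA, .data$Lj_derived_RA))
    agg |>
      dplyr::group_by(.data$host_species) |>
      dplyr::summarise(mann_whitney(.data$native_ra, .data$nonnative_ra),
                       mean_native_ra = mean(.data$native_ra),
                       mean_nonnative_ra = mean(.data$nonnative_ra),
                       .groups = "drop") |>
      dplyr::mutate(family_removed = fam,
                    direction = dplyr::case_when(
                      mean_native_ra > mean_nonnative_ra ~ "native_higher",
                      mean_native_ra < mean_nonnative_ra ~ "native_lower",
                      TRUE ~ "tied"), .before = 1)
  }
  fams <- c("none", unique(panel$family))
  dplyr::bind_rows(lapply(fams, function(f) {
    if (f == "none") {
      # baseline: remove nothing (renormalization is a no-op for RA input)
      res <- one_removal("__none__")
    } else res <- one_removal(f)
    res
  })) |>
    dplyr::mutate(family_removed = sub("__none__", "none", .data$family_removed)) |>
    dplyr::select("family_removed", "host_species", "mean_native_ra",
                  "mean_nonnative_ra", "direction", "U", "p_value")
}
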