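#' Plot a PCoA ordination
#'
#' Scatter of the first two principal coordinates, axes labelled with the
#' percentage of (retained) variance they explain; points can be coloured and
#' shaped by metadata columns.
#'
#' @param object A `syncom_pcoa` from [pcoa()].
#' @param metadata Optional sample metadata joined on `sample_id`.
#' @param colour,shape Metadata column names for the aesthetics.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.syncom_pcoa <- function(object, metadata = NULL, colour = NULL,
                                 shape = NULL, ...) {
  pts <- object$points
  if (!is.null(metadata)) pts <- dplyr::left_join(pts, metadata, by = "sample_id")
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_var[1]),
      y = if (length(object$prop_var) > 1) {
        sprintf("PCo2 (%.1f%%)", 100 * object$prop_var[2])
      } else "PCo2") +
    ggplot2::theme_classic()
  aes_extra <- list()
  if (!is.null(colour)) aes_extra$colour <- ggplot2::sym(colour)
  if (!is.null(shape)) aes_extra$shape <- ggplot2::sym(shape)
  p + ggplot2::geom_point(mapping = do.call(ggplot2::aes, aes_extra), size = 2)
}

#' Boxplots of aggregated relative abundance by host-of-origin
#'
#' The community-level host-preference readout: per-sample aggregated RA of
#' Lj-derived and At-derived strains, split by host species (and optionally
#' any other metadata facet).
#'
#' @param agg Output of [aggregate_by_origin()].
#' @param metadata Sample metadata with `host_species`.
#' @param facet Optional metadata column to facet by (e.g. `first_inoculum`).
#' @return A ggplot object.
#' @export
plot_aggregated_ra <- function(agg, metadata, facet = NULL) {
  df <- dplyr::inner_join(agg, metadata, by = "sample_id") |>
    tidyr::pivot_longer(c("Lj_derived_RA", "At_derived_RA"),
                        names_to = "origin", values_to = "ra") |>
    dplyr::mutate(origin = sub("_derived_RA", "-derived", .data$origin))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$host_species, .data$ra,
                                        fill = .data$origin)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Host species", y = "Aggregated relative abundance",
                  fill = "Strain origin") +
    ggplot2::theme_classic()
  if (!is.null(facet)) p <- p + ggplot2::facet_wrap(facet)
  p
}

#' Dot plot of per-strain host-preference indices
#'
#' Each strain is a point at its log2 host-preference index, sized by its
#' mean relative abundance and ringed when significantly host-preferring.
#'
#' @param pref Output of [host_preference_index()].
#' @param tests Optional output of [test_preference()] to mark significance.
#' @return A ggplot object.
#' @export
plot_preference <- function(pref, tests = NULL) {
  df <- dplyr::filter(pref, !.data$filtered) |>
    dplyr::mutate(mean_ra = (.data$mean_ra_cognate + .data$mean_ra_other) / 2)
  if (!is.null(tests)) {
    df <- dplyr::left_join(df, tests[c("experiment", "strain_id", "significant")],
                           by = c("experiment", "strain_id"))
  } else df$significant <- NA
  p <- ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$strain_id, log2(.data$hpi)),
                                        log2(.data$hpi))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean_ra,
                                     colour = .data$host_of_origin)) +
    ggplot2::labs(x = NULL, y = "log2 host preference index",
                  size = "Mean RA", colour = "Host of origin") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  if (!all(is.na(df$significant))) {
    p <- p + ggplot2::geom_point(data = df[!is.na(df$significant) & df$significant, ],
                                 shape = 1, size = 4, stroke = 0.9)
  }
  p
}

#' Rank-abundance curve with recovery status
#'
#' OTUs of the natural community ordered by decreasing relative abundance,
#' coloured by whether the culture collection recovered them; the abundant
#' cut-off is drawn as a horizontal line.
#'
#' @param report A `recovery_report` from [recovery_report()].
#' @param abundance_threshold The cut-off line to draw (default 0.001).
#' @return A ggplot object.
#' @export
plot_rank_abundance <- function(report, abundance_threshold = 0.001) {
  stopifnot(inherits(report, "recovery_report"))
  ggplot2::ggplot(report$per_otu,
                  ggplot2::aes(.data$rank, .data$ra, colour = .data$recovered)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_hline(yintercept = abundance_threshold, linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "OTU rank", y = "Relative abundance",
                  colour = "Recovered") +
    ggplot2::theme_classic()
}

#' Scatter of invasiveness versus host-preference index
#'
#' @param pref,inv Index tables from [host_preference_index()] and
#'   [invasiveness_index()] (one experiment each).
#' @return A ggplot object of log2 invasiveness against log2 host preference
#'   with a least-squares line.
#' @export
plot_index_correlation <- function(pref, inv) {
  both <- dplyr::inner_join(
    dplyr::filter(pref, !.data$filtered),
    dplyr::filter(inv, !.data$filtered)[c("strain_id", "inv_index")],
    by = "strain_id")
  ggplot2::ggplot(both, ggplot2::aes(log2(.data$hpi), log2(.data$inv_index),
                                     colour = .data$host_of_origin)) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log2 host preference index",
                  y = "log2 invasiveness index",
                  colour = "Host of origin") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
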