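#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PERMANOVA result
#' @param x A `syncom_permanova` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic` (pseudo-F), `R2`, `p_value`,
#'   `df_among`, `df_resid`, `n_perm`.
#' @method tidy syncom_permanova
#' @export
tidy.syncom_permanova <- function(x, ...) {
  tibble(statistic = x$statistic, R2 = x$R2, p_value = x$p_value,
         df_among = x$df[1], df_resid = x$df[2], n_perm = x$n_perm)
}

#' @rdname tidy.syncom_permanova
#' @method glance syncom_permanova
#' @export
glance.syncom_permanova <- function(x, ...) {
  tibble(n = x$n, n_groups = x$n_groups, R2 = x$R2, p_value = x$p_value)
}

#' Tidy a principal-coordinates result
#' @param x A `syncom_pcoa` object.
#' @param ... Unused.
#' @return `tidy()`: sample coordinates (long-ready wide tibble);
#'   `glance()`: one row per retained axis with eigenvalue and variance
#'   proportion.
#' @method tidy syncom_pcoa
#' @export
tidy.syncom_pcoa <- function(x, ...) x$points

#' @rdname tidy.syncom_pcoa
#' @method glance syncom_pcoa
#' @export
glance.syncom_pcoa <- function(x, ...) {
  tibble(axis = seq_along(x$prop_var),
         eigenvalue = x$eig[x$eig > 0][seq_along(x$prop_var)],
         prop_var = x$prop_var)
}

#' Tidy a recovery report
#' @param x A `recovery_report` object.
#' @param ... Unused.
#' @return `tidy()`: the per-OTU rank-abundance table; `glance()`: the
#'   one-row summary (percentage of abundant OTUs recovered, accumulated
#'   recovered relative abundance).
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$per_otu

#' @rdname tidy.recovery_report
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) x$summary

#' Tidy a perfect-match mapping result
#' @param x A `mapping_result` object.
#' @param ... Unused.
#' @return `tidy()`: per-sample mapped/unmapped/ambiguous summary;
#'   `glance()`: totals over all samples.
#' @method tidy mapping_result
#' @export
tidy.mapping_result <- function(x, ...) x$summary

#' @rdname tidy.mapping_result
#' @method glance mapping_result
#' @export
glance.mapping_result <- function(x, ...) {
  dplyr::summarise(x$summary,
                   n_samples = dplyr::n(),
                   mapped = sum(.data$mapped),
                   unmapped = sum(.data$unmapped),
                   ambiguous = sum(.data$ambiguous),
                   total = sum(.data$total))
}

#' Tidy a Kruskal-Wallis/Dunn result
#' @param x A `syncom_kw` object.
#' @param ... Unused.
#' @return `tidy()`: the pairwise Dunn comparisons with BH-adjusted p-values
#'   and the letter display; `glance()`: the omnibus test.
#' @method tidy syncom_kw
#' @export
tidy.syncom_kw <- function(x, ...) {
  dplyr::mutate(x$pairwise,
                letters1 = unname(x$letters[.data$group1]),
                letters2 = unname(x$letters[.data$group2]))
}

#' @rdname tidy.syncom_kw
#' @method glance syncom_kw
#' @export
glance.syncom_kw <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @export
print.syncom_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$df[1], x$df[2], x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery report: %d OTUs, %d abundant; %.1f%% of abundant OTUs recovered; accumulated recovered RA = %.3f\n",
              s$n_otus, s$n_abundant, s$pct_abundant_recovered,
              s$accumulated_ra_recovered))
  invisible(x)
}

#' @export
print.syncom_sim <- function(x, ...) {
  cat(sprintf("SynCom simulation: %d samples x %d strains (%s)\n",
              nrow(x$counts), ncol(x$counts) - 1L,
              x$truth$params$treatment))
  invisible(x)
}
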