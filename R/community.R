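#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total. Samples whose total is zero are
#' flagged and left as all-zero rows so they can be excluded downstream.
#'
#' @param counts Samples x features count tibble (first column `sample_id`).
#'
#' @return A tibble of the same shape with relative abundances; the attribute
#'   `"empty_samples"` lists zero-total sample ids.
#' @export
relative_abundance <- function(counts) {
  validate_count_table(counts)
  m <- counts_matrix(counts)
  tot <- rowSums(m)
  empty <- rownames(m)[tot == 0]
  tot[tot == 0] <- 1
  out <- matrix_to_tibble(m / tot)
  attr(out, "empty_samples") <- empty
  out
}

#' Shannon diversity of an abundance vector
#'
#' `H = -sum(p_i * log(p_i))` over positive entries, natural logarithm.
#'
#' @param p Relative-abundance vector summing to 1 (or a samples x features
#'   abundance tibble, giving one value per sample).
#' @return Shannon index (numeric; named vector for a table input).
#' @examples
#' shannon(rep(0.25, 4))  # log(4)
#' @export
shannon <- function(p) {
  if (is.data.frame(p)) {
    m <- counts_matrix(p)
    return(apply(m, 1, shannon))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("`p` must be a non-negative vector summing to 1.")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity
#'
#' `d = 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`, in `[0, 1]` for
#' non-negative inputs. With a table input, returns the full distance matrix
#' (via [vegan::vegdist()]).
#'
#' @param x,y Non-negative abundance vectors of equal length; or `x` a
#'   samples x features tibble and `y` missing.
#' @return A dissimilarity, or a `dist` object for table input.
#' @export
bray_curtis <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    m <- counts_matrix(x)
    return(vegan::vegdist(m, method = "bray"))
  }
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (any(x < 0) || any(y < 0)) abort("Inputs must be non-negative.")
  s <- sum(x) + sum(y)
  if (s == 0) abort("Bray-Curtis is undefined for two all-zero vectors.")
  1 - 2 * sum(pmin(x, y)) / s
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Eigendecomposition of the double-centred `-0.5 * D^2` matrix. Axes are
#' ordered by eigenvalue; negative eigenvalues (non-Euclidean distances) are
#' excluded from the variance denominator and reported separately.
#'
#' @param d A `dist` object or a symmetric, zero-diagonal distance matrix.
#'
#' @return An object of class `syncom_pcoa`: list with `points` (tibble:
#'   `sample_id`, `axis1`, `axis2`, ...), `eig` (all eigenvalues),
#'   `prop_var` (variance proportion per retained axis) and `negative_eig`.
#' @export
pcoa <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12)) {
      abort("`d` must be symmetric with a zero diagonal.")
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  pts <- fit$points[, seq_len(min(sum(pos), ncol(fit$points))), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  rownames(pts) <- ids
  structure(list(points = matrix_to_tibble(pts),
                 eig = eig,
                 prop_var = eig[pos] / sum(eig[pos]),
                 negative_eig = eig[eig < 0]),
            class = "syncom_pcoa")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (via [vegan::adonis2()]):
#' a pseudo-F statistic from among- versus within-group sums of squared
#' distances, with the p-value `(1 + #(perm F >= obs F)) / (1 + n_perm)`.
#' Permutations can be restricted within strata (e.g. experiment batches).
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param labels Group label per sample (>= 2 groups, each with >= 2 members).
#' @param n_perm Number of random permutations (default 5000).
#' @param seed Optional integer seed for the permutations.
#' @param strata Optional grouping restricting permutations to occur within
#'   its levels.
#'
#' @return An object of class `syncom_permanova`: list with `statistic`
#'   (pseudo-F), `R2`, `p_value`, `df`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 5000, seed = NULL, strata = NULL) {
  if (!inherits(d, "dist")) {
    dm <- as.matrix(d)
    if (!isSymmetric(unname(dm))) abort("`d` must be symmetric.")
    d <- stats::as.dist(dm)
  }
  labels <- factor(labels)
  if (length(labels) != attr(d, "Size")) {
    abort("`labels` must have one entry per sample in `d`.")
  }
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    abort("PERMANOVA needs >= 2 groups with >= 2 members each.")
  }
  if (!is.null(seed)) withr::local_seed(child_seed(seed, 6L))
  dat <- data.frame(group = labels)
  perm <- if (is.null(strata)) n_perm else {
    permute::how(nperm = n_perm, blocks = factor(strata))
  }
  fit <- vegan::adonis2(d ~ group, data = dat, permutations = perm)
  structure(list(statistic = fit$F[1], R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 df = c(fit$Df[1], fit$Df[2]), n_perm = n_perm,
                 n = length(labels), n_groups = nlevels(labels)),
            class = "syncom_permanova")
}

#' Aggregate relative abundances by strain host-of-origin
#'
#' Per-sample sums of relative abundances over all Lj-derived and all
#' At-derived strains — the community-level readout of host preference
#' (native strains reaching higher aggregated RA on their cognate host).
#'
#' @param ab Abundance tibble (samples x strains, first column `sample_id`).
#' @param panel Strain panel assigning each feature a `host_of_origin`.
#'
#' @return Tibble `sample_id`, `Lj_derived_RA`, `At_derived_RA`.
#' @export
aggregate_by_origin <- function(ab, panel) {
  validate_panel(panel)
  m <- counts_matrix(ab)
  missing <- setdiff(colnames(m), panel$strain_id)
  if (length(missing) > 0) {
    abort(paste0("Features missing from panel: ", paste(missing, collapse = ", ")))
  }
  origin <- panel$host_of_origin[match(colnames(m), panel$strain_id)]
  tibble(sample_id = rownames(m),
         Lj_derived_RA = unname(rowSums(m[, origin == "Lj", drop = FALSE])),
         At_derived_RA = unname(rowSums(m[, origin == "At", drop = FALSE])))
}

# Dunn's z-statistics on mean ranks with tie correction.
dunn_posthoc <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    tibble(group1 = pr[1], group2 = pr[2], z = unname(z),
           p_value = 2 * stats::pnorm(-abs(unname(z))))
  }))
}

# Compact letter display: groups sharing a letter are not significantly
# different. Letters correspond to maximal cliques of the
# "not-significantly-different" graph.
letter_display <- function(group_levels, sig_pairs) {
  k <- length(group_levels)
  nsd <- matrix(TRUE, k, k, dimnames = list(group_levels, group_levels))
  for (i in seq_len(nrow(sig_pairs))) {
    if (sig_pairs$significant[i]) {
      nsd[sig_pairs$group1[i], sig_pairs$group2[i]] <- FALSE
      nsd[sig_pairs$group2[i], sig_pairs$group1[i]] <- FALSE
    }
  }
  diag(nsd) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  out <- stats::setNames(rep("", k), group_levels)
  for (ci in seq_along(cliques)) {
    for (gl in names(cliques[[ci]])) out[gl] <- paste0(out[gl], letters[ci])
  }
  out
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Rank-based Kruskal-Wallis test (tie-corrected) across groups, followed by
#' Dunn's pairwise z-tests on mean ranks with Benjamini-Hochberg adjustment,
#' and a compact letter display in which groups sharing a letter are not
#' significantly different.
#'
#' @param values Numeric observations.
#' @param groups Group label per observation (>= 2 non-empty groups).
#' @param alpha Significance level for the letter display (default 0.05).
#'
#' @return An object of class `syncom_kw`: list with `statistic`, `df`,
#'   `p_value`, `pairwise` (tibble with BH-adjusted p-values) and `letters`.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  g <- if (is.factor(groups)) groups else factor(groups)
  if (nlevels(g) < 2) abort("Need >= 2 groups.")
  if (any(table(g) == 0)) abort("Every group needs >= 1 observation.")
  kw <- stats::kruskal.test(values, g)
  pw <- dunn_posthoc(values, g) |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, method = "BH"),
                  significant = .data$q_value <= alpha)
  structure(list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pw,
                 letters = letter_display(levels(g), pw)),
            class = "syncom_kw")
}

#' qPCR bacterial load relative to a plant gene
#'
#' Load = `2^-Ct(16S) / 2^-Ct(plant) = 2^(Ct_plant - Ct_16S)`: the abundance
#' of the bacterial 16S rRNA gene normalized to a single-copy plant gene
#' within the same sample.
#'
#' @param qpcr Data frame with columns `Ct_16S` and `Ct_plant` (finite,
#'   positive cycle thresholds); or two numeric vectors `Ct_16S`, `Ct_plant`.
#' @param Ct_plant Plant-gene Ct values when `qpcr` is a numeric vector.
#'
#' @return The input tibble with a `load` column (or a numeric vector for
#'   vector input).
#' @examples
#' qpcr_load(data.frame(sample_id = "s1", Ct_16S = 18, Ct_plant = 21))$load  # 8
#' @export
qpcr_load <- function(qpcr, Ct_plant = NULL) {
  if (is.data.frame(qpcr)) {
    stopifnot(all(c("Ct_16S", "Ct_plant") %in% names(qpcr)))
    ct16 <- qpcr$Ct_16S; ctp <- qpcr$Ct_plant
  } else {
    ct16 <- qpcr; ctp <- Ct_plant
  }
  if (any(!is.finite(ct16)) || any(!is.finite(ctp)) ||
      any(ct16 <= 0) || any(ctp <= 0)) {
    abort("Ct values must be finite and positive.")
  }
  load <- 2^(ctp - ct16)
  if (is.data.frame(qpcr)) dplyr::mutate(as_tibble(qpcr), load = load) else load
}
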