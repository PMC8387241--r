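# Shared fixtures and independent oracles used across test files.

hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

tiny_panel <- function(n = 4, seq_len = 120, seed = 7) {
  make_strain_panel(n, n, seq_len = seq_len, family_divergence = 0.10,
                    seed = seed)
}

# A hand-built panel with fully controlled sequences.
manual_panel <- function() {
  tibble::tibble(
    strain_id = c("LjA", "AtA", "LjB", "AtB"),
    host_of_origin = c("Lj", "At", "Lj", "At"),
    family = c("FA", "FA", "FB", "FB"),
    species = paste0("sp", 1:4),
    ref_seq = c(strrep("ACGT", 25),
                paste0(strrep("ACGT", 24), "ACGA"),
                strrep("GGCC", 25),
                paste0(strrep("GGCC", 24), "GGCA")))
}

# Minimal abundance table + metadata with known per-sample strain RAs.
# `ra` is a named list: sample_id -> numeric vector over strain ids.
manual_ab <- function(ra, strain_ids) {
  m <- do.call(rbind, ra)
  colnames(m) <- strain_ids
  dplyr::bind_cols(tibble::tibble(sample_id = names(ra)),
                   tibble::as_tibble(m))
}

manual_meta <- function(sample_id, host_species, compartment = "root",
                        treatment = "competition", first_inoculum = "mixed",
                        second_inoculum = "none", experiment = "exp1") {
  tibble::tibble(sample_id = sample_id, experiment = experiment,
                 host_species = host_species, host_genotype = "wt",
                 compartment = compartment, treatment = treatment,
                 first_inoculum = first_inoculum,
                 second_inoculum = second_inoculum,
                 replicate = seq_along(sample_id))
}

# Brute-force oracle: two-sided exact Mann-Whitney by full enumeration of
# group assignments of the pooled observations.
mw_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_less, p_greater)))
}

# Brute-force Kruskal-Wallis statistic with tie correction.
kw_brute <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Global-alignment identity oracle for equal-length gap-free comparisons.
identity_oracle <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  1 - hamming_chr(a, b) / nchar(a)
}

# samples x features tibble -> matrix (test-side helper, independent of
# package internals)
count_mat <- function(tbl) {
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl[[1]]
  m
}
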