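#' Build a taxonomically paired two-host strain panel
#'
#' Generates a synthetic panel of bacterial strains modelled on paired
#' synthetic communities (SynComs) from two host species, *Lotus japonicus*
#' ("Lj") and *Arabidopsis thaliana* ("At"): each bacterial family
#' contributes exactly one Lj-derived and one At-derived strain. Every
#' strain carries a v5-v7-like 16S reference fragment. Family members are
#' near-identical (they would co-cluster at 97% identity) but always
#' distinguishable at one or more positions, while strains from different
#' families diverge by at least `family_divergence` of their length.
#'
#' @param n_per_host Number of strains per host species (the panel has
#'   `2 * n_per_host` strains). Must equal `n_families` (paired panel).
#' @param n_families Number of bacterial families.
#' @param seq_len Reference fragment length in nucleotides (>= 50).
#' @param family_divergence Minimum between-family sequence divergence, as a
#'   fraction of `seq_len`, in (0, 0.5).
#' @param seed Integer seed; the same arguments and seed give a
#'   byte-identical panel.
#'
#' @return A tibble with columns `strain_id`, `host_of_origin` ("Lj"/"At"),
#'   `family`, `species` and `ref_seq`.
#' @examples
#' panel <- make_strain_panel(16, 16, seq_len = 360,
#'                            family_divergence = 0.1, seed = 7)
#' table(panel$host_of_origin)
#' @export
make_strain_panel <- function(n_per_host, n_families, seq_len = 360,
                              family_divergence = 0.10, seed = 1) {
  n_per_host <- assert_count(n_per_host, "n_per_host")
  n_families <- assert_count(n_families, "n_families")
  if (n_per_host != n_families) {
    abort("Paired panel: `n_families` must equal `n_per_host`.")
  }
  if (n_per_host == 0L) {
    return(tibble(strain_id = character(), host_of_origin = character(),
                  family = character(), species = character(),
                  ref_seq = character()))
  }
  seq_len <- assert_count(seq_len, "seq_len", min = 50L)
  family_divergence <- assert_fraction(family_divergence, "family_divergence",
                                       lo = 0, hi = 0.5,
                                       open_lo = TRUE, open_hi = TRUE)
  withr::local_seed(child_seed(seed, 1L))

  bases <- c("A", "C", "G", "T")
  k_between <- ceiling(family_divergence * seq_len)
  m_max <- ceiling(0.03 * seq_len)
  # backbones must stay apart even after each member mutates at <= m_max sites
  k_backbone <- k_between + 2L * m_max
  if (k_backbone > seq_len) {
    abort("`family_divergence` too large for this `seq_len` with paired mutations.")
  }

  rand_seq <- function() sample(bases, seq_len, replace = TRUE)
  hamming <- function(a, b) sum(a != b)

  backbones <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    repeat {
      cand <- rand_seq()
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          if (hamming(cand, backbones[[j]]) < k_backbone) { ok <- FALSE; break }
        }
      }
      if (ok) { backbones[[i]] <- cand; break }
    }
  }

  mutate_at <- function(s, pos) {
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    s
  }

  rows <- vector("list", 2L * n_families)
  for (i in seq_len(n_families)) {
    fam <- sprintf("F%02d", i)
    lj_seq <- backbones[[i]]
    m <- sample.int(m_max, 1L)
    at_seq <- mutate_at(lj_seq, sample.int(seq_len, m))
    rows[[2L * i - 1L]] <- tibble(
      strain_id = sprintf("Lj%s", fam), host_of_origin = "Lj", family = fam,
      species = sprintf("%s_spLj", fam), ref_seq = paste(lj_seq, collapse = ""))
    rows[[2L * i]] <- tibble(
      strain_id = sprintf("At%s", fam), host_of_origin = "At", family = fam,
      species = sprintf("%s_spAt", fam), ref_seq = paste(at_seq, collapse = ""))
  }
  panel <- dplyr::bind_rows(rows)
  validate_panel(panel)
  panel
}
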