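pref_fixture <- function() {
  panel <- manual_panel()
  # 3 root samples per host with fixed strain RAs
  ra <- list(
    L1 = c(0.022, 0.008, 0.47, 0.50),
    L2 = c(0.020, 0.010, 0.47, 0.50),
    L3 = c(0.018, 0.012, 0.47, 0.50),
    A1 = c(0.012, 0.0004, 0.4876, 0.50),
    A2 = c(0.010, 0.0005, 0.4895, 0.50),
    A3 = c(0.008, 0.0006, 0.4914, 0.50))
  ab <- manual_ab(ra, panel$strain_id)
  meta <- manual_meta(names(ra), c("Lj", "Lj", "Lj", "At", "At", "At"))
  list(panel = panel, ab = ab, meta = meta)
}

test_that("host preference index is the ratio of mean RAs with the 0.1% filter", {
  fx <- pref_fixture()
  pref <- host_preference_index(fx$ab, fx$meta, fx$panel)
  lja <- pref[pref$strain_id == "LjA", ]
  # mean 0.02 on Lj (cognate), 0.01 on At -> hpi = 2
  expect_equal(lja$hpi, 2)
  expect_equal(lja$mean_ra_cognate, 0.02)
  expect_equal(lja$mean_ra_other, 0.01)
  # AtA averages 0.0005 on Lj (other host): below 0.1% -> excluded
  ata <- pref[pref$strain_id == "AtA", ]
  expect_true(ata$filtered)
  expect_true(is.na(ata$hpi))
  # boundary: mean exactly 0.001 is retained (inclusive)
  ab2 <- fx$ab
  ab2$AtA[4:6] <- 0.001
  pref2 <- host_preference_index(ab2, fx$meta, fx$panel)
  expect_false(pref2$filtered[pref2$strain_id == "AtA"])
})

test_that("swapping all host labels maps every index to its reciprocal", {
  fx <- pref_fixture()
  pref <- host_preference_index(fx$ab, fx$meta, fx$panel)
  swap <- function(x) ifelse(x == "Lj", "At", "Lj")
  meta_sw <- dplyr::mutate(fx$meta, host_species = swap(host_species))
  pref_sw <- host_preference_index(fx$ab, meta_sw, fx$panel)
  joined <- dplyr::inner_join(pref, pref_sw, by = "strain_id",
                              suffix = c("", "_sw"))
  ok <- !joined$filtered
  expect_equal(joined$hpi_sw[ok], 1 / joined$hpi[ok])
})

test_that("raising the abundance filter never adds strains", {
  fx <- pref_fixture()
  kept <- vapply(c(0, 0.0005, 0.001, 0.005, 0.02), function(thr) {
    sum(!host_preference_index(fx$ab, fx$meta, fx$panel,
                               min_mean_ra = thr)$filtered)
  }, 0)
  expect_true(all(diff(kept) <= 0))
})

test_that("preference test matches exact Mann-Whitney enumeration at small n", {
  set.seed(11)
  panel <- manual_panel()
  n <- 5  # <= 8 per group: exact enumeration regime
  ra <- lapply(seq_len(2 * n), function(i) {
    p <- abs(stats::rnorm(4)) + 0.01; p / sum(p)
  })
  names(ra) <- sprintf("s%02d", seq_len(2 * n))
  ab <- manual_ab(ra, panel$strain_id)
  meta <- manual_meta(names(ra), rep(c("Lj", "At"), each = n))
  res <- test_preference(ab, meta, panel)
  m <- count_mat(ab)
  for (s in panel$strain_id) {
    cog <- panel$host_of_origin[panel$strain_id == s]
    x <- m[meta$sample_id[meta$host_species == cog], s]
    y <- m[meta$sample_id[meta$host_species != cog], s]
    oracle <- mw_enumeration(x, y)
    row <- res[res$strain_id == s, ]
    expect_equal(row$U, oracle$U)
    expect_equal(row$p_value, oracle$p)
  }
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("identical distributions across hosts yield no significant strains", {
  panel <- manual_panel()
  ra <- rep(list(c(0.25, 0.25, 0.25, 0.25)), 8)
  names(ra) <- sprintf("s%d", 1:8)
  ab <- manual_ab(ra, panel$strain_id)
  meta <- manual_meta(names(ra), rep(c("Lj", "At"), 4))
  res <- test_preference(ab, meta, panel)
  expect_true(all(res$p_value == 1))  # all tied -> convention p = 1
  expect_false(any(res$significant))
})

inv_fixture <- function(at_on_at = c(0.30, 0.34), at_on_lj = c(0.15, 0.17)) {
  panel <- manual_panel()
  # sequential samples: Lj resident / At invading on both hosts
  ra <- list(
    iL1 = c(0.50, at_on_lj[1], 0.35, at_on_lj[1]),
    iL2 = c(0.46, at_on_lj[2], 0.37, at_on_lj[2]),
    iA1 = c(0.25, at_on_at[1], 0.15, at_on_at[1]),
    iA2 = c(0.20, at_on_at[2], 0.12, at_on_at[2]))
  ab <- manual_ab(ra, panel$strain_id)
  meta <- manual_meta(names(ra), c("Lj", "Lj", "At", "At"),
                      treatment = "sequential",
                      first_inoculum = "Lj", second_inoculum = "At")
  list(panel = panel, ab = ab, meta = meta)
}

test_that("invasiveness index uses invading samples only, same filter rules", {
  fx <- inv_fixture()
  inv <- invasiveness_index(fx$ab, fx$meta, fx$panel)
  # only At strains were ever the second inoculum
  expect_setequal(inv$strain_id, c("AtA", "AtB"))
  ata <- inv[inv$strain_id == "AtA", ]
  expect_equal(ata$mean_ra_invading_cognate, 0.32)
  expect_equal(ata$mean_ra_invading_other, 0.16)
  expect_equal(ata$inv_index, 2)
  # equal success on both hosts -> index 1
  fx2 <- inv_fixture(at_on_at = c(0.2, 0.2), at_on_lj = c(0.2, 0.2))
  inv2 <- invasiveness_index(fx2$ab, fx2$meta, fx2$panel)
  expect_equal(inv2$inv_index[inv2$strain_id == "AtA"], 1)
  # boundary: exactly 0.001 in both hosts is retained
  fx3 <- inv_fixture(at_on_at = c(0.001, 0.001), at_on_lj = c(0.001, 0.001))
  inv3 <- invasiveness_index(fx3$ab, fx3$meta, fx3$panel)
  expect_false(inv3$filtered[inv3$strain_id == "AtA"])
  # no invasion samples at all -> error
  expect_error(invasiveness_index(fx$ab,
                                  dplyr::mutate(fx$meta, treatment = "competition"),
                                  fx$panel),
               "invasion")
})

test_that("index correlation is 1 when invasiveness mirrors preference", {
  panel <- manual_panel()
  pref <- tibble::tibble(experiment = "e", strain_id = panel$strain_id,
                         host_of_origin = panel$host_of_origin,
                         family = panel$family,
                         mean_ra_other = c(0.01, 0.02, 0.03, 0.04),
                         mean_ra_cognate = c(0.02, 0.08, 0.03, 0.02),
                         filtered = FALSE,
                         hpi = c(2, 4, 1, 0.5))
  inv <- dplyr::rename(pref, mean_ra_invading_cognate = mean_ra_cognate,
                       mean_ra_invading_other = mean_ra_other,
                       inv_index = hpi)
  res <- correlate_indices(pref, inv)
  expect_equal(res$r, 1)
  expect_equal(res$n, 4)
  expect_lt(res$p_value, 0.01)
  expect_error(correlate_indices(pref[1:2, ], inv[1:2, ]), "3 strains")
})

test_that("index correlation is invariant under a joint host-label swap", {
  set.seed(12)
  panel <- tiny_panel(n = 8, seq_len = 80)
  phi <- stats::setNames(2^stats::rnorm(16, 1, 0.8), panel$strain_id)
  des_c <- design_spec(replicates = 6)
  des_s <- design_spec(treatment = "sequential", replicates = 6)
  eff <- effect_spec(phi_root = phi, depth = 2e4, pi_priority = 2)
  simc <- simulate_competition(panel, des_c, eff, seed = 31)
  simi <- simulate_invasion(panel, des_s, eff, seed = 32)
  pref <- host_preference_index(relative_abundance(simc$counts),
                                simc$metadata, panel)
  inv <- invasiveness_index(relative_abundance(simi$counts),
                            simi$metadata, panel)
  r0 <- correlate_indices(pref, inv)$r
  swap <- function(x) ifelse(x == "Lj", "At", "Lj")
  meta_c_sw <- dplyr::mutate(simc$metadata, host_species = swap(host_species))
  meta_i_sw <- dplyr::mutate(simi$metadata, host_species = swap(host_species))
  pref_sw <- host_preference_index(relative_abundance(simc$counts),
                                   meta_c_sw, panel)
  inv_sw <- invasiveness_index(relative_abundance(simi$counts),
                               meta_i_sw, panel)
  r1 <- correlate_indices(pref_sw, inv_sw)$r
  expect_equal(r1, r0, tolerance = 1e-10)
})

test_that("family knockout preserves direction and conserves mass", {
  set.seed(13)
  panel <- tiny_panel(n = 6, seq_len = 80)
  sim <- simulate_competition(panel, design_spec(replicates = 8),
                              effect_spec(phi_root = 4, depth = 2e4), seed = 41)
  ab <- relative_abundance(sim$counts)
  ko <- family_knockout(ab, sim$metadata, panel)
  expect_setequal(unique(ko$family_removed), c("none", unique(panel$family)))
  # conservation: native + non-native shares sum to 1 after renormalization
  expect_true(all(abs(ko$mean_native_ra + ko$mean_nonnative_ra - 1) < 1e-9))
  # uniform preference: native strains stay ahead under every removal
  expect_true(all(ko$direction == "native_higher"))
  # removing a family absent everywhere changes nothing
  ab0 <- ab
  fam1 <- panel$strain_id[panel$family == panel$family[1]]
  ab0[fam1] <- 0
  ab0 <- relative_abundance(dplyr::mutate(ab0, dplyr::across(-sample_id,
                                                             ~ round(.x * 1e6))))
  ko0 <- family_knockout(ab0, sim$metadata, panel)
  base <- ko0[ko0$family_removed == "none", ]
  rem <- ko0[ko0$family_removed == panel$family[1], ]
  expect_equal(base$mean_native_ra, rem$mean_native_ra, tolerance = 1e-12)
  expect_equal(base$p_value, rem$p_value)
})
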