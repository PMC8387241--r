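#' @include design.R
NULL

# Resolve a scalar-or-per-strain phi into a named vector over the panel.
resolve_phi <- function(phi, panel, name) {
  n <- nrow(panel)
  if (length(phi) == 1L) phi <- rep(phi, n)
  if (!is.null(names(phi))) {
    if (!all(panel$strain_id %in% names(phi))) {
      abort(sprintf("`%s` names must cover all panel strains.", name))
    }
    phi <- phi[panel$strain_id]
  } else if (length(phi) != n) {
    abort(sprintf("`%s` must be a scalar or one value per strain.", name))
  }
  stats::setNames(as.double(phi), panel$strain_id)
}

# Per-family base abundances, log-normal, shared within a family pair.
draw_bases <- function(panel, sdlog) {
  fams <- unique(panel$family)
  b <- stats::rlnorm(length(fams), meanlog = 0, sdlog = sdlog)
  stats::setNames(b[match(panel$family, fams)], panel$strain_id)
}

# Strain weights for one sample under the host-preference model. Soil is
# neutral; nfr5-type genotypes retain only a fraction of the root effect.
sample_weights <- function(base, panel, host_species, host_genotype,
                           compartment, effects, phi_root, phi_rhizo,
                           priority_boost = NULL) {
  phi <- rep(1, nrow(panel))
  if (compartment %in% c("root", "rhizosphere")) {
    native <- panel$host_of_origin == host_species
    raw <- if (compartment == "root") phi_root else phi_rhizo
    if (compartment == "root" && identical(host_genotype, "nfr5")) {
      raw <- 1 + effects$nfr5_attenuation * (raw - 1)
    }
    phi[native] <- raw[native]
  }
  w <- base * phi
  if (!is.null(priority_boost)) w <- w * priority_boost
  w
}

finish_sim <- function(rows, panel, effects, truth_params, bases) {
  counts <- dplyr::bind_rows(lapply(rows, `[[`, "counts"))
  metadata <- dplyr::bind_rows(lapply(rows, `[[`, "meta"))
  expected <- dplyr::bind_rows(lapply(rows, `[[`, "expected"))
  truth <- list(params = truth_params,
                bases = tibble(strain_id = names(bases), base = unname(bases)),
                expected_ra = expected)
  structure(list(counts = counts, metadata = metadata, truth = truth),
            class = "syncom_sim")
}

sim_one_sample <- function(sample_id, w, depth, conc, panel) {
  p <- w / sum(w)
  cnt <- rdirmultinom(depth, p, conc)
  list(
    counts = dplyr::bind_cols(tibble(sample_id = sample_id),
                              as_tibble(as.list(stats::setNames(cnt, panel$strain_id)))),
    expected = dplyr::bind_cols(tibble(sample_id = sample_id),
                                as_tibble(as.list(stats::setNames(p, panel$strain_id)))))
}

#' Simulate a mixed-SynCom competition experiment
#'
#' Generates strain-level count tables for a competition design: the full
#' panel is inoculated at once onto each host, and root / rhizosphere / soil
#' samples are sequenced. Expected relative abundances follow a normalized
#' weight model: strain `s` in a sample of host `h`, compartment `c` has
#' weight `base_s * phi_c` if `s` is native to `h` (and `base_s` otherwise),
#' where per-family base abundances are drawn once per experiment from a
#' log-normal and shared within each Lj/At family pair, and soil is always
#' neutral. Counts are Dirichlet-multinomial around the expected relative
#' abundances at the configured depth and overdispersion.
#'
#' @param panel Strain panel from [make_strain_panel()].
#' @param design A [design_spec()] with `treatment = "competition"`.
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#'
#' @return An object of class `syncom_sim`: a list with `counts` (tibble,
#'   samples x strains), `metadata` (one row per sample) and `truth`
#'   (generative parameters, per-strain base abundances and the realized
#'   expected relative abundances).
#' @examples
#' panel <- make_strain_panel(4, 4, seed = 1)
#' sim <- simulate_competition(panel, design_spec(replicates = 3),
#'                             effect_spec(depth = 1000), seed = 1)
#' sim$counts[1:3, 1:4]
#' @export
simulate_competition <- function(panel, design = design_spec(),
                                 effects = effect_spec(), seed = 1) {
  validate_panel(panel)
  if (nrow(panel) == 0) abort("`panel` must be non-empty.")
  if (design$treatment != "competition") {
    abort("`design$treatment` must be 'competition'.")
  }
  withr::local_seed(child_seed(seed, 2L))
  phi_root <- resolve_phi(effects$phi_root, panel, "phi_root")
  phi_rhizo <- resolve_phi(effects$phi_rhizo, panel, "phi_rhizo")
  bases <- draw_bases(panel, effects$base_sdlog)

  rows <- list()
  for (hi in seq_len(nrow(design$hosts))) {
    sp <- design$hosts$species[hi]; gt <- design$hosts$genotype[hi]
    for (comp in design$compartments) {
      for (r in seq_len(design$replicates)) {
        sid <- sprintf("%s_%s.%s_%s_r%02d", design$experiment, sp, gt, comp, r)
        w <- sample_weights(bases, panel, sp, gt, comp, effects,
                            phi_root, phi_rhizo)
        one <- sim_one_sample(sid, w, effects$depth, effects$overdispersion, panel)
        one$meta <- tibble(sample_id = sid, experiment = design$experiment,
                           host_species = sp, host_genotype = gt,
                           compartment = comp, treatment = "competition",
                           first_inoculum = "mixed", second_inoculum = "none",
                           replicate = r)
        rows[[length(rows) + 1L]] <- one
      }
    }
  }
  params <- c(list(treatment = "competition", depth = effects$depth,
                   overdispersion = effects$overdispersion,
                   nfr5_attenuation = effects$nfr5_attenuation,
                   base_sdlog = effects$base_sdlog, seed = seed),
              as.list(stats::setNames(phi_root, paste0("phi_root.", names(phi_root)))),
              as.list(stats::setNames(phi_rhizo, paste0("phi_rhizo.", names(phi_rhizo)))))
  finish_sim(rows, panel, effects, params, bases)
}

#' Simulate a sequential-inoculation (invasion) experiment
#'
#' Emulates priority-effect experiments: a resident SynCom is established
#' first and a second SynCom invades later. Resident strains' weights are
#' multiplied by `pi_priority`; host-preference factors apply exactly as in
#' [simulate_competition()]. Both arms are emitted (each host-of-origin
#' SynCom takes the resident and the invader role), together with
#' mixed-inoculation control samples in which no strain has a priority
#' advantage.
#'
#' @inheritParams simulate_competition
#' @param design A [design_spec()] with `treatment = "sequential"`.
#' @param resident_set,invader_set Strain-id sets for the first arm; must be
#'   disjoint and jointly cover the panel. Default: the Lj-derived strains
#'   resident, the At-derived strains invading (the second arm swaps roles).
#' @param include_mixed_control Emit the mixed (simultaneous) control arm.
#'
#' @return A `syncom_sim` (see [simulate_competition()]); metadata columns
#'   `first_inoculum` / `second_inoculum` label every sample's inoculation
#'   order by SynCom identity.
#' @export
simulate_invasion <- function(panel,
                              design = design_spec(treatment = "sequential"),
                              effects = effect_spec(), seed = 1,
                              resident_set = NULL, invader_set = NULL,
                              include_mixed_control = TRUE) {
  validate_panel(panel)
  if (nrow(panel) == 0) abort("`panel` must be non-empty.")
  if (design$treatment != "sequential") {
    abort("`design$treatment` must be 'sequential'.")
  }
  if (is.null(resident_set)) resident_set <- panel$strain_id[panel$host_of_origin == "Lj"]
  if (is.null(invader_set)) invader_set <- panel$strain_id[panel$host_of_origin == "At"]
  if (length(intersect(resident_set, invader_set)) > 0) {
    abort("`resident_set` and `invader_set` must be disjoint.")
  }
  if (!setequal(union(resident_set, invader_set), panel$strain_id)) {
    abort("`resident_set` and `invader_set` must partition the panel.")
  }
  lab <- function(ids) {
    h <- unique(panel$host_of_origin[panel$strain_id %in% ids])
    if (length(h) == 1) h else if (setequal(ids, resident_set)) "SC1" else "SC2"
  }
  set_labels <- list(resident = lab(resident_set), invader = lab(invader_set))
  sets <- stats::setNames(list(resident_set, invader_set),
                          c(set_labels$resident, set_labels$invader))

  withr::local_seed(child_seed(seed, 3L))
  phi_root <- resolve_phi(effects$phi_root, panel, "phi_root")
  phi_rhizo <- resolve_phi(effects$phi_rhizo, panel, "phi_rhizo")
  bases <- draw_bases(panel, effects$base_sdlog)

  arms <- list(c(first = names(sets)[1], second = names(sets)[2]),
               c(first = names(sets)[2], second = names(sets)[1]))
  if (include_mixed_control) arms <- c(arms, list(c(first = "mixed", second = "none")))

  rows <- list()
  for (hi in seq_len(nrow(design$hosts))) {
    sp <- design$hosts$species[hi]; gt <- design$hosts$genotype[hi]
    for (comp in design$compartments) {
      for (arm in arms) {
        boost <- rep(1, nrow(panel))
        if (arm[["first"]] != "mixed") {
          boost[panel$strain_id %in% sets[[arm[["first"]]]]] <- effects$pi_priority
        }
        for (r in seq_len(design$replicates)) {
          sid <- sprintf("%s_%s.%s_%s_%st%s_r%02d", design$experiment, sp, gt,
                         comp, arm[["first"]], arm[["second"]], r)
          w <- sample_weights(bases, panel, sp, gt, comp, effects,
                              phi_root, phi_rhizo, priority_boost = boost)
          one <- sim_one_sample(sid, w, effects$depth, effects$overdispersion, panel)
          one$meta <- tibble(sample_id = sid, experiment = design$experiment,
                             host_species = sp, host_genotype = gt,
                             compartment = comp, treatment = "sequential",
                             first_inoculum = arm[["first"]],
                             second_inoculum = arm[["second"]],
                             replicate = r)
          rows[[length(rows) + 1L]] <- one
        }
      }
    }
  }
  params <- c(list(treatment = "sequential", depth = effects$depth,
                   overdispersion = effects$overdispersion,
                   pi_priority = effects$pi_priority,
                   nfr5_attenuation = effects$nfr5_attenuation,
                   base_sdlog = effects$base_sdlog, seed = seed),
              as.list(stats::setNames(phi_root, paste0("phi_root.", names(phi_root)))))
  finish_sim(rows, panel, effects, params, bases)
}
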