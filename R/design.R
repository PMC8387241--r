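#' Describe a gnotobiotic experiment layout
#'
#' A design names the host plants (species and genotype), the sampled
#' compartments, the number of replicate pots per host x compartment cell and
#' the inoculation treatment: `"competition"` (all strains inoculated at
#' once) or `"sequential"` (a resident SynCom established first, a second
#' SynCom invading later, plus mixed-inoculation controls).
#'
#' @param hosts Data frame with columns `species` ("Lj"/"At") and `genotype`
#'   (e.g. "wt", "nfr5"); defaults to wild-type Lj and At.
#' @param compartments Character subset of `c("root", "rhizosphere", "soil")`.
#' @param replicates Replicate samples per host x compartment (x inoculation
#'   arm for sequential designs); >= 1.
#' @param treatment `"competition"` or `"sequential"`.
#' @param experiment Experiment label written into the sample metadata.
#'
#' @return A list of class `syncom_design`.
#' @export
design_spec <- function(hosts = tibble(species = c("Lj", "At"),
                                       genotype = c("wt", "wt")),
                        compartments = "root",
                        replicates = 12,
                        treatment = c("competition", "sequential"),
                        experiment = "exp1") {
  treatment <- match.arg(treatment)
  if (!is.data.frame(hosts) || !all(c("species", "genotype") %in% names(hosts)) ||
      !all(hosts$species %in% c("Lj", "At"))) {
    abort("`hosts` needs columns species ('Lj'/'At') and genotype.")
  }
  if (!all(compartments %in% c("root", "rhizosphere", "soil")) ||
      length(compartments) < 1) {
    abort("`compartments` must be a non-empty subset of root/rhizosphere/soil.")
  }
  replicates <- assert_count(replicates, "replicates", min = 1L)
  structure(list(hosts = as_tibble(hosts), compartments = compartments,
                 replicates = replicates, treatment = treatment,
                 experiment = experiment),
            class = "syncom_design")
}

#' Effect sizes for the community simulator
#'
#' Parameters of the generative model behind [simulate_competition()] and
#' [simulate_invasion()]. A native strain's weight in a cognate-host root
#' sample is multiplied by `phi_root` (rhizosphere: `phi_rhizo`; unplanted
#' soil is always neutral). In symbiosis-mutant hosts (genotype "nfr5") the
#' root preference effect is attenuated: the applied factor becomes
#' `1 + nfr5_attenuation * (phi_root - 1)`. In sequential designs the
#' first-inoculated (resident) strains' weights are multiplied by
#' `pi_priority`.
#'
#' @param phi_root Host-preference fold-factor in root samples; a scalar or a
#'   per-strain vector (named by strain id, or in panel order) >= 0.
#' @param phi_rhizo Same for rhizosphere samples (default 1, no preference).
#' @param nfr5_attenuation Fraction in `[0, 1]` of the root preference effect
#'   retained in symbiosis-deficient (nfr5) hosts.
#' @param pi_priority Resident-advantage fold-factor for sequential designs.
#' @param depth Sequencing depth (reads per sample).
#' @param overdispersion Dirichlet concentration; counts are
#'   Dirichlet-multinomial with this concentration around the expected
#'   relative abundances. `Inf` gives plain multinomial sampling.
#' @param base_sdlog Standard deviation (log scale) of the log-normal
#'   per-family base abundances, drawn once per experiment and shared by the
#'   two members of a family pair.
#'
#' @return A list of class `syncom_effects`.
#' @export
effect_spec <- function(phi_root = 4, phi_rhizo = 1, nfr5_attenuation = 0.5,
                        pi_priority = 3, depth = 1e5, overdispersion = 200,
                        base_sdlog = 1) {
  if (any(!is.finite(phi_root)) || any(phi_root < 0)) {
    abort("`phi_root` must be finite and >= 0.")
  }
  if (any(!is.finite(phi_rhizo)) || any(phi_rhizo < 0)) {
    abort("`phi_rhizo` must be finite and >= 0.")
  }
  nfr5_attenuation <- assert_fraction(nfr5_attenuation, "nfr5_attenuation")
  if (!is.finite(pi_priority) || pi_priority < 0) {
    abort("`pi_priority` must be finite and >= 0.")
  }
  depth <- assert_count(depth, "depth", min = 1L)
  if (!(is.numeric(overdispersion) && length(overdispersion) == 1 &&
        overdispersion > 0)) {
    abort("`overdispersion` must be a positive scalar (Inf allowed).")
  }
  structure(list(phi_root = phi_root, phi_rhizo = phi_rhizo,
                 nfr5_attenuation = nfr5_attenuation,
                 pi_priority = pi_priority, depth = depth,
                 overdispersion = overdispersion, base_sdlog = base_sdlog),
            class = "syncom_effects")
}
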