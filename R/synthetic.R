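# Synthetic titrations and partition assays with known ground truth.
#
# The generator emulates the two experimental arms of a peptide/membrane-
# protein interface study:
#   * a "lipid" arm -- weak, fast-exchange binding to detergent micelles,
#     where the signature is chemical-shift movement (CSP-dominant);
#   * a "protein" arm -- tighter binding to the membrane-protein partner,
#     where a subset of interface residues broadens and can vanish
#     (broadening-dominant), riding on the same fast-exchange CSP.
# Every scenario carries its ground truth (Kd, per-residue shift endpoints,
# broadening susceptibilities) so downstream fits are testable by parameter
# recovery.

#' Build a titration scenario
#'
#' @param roster data.frame describing the residue cast: `residue`,
#'   `atom_group` (`"bb"`/`"sc"`), `shift_H0`, `shift_N0` (free-state
#'   shifts, ppm), `intensity0`, `ddH_max`, `ddN_max` (bound-state shift
#'   changes, ppm), `domega` (dimensionless exchange-broadening
#'   susceptibility; 0 = no broadening), `interface` (logical).
#'   Non-interface residues must have zero `ddH_max`, `ddN_max`, `domega`.
#' @param P Labelled-species concentration, uM.
#' @param L_schedule Strictly increasing titrant concentrations, uM.
#' @param Kd_true Ground-truth dissociation constant, uM.
#' @param k_ex Exchange rate scale, s^-1; larger = faster exchange = less
#'   broadening.
#' @param broadening_constant Dimensionless constant `c` of the intensity
#'   model (see [simulate_titration()]).
#' @param detection_floor Intensity ratio below which a peak is considered
#'   broadened beyond detection and omitted from the list.
#' @param shift_noise Gaussian noise SD added to every measured shift, ppm.
#' @param intensity_noise Fractional Gaussian noise SD on intensities.
#' @param titrant Label for the titrant species.
#' @param seed Integer seed; identical seeds give identical simulations.
#' @return A `titration_scenario` list, validated.
#' @export
titration_scenario <- function(roster = default_roster("protein"),
                               P = 20, L_schedule = c(10, 20, 60, 100),
                               Kd_true = 140, k_ex = 500,
                               broadening_constant = 1,
                               detection_floor = 0.05,
                               shift_noise = 0.003, intensity_noise = 0.02,
                               titrant = "partner", seed = 1) {
  need <- c("residue", "atom_group", "shift_H0", "shift_N0", "intensity0",
            "ddH_max", "ddN_max", "domega", "interface")
  if (!all(need %in% names(roster)))
    stop_validation("roster needs columns: ", paste(need, collapse = ", "))
  noniface <- !roster$interface
  if (any(roster$ddH_max[noniface] != 0 | roster$ddN_max[noniface] != 0 |
            roster$domega[noniface] != 0))
    stop_validation("non-interface residues must have zero ddH_max, ",
                    "ddN_max and domega")
  if (any(diff(L_schedule) <= 0) || any(L_schedule < 0))
    stop_validation("L_schedule must be non-negative and strictly increasing")
  if (P <= 0 || Kd_true < 0 || k_ex <= 0)
    stop_validation("require P > 0, Kd_true >= 0, k_ex > 0")
  if (shift_noise < 0 || intensity_noise < 0 || detection_floor < 0)
    stop_validation("noise and detection floor must be >= 0")
  structure(list(roster = roster, P = P, L_schedule = L_schedule,
                 Kd_true = Kd_true, k_ex = k_ex,
                 broadening_constant = broadening_constant,
                 detection_floor = detection_floor,
                 shift_noise = shift_noise,
                 intensity_noise = intensity_noise,
                 titrant = titrant, seed = as.integer(seed)),
            class = "titration_scenario")
}

#' Default synthetic residue rosters
#'
#' Two desk-scale casts of 34 backbone amides (plus, for the protein arm,
#' two Trp sidechain indole NHs).  They are synthetic: residue identities
#' echo the cast of a spider-toxin voltage-sensor study only so that worked
#' examples read naturally; the shift values and response magnitudes are
#' invented, order-of-magnitude-plausible numbers.
#'
#' * `"protein"`: broadening-dominant arm.  Severe residues (`R24`, the
#'   `W25` indole) carry a large exchange susceptibility and vanish at high
#'   titrant; a moderate group (`G3`, `K10`, the `W27` indole, `F34`)
#'   broadens measurably; interface residues also shift.
#' * `"lipid"`: CSP-dominant arm.  Six interface residues move with
#'   saturating combined shift changes >= 0.05 ppm; nothing broadens.
#'
#' @param arm `"protein"` or `"lipid"`.
#' @return A roster data.frame for [titration_scenario()].
#' @export
default_roster <- function(arm = c("protein", "lipid")) {
  arm <- match.arg(arm)
  n <- 34
  letters34 <- c("E", "C", "G", "K", "F", "M", "W", "K", "C", "K",
                 "I", "C", "N", "S", "Y", "E", "K", "D", "L", "V",
                 "G", "S", "C", "R", "W", "K", "W", "C", "E", "L",
                 "A", "S", "C", "F")  # synthetic 34-residue cast
  res <- paste0(letters34, seq_len(n))
  # deterministic, dispersed free-state shifts inside the amide region
  sH <- 7.2 + 0.09 * ((seq_len(n) * 7) %% 23)
  sN <- 106 + ((seq_len(n) * 11) %% 29)
  inten <- 1e6 * (0.8 + 0.02 * ((seq_len(n) * 5) %% 21))
  roster <- data.frame(residue = res, atom_group = "bb",
                       shift_H0 = sH, shift_N0 = sN, intensity0 = inten,
                       ddH_max = 0, ddN_max = 0, domega = 0,
                       interface = FALSE, stringsAsFactors = FALSE)
  if (arm == "lipid") {
    iface <- c(5, 7, 8, 24, 27, 30)  # hydrophobic-patch cast
    ddH <- c(0.06, 0.12, 0.08, 0.10, 0.07, 0.05)
    ddN <- c(0.20, 0.50, 0.30, 0.30, 0.40, 0.10)
    roster$ddH_max[iface] <- ddH
    roster$ddN_max[iface] <- ddN
    roster$interface[iface] <- TRUE
  } else {
    sev <- match("R24", roster$residue)
    mod <- match(c("G3", "K10", "F34"), roster$residue)
    roster$interface[c(sev, mod)] <- TRUE
    roster$domega[sev] <- 100
    roster$domega[mod] <- 45
    roster$ddH_max[c(sev, mod)] <- c(0.08, 0.04, 0.05, 0.06)
    roster$ddN_max[c(sev, mod)] <- c(0.30, 0.20, 0.15, 0.25)
    sc <- data.frame(residue = c("W25", "W27"), atom_group = "sc",
                     shift_H0 = c(10.15, 10.05), shift_N0 = c(129.3, 129.9),
                     intensity0 = c(9e5, 8.5e5),
                     ddH_max = c(0.06, 0.05), ddN_max = c(0.25, 0.20),
                     domega = c(100, 45), interface = TRUE,
                     stringsAsFactors = FALSE)
    roster <- rbind(roster, sc)
  }
  roster
}

#' Simulate an HSQC titration series
#'
#' Forward model, per titration point with titrant concentration L:
#'
#' * bound fraction `fb = fraction_bound(P, L, Kd_true)`;
#' * fast-exchange population-average shifts:
#'   `shift = shift0 + fb * dd_max` in each dimension;
#' * fast-exchange broadening: intensity ratio
#'   `exp(-c * fb * (1 - fb) * domega^2 / k_ex)` -- the exchange
#'   contribution to the linewidth, maximal near half-saturation;
#' * peaks whose noiseless ratio falls below the detection floor are
#'   omitted (broadened out);
#' * Gaussian noise on shifts (additive, ppm) and intensities
#'   (multiplicative, fractional) from the scenario's seeded stream.
#'
#' Identical seeds give identical output.
#'
#' @param scenario A [titration_scenario()].
#' @return A `titration_series` (see [match_series()]) with attribute
#'   `truth` holding the scenario.
#' @export
simulate_titration <- function(scenario) {
  if (!inherits(scenario, "titration_scenario"))
    stop_validation("scenario must be a titration_scenario")
  ro <- scenario$roster
  n <- nrow(ro)
  with_seed(scenario$seed, {
    make_point <- function(L) {
      fb <- fraction_bound(scenario$P, L, scenario$Kd_true)
      sH <- ro$shift_H0 + fb * ro$ddH_max +
        stats::rnorm(n, 0, scenario$shift_noise)
      sN <- ro$shift_N0 + fb * ro$ddN_max +
        stats::rnorm(n, 0, scenario$shift_noise)
      ratio <- exp(-scenario$broadening_constant * fb * (1 - fb) *
                     ro$domega^2 / scenario$k_ex)
      inten <- ro$intensity0 * ratio *
        (1 + stats::rnorm(n, 0, scenario$intensity_noise))
      inten <- pmax(inten, 0)
      keep <- ratio >= scenario$detection_floor
      peak_list(ro$residue[keep], sH[keep], sN[keep], inten[keep],
                ro$atom_group[keep],
                condition = list(labelled_uM = scenario$P,
                                 titrant = scenario$titrant,
                                 titrant_conc = L,
                                 temperature_C = 25))
    }
    reference <- make_point(0)
    points <- lapply(scenario$L_schedule, make_point)
    series <- match_series(reference, points,
                           labelled_total = scenario$P)
    attr(series, "truth") <- scenario
    series
  })
}

#' Simulate a binding-observation table at a fixed design
#'
#' Direct generator for intensity-change (or CSP) titration responses under
#' the single-site quadratic model -- the input format of [fit_kd()].
#'
#' @param P Labelled-species concentration, uM.
#' @param L Titrant concentrations, uM.
#' @param Kd_true Ground-truth dissociation constant, uM.
#' @param delta_max_true Saturating response.
#' @param noise_sd Additive Gaussian noise SD, units of the observable.
#' @param seed Seed used when `noise_sd > 0`.
#' @return data.frame `L`, `delta_obs` with attribute `truth`.
#' @export
simulate_binding_series <- function(P, L, Kd_true, delta_max_true = 1,
                                    noise_sd = 0, seed = 1) {
  y <- predict_delta_obs(P, L, Kd_true, delta_max_true)
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(L), 0, noise_sd))
  out <- data.frame(L = L, delta_obs = y)
  attr(out, "truth") <- list(P = P, Kd = Kd_true, delta_max = delta_max_true,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Build a partition-assay scenario
#'
#' @param Kp_true Ground-truth mole-fraction partition coefficient.
#' @param lipid_schedule Lipid concentrations, M, non-negative increasing.
#' @param peptide_total Total peptide, uM.
#' @param water_conc Molar water concentration, M.
#' @param noise Fractional (multiplicative) Gaussian noise SD on free
#'   signals.
#' @param seed Integer seed.
#' @return A `partition_scenario` list.
#' @export
partition_scenario <- function(Kp_true = 2.4e5,
                               lipid_schedule = c(0.2, 0.5, 0.9, 1.3) * 1e-3,
                               peptide_total = 10,
                               water_conc = WATER_CONC_M,
                               noise = 0, seed = 1) {
  if (any(diff(lipid_schedule) <= 0) || any(lipid_schedule < 0))
    stop_validation("lipid_schedule must be non-negative and increasing")
  if (Kp_true < 0 || noise < 0 || peptide_total <= 0)
    stop_validation("require Kp_true >= 0, noise >= 0, peptide_total > 0")
  structure(list(Kp_true = Kp_true, lipid_schedule = lipid_schedule,
                 peptide_total = peptide_total, water_conc = water_conc,
                 noise = noise, seed = as.integer(seed)),
            class = "partition_scenario")
}

#' Simulate a liposome centrifugation assay
#'
#' Free-peptide concentrations follow the mole-fraction partition model:
#' `free = total * free_fraction(Kp_true, lipid, water)`, with optional
#' multiplicative Gaussian noise from the seeded stream.
#'
#' @param scenario A [partition_scenario()].
#' @return Measurement data.frame (`lipid_conc_M`, `free_signal`,
#'   `peptide_total_uM`) consumable by [fit_kp()]; attribute `truth` holds
#'   the scenario.
#' @export
simulate_partition_assay <- function(scenario) {
  if (!inherits(scenario, "partition_scenario"))
    stop_validation("scenario must be a partition_scenario")
  free <- scenario$peptide_total *
    free_fraction(scenario$Kp_true, scenario$lipid_schedule,
                  scenario$water_conc)
  if (scenario$noise > 0)
    free <- with_seed(scenario$seed, {
      pmax(free * (1 + stats::rnorm(length(free), 0, scenario$noise)), 0)
    })
  out <- data.frame(lipid_conc_M = scenario$lipid_schedule,
                    free_signal = free,
                    peptide_total_uM = scenario$peptide_total)
  attr(out, "truth") <- scenario
  out
}

#' Worked-example interface evidence table
#'
#' A ready-made evidence table for a spider-toxin (partner `"A"`) bound to a
#' channel voltage-sensor domain (partner `"B"`), of the kind produced by
#' combining [broadening_profile()] severities with mutagenesis and
#' surface-accessibility annotations.  Used in documentation and tests of
#' [select_active_passive()].
#'
#' @return Evidence data.frame (see [select_active_passive()]).
#' @export
example_interface_evidence <- function() {
  toxin <- data.frame(
    residue = c("R24", "W25", "K10", "W27", "F34", "N13"),
    partner = "A",
    severity = c("severe", "severe", "significant", "significant",
                 "significant", "none"),
    csp_significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    mutagenesis_hit = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    surface_exposed = TRUE,
    stringsAsFactors = FALSE)
  vsd_active <- c("E45", "Q49", "E107")
  vsd_passive <- c("V43", "Y46", "T47", "L50", "S51", "L55",
                   "F116", "V119", "R123", "I127")
  vsd_buried <- c("G101", "F137", "L148")
  vsd <- data.frame(
    residue = c(vsd_active, vsd_passive, vsd_buried),
    partner = "B",
    severity = "significant",
    csp_significant = TRUE,
    mutagenesis_hit = c(rep(TRUE, 3), rep(FALSE, 13)),
    surface_exposed = c(rep(TRUE, 13), rep(FALSE, 3)),
    stringsAsFactors = FALSE)
  rbind(toxin, vsd)
}
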