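# Shared fixtures: all built in code at test time.

# Independent bisection oracle for the two-state mass-action equilibrium:
# solves (P - B)(L - B) = Kd * B for the bound concentration B in
# [0, min(P, L)] and returns B / P.  Deliberately shares no code with
# fraction_bound().
fb_bisect <- function(P, L, Kd, tol = 1e-14) {
  if (L == 0) return(0)
  f <- function(B) (P - B) * (L - B) - Kd * B
  lo <- 0; hi <- min(P, L)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * min(P, L)) break
  }
  ((lo + hi) / 2) / P
}

# Small in-code Sparky and CSV peak lists.
sparky_text <- function() {
  paste(c("Assignment w1 w2 Height",
          "R24N-H 121.30 8.45 1.0e6",
          "W25NE1-HE1 129.50 10.10 8.0e5",
          "N13N-H 118.20 8.10 1.2e6"), collapse = "\n")
}

csv_text <- function() {
  paste(c("residue,atom_group,shift_H_ppm,shift_N_ppm,intensity",
          "R24,bb,8.45,121.3,1000000",
          "W25,sc,10.1,129.5,800000",
          "N13,bb,8.1,118.2,1200000"), collapse = "\n")
}

make_pl <- function(residue, shift_H, shift_N, intensity = 1e6,
                    atom_group = "bb", conc = 0, labelled = 20) {
  peak_list(residue, shift_H, shift_N, intensity, atom_group,
            condition = list(labelled_uM = labelled, titrant = "partner",
                             titrant_conc = conc, temperature_C = 25))
}

# Minimal two-residue PDB fragment with fixed-format columns.
pdb_fixture <- function() {
  c("HEADER    SYNTHETIC TEST STRUCTURE",
    "ATOM      1  N   ARG A  24      11.104  13.207   9.002  1.00 20.00           N",
    "ATOM      2  CA  ARG A  24      12.560  13.300   9.100  1.00 21.15           C",
    "ATOM      3  N   TRP A  25      13.000  14.100  10.200  1.00 19.00           N",
    "ATOM      4  CA  TRP A  25      14.400  14.300  10.600  1.00 18.30           C",
    "TER       5      TRP A  25",
    "END")
}

lipid_scenario <- function(seed = 1, noise = TRUE) {
  titration_scenario(default_roster("lipid"), P = 30,
                     L_schedule = c(2000, 4000, 10000, 20000),
                     Kd_true = 5000, titrant = "micelle",
                     shift_noise = if (noise) 0.003 else 0,
                     intensity_noise = if (noise) 0.02 else 0,
                     seed = seed)
}

planted_lipid_interface <- c("F5", "W7", "K8", "R24", "W27", "L30")
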