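# Shared fixtures: all built in code, nothing on disk.

# Volmer-type branch sampled on a pressure grid, noiseless.
volmer_branch <- function(A0 = 40, pi_c = 5.7, kT = 428.2,
                          p = seq(0, 35, by = 0.1)) {
  isotherm(area = A0 + kT / (p + pi_c), pressure = p,
           compound_id = "volmer-fixture")
}

# Default study components used across tests.
fix_p1 <- eos_dmpc()
fix_p2 <- eos_non_spreading("drug-like")
fix_fractions <- c(0.015, 0.03, 0.045, 0.06, 0.09, 0.12, 0.25, 0.50)

# Write an isotherm file from raw text lines (for parser edge cases).
write_iso_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

good_iso_lines <- c(
  "# compound_id=DMPC",
  "# molar_fraction_x2=0",
  "# temperature_C=37",
  "area_A2,pressure_mN_per_m",
  "130.0,0.02",
  "120.0,0.15",
  "100.0,1.2",
  "80.0,5.4",
  "60.0,15.7")
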