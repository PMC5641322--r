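# shared builders for synthetic inputs used across test files

withr_like_tempdir <- function() {
  d <- tempfile("anammoxIPT-test-")
  dir.create(d)
  d
}

noiseless_spec <- function(A = 3.5, D = 0.7, Fn = 1, Fa = 0, seed = 1) {
  simulation_spec(true_anammox = A, true_denitrification = D,
                  F = labeled_fraction(F_nitrite = Fn, F_ammonium = Fa),
                  noise_sd = 0, seed = seed)
}

# exact-line series: excess = slope * time(d), single replicate
line_series <- function(slope29, slope30, times_h = c(0, 14, 24, 36, 48)) {
  data.frame(time_h = times_h, replicate = "R1",
             excess29_nmol_per_L = slope29 * times_h / 24,
             excess30_nmol_per_L = slope30 * times_h / 24)
}

# closed-form OLS slope, independent of fit_production_rates
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

marker_row <- function(well, marker, molecule, copies, bd = FALSE,
                       loq = 1e3) {
  data.frame(well = well, marker = marker, molecule = molecule,
             copies = copies, below_detection = bd,
             quantification_limit = loq, stringsAsFactors = FALSE)
}

# minimal one-well marker table with adjustable copy numbers
one_well_table <- function(well = "H53", hzsa = 100, aoa = 50, aob = 50,
                           nirs = 9.5e6, ssu = 1e8, molecule = "gene",
                           hzsa_bd = FALSE, aoa_bd = FALSE, aob_bd = FALSE) {
  rbind(marker_row(well, "hzsA", molecule, hzsa, hzsa_bd),
        marker_row(well, "amoA_AOA", molecule, aoa, aoa_bd),
        marker_row(well, "amoA_AOB", molecule, aob, aob_bd),
        marker_row(well, "nirS", "gene", nirs),
        marker_row(well, "16S", "gene", ssu))
}
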