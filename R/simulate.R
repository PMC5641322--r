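# Seeded generators emulating the incubation experiments and the
# cross-well marker survey. All draws are bit-reproducible under a fixed
# seed; the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a synthetic incubation experiment
#'
#' Bundles the ground truth for a simulated tracer incubation: the true
#' anammox and denitrification rates, labeled fractions, measurement noise
#' and the bottle design. The default design and tracer levels mirror a
#' groundwater \eqn{^{15}}NO2- incubation (5 uM tracer, triplicates at
#' 0/14/24/36/48 h, 30 mL water / 8 mL headspace, 15 degC).
#'
#' @param true_anammox,true_denitrification True rates (nmol N2 L-1 d-1).
#' @param F A [labeled_fraction()]; the default (F_nitrite = 1) is the
#'   undiluted-label limit of a nitrite-tracer incubation over a
#'   below-detection in-situ nitrite pool.
#' @param noise_sd Measurement noise standard deviation (nmol L-1),
#'   applied independently to every excess observation.
#' @param noise_type `"additive"` Gaussian (default) or `"multiplicative"`
#'   (log-normal factor with the same relative sd).
#' @param design An [incubation_design()].
#' @param seed Integer seed governing all draws.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(true_anammox = 3.5, true_denitrification = 0.7,
                            F = labeled_fraction(F_nitrite = 1),
                            noise_sd = 0.5,
                            noise_type = c("additive", "multiplicative"),
                            design = incubation_design(),
                            seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(inherits(F, "labeled_fraction"),
            inherits(design, "incubation_design"))
  if (true_anammox < 0 || true_denitrification < 0)
    stop("true rates must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(true_anammox = true_anammox,
                 true_denitrification = true_denitrification,
                 F = F, noise_sd = noise_sd, noise_type = noise_type,
                 design = design, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an isotopologue accumulation time series
#'
#' Generates per-bottle excess \eqn{^{29}}N2 and \eqn{^{30}}N2
#' observations under zero-order kinetics: the expected excess at time t is
#' P29 * t and P30 * t with (P29, P30) from [forward_pairing()] applied to
#' the spec's true rates. Tracer consumption is neglected (nmol-scale
#' turnover against umol-scale pools over 48 h). Each observation receives
#' independent measurement noise; observations may therefore go slightly
#' negative at early times, as real GC-IRMS excess data do.
#'
#' @param spec A [simulation_spec()].
#' @return A data frame with columns `time_h`, `replicate`,
#'   `excess29_nmol_per_L`, `excess30_nmol_per_L`; the spec is attached as
#'   attribute `"spec"`.
#' @examples
#' s <- simulate_incubation(simulation_spec(noise_sd = 0))
#' head(s)
#' @export
simulate_incubation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  P <- forward_pairing(spec$true_anammox, spec$true_denitrification, spec$F)
  d <- spec$design
  time_h <- rep(d$sampling_times_h, each = d$replicates_per_time)
  replicate <- rep(seq_len(d$replicates_per_time),
                   times = length(d$sampling_times_h))
  t_d <- time_h / 24
  mu29 <- P$P29 * t_d
  mu30 <- P$P30 * t_d
  n <- length(time_h)
  obs <- with_seed(spec$seed, {
    if (spec$noise_type == "additive") {
      list(e29 = mu29 + stats::rnorm(n, 0, spec$noise_sd),
           e30 = mu30 + stats::rnorm(n, 0, spec$noise_sd))
    } else {
      # log-normal factor with unit mean and relative sd = noise_sd
      sdl <- sqrt(log1p(spec$noise_sd^2))
      list(e29 = mu29 * stats::rlnorm(n, -sdl^2 / 2, sdl),
           e30 = mu30 * stats::rlnorm(n, -sdl^2 / 2, sdl))
    }
  })
  out <- data.frame(time_h = time_h,
                    replicate = paste0("R", replicate),
                    excess29_nmol_per_L = obs$e29,
                    excess30_nmol_per_L = obs$e30,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}

#' Monte-Carlo pairing oracle
#'
#' Brute-force check of the binomial pairing model: simulates individual
#' N2 molecules. Each molecule is an anammox product with probability
#' A / (A + D), in which case its two atoms are drawn Bernoulli(F_ammonium)
#' and Bernoulli(F_nitrite); otherwise it is a denitrification product
#' with two independent Bernoulli(F_nitrite) atoms. The observed mass
#' distribution converges to the [forward_pairing()] proportions.
#'
#' @param A,D Rates, A + D > 0.
#' @param F A [labeled_fraction()].
#' @param n_draws Number of molecules, >= 1.
#' @param seed Integer seed.
#' @return Named numeric vector of observed proportions
#'   `c(p28 = , p29 = , p30 = )` with attribute `"n_draws"`.
#' @export
pairing_oracle <- function(A, D, F, n_draws = 1e6, seed = 1L) {
  stopifnot(inherits(F, "labeled_fraction"))
  if (A < 0 || D < 0 || A + D <= 0)
    stop("need A, D >= 0 with A + D > 0", call. = FALSE)
  if (n_draws < 1) stop("'n_draws' must be >= 1", call. = FALSE)
  n_draws <- as.integer(n_draws)
  with_seed(seed, {
    is_ana <- stats::runif(n_draws) < A / (A + D)
    p1 <- ifelse(is_ana, F$F_ammonium, F$F_nitrite)
    atom1 <- stats::runif(n_draws) < p1
    atom2 <- stats::runif(n_draws) < F$F_nitrite
    mass <- atom1 + atom2
    c(p28 = mean(mass == 0), p29 = mean(mass == 1), p30 = mean(mass == 2))
  }) -> props
  attr(props, "n_draws") <- n_draws
  props
}

#' Parameter-recovery experiment
#'
#' Repeats simulate -> fit -> estimate over independent synthetic
#' incubations and summarises how well the estimation chain recovers the
#' true anammox and denitrification rates: mean bias, root-mean-square
#' error, and the coverage of nominal 95% confidence intervals
#' (estimate +/- t(0.975, df) * se). Replicate seeds are derived
#' deterministically from the spec seed.
#'
#' @param spec A [simulation_spec()] (must use a nitrite-labeled F,
#'   F_nitrite > 0).
#' @param n_reps Number of independent replications, >= 1.
#' @param conf_level Nominal confidence level of the checked intervals.
#' @return A data frame with one row per parameter (`A`, `D`) and columns
#'   `truth`, `bias`, `rmse`, `coverage`, `n_reps`.
#' @export
recovery_experiment <- function(spec, n_reps = 500, conf_level = 0.95) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  if (spec$F$F_nitrite <= 0)
    stop("recovery requires a nitrite-labeled design (F_nitrite > 0)",
         call. = FALSE)
  estA <- estD <- covA <- covD <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    ser <- simulate_incubation(spec_i)
    P <- fit_production_rates(ser)
    est <- estimate_rates_nitrite_label(P, spec$F)
    q <- stats::qt(1 - (1 - conf_level) / 2, df = P$df)
    estA[i] <- est$anammox
    estD[i] <- est$denitrification
    covA[i] <- abs(est$anammox - spec$true_anammox) <= q * est$se_A
    covD[i] <- abs(est$denitrification - spec$true_denitrification) <=
      q * est$se_D
  }
  data.frame(
    parameter = c("A", "D"),
    truth = c(spec$true_anammox, spec$true_denitrification),
    bias = c(mean(estA) - spec$true_anammox,
             mean(estD) - spec$true_denitrification),
    rmse = c(sqrt(mean((estA - spec$true_anammox)^2)),
             sqrt(mean((estD - spec$true_denitrification)^2))),
    coverage = c(mean(covA), mean(covD)),
    n_reps = n_reps,
    stringsAsFactors = FALSE)
}

#' Specify a synthetic cross-well marker survey
#'
#' Describes a set of groundwater wells spanning an oxygen gradient, with
#' log-normally distributed functional-gene and transcript abundances. The
#' anammox marker hzsA declines with oxygen on the log scale at
#' `effect_size`, so the hzsA/amoA ratio decreases monotonically (in
#' expectation) along the gradient, emulating the contrast between suboxic
#' anammox hotspots and oxic nitrifier-dominated wells.
#'
#' Default magnitudes are typical for oligotrophic groundwater qPCR data:
#' 16S rRNA genes ~1e8 L-1, hzsA genes up to ~1e7 L-1 at the anoxic end,
#' amoA (AOA + AOB) ~1e5 L-1, nirS ~1e6 L-1, nirK two orders of magnitude
#' below nirS; transcripts one order of magnitude below the corresponding
#' genes. The default effect size (-0.08 per umol L-1 O2 on the natural
#' log scale) spans ~3.5 decades of hzsA/amoA ratio (about 100 down to
#' 0.03) across a 0-100 umol L-1 oxygen gradient, with hzsA transcripts
#' crossing the 1e3 L-1 quantification limit near the oxic end - the
#' near-detection-limit wells such surveys exclude from transcript
#' indices.
#'
#' @param n_wells Number of wells, >= 3.
#' @param oxygen_range Range (min, max) of oxygen concentrations
#'   (umol L-1); wells are spaced evenly across it.
#' @param meanlog Named numeric vector of natural-log mean gene abundances
#'   (copies L-1) per marker at the low-oxygen end of the gradient.
#' @param sdlog Log-scale dispersion (common to all markers), >= 0.
#' @param transcript_offset Natural-log offset of transcripts below genes.
#' @param effect_size Slope of log(hzsA) vs oxygen (per umol L-1); the
#'   amoA markers are flat, so this is also the slope of log(hzsA/amoA).
#' @param detection_limit Copies L-1 below which a measurement is flagged
#'   below detection (default 1e3, a typical transcript quantification
#'   limit).
#' @param seed Integer seed.
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(n_wells = 8,
                        oxygen_range = c(0, 100),
                        meanlog = c("16S" = log(1e8), hzsA = log(1e7),
                                    nirS = log(1e6), nirK = log(1e4),
                                    amoA_AOA = log(5e4), amoA_AOB = log(5e4)),
                        sdlog = 0.5,
                        transcript_offset = log(10),
                        effect_size = -0.08,
                        detection_limit = 1e3,
                        seed = 1L) {
  if (n_wells < 3) stop("'n_wells' must be >= 3", call. = FALSE)
  if (sdlog < 0) stop("'sdlog' must be >= 0", call. = FALSE)
  needed <- c("16S", "hzsA", "nirS", "nirK", "amoA_AOA", "amoA_AOB")
  miss <- setdiff(needed, names(meanlog))
  if (length(miss))
    stop("'meanlog' is missing marker(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(n_wells = as.integer(n_wells),
                 oxygen_range = as.numeric(oxygen_range),
                 meanlog = meanlog, sdlog = sdlog,
                 transcript_offset = transcript_offset,
                 effect_size = effect_size,
                 detection_limit = detection_limit,
                 seed = as.integer(seed)),
            class = "survey_spec")
}

#' Simulate a cross-well marker abundance survey
#'
#' Draws gene and transcript abundances for every marker in every well of
#' a [survey_spec()]. Abundances are log-normal; the hzsA log-mean
#' declines with oxygen at the spec's effect size. Values below the
#' detection limit are flagged `below_detection` (and retained, so
#' downstream code controls the exclusion policy).
#'
#' @param spec A [survey_spec()].
#' @return A list with `markers` (a marker abundance table: columns
#'   `well`, `marker`, `molecule`, `copies`, `below_detection`,
#'   `quantification_limit`) and `oxygen` (named vector of per-well oxygen,
#'   umol L-1).
#' @examples
#' sv <- simulate_marker_survey(survey_spec(seed = 42))
#' head(sv$markers)
#' @export
simulate_marker_survey <- function(spec) {
  stopifnot(inherits(spec, "survey_spec"))
  wells <- sprintf("W%02d", seq_len(spec$n_wells))
  oxygen <- seq(spec$oxygen_range[1], spec$oxygen_range[2],
                length.out = spec$n_wells)
  names(oxygen) <- wells
  markers <- names(spec$meanlog)
  grid <- expand.grid(well = wells, marker = markers,
                      molecule = c("gene", "transcript"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- spec$meanlog[grid$marker] +
    ifelse(grid$marker == "hzsA",
           spec$effect_size * oxygen[grid$well], 0) -
    ifelse(grid$molecule == "transcript", spec$transcript_offset, 0)
  copies <- with_seed(spec$seed,
                      stats::rlnorm(nrow(grid), meanlog = mu,
                                    sdlog = spec$sdlog))
  out <- data.frame(well = grid$well, marker = grid$marker,
                    molecule = grid$molecule, copies = copies,
                    below_detection = copies < spec$detection_limit,
                    quantification_limit = spec$detection_limit,
                    stringsAsFactors = FALSE)
  list(markers = out, oxygen = oxygen)
}
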