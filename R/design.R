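#' Describe an anoxic tracer incubation experiment
#'
#' Captures the physical setup of a \eqn{^{15}}N tracer incubation used for
#' isotope-pairing rate measurements: bottle volumes, temperature, the
#' destructive-sampling schedule, and the tracer and background substrate
#' concentrations. The defaults reproduce a typical groundwater incubation:
#' 30 mL of water under an 8 mL helium headspace at 15 degC, triplicate
#' bottles sacrificed at 0, 14, 24, 36 and 48 h.
#'
#' Two tracer treatments are supported. In the `"NITRITE_15N"` treatment
#' only \eqn{^{15}}NO2- is added, so both anammox and denitrification
#' produce labeled N2 and both rates are identifiable. In the
#' `"AMMONIUM_15N"` treatment \eqn{^{15}}NH4+ is added together with
#' unlabeled \eqn{^{14}}NO2-; only anammox produces \eqn{^{29}}N2 and only
#' the anammox rate is identifiable.
#'
#' @param water_volume_ml Incubation water volume (mL).
#' @param headspace_volume_ml Headspace gas volume (mL).
#' @param temperature_c Incubation temperature (degC).
#' @param sampling_times_h Elapsed sampling times (h); must be non-negative,
#'   strictly increasing and include 0.
#' @param replicates_per_time Number of replicate bottles destructively
#'   sampled at each time point.
#' @param treatment `"NITRITE_15N"` or `"AMMONIUM_15N"`.
#' @param added_15N_ammonium,added_15N_nitrite,added_14N_nitrite Tracer and
#'   carrier additions (umol L-1).
#' @param background_ammonium,background_nitrite In-situ (pre-addition)
#'   substrate concentrations (umol L-1).
#'
#' @return An object of class `incubation_design` (a named list).
#' @seealso [labeled_fraction_from_design()], [simulate_incubation()]
#' @examples
#' incubation_design()  # 15NO2- treatment, 5 uM tracer
#' incubation_design(treatment = "AMMONIUM_15N",
#'                   added_15N_ammonium = 50, added_15N_nitrite = 0,
#'                   added_14N_nitrite = 5)
#' @export
incubation_design <- function(water_volume_ml = 30,
                              headspace_volume_ml = 8,
                              temperature_c = 15,
                              sampling_times_h = c(0, 14, 24, 36, 48),
                              replicates_per_time = 3,
                              treatment = c("NITRITE_15N", "AMMONIUM_15N"),
                              added_15N_ammonium = 0,
                              added_15N_nitrite = 5,
                              added_14N_nitrite = 0,
                              background_ammonium = 0,
                              background_nitrite = 0) {
  treatment <- match.arg(treatment)
  if (!is.numeric(water_volume_ml) || water_volume_ml <= 0)
    stop("'water_volume_ml' must be > 0", call. = FALSE)
  if (!is.numeric(headspace_volume_ml) || headspace_volume_ml <= 0)
    stop("'headspace_volume_ml' must be > 0", call. = FALSE)
  t <- as.numeric(sampling_times_h)
  if (length(t) < 1 || any(t < 0) || any(diff(t) <= 0) || t[1] != 0)
    stop("'sampling_times_h' must be non-negative, strictly increasing and include 0",
         call. = FALSE)
  if (replicates_per_time < 1)
    stop("'replicates_per_time' must be >= 1", call. = FALSE)
  conc <- c(added_15N_ammonium = added_15N_ammonium,
            added_15N_nitrite = added_15N_nitrite,
            added_14N_nitrite = added_14N_nitrite,
            background_ammonium = background_ammonium,
            background_nitrite = background_nitrite)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  if (treatment == "NITRITE_15N" && added_15N_ammonium != 0)
    stop("NITRITE_15N treatment must have added_15N_ammonium = 0", call. = FALSE)
  if (treatment == "AMMONIUM_15N" && added_15N_nitrite != 0)
    stop("AMMONIUM_15N treatment must have added_15N_nitrite = 0", call. = FALSE)

  structure(list(water_volume_ml = water_volume_ml,
                 headspace_volume_ml = headspace_volume_ml,
                 temperature_c = temperature_c,
                 sampling_times_h = t,
                 replicates_per_time = as.integer(replicates_per_time),
                 treatment = treatment,
                 added_15N_ammonium = added_15N_ammonium,
                 added_15N_nitrite = added_15N_nitrite,
                 added_14N_nitrite = added_14N_nitrite,
                 background_ammonium = background_ammonium,
                 background_nitrite = background_nitrite),
            class = "incubation_design")
}

#' @export
print.incubation_design <- function(x, ...) {
  cat("Incubation design (", x$treatment, ")\n", sep = "")
  cat("  water ", x$water_volume_ml, " mL, headspace ", x$headspace_volume_ml,
      " mL, ", x$temperature_c, " degC\n", sep = "")
  cat("  sampling (h): ", paste(x$sampling_times_h, collapse = ", "),
      "  x ", x$replicates_per_time, " bottles\n", sep = "")
  cat("  additions (umol/L): 15NH4+ ", x$added_15N_ammonium,
      ", 15NO2- ", x$added_15N_nitrite,
      ", 14NO2- ", x$added_14N_nitrite, "\n", sep = "")
  cat("  background (umol/L): NH4+ ", x$background_ammonium,
      ", NO2- ", x$background_nitrite, "\n", sep = "")
  invisible(x)
}

#' 15N labeled fractions of the substrate pools
#'
#' Bundles the \eqn{^{15}}N atom fractions of the nitrite and ammonium
#' pools after tracer addition, corrected for dilution by the unlabeled
#' background pools.
#'
#' @param F_nitrite,F_ammonium Fractions in \[0, 1\].
#' @return An object of class `labeled_fraction`.
#' @seealso [compute_labeled_fraction()]
#' @export
labeled_fraction <- function(F_nitrite = 0, F_ammonium = 0) {
  for (f in c(F_nitrite, F_ammonium))
    if (!is.finite(f) || f < 0 || f > 1)
      stop("labeled fractions must lie in [0, 1]", call. = FALSE)
  structure(list(F_nitrite = F_nitrite, F_ammonium = F_ammonium),
            class = "labeled_fraction")
}

#' @export
print.labeled_fraction <- function(x, ...) {
  cat("Labeled fractions: F_nitrite =", format(x$F_nitrite),
      " F_ammonium =", format(x$F_ammonium), "\n")
  invisible(x)
}

#' Labeled fraction of one substrate pool after tracer addition
#'
#' The labeled fraction is the ratio of the added \eqn{^{15}}N tracer
#' concentration to the total (labeled + unlabeled) pool concentration.
#' Two conventions are supported, matching common field practice: the total
#' is either reconstructed as background + added (`background_14N`), or a
#' post-addition measured total is supplied directly (`measured_total`),
#' the usual convention for ammonium where the in-situ pool is large and
#' measured after spiking.
#'
#' @param added_15N Added tracer concentration (umol L-1), >= 0.
#' @param background_14N Unlabeled background concentration (umol L-1).
#'   Supply exactly one of `background_14N` or `measured_total`.
#' @param measured_total Measured post-addition total concentration
#'   (umol L-1).
#' @return The labeled fraction, a number in \[0, 1\].
#' @examples
#' compute_labeled_fraction(5, background_14N = 0)    # 1: undiluted tracer
#' compute_labeled_fraction(50, background_14N = 30)  # 0.625
#' compute_labeled_fraction(50, measured_total = 80)  # 0.625
#' @export
compute_labeled_fraction <- function(added_15N, background_14N = NULL,
                                     measured_total = NULL) {
  if (!is.finite(added_15N) || added_15N < 0)
    stop("'added_15N' must be finite and >= 0", call. = FALSE)
  if (is.null(background_14N) == is.null(measured_total))
    stop("supply exactly one of 'background_14N' or 'measured_total'",
         call. = FALSE)
  if (!is.null(measured_total)) {
    if (measured_total == 0) {
      if (added_15N > 0)
        stop("total pool is zero but tracer was added", call. = FALSE)
      return(0)
    }
    if (measured_total < added_15N)
      stop("inconsistent input: 'measured_total' < 'added_15N'", call. = FALSE)
    return(added_15N / measured_total)
  }
  if (background_14N < 0)
    stop("'background_14N' must be >= 0", call. = FALSE)
  total <- added_15N + background_14N
  if (total == 0) {
    if (added_15N > 0)  # unreachable, kept for clarity of the contract
      stop("total pool is zero but tracer was added", call. = FALSE)
    return(0)
  }
  added_15N / total
}

#' Derive labeled fractions from an incubation design
#'
#' Applies [compute_labeled_fraction()] to both substrate pools of a
#' design. For the nitrite pool the total is background + added
#' (\eqn{^{15}}N and \eqn{^{14}}N carrier); for the ammonium pool a
#' measured post-addition total may be supplied, otherwise background +
#' added is used. A background nitrite below detection reported as 0 gives
#' F_nitrite = 1 (undiluted label).
#'
#' @param design An [incubation_design()].
#' @param measured_total_ammonium Optional measured post-addition total
#'   ammonium (umol L-1).
#' @return A [labeled_fraction()].
#' @export
labeled_fraction_from_design <- function(design,
                                         measured_total_ammonium = NULL) {
  stopifnot(inherits(design, "incubation_design"))
  Fn <- if (design$added_15N_nitrite > 0) {
    compute_labeled_fraction(
      design$added_15N_nitrite,
      background_14N = design$background_nitrite + design$added_14N_nitrite)
  } else 0
  Fa <- if (design$added_15N_ammonium > 0) {
    if (!is.null(measured_total_ammonium))
      compute_labeled_fraction(design$added_15N_ammonium,
                               measured_total = measured_total_ammonium)
    else
      compute_labeled_fraction(design$added_15N_ammonium,
                               background_14N = design$background_ammonium)
  } else 0
  labeled_fraction(F_nitrite = Fn, F_ammonium = Fa)
}

#' Convert a headspace N2 amount to a per-litre aqueous concentration
#'
#' Headspace isotopologue amounts from GC-IRMS are expressed per litre of
#' incubation water. With `include_dissolved = FALSE` (default) only the
#' headspace amount is counted. With `include_dissolved = TRUE` the total
#' bottle N2 is reconstructed assuming gas-liquid equilibrium with a
#' Bunsen-type solubility coefficient `solubility_coeff` (dimensionless,
#' aqueous/gas concentration ratio at the incubation temperature):
#' total = headspace * (1 + beta * V_water / V_headspace).
#'
#' @param amount_nmol N2 amount measured in the headspace (nmol).
#' @param design An [incubation_design()] supplying the volumes.
#' @param include_dissolved Also count N2 dissolved in the water phase?
#' @param solubility_coeff Bunsen-type coefficient beta >= 0; ignored when
#'   `include_dissolved = FALSE`.
#' @return Concentration in nmol N2 per litre of incubation water.
#' @examples
#' d <- incubation_design()
#' headspace_to_aqueous(0.105, d)  # 3.5 nmol/L
#' @export
headspace_to_aqueous <- function(amount_nmol, design,
                                 include_dissolved = FALSE,
                                 solubility_coeff = 0) {
  stopifnot(inherits(design, "incubation_design"))
  if (!is.numeric(amount_nmol) || any(!is.finite(amount_nmol)))
    stop("'amount_nmol' must be finite", call. = FALSE)
  if (solubility_coeff < 0)
    stop("'solubility_coeff' must be >= 0", call. = FALSE)
  total <- if (include_dissolved) {
    amount_nmol * (1 + solubility_coeff *
                     design$water_volume_ml / design$headspace_volume_ml)
  } else amount_nmol
  total / (design$water_volume_ml / 1000)
}
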