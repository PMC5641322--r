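#' Forward binomial-pairing model of N2 isotopologue production
#'
#' Given true anammox and denitrification rates and the \eqn{^{15}}N
#' labeled fractions of the substrate pools, returns the instantaneous
#' production rate of each N2 isotopologue. Denitrification draws both N
#' atoms from the nitrite pool (binomial pairing with success probability
#' `F_nitrite`); anammox draws one atom from the ammonium pool and one from
#' the nitrite pool:
#' \deqn{P_{30} = D F_n^2 + A F_a F_n}
#' \deqn{P_{29} = 2 D F_n (1-F_n) + A [F_a (1-F_n) + F_n (1-F_a)]}
#' \deqn{P_{28} = D (1-F_n)^2 + A (1-F_a)(1-F_n)}
#' Mass balance holds: P28 + P29 + P30 = A + D.
#'
#' @param A Anammox rate (nmol N2 L-1 d-1), >= 0.
#' @param D Denitrification rate (nmol N2 L-1 d-1), >= 0.
#' @param F A [labeled_fraction()].
#' @return An object of class `pairing_rates`: list with `P28`, `P29`,
#'   `P30` (nmol N2 L-1 d-1).
#' @seealso [estimate_rates_nitrite_label()], [pairing_oracle()]
#' @examples
#' forward_pairing(1, 0, labeled_fraction(F_nitrite = 0, F_ammonium = 1))
#' forward_pairing(0, 1, labeled_fraction(F_nitrite = 1))
#' @export
forward_pairing <- function(A, D, F) {
  stopifnot(inherits(F, "labeled_fraction"))
  if (!is.finite(A) || A < 0 || !is.finite(D) || D < 0)
    stop("rates 'A' and 'D' must be finite and >= 0", call. = FALSE)
  Fn <- F$F_nitrite
  Fa <- F$F_ammonium
  P30 <- D * Fn^2 + A * Fa * Fn
  P29 <- 2 * D * Fn * (1 - Fn) + A * (Fa * (1 - Fn) + Fn * (1 - Fa))
  P28 <- D * (1 - Fn)^2 + A * (1 - Fa) * (1 - Fn)
  structure(list(P28 = P28, P29 = P29, P30 = P30), class = "pairing_rates")
}

#' @export
print.pairing_rates <- function(x, ...) {
  cat("Isotopologue production (nmol N2/L/d): 28N2 =", format(x$P28),
      " 29N2 =", format(x$P29), " 30N2 =", format(x$P30), "\n")
  invisible(x)
}

#' Fit zero-order isotopologue production rates by OLS
#'
#' Fits ordinary least-squares regressions of excess \eqn{^{29}}N2 and
#' \eqn{^{30}}N2 concentration against incubation time, pooling all
#' replicate bottles (destructive sampling makes bottles independent).
#' Times are supplied in hours and slopes are reported per day. One-sided
#' p-values test slope > 0 (production, not consumption).
#'
#' With `average_replicates = TRUE` time-point means are regressed instead
#' of individual bottles; the default pools bottles, which uses the full
#' replicate-level information.
#'
#' @param series A data frame with columns `time_h`, `replicate`,
#'   `excess29_nmol_per_L`, `excess30_nmol_per_L` (the format written by
#'   [simulate_incubation()] and read by [read_isotopologue_series()]).
#' @param average_replicates Regress per-time means instead of pooled
#'   bottles.
#' @return An object of class `production_rates`: slopes `P29`, `P30`
#'   (nmol N2 L-1 d-1), standard errors `se_P29`, `se_P30`, `r2_29`,
#'   `r2_30`, one-sided p-values `p_29`, `p_30`, `df` and `n_points`.
#' @examples
#' s <- simulate_incubation(simulation_spec(true_anammox = 3.5,
#'   true_denitrification = 0.7, noise_sd = 0))
#' fit_production_rates(s)
#' @export
fit_production_rates <- function(series, average_replicates = FALSE) {
  series <- validate_series(series)
  if (average_replicates) {
    agg <- stats::aggregate(
      series[c("excess29_nmol_per_L", "excess30_nmol_per_L")],
      by = list(time_h = series$time_h), FUN = mean)
    series <- agg
  }
  tt <- unique(series$time_h)
  if (length(tt) < 3)
    stop("need >= 3 distinct time points to fit a rate", call. = FALSE)
  time_d <- series$time_h / 24

  fit_one <- function(y) {
    fit <- stats::lm(y ~ time_d)
    # summary.lm warns on zero-residual fits; noiseless series are a
    # legitimate input (and the documented exact-line contract)
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    slope <- unname(stats::coef(fit)[2])
    se <- unname(sm$coefficients[2, 2])
    df <- fit$df.residual
    # r.squared is NaN for an all-constant response; define it as 1 for a
    # perfect (zero-residual) fit and 0 otherwise
    r2 <- sm$r.squared
    if (!is.finite(r2)) r2 <- if (sum(stats::resid(fit)^2) < 1e-24) 1 else 0
    if (se == 0 || !is.finite(se)) {
      p <- if (slope > 0) 0 else if (slope < 0) 1 else 0.5
      if (se != 0) se <- NA_real_
    } else {
      p <- stats::pt(slope / se, df = df, lower.tail = FALSE)
    }
    list(slope = slope, se = se, r2 = r2, p = p, df = df)
  }
  f29 <- fit_one(series$excess29_nmol_per_L)
  f30 <- fit_one(series$excess30_nmol_per_L)
  structure(list(P29 = f29$slope, P30 = f30$slope,
                 se_P29 = f29$se, se_P30 = f30$se,
                 r2_29 = f29$r2, r2_30 = f30$r2,
                 p_29 = f29$p, p_30 = f30$p,
                 df = f29$df, n_points = nrow(series)),
            class = "production_rates")
}

#' Construct production rates directly (without a regression)
#'
#' Convenience constructor used when slopes are already known, e.g. when
#' feeding published rates through the inverse estimators.
#'
#' @param P29,P30 Slopes (nmol N2 L-1 d-1).
#' @param se_P29,se_P30 Slope standard errors (0 when exact).
#' @param df Residual degrees of freedom backing the standard errors.
#' @return A `production_rates` object.
#' @export
production_rates <- function(P29, P30, se_P29 = 0, se_P30 = 0, df = Inf) {
  structure(list(P29 = P29, P30 = P30, se_P29 = se_P29, se_P30 = se_P30,
                 r2_29 = NA_real_, r2_30 = NA_real_,
                 p_29 = NA_real_, p_30 = NA_real_,
                 df = df, n_points = NA_integer_),
            class = "production_rates")
}

#' @export
print.production_rates <- function(x, ...) {
  cat("Isotopologue production slopes (nmol N2/L/d, pooled OLS, n =",
      x$n_points, "):\n")
  cat(sprintf("  P29 = %.4g (se %.3g, r2 %.3g, one-sided p %.3g)\n",
              x$P29, x$se_P29, x$r2_29, x$p_29))
  cat(sprintf("  P30 = %.4g (se %.3g, r2 %.3g, one-sided p %.3g)\n",
              x$P30, x$se_P30, x$r2_30, x$p_30))
  invisible(x)
}

#' Invert the pairing model for the 15NO2- treatment
#'
#' In an incubation where only the nitrite pool carries label
#' (F_ammonium = 0), the pairing model inverts uniquely:
#' \deqn{D = P_{30} / F_n^2}
#' \deqn{A = (P_{29} - 2 F_n (1-F_n) D) / F_n}
#' Standard errors are propagated from the slope standard errors by the
#' delta method, treating the labeled fraction as exact. Negative point
#' estimates are reported as-is with `detected` set to `FALSE` and a
#' warning recorded, never truncated.
#'
#' @param P A `production_rates` object (from [fit_production_rates()]).
#' @param F A [labeled_fraction()]; `F_nitrite` must be in (0, 1\].
#' @param alpha Significance level for the one-sided slope detection tests.
#' @param clamp_contribution Clamp the anammox contribution into \[0, 1\]
#'   when a negative rate estimate pushes it outside (flagged, off by
#'   default).
#' @return An object of class `process_rates`: `anammox`,
#'   `denitrification`, `se_A`, `se_D`, `total`, `se_total`,
#'   `contribution` (anammox fraction of total), `detected_A`,
#'   `detected_D`, `warnings`.
#' @examples
#' P <- production_rates(P29 = 3.5, P30 = 0.7)
#' estimate_rates_nitrite_label(P, labeled_fraction(F_nitrite = 1))
#' @export
estimate_rates_nitrite_label <- function(P, F, alpha = 0.05,
                                         clamp_contribution = FALSE) {
  stopifnot(inherits(P, "production_rates"), inherits(F, "labeled_fraction"))
  Fn <- F$F_nitrite
  if (Fn <= 0)
    stop("F_nitrite = 0: rates are not identifiable without nitrite label",
         call. = FALSE)
  warnings <- character()

  D <- P$P30 / Fn^2
  A <- (P$P29 - 2 * Fn * (1 - Fn) * D) / Fn
  # A = P29/Fn - 2(1-Fn)/Fn^2 * P30 ; D = P30/Fn^2  (linear in the slopes)
  cA29 <- 1 / Fn
  cA30 <- -2 * (1 - Fn) / Fn^2
  se_A <- sqrt((cA29 * P$se_P29)^2 + (cA30 * P$se_P30)^2)
  se_D <- P$se_P30 / Fn^2
  # total = A + D shares the P30 slope between A and D
  se_total <- sqrt((cA29 * P$se_P29)^2 + ((cA30 + 1 / Fn^2) * P$se_P30)^2)

  detected_D <- isTRUE(P$p_30 < alpha) && D > 0
  detected_A <- isTRUE(P$p_29 < alpha) && A > 0
  if (A < 0) {
    warnings <- c(warnings, sprintf(
      "negative anammox estimate (%.4g); reported as-is, detected_A = FALSE", A))
    detected_A <- FALSE
  }
  ct <- contribution_and_total(A, D, clamp = clamp_contribution)
  warnings <- c(warnings, ct$warnings)

  structure(list(anammox = A, denitrification = D,
                 se_A = se_A, se_D = se_D,
                 total = ct$total, se_total = se_total,
                 contribution = ct$contribution,
                 detected_A = detected_A, detected_D = detected_D,
                 treatment = "NITRITE_15N", alpha = alpha,
                 warnings = warnings),
            class = "process_rates")
}

#' Estimate the anammox rate from the 15NH4+ treatment
#'
#' With labeled ammonium and unlabeled nitrite, anammox produces
#' \eqn{^{29}}N2 by pairing one labeled ammonium-N with one unlabeled
#' nitrite-N, so A = P29 / F_ammonium. Denitrification produces no labeled
#' N2 in this treatment and is reported as not identifiable (`NA`). A
#' significantly positive \eqn{^{30}}N2 slope contradicts the unlabeled
#' nitrite assumption and is surfaced as a warning.
#'
#' @inheritParams estimate_rates_nitrite_label
#' @param F A [labeled_fraction()]; `F_ammonium` must be in (0, 1\].
#' @return A `process_rates` object with `denitrification`, `total` and
#'   `contribution` set to `NA`.
#' @examples
#' P <- production_rates(P29 = 4.7, P30 = 0)
#' estimate_rate_ammonium_label(P, labeled_fraction(F_ammonium = 1))
#' @export
estimate_rate_ammonium_label <- function(P, F, alpha = 0.05) {
  stopifnot(inherits(P, "production_rates"), inherits(F, "labeled_fraction"))
  Fa <- F$F_ammonium
  if (Fa <= 0)
    stop("F_ammonium = 0: anammox rate is not identifiable without ammonium label",
         call. = FALSE)
  warnings <- character()
  A <- P$P29 / Fa
  se_A <- P$se_P29 / Fa
  detected_A <- isTRUE(P$p_29 < alpha) && A > 0
  if (A < 0) {
    warnings <- c(warnings, sprintf(
      "negative anammox estimate (%.4g); reported as-is, detected_A = FALSE", A))
    detected_A <- FALSE
  }
  if (isTRUE(P$p_30 < alpha) && P$P30 > 0)
    warnings <- c(warnings, paste0(
      "significant 30N2 production (P30 = ", format(P$P30, digits = 4),
      ") in the 15NH4+ treatment: nitrite pool may carry label ",
      "(model violation)"))
  structure(list(anammox = A, denitrification = NA_real_,
                 se_A = se_A, se_D = NA_real_,
                 total = NA_real_, se_total = NA_real_,
                 contribution = NA_real_,
                 detected_A = detected_A, detected_D = NA,
                 treatment = "AMMONIUM_15N", alpha = alpha,
                 warnings = warnings),
            class = "process_rates")
}

#' Bootstrap uncertainty for the nitrite-label estimator
#'
#' Alternative to the delta-method errors: resamples bottles with
#' replacement within each time point (preserving the destructive-
#' sampling design), refits the slopes and re-inverts the pairing model.
#' Useful when the OLS error assumptions (homoscedastic, Gaussian) are in
#' doubt.
#'
#' @param series An isotopologue series data frame (see
#'   [fit_production_rates()]).
#' @param F A [labeled_fraction()] with `F_nitrite` in (0, 1\].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed (fixed default for reproducibility).
#' @param conf_level Level of the reported percentile intervals.
#' @return A data frame with one row per parameter (`A`, `D`): point
#'   `estimate`, bootstrap `se`, and percentile interval `lower`,
#'   `upper`.
#' @export
bootstrap_rates <- function(series, F, n_boot = 1000, seed = 20240101L,
                            conf_level = 0.95) {
  series <- validate_series(series)
  est0 <- estimate_rates_nitrite_label(fit_production_rates(series), F)
  groups <- split(seq_len(nrow(series)), series$time_h)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]),
        use.names = FALSE)
      e <- estimate_rates_nitrite_label(
        fit_production_rates(series[idx, , drop = FALSE]), F)
      c(e$anammox, e$denitrification)
    }, numeric(2))
  })
  a <- (1 - conf_level) / 2
  qs <- apply(draws, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(parameter = c("A", "D"),
             estimate = c(est0$anammox, est0$denitrification),
             se = c(stats::sd(draws[1, ]), stats::sd(draws[2, ])),
             lower = qs[1, ], upper = qs[2, ],
             stringsAsFactors = FALSE)
}

#' Total N2 production and anammox contribution
#'
#' @param A Anammox rate (nmol N2 L-1 d-1).
#' @param D Denitrification rate (nmol N2 L-1 d-1).
#' @param clamp Clamp the contribution into \[0, 1\] when negative inputs
#'   push it outside (the clamp is recorded in `warnings`).
#' @return A list with `total` (A + D), `contribution` (A / (A + D), `NA`
#'   with a flag when total = 0), and `warnings`.
#' @examples
#' contribution_and_total(3.5, 0.7)  # total 4.2, contribution 0.833 (83%)
#' @export
contribution_and_total <- function(A, D, clamp = FALSE) {
  stopifnot(is.finite(A), is.finite(D))
  total <- A + D
  warnings <- character()
  if (total == 0) {
    contribution <- NA_real_
    warnings <- c(warnings, "total rate is zero: contribution undefined")
  } else {
    contribution <- A / total
    if (contribution < 0 || contribution > 1) {
      if (clamp) {
        warnings <- c(warnings, sprintf(
          "contribution %.4g clamped into [0, 1] (negative rate input)",
          contribution))
        contribution <- min(max(contribution, 0), 1)
      } else {
        warnings <- c(warnings,
                      "contribution outside [0, 1] (negative rate input)")
      }
    }
  }
  list(total = total, contribution = contribution, warnings = warnings)
}

#' @export
print.process_rates <- function(x, ...) {
  cat("Process rates (", x$treatment, "):\n", sep = "")
  cat(sprintf("  anammox         A = %.4g nmol N2/L/d (se %.3g, detected: %s)\n",
              x$anammox, x$se_A, x$detected_A))
  if (is.na(x$denitrification)) {
    cat("  denitrification not identifiable in this treatment\n")
  } else {
    cat(sprintf("  denitrification D = %.4g nmol N2/L/d (se %.3g, detected: %s)\n",
                x$denitrification, x$se_D, x$detected_D))
    cat(sprintf("  total = %.4g nmol N2/L/d; anammox contribution = %.1f%%\n",
                x$total, 100 * x$contribution))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# shared column/shape validation for isotopologue series tables
validate_series <- function(series) {
  needed <- c("time_h", "excess29_nmol_per_L", "excess30_nmol_per_L")
  miss <- setdiff(needed, names(series))
  if (length(miss))
    stop("series is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(series) == 0) stop("series has no rows", call. = FALSE)
  for (col in needed)
    if (!is.numeric(series[[col]]))
      stop("series column '", col, "' must be numeric", call. = FALSE)
  if (any(!is.finite(series$time_h)) || any(series$time_h < 0))
    stop("series times must be finite and >= 0", call. = FALSE)
  series
}
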