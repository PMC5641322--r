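# Cross-well molecular and lipid biomarker indices: hzsA/amoA and
# nirS/16S ratios with below-detection exclusion rules, ladderane relative
# concentrations, and Spearman rank correlation with exact permutation
# p-values for the small well counts typical of groundwater transects.

validate_marker_table <- function(table) {
  needed <- c("well", "marker", "molecule", "copies", "below_detection")
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("marker table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(table$copies < 0, na.rm = TRUE))
    stop("marker copies must be >= 0", call. = FALSE)
  table
}

get_marker <- function(table, well, marker, molecule) {
  rows <- table[table$well == well & table$marker == marker &
                  table$molecule == molecule, , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  rows[1, , drop = FALSE]
}

#' hzsA / amoA ratio index per well
#'
#' Ratio of the anammox marker hzsA to the summed ammonia-oxidizer markers
#' (archaeal + bacterial amoA), an indicator of the predominance of
#' anaerobic over aerobic ammonium oxidation in genetic potential (genes)
#' or transcriptional activity (transcripts). Below-detection measurements
#' are excluded rather than imputed: a well whose hzsA, or both of whose
#' amoA components, are below detection gets no numeric ratio and an
#' exclusion reason. If exactly one amoA domain is below detection the
#' ratio is computed against the quantified one and flagged `partial`.
#'
#' @param table A marker abundance table (columns `well`, `marker`,
#'   `molecule`, `copies`, `below_detection`), e.g. from
#'   [simulate_marker_survey()] or [read_marker_table()].
#' @param molecule `"gene"` or `"transcript"`.
#' @return A data frame with one row per well: `well`, `molecule`,
#'   `hzsa_amoa`, `excluded`, `partial`, `reason`.
#' @examples
#' sv <- simulate_marker_survey(survey_spec(seed = 1))
#' hzsa_amoa_ratio(sv$markers, "transcript")
#' @export
hzsa_amoa_ratio <- function(table, molecule = c("gene", "transcript")) {
  molecule <- match.arg(molecule)
  table <- validate_marker_table(table)
  wells <- unique(table$well)
  out <- lapply(wells, function(w) {
    hz <- get_marker(table, w, "hzsA", molecule)
    aoa <- get_marker(table, w, "amoA_AOA", molecule)
    aob <- get_marker(table, w, "amoA_AOB", molecule)
    if (is.null(hz))
      stop("well '", w, "' has no hzsA ", molecule, " entry", call. = FALSE)
    if (is.null(aoa) && is.null(aob))
      stop("well '", w, "' has no amoA ", molecule, " entry", call. = FALSE)
    res <- data.frame(well = w, molecule = molecule, hzsa_amoa = NA_real_,
                      excluded = FALSE, partial = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (hz$below_detection) {
      res$excluded <- TRUE
      res$reason <- "hzsA below detection"
      return(res)
    }
    amoa <- c(if (!is.null(aoa) && !aoa$below_detection) aoa$copies,
              if (!is.null(aob) && !aob$below_detection) aob$copies)
    n_present <- sum(!is.null(aoa), !is.null(aob))
    if (length(amoa) == 0) {
      res$excluded <- TRUE
      res$reason <- "amoA below detection"
      return(res)
    }
    if (length(amoa) < n_present) {
      res$partial <- TRUE
      res$reason <- "one amoA domain below detection"
    }
    res$hzsa_amoa <- hz$copies / sum(amoa)
    res
  })
  do.call(rbind, out)
}

#' nirS / 16S rRNA gene ratio per well
#'
#' Approximates the relative proportion of nirS-type denitrifiers in the
#' total bacterial community from gene copy numbers.
#'
#' @param table A marker abundance table (see [hzsa_amoa_ratio()]).
#' @return A data frame with one row per well: `well`, `molecule`
#'   (`"gene"`), `nirs_16s`, `excluded`, `reason`.
#' @export
nirs_16s_ratio <- function(table) {
  table <- validate_marker_table(table)
  wells <- unique(table$well)
  out <- lapply(wells, function(w) {
    nirs <- get_marker(table, w, "nirS", "gene")
    ssu <- get_marker(table, w, "16S", "gene")
    if (is.null(nirs) || is.null(ssu))
      stop("well '", w, "' lacks nirS and/or 16S gene rows", call. = FALSE)
    res <- data.frame(well = w, molecule = "gene", nirs_16s = NA_real_,
                      excluded = FALSE, reason = "", stringsAsFactors = FALSE)
    if (ssu$below_detection || ssu$copies == 0) {
      res$excluded <- TRUE
      res$reason <- "16S denominator undefined"
      return(res)
    }
    if (nirs$below_detection) {
      res$excluded <- TRUE
      res$reason <- "nirS below detection"
      return(res)
    }
    res$nirs_16s <- nirs$copies / ssu$copies
    res
  })
  do.call(rbind, out)
}

# all permutations of 1..n as an (n!) x n integer matrix; n <= 8 keeps
# this under 41k rows
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perms(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, m * n, n)
  for (i in seq_len(n)) {
    idx <- ((i - 1L) * m + 1L):(i * m)
    out[idx, 1L] <- i
    rest <- seq_len(n)[-i]
    out[idx, -1L] <- matrix(rest[p], m, n - 1L)
  }
  out
}

rank_cor <- function(rx, ry) {
  # Pearson correlation of average ranks = Spearman's rho with ties
  stats::cor(rx, ry)
}

#' Spearman rank correlation with well exclusions and exact permutation p
#'
#' Spearman's rho (average-rank tie handling) between a per-well index and
#' oxygen, after dropping an explicit exclusion set (e.g. wells whose
#' transcripts sit at the detection limit). The p-value is two-sided and
#' computed by exact enumeration of all n! rank permutations for n <= 8,
#' by seeded Monte-Carlo permutation (20000 draws) for n of 9 or 10, and
#' by the t approximation for larger n.
#'
#' @param values Named numeric vector (names are well labels) of the
#'   index.
#' @param oxygen Named numeric vector of oxygen concentrations
#'   (umol L-1); matched to `values` by name.
#' @param exclude Character vector of wells to exclude.
#' @return A list with `rho`, `p`, `n`, `method` (`"exact"`,
#'   `"monte-carlo"` or `"t-approximation"`), `excluded`, and `degenerate`
#'   (`TRUE` when either variable is constant, in which case `rho` is
#'   `NA`).
#' @examples
#' v <- c(A = 10, B = 5, C = 2, D = 1, E = 0.5, F = 0.1)
#' o <- c(A = 1, B = 2, C = 3, D = 4, E = 5, F = 6)
#' spearman_with_exclusions(v, o)  # rho = -1, exact p = 2/720
#' @export
spearman_with_exclusions <- function(values, oxygen, exclude = character()) {
  if (is.null(names(values)) || is.null(names(oxygen)))
    stop("'values' and 'oxygen' must be named by well", call. = FALSE)
  keep <- intersect(names(values), names(oxygen))
  keep <- setdiff(keep, exclude)
  keep <- keep[is.finite(values[keep]) & is.finite(oxygen[keep])]
  n <- length(keep)
  if (n < 3)
    stop("fewer than 3 wells remain after exclusions", call. = FALSE)
  x <- values[keep]
  y <- oxygen[keep]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate",
                excluded = exclude, degenerate = TRUE))
  rx <- rank(x)
  ry <- rank(y)
  rho <- rank_cor(rx, ry)
  eps <- 1e-12
  if (n <= 8) {
    P <- perms(n)
    ryp <- matrix(ry[P], nrow(P), n)
    rxc <- rx - mean(rx)
    ryc <- ryp - mean(ry)
    denom <- sqrt(sum(rxc^2) * rowSums(ryc^2))
    rho_perm <- as.numeric(ryc %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - eps)
    method <- "exact"
  } else if (n <= 10) {
    B <- 20000L
    rho_perm <- with_seed(171717L, {
      vapply(seq_len(B), function(i) rank_cor(rx, sample(ry)), numeric(1))
    })
    p <- (1 + sum(abs(rho_perm) >= abs(rho) - eps)) / (B + 1)
    method <- "monte-carlo"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method, excluded = exclude,
       degenerate = FALSE)
}

#' Ladderane relative concentrations from GC peak areas
#'
#' Relative concentration of anammox-specific ladderane lipids: the summed
#' peak areas of the \[3\]- and \[5\]-ladderane FAMEs divided by the peak
#' area of the C19:0 internal standard added before GC analysis. Relative
#' concentrations below 0.01 are flagged below detection.
#'
#' @param peaks A data frame with columns `well`, `date`,
#'   `area_ladderane3`, `area_ladderane5`, `area_C19_IS`.
#' @param detection_threshold Relative concentration below which a value
#'   is flagged below detection.
#' @return The input with added columns `rel_conc` and `below_detection`.
#' @examples
#' pk <- data.frame(well = "H53", date = "2015-11-01",
#'                  area_ladderane3 = 2, area_ladderane5 = 3,
#'                  area_C19_IS = 10)
#' ladderane_relative_concentration(pk)  # rel_conc 0.5
#' @export
ladderane_relative_concentration <- function(peaks,
                                             detection_threshold = 0.01) {
  needed <- c("well", "date", "area_ladderane3", "area_ladderane5",
              "area_C19_IS")
  miss <- setdiff(needed, names(peaks))
  if (length(miss))
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(peaks$area_ladderane3 < 0) || any(peaks$area_ladderane5 < 0))
    stop("peak areas must be >= 0", call. = FALSE)
  if (any(peaks$area_C19_IS <= 0))
    stop("internal standard peak area must be > 0 for a computable ratio",
         call. = FALSE)
  peaks$rel_conc <- (peaks$area_ladderane3 + peaks$area_ladderane5) /
    peaks$area_C19_IS
  peaks$below_detection <- peaks$rel_conc < detection_threshold
  peaks
}

#' Fold difference of ladderane relative concentration between two wells
#'
#' Contrasts the (date-averaged) relative ladderane concentration of one
#' well against another, e.g. a suboxic anammox hotspot against an oxic
#' reference well. Below-detection measurements are excluded from the
#' averages; a contrast whose denominator is below detection or zero is
#' returned as `NA` with a flag.
#'
#' @param rel Output of [ladderane_relative_concentration()], or a named
#'   numeric vector of per-well relative concentrations.
#' @param well_a,well_b Wells to contrast (numerator, denominator).
#' @return A list with `factor` (rel_a / rel_b), `rel_a`, `rel_b`, and
#'   `undefined` (TRUE when the denominator is not quantifiable).
#' @export
well_contrast_factor <- function(rel, well_a, well_b) {
  if (is.data.frame(rel)) {
    usable <- rel[!rel$below_detection, , drop = FALSE]
    val <- function(w) {
      v <- usable$rel_conc[usable$well == w]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    ra <- val(well_a)
    rb <- val(well_b)
    if (!well_a %in% rel$well || !well_b %in% rel$well)
      stop("both wells must be present in the table", call. = FALSE)
  } else {
    if (!all(c(well_a, well_b) %in% names(rel)))
      stop("both wells must be present", call. = FALSE)
    ra <- unname(rel[well_a])
    rb <- unname(rel[well_b])
  }
  if (!is.finite(rb) || rb == 0)
    return(list(factor = NA_real_, rel_a = ra, rel_b = rb, undefined = TRUE))
  list(factor = ra / rb, rel_a = ra, rel_b = rb, undefined = FALSE)
}
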