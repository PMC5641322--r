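# Delimited-text readers and writers. Dialect is fixed for unambiguous
# cross-language exchange: comma separator, period decimal, UTF-8,
# mandatory header row.

read_table_checked <- function(path, needed, what) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    stop(what, " file is empty: ", path, call. = FALSE)
  x <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e)
      stop("failed to parse ", what, " file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop(what, " file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x
}

#' Read and write isotopologue time-series tables
#'
#' Comma-separated, UTF-8, header row mandatory; columns `time_h`,
#' `replicate`, `excess29_nmol_per_L`, `excess30_nmol_per_L`. If a design
#' is supplied, every observation time must appear in its sampling
#' schedule. Negative excess values (possible within measurement noise)
#' are kept and flagged with a warning, not rejected.
#'
#' @param path File path.
#' @param design Optional [incubation_design()] to validate times against.
#' @return `read_isotopologue_series()`: the series data frame.
#' @export
read_isotopologue_series <- function(path, design = NULL) {
  x <- read_table_checked(path, c("time_h", "replicate",
                                  "excess29_nmol_per_L",
                                  "excess30_nmol_per_L"),
                          "isotopologue series")
  x <- validate_series(x)
  if (!is.null(design)) {
    stopifnot(inherits(design, "incubation_design"))
    bad <- setdiff(unique(x$time_h), design$sampling_times_h)
    if (length(bad))
      stop("series contains times not in the design schedule: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  neg <- x$excess29_nmol_per_L < 0 | x$excess30_nmol_per_L < 0
  if (any(neg))
    warning(sum(neg), " observation(s) with negative excess (kept; ",
            "expected within measurement noise at early times)",
            call. = FALSE)
  x
}

#' @rdname read_isotopologue_series
#' @param series A series data frame.
#' @export
write_isotopologue_series <- function(series, path) {
  validate_series(series)
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# flat key = value configuration files -------------------------------------

read_keyvalue <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop("malformed config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  vals <- lapply(kv, function(m) trimws(m[3]))
  names(vals) <- vapply(kv, function(m) trimws(m[2]), character(1))
  vals
}

write_keyvalue <- function(x, path) {
  writeLines(paste0(names(x), " = ",
                    vapply(x, function(v) paste(format(v), collapse = ","),
                           character(1))),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read and write incubation designs as key-value files
#'
#' Keys mirror the [incubation_design()] arguments
#' (`water_volume_ml`, `headspace_volume_ml`, `temperature_c`,
#' `sampling_times_h` as a comma-separated list, `replicates_per_time`,
#' `treatment`, `added_15N_ammonium`, `added_15N_nitrite`,
#' `added_14N_nitrite`, `background_ammonium`, `background_nitrite`).
#' Missing keys fall back to the constructor defaults; `#` starts a
#' comment.
#'
#' @param path File path.
#' @return `read_incubation_design()`: an [incubation_design()].
#' @export
read_incubation_design <- function(path) {
  kv <- read_keyvalue(path)
  known <- names(formals(incubation_design))
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("unknown design key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (k in names(kv)) {
    v <- kv[[k]]
    args[[k]] <- if (k == "treatment") v
    else if (k == "sampling_times_h")
      as.numeric(strsplit(v, ",")[[1]])
    else as.numeric(v)
  }
  do.call(incubation_design, args)
}

#' @rdname read_incubation_design
#' @param design An [incubation_design()].
#' @export
write_incubation_design <- function(design, path) {
  stopifnot(inherits(design, "incubation_design"))
  write_keyvalue(unclass(design), path)
}

#' Read and write marker abundance tables
#'
#' Comma-separated, header row; columns `well`, `marker` (one of `16S`,
#' `hzsA`, `nirS`, `nirK`, `amoA_AOA`, `amoA_AOB`), `molecule` (`gene` or
#' `transcript`), `copies` (copies per litre groundwater),
#' `below_detection` (logical) and optionally `quantification_limit`.
#'
#' @param path File path.
#' @return `read_marker_table()`: the marker table data frame.
#' @export
read_marker_table <- function(path) {
  x <- read_table_checked(path, c("well", "marker", "molecule", "copies",
                                  "below_detection"), "marker table")
  x$below_detection <- as.logical(x$below_detection)
  validate_marker_table(x)
}

#' @rdname read_marker_table
#' @param table A marker table data frame.
#' @export
write_marker_table <- function(table, path) {
  validate_marker_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read ladderane GC peak-area tables
#'
#' Comma-separated, header row; columns `well`, `date`, `area_ladderane3`,
#' `area_ladderane5`, `area_C19_IS` (arbitrary GC peak-area units).
#'
#' @param path File path.
#' @return The peak table data frame.
#' @export
read_peak_table <- function(path) {
  read_table_checked(path, c("well", "date", "area_ladderane3",
                             "area_ladderane5", "area_C19_IS"),
                     "ladderane peak table")
}
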