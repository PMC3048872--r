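# Thermogram container and plain-text I/O.
#
# Processing stages move strictly forward:
#   raw -> reference_subtracted -> molar -> excess
# Raw and reference-subtracted values are cell heat capacities in an
# arbitrary energy unit per kelvin; molar normalization divides by the
# moles of protein in the cell, and baseline removal yields the excess
# molar heat capacity used for fitting (kcal mol^-1 K^-1 throughout this
# package's simulated data).

.STAGES <- c("raw", "reference_subtracted", "molar", "excess")

#' Construct a thermogram
#'
#' @param temperature strictly increasing temperature grid, degrees
#'   Celsius.
#' @param cp heat-capacity values, one per temperature.
#' @param scan_rate scan rate, K/min (metadata only; the equilibrium
#'   analysis never uses it).
#' @param conc protein concentration in the cell, mol/L.
#' @param cell_volume calorimeter cell volume, L.
#' @param stage processing stage, one of `"raw"`,
#'   `"reference_subtracted"`, `"molar"`, `"excess"`.
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(temperature, cp, scan_rate = NA_real_,
                       conc = NA_real_, cell_volume = NA_real_,
                       stage = "raw") {
  temperature <- as.numeric(temperature)
  cp <- as.numeric(cp)
  stage <- match.arg(stage, .STAGES)
  if (length(temperature) != length(cp)) {
    dscfit_stop("temperature and cp must have equal length",
                "dscfit_invalid_input")
  }
  if (any(diff(temperature) <= 0)) {
    dscfit_stop("temperature grid must be strictly increasing",
                "dscfit_invalid_input")
  }
  if (!all(is.finite(cp))) {
    dscfit_stop("cp values must be finite", "dscfit_invalid_input")
  }
  structure(list(temperature = temperature, cp = cp,
                 scan_rate = scan_rate, conc = conc,
                 cell_volume = cell_volume, stage = stage),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram [%s]: %d points, %.1f-%.1f degC\n",
              x$stage, length(x$temperature),
              min(x$temperature), max(x$temperature)))
  if (is.finite(x$scan_rate))
    cat(sprintf("  scan rate %.2f K/min", x$scan_rate))
  if (is.finite(x$conc))
    cat(sprintf("  conc %.3g M", x$conc))
  if (is.finite(x$cell_volume))
    cat(sprintf("  cell %.3g L", x$cell_volume))
  cat("\n")
  invisible(x)
}

#' @export
plot.thermogram <- function(x, ...) {
  graphics::plot(x$temperature, x$cp, type = "l",
                 xlab = "Temperature (degC)",
                 ylab = sprintf("Cp (%s)", x$stage), ...)
  invisible(x)
}

#' Read a thermogram from delimited text
#'
#' The format is two whitespace- or comma-delimited numeric columns
#' (temperature in degrees Celsius, heat capacity), preceded by
#' `#`-prefixed header lines carrying `key=value` metadata:
#' `scan_rate_K_per_min`, `conc_molar`, `cell_volume_L`, `stage`.
#'
#' @param path file path.
#' @return A [thermogram()].
#' @seealso [write_thermogram()]
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    dscfit_stop(sprintf("empty thermogram file: %s", path),
                "dscfit_read_error")
  }
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list(scan_rate_K_per_min = NA_real_, conc_molar = NA_real_,
               cell_volume_L = NA_real_, stage = "raw")
  for (h in hdr) {
    kv <- sub("^\\s*#\\s*", "", h)
    if (!grepl("=", kv, fixed = TRUE)) next
    key <- trimws(sub("=.*", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    if (key %in% names(meta)) {
      meta[[key]] <- if (key == "stage") val else as.numeric(val)
    }
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    dscfit_stop(sprintf("no data rows in thermogram file: %s", path),
                "dscfit_read_error")
  }
  df <- utils::read.table(text = gsub(",", " ", body),
                          col.names = c("temperature", "cp"))
  thermogram(df$temperature, df$cp,
             scan_rate = meta$scan_rate_K_per_min,
             conc = meta$conc_molar,
             cell_volume = meta$cell_volume_L,
             stage = meta$stage)
}

#' Write a thermogram to delimited text
#'
#' Emits the same dialect [read_thermogram()] accepts; a read/write
#' round-trip is lossless at full double precision.
#'
#' @param tg a [thermogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  hdr <- c(
    sprintf("# scan_rate_K_per_min=%s", format(tg$scan_rate, digits = 17)),
    sprintf("# conc_molar=%s", format(tg$conc, digits = 17)),
    sprintf("# cell_volume_L=%s", format(tg$cell_volume, digits = 17)),
    sprintf("# stage=%s", tg$stage))
  rows <- sprintf("%s\t%s",
                  format(tg$temperature, digits = 17, trim = TRUE),
                  format(tg$cp, digits = 17, trim = TRUE))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Subtract a buffer reference scan
#'
#' Subtracts a buffer-buffer reference thermogram from a sample scan,
#' interpolating the reference linearly onto the sample grid. Points of
#' the sample grid outside the reference range are dropped (no
#' extrapolation).
#'
#' @param sample raw-stage sample [thermogram()].
#' @param reference raw-stage reference [thermogram()] whose temperature
#'   range overlaps the sample's.
#' @return A `reference_subtracted`-stage thermogram on the (possibly
#'   truncated) sample grid.
#' @export
subtract_reference <- function(sample, reference) {
  if (sample$stage != "raw" || reference$stage != "raw") {
    dscfit_stop("both thermograms must be raw stage",
                "dscfit_invalid_input")
  }
  lo <- max(min(sample$temperature), min(reference$temperature))
  hi <- min(max(sample$temperature), max(reference$temperature))
  if (lo > hi) {
    dscfit_stop("sample and reference temperature ranges do not overlap",
                "dscfit_incompatible_grids")
  }
  keep <- sample$temperature >= lo & sample$temperature <= hi
  if (!all(keep)) {
    warning("sample grid truncated to the reference temperature range")
  }
  tt <- sample$temperature[keep]
  ref <- stats::approx(reference$temperature, reference$cp, xout = tt)$y
  thermogram(tt, sample$cp[keep] - ref,
             scan_rate = sample$scan_rate, conc = sample$conc,
             cell_volume = sample$cell_volume,
             stage = "reference_subtracted")
}

#' Normalize a thermogram to molar heat capacity
#'
#' Divides the cell heat capacity by the moles of protein in the cell
#' (concentration times cell volume). The energy unit is preserved.
#'
#' @param tg a `reference_subtracted`-stage (or raw) [thermogram()] with
#'   `conc` and `cell_volume` metadata.
#' @return A `molar`-stage thermogram.
#' @export
to_molar <- function(tg) {
  if (tg$stage == "molar" || tg$stage == "excess") {
    dscfit_stop("thermogram is already molar or excess stage",
                "dscfit_invalid_input")
  }
  if (!is.finite(tg$conc) || !is.finite(tg$cell_volume)) {
    dscfit_stop("protein concentration and cell volume metadata required",
                "dscfit_missing_metadata")
  }
  stopifnot_positive(tg$conc, "conc", "dscfit_missing_metadata")
  stopifnot_positive(tg$cell_volume, "cell_volume",
                     "dscfit_missing_metadata")
  moles <- tg$conc * tg$cell_volume
  thermogram(tg$temperature, tg$cp / moles,
             scan_rate = tg$scan_rate, conc = tg$conc,
             cell_volume = tg$cell_volume, stage = "molar")
}
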