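# End-to-end analysis driver: raw thermogram files -> processed excess
# curves -> two-state fits -> report, plus CD melts, titration series and
# structure-energetics blocks, all from one configuration list or YAML
# file. The report is a plain list serializable to JSON without loss
# (timestamp aside, re-running an identical configuration reproduces it
# exactly).

#' Read a CD melt curve from delimited text
#'
#' Two numeric columns (temperature degC, signal); `#` lines ignored.
#'
#' @param path file path.
#' @return A `melt_curve` data frame.
#' @export
read_melt_curve <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    dscfit_stop(sprintf("empty melt file: %s", path), "dscfit_read_error")
  }
  df <- utils::read.table(text = gsub(",", " ", body),
                          col.names = c("temperature", "signal"))
  class(df) <- c("melt_curve", "data.frame")
  df
}

#' Read a Tm titration series from delimited text
#'
#' Two numeric columns (ligand concentration mol/L, Tm degC).
#'
#' @param path file path.
#' @return A `titration_series` data frame.
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    dscfit_stop(sprintf("empty titration file: %s", path),
                "dscfit_read_error")
  }
  df <- utils::read.table(text = gsub(",", " ", body),
                          col.names = c("conc", "tm"))
  class(df) <- c("titration_series", "data.frame")
  df
}

stage_try <- function(stage, dataset, expr) {
  tryCatch(expr, error = function(e) {
    dscfit_stop(sprintf("stage '%s' failed for '%s': %s",
                        stage, dataset, conditionMessage(e)),
                "dscfit_pipeline_error")
  })
}

fit_block <- function(fit) {
  list(params = unclass(fit$params),
       std_errors = as.list(fit$std_errors),
       rss = fit$rss, n_points = fit$n_points,
       converged = fit$converged)
}

#' Run the full analysis pipeline
#'
#' Drives every stage the package provides from a single configuration:
#' for each DSC dataset, read (or accept) a thermogram, optionally
#' subtract a buffer reference, normalize to molar heat capacity, remove
#' the chemical baseline and fit the two-state model; fit CD melts and
#' titration series; and evaluate structure-energetics predictions. Any
#' stage error aborts with the stage and dataset name.
#'
#' @param config a list, or path to a YAML file, with optional entries:
#' \describe{
#'   \item{dsc}{list of datasets, each a list with `name`, `file` (path,
#'     [read_thermogram()] dialect) or `thermogram` (a [thermogram()]),
#'     optional `reference` (path to a raw buffer scan), optional
#'     `pre_window`/`post_window` (length-2 degC intervals).}
#'   \item{cd}{list of datasets with `name` and `file`
#'     ([read_melt_curve()]) or `melt` (data frame).}
#'   \item{titration}{list of datasets with `name`, `file`
#'     ([read_titration()]) or `series`, and `dh0` (kcal/mol).}
#'   \item{energetics}{list of blocks with `name`, `dasa_ap`, `dasa_pol`,
#'     `tm`, optional `dh_exp`.}
#'   \item{seed}{integer seed recorded in the provenance (default 0).}
#' }
#' @return A list of class `analysis_report` with one block per dataset
#'   plus `provenance` (package version, seed, input hashes, resolved
#'   configuration, timestamp).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 0
  hashes <- list()
  note_hash <- function(path) {
    hashes[[path]] <<- unname(tools::md5sum(path))
  }

  dsc <- lapply(config$dsc %||% list(), function(ds) {
    nm <- ds$name %||% "dsc"
    tg <- stage_try("read", nm, {
      if (!is.null(ds$thermogram)) ds$thermogram
      else {
        note_hash(ds$file)
        read_thermogram(ds$file)
      }
    })
    if (!is.null(ds$reference)) {
      ref <- stage_try("read_reference", nm, {
        note_hash(ds$reference)
        read_thermogram(ds$reference)
      })
      tg <- stage_try("subtract_reference", nm,
                      subtract_reference(tg, ref))
    }
    if (tg$stage %in% c("raw", "reference_subtracted")) {
      tg <- stage_try("to_molar", nm, to_molar(tg))
    }
    bl <- NULL
    if (tg$stage == "molar") {
      spec <- baseline_spec(pre_window = ds$pre_window,
                            post_window = ds$post_window)
      bl <- stage_try("remove_chemical_baseline", nm,
                      remove_chemical_baseline(tg, spec))
      tg <- bl$excess
    }
    fit <- stage_try("fit_two_state", nm, fit_two_state(tg))
    out <- fit_block(fit)
    out$name <- nm
    out$vant_hoff_ratio <- vant_hoff_ratio(fit)
    if (!is.null(bl)) {
      out$baseline <- list(pre_trend = bl$pre_trend,
                           post_trend = bl$post_trend,
                           iterations = bl$iterations,
                           converged = bl$converged)
    }
    out
  })

  cd <- lapply(config$cd %||% list(), function(ds) {
    nm <- ds$name %||% "cd"
    melt <- stage_try("read", nm, {
      if (!is.null(ds$melt)) ds$melt
      else {
        note_hash(ds$file)
        read_melt_curve(ds$file)
      }
    })
    fit <- stage_try("fit_cd_melt", nm, fit_cd_melt(melt))
    out <- fit_block(fit)
    out$name <- nm
    out
  })

  titr <- lapply(config$titration %||% list(), function(ds) {
    nm <- ds$name %||% "titration"
    series <- stage_try("read", nm, {
      if (!is.null(ds$series)) ds$series
      else {
        note_hash(ds$file)
        read_titration(ds$file)
      }
    })
    fit <- stage_try("fit_titration", nm, fit_titration(series, ds$dh0))
    out <- fit_block(fit)
    out$name <- nm
    out
  })

  energ <- lapply(config$energetics %||% list(), function(b) {
    pred <- stage_try("energetics", b$name %||% "energetics",
                      predict_energetics(b$dasa_ap, b$dasa_pol, b$tm,
                                         dh_exp = b$dh_exp))
    c(list(name = b$name %||% "energetics"),
      Filter(Negate(is.null), unclass(pred)))
  })

  report <- list(
    dsc = dsc, cd = cd, titration = titr, energetics = energ,
    provenance = list(
      package = "dscfit",
      version = as.character(utils::packageVersion("dscfit")),
      seed = seed,
      input_hashes = hashes,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  for (d in x$dsc) {
    cat(sprintf(
      "  DSC %-12s Tm = %6.2f degC  dH = %6.1f  dH_vH = %6.1f kcal/mol  ratio %.2f\n",
      d$name, d$params$tm, d$params$dh_cal, d$params$dh_vh,
      d$vant_hoff_ratio))
  }
  for (d in x$cd) {
    cat(sprintf("  CD  %-12s Tm_app = %6.2f degC\n",
                d$name, d$params$tm_app))
  }
  for (d in x$titration) {
    cat(sprintf("  TIT %-12s Tm0 = %6.2f degC  Kd = %.3g M\n",
                d$name, d$params$tm0, d$params$kd))
  }
  for (d in x$energetics) {
    cat(sprintf(
      "  NRG %-12s dCp = %.1f  dH60 = %.1f  dH(Tm=%.1f) = %.1f kcal/mol\n",
      d$name, d$dcp_calc, d$dh_calc_60, d$tm, d$dh_calc_at_tm))
  }
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an analysis report back from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return The report list (class `analysis_report`).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  class(rep) <- "analysis_report"
  rep
}
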