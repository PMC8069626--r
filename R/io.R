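#' Read a release profile from CSV
#'
#' Expects a header `time_h,fraction_released`. Alternatively a mass-based
#' file with columns `time_h,mass_mg` can be read by supplying the total
#' loaded mass `m_inf` (mg); masses are then normalised to fractions. Times
#' must be strictly increasing; the error message names the first offending
#' row.
#'
#' @param path Path to a CSV file (comma-separated, dot decimal, UTF-8,
#'   header mandatory).
#' @param m_inf Loaded drug mass in mg, required when the file carries a
#'   `mass_mg` column instead of `fraction_released`.
#' @param label Optional label; defaults to the file name.
#' @return A [release_profile()].
#' @export
read_profile_csv <- function(path, m_inf = NULL, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_h" %in% names(df)) {
    stop("CSV must have a `time_h` column", call. = FALSE)
  }
  if ("fraction_released" %in% names(df)) {
    frac <- df$fraction_released
  } else if ("mass_mg" %in% names(df)) {
    if (is.null(m_inf)) {
      stop("file has a `mass_mg` column: supply `m_inf` (mg) to normalise",
           call. = FALSE)
    }
    if (!is.finite(m_inf) || m_inf <= 0) {
      stop("`m_inf` must be > 0", call. = FALSE)
    }
    frac <- df$mass_mg / m_inf
  } else {
    stop("CSV must have a `fraction_released` (or `mass_mg`) column",
         call. = FALSE)
  }
  if (is.null(label)) label <- basename(path)
  release_profile(df$time_h, frac, label = label)
}

#' Write a release profile to CSV
#'
#' Writes the standard `time_h,fraction_released` format read back by
#' [read_profile_csv()].
#'
#' @param profile A [release_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "release_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialise a fit result to a JSON report
#'
#' Writes a machine-readable record of a [fit_release()] result --
#' parameters, contributions, metrics, the conversion factor used and
#' provenance fields -- that round-trips losslessly through
#' [read_fit_report()].
#'
#' @param fit A `fit_result`.
#' @param path Output path for the JSON report.
#' @param input Optional name of the input profile file.
#' @param seed Optional seed recorded for provenance.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path, input = NULL, seed = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  rec <- list(
    software = "relkin",
    version = as.character(utils::packageVersion("relkin")),
    input = input,
    seed = seed,
    label = fit$profile$label,
    gamma = fit$gamma,
    thickness = fit$thickness,
    params = list(mu = as.list(fit$params$mu), k_b = fit$params$k_b,
                  D_e = fit$params$D_e, k_os = fit$params$k_os),
    contributions = as.list(fit$contributions),
    delta_pi = fit$delta_pi,
    rmse = fit$rmse,
    r_squared = fit$r_squared,
    objective = fit$objective,
    converged = fit$converged,
    n_starts_used = fit$n_starts_used
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON fit report
#'
#' @param path Path written by [write_fit_report()].
#' @return The report as a named list; `$params` is restored to a
#'   [composite_params()] object.
#' @export
read_fit_report <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$params <- composite_params(
    c(rec$params$mu$burst, rec$params$mu$diffusion, rec$params$mu$osmosis),
    k_b = rec$params$k_b, D_e = rec$params$D_e, k_os = rec$params$k_os)
  rec
}

#' Read a structured configuration file
#'
#' Reads a YAML (or JSON) configuration holding geometry constants, the
#' osmotic conversion factor and fitting bounds, as used by the command-line
#' interface. Recognised top-level keys: `gamma`, `thickness`, `m_inf`,
#' `geometry` (fields of [geometry_constants()]), `bounds` (with `k_b`,
#' `D_e`, `k_os` 2-vectors) and `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Locate the command-line interface script
#'
#' The package ships a thin `Rscript` command-line interface over its
#' functions, with subcommands `simulate`, `fit`, `predict` and `physics`.
#' Run it as `Rscript $(Rscript -e 'cat(relkin::relkin_cli_path())') <cmd>`.
#'
#' @return Absolute path of the installed CLI script.
#' @export
relkin_cli_path <- function() {
  system.file("cli", "relkin", package = "relkin", mustWork = TRUE)
}
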