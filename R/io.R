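# Readers/writers for the delimited formats the pipeline consumes, and the
# end-to-end runner.

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(paste0("`", name, "` must be finite numeric."))
  }
  invisible(x)
}

#' Read a methyl peak list
#'
#' Two dialects: `"csv"` expects a header
#' `residue,restype,methyl,dH_ppm,dC_ppm`; `"sparky"` parses Sparky-style
#' assignment lists with lines like `I277CD1-HD1  12.345  0.678`
#' (label, w1 = 13C ppm, w2 = 1H ppm).
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"sparky"`.
#' @param state_name State label attached to the list.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, dialect = c("csv", "sparky"),
                           state_name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (dialect == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    return(peak_list(df, state_name))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!grepl("^Assignment", lines)]  # Sparky header
  rows <- purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\\s+")[[1]]
    if (length(parts) < 3L) {
      abort(paste0("Malformed Sparky row at line ", i, ": ", line))
    }
    m <- regmatches(parts[1],
                    regexec("^([ILV])(\\d+)([A-Z]+\\d*)-[A-Z]+\\d*$", parts[1]))[[1]]
    if (length(m) == 0L) {
      abort(paste0("Cannot parse Sparky label at line ", i, ": ", parts[1]))
    }
    w <- suppressWarnings(as.numeric(parts[2:3]))
    if (any(is.na(w))) {
      abort(paste0("Non-numeric shifts at line ", i, ": ", line))
    }
    tibble(residue = as.integer(m[3]), restype = m[2], methyl = m[4],
           dC_ppm = w[1], dH_ppm = w[2])
  })
  peak_list(dplyr::bind_rows(rows), state_name)
}

#' Write a methyl peak list
#'
#' @param peaks A [peak_list()] or compatible tibble.
#' @param path Output path (CSV with the standard header).
#' @export
write_peak_list <- function(peaks, path) {
  readr::write_csv(as_tibble(peaks)[
    c("residue", "restype", "methyl", "dH_ppm", "dC_ppm")], path)
  invisible(path)
}

#' Read a two-column delimited spectrum
#'
#' @param path File with columns wavelength (nm) and value.
#' @param kind `"emission"` or `"extinction"`.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  df <- readr::read_csv(path, show_col_types = FALSE)
  spectrum(df[[1]], df[[2]], kind)
}

#' Read a two-column time trace
#'
#' @param path File with columns time (s) and signal (or product).
#' @return Tibble with `time` and `signal`.
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble(time = df[[1]], signal = df[[2]])
}

#' Read a dispersion table
#'
#' Expects columns `residue`, `nu_cpmg` (or `inv_taucp`), `R2_eff`,
#' optional `sigma`.
#'
#' @param path File path.
#' @return Long tibble suitable for [fit_dispersion_panel()].
#' @export
read_dispersion <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("inv_taucp" %in% names(df) && !"nu_cpmg" %in% names(df)) {
    df$nu_cpmg <- df$inv_taucp
  }
  need <- c("residue", "nu_cpmg", "R2_eff")
  if (!all(need %in% names(df))) {
    abort(paste0("Dispersion table needs columns: ",
                 paste(need, collapse = ", ")))
  }
  as_tibble(df)
}

#' Run the configured analysis stages end to end
#'
#' Executes whichever stages the config describes — shift-vector state
#' comparison, kinetic fits and the fidelity table, FRET distances, a
#' stopped-flow global fit, and a CPMG panel — writes per-stage tables and
#' a JSON summary to `out_dir`, and logs the seed and parameters. A
#' failing stage is recorded and the remaining independent stages still
#' run.
#'
#' @param config Named list. Recognised entries: `shiftvec` (list with
#'   `test`, `open`, `closed` peak lists or file paths, optional
#'   `threshold`, `cos_cutoff`), `kinetics` (list with `params` fidelity
#'   input table or path, optional `rounding`), `fret` (list with `E` and
#'   `R0`, or `donor`/`acceptor` spectra paths plus `E`), `cpmg` (list
#'   with `data` dispersion table or path, optional `alpha`,
#'   `rex_cutoff`), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of stage results; `$errors` collects stage
#'   failures.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  errors <- list()
  summary <- list(schema_version = "1.0",
                  seed = config$seed %||% NA_integer_,
                  packages = list(polscape = as.character(
                    utils::packageVersion("polscape"))))
  if (!is.null(config$seed)) set.seed(config$seed)

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      summary$stages[[name]] <<- list(status = "failed",
                                      error = conditionMessage(res))
    } else {
      results[[name]] <<- res$value
      summary$stages[[name]] <<- c(list(status = "ok"), res$summary)
    }
  }

  load_peaks <- function(x, nm) {
    if (is.character(x)) read_peak_list(x, state_name = nm) else peak_list(x, nm)
  }

  if (!is.null(config$shiftvec)) {
    run_stage("shiftvec", function() {
      sv <- config$shiftvec
      cmp <- compare_states(
        load_peaks(sv$test, "test"), load_peaks(sv$open, "open"),
        load_peaks(sv$closed, "closed"),
        threshold = sv$threshold %||% 0.025,
        cos_cutoff = sv$cos_cutoff %||% 0.8)
      readr::write_csv(cmp$rows, file.path(out_dir, "shiftvec_rows.csv"))
      list(value = cmp, summary = as.list(cmp$summary))
    })
  }
  if (!is.null(config$kinetics)) {
    run_stage("kinetics", function() {
      kin <- config$kinetics
      params <- if (is.character(kin$params)) {
        readr::read_csv(kin$params, show_col_types = FALSE)
      } else as_tibble(kin$params)
      tbl <- fidelity_table(params, rounding = kin$rounding %||% "as_printed")
      readr::write_csv(tbl, file.path(out_dir, "fidelity_table.csv"))
      list(value = tbl,
           summary = list(n_rows = nrow(tbl),
                          fidelity = setNames(as.list(tbl$fidelity),
                                              paste(tbl$enzyme, tbl$template))))
    })
  }
  if (!is.null(config$fret)) {
    run_stage("fret", function() {
      fr <- config$fret
      R0 <- fr$R0
      if (is.null(R0) && !is.null(fr$donor)) {
        donor <- if (is.character(fr$donor)) {
          read_spectrum(fr$donor, "emission")
        } else fr$donor
        acceptor <- if (is.character(fr$acceptor)) {
          read_spectrum(fr$acceptor, "extinction")
        } else fr$acceptor
        J <- overlap_integral(donor, acceptor)
        R0 <- forster_radius(J, kappa2 = fr$kappa2 %||% 2 / 3,
                             eta = fr$eta %||% 1.344, f_d = fr$f_d %||% 0.7)
      }
      out <- tibble(E = fr$E, R0 = R0,
                    distance_A = distance_from_efficiency(fr$E, R0))
      readr::write_csv(out, file.path(out_dir, "fret_distances.csv"))
      list(value = out, summary = list(R0 = R0,
                                       distances = out$distance_A))
    })
  }
  if (!is.null(config$cpmg)) {
    run_stage("cpmg", function() {
      cp <- config$cpmg
      data <- if (is.character(cp$data)) read_dispersion(cp$data) else
        as_tibble(cp$data)
      fits <- fit_dispersion_panel(data, alpha = cp$alpha %||% 0.05,
                                   rex_cutoff = cp$rex_cutoff %||% 2)
      readr::write_csv(fits, file.path(out_dir, "cpmg_fits.csv"))
      list(value = fits,
           summary = list(n_residues = nrow(fits),
                          n_flexible = count_flexible(fits)))
    })
  }

  summary$errors <- errors
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(
    c(paste("polscape", utils::packageVersion("polscape")),
      paste("seed:", config$seed %||% "none"),
      paste("stages run:", paste(names(summary$stages), collapse = ", ")),
      if (length(errors) > 0) paste("failed:", paste(names(errors), collapse = ", "))),
    file.path(out_dir, "run.log"))
  results$errors <- errors
  invisible(results)
}
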