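#' Read a two-column spectrum table
#'
#' Reads delimited text (comma, tab or whitespace) with columns wavelength
#' (nm) and value (mm^-1 for absorption/scattering spectra). A single
#' non-numeric header line is allowed and skipped. Rows are sorted by
#' wavelength; exact duplicate rows are collapsed, duplicate wavelengths
#' with differing values are an error.
#'
#' @param path File path.
#' @return Tibble with columns `wavelength_nm`, `value`.
#' @export
read_spectrum_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "sfdlayers_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    abort(sprintf("empty spectrum file: %s", path),
          class = "sfdlayers_io_error")
  }
  parse_line <- function(s) {
    parts <- strsplit(trimws(s), "[,\t ]+")[[1]]
    suppressWarnings(as.numeric(parts))
  }
  first <- parse_line(lines[keep[1]])
  if (anyNA(first)) keep <- keep[-1]  # header line
  if (length(keep) == 0) {
    abort(sprintf("no data rows in spectrum file: %s", path),
          class = "sfdlayers_io_error")
  }
  rows <- lapply(keep, function(i) {
    v <- parse_line(lines[i])
    if (length(v) != 2 || anyNA(v)) {
      abort(sprintf("parse error at line %d of %s: expected two numeric fields",
                    i, path),
            class = "sfdlayers_io_error")
    }
    v
  })
  m <- do.call(rbind, rows)
  tb <- tibble::tibble(wavelength_nm = m[, 1], value = m[, 2])
  tb <- dplyr::distinct(tb)
  dup <- tb$wavelength_nm[duplicated(tb$wavelength_nm)]
  if (length(dup)) {
    abort(sprintf("duplicate wavelength %g nm with differing values in %s",
                  dup[1], path),
          class = "sfdlayers_io_error")
  }
  dplyr::arrange(tb, .data$wavelength_nm)
}

#' Write a two-column spectrum table
#'
#' Tab-separated, full double precision; round-trips through
#' [read_spectrum_table()].
#'
#' @param x Tibble/data frame whose first two columns are wavelength and
#'   value (a `chromophore_basis` works directly).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(x, path) {
  tb <- tibble::tibble(wavelength_nm = x[[1]], value = x[[2]])
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Read and write reflectance maps
#'
#' Long-format delimited text with columns `wavelength_nm`, `fx_per_mm`,
#' `rd` (extension `.csv` or `.tsv`), or a compact JSON form holding the two
#' grid vectors and the reflectance matrix (extension `.json`). Both
#' round-trip exactly; values outside `[0, 1]` are rejected with the
#' offending cells named.
#'
#' @param path File path; format chosen by extension.
#' @return A `reflectance_map` tibble.
#' @export
read_reflectance_map <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "sfdlayers_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("wavelengths_nm", "fx_per_mm", "rd")
    if (!all(need %in% names(obj))) {
      abort("reflectance JSON needs fields wavelengths_nm, fx_per_mm, rd",
            class = "sfdlayers_io_error")
    }
    rd <- if (is.matrix(obj$rd)) obj$rd else {
      matrix(unlist(obj$rd), nrow = length(obj$wavelengths_nm), byrow = TRUE)
    }
    return(new_reflectance_map(obj$wavelengths_nm, obj$fx_per_mm, rd))
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  validate_reflectance_map(tb)
}

#' @rdname read_reflectance_map
#' @param map A `reflectance_map`.
#' @export
write_reflectance_map <- function(map, path) {
  map <- validate_reflectance_map(map)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- rd_matrix(map)
    obj <- list(wavelengths_nm = attr(map, "wavelengths"),
                fx_per_mm = attr(map, "frequencies"),
                rd = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  } else if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(tibble::as_tibble(map), path)
  } else {
    readr::write_csv(tibble::as_tibble(map), path)
  }
  invisible(path)
}

# Run configuration (YAML) ---------------------------------------------------

#' Read a run configuration
#'
#' YAML schema (version 1):
#' \preformatted{
#' schema_version: 1
#' wavelengths: {min: 450, max: 1000, count: 32}
#' frequencies: {min: 0, max: 0.5, step: 0.01}
#' shef: {order: 9, mode_floor: 1e-9}
#' medium:
#'   n: 1.4
#'   n_ambient: 1.0
#'   g: 0.8
#'   thickness_mm: 0.3
#'   top:
#'     scattering: {A: 1.1, b: 1.3, lambda0: 750}
#'     absorption: {preset: naphthol}   # or {baseline, centers, widths, heights}
#'   bottom:
#'     scattering: {A: 1.0, b: 1.2}
#'     absorption: {preset: hemoglobin, beta: 1.0}  # or {file: basis.tsv, beta}
#' noise: {multiplicative_sigma: 0.005, additive_sigma: 1e-4, seed: 1}
#' }
#' All blocks have defaults; an empty file yields the default phantom run.
#'
#' @param path YAML file path.
#' @return Nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.null(cfg$schema_version) && cfg$schema_version != 1) {
    abort(sprintf("unsupported config schema_version %s", cfg$schema_version),
          class = "sfdlayers_io_error")
  }
  cfg$schema_version <- 1
  structure(cfg, class = "run_config")
}

config_wavelengths <- function(cfg) {
  w <- cfg$wavelengths %||% list()
  seq(w$min %||% 450, w$max %||% 1000, length.out = w$count %||% 32)
}

config_frequencies <- function(cfg) {
  f <- cfg$frequencies %||% list()
  seq(f$min %||% 0, f$max %||% 0.5, by = f$step %||% 0.01)
}

config_shef <- function(cfg) {
  s <- cfg$shef %||% list()
  shef_config(order = s$order %||% 9, mode_floor = s$mode_floor %||% 1e-9)
}

config_noise <- function(cfg, seed = NULL) {
  n <- cfg$noise %||% list()
  noise_model(multiplicative_sigma = n$multiplicative_sigma %||% 0.005,
              additive_sigma = n$additive_sigma %||% 1e-4,
              seed = seed %||% n$seed %||% 1L)
}

config_absorption <- function(a, wavelengths) {
  a <- a %||% list(preset = "naphthol")
  if (!is.null(a$file)) {
    tb <- read_spectrum_table(a$file)
    return(list(kind = "basis",
                basis = chromophore_basis(tb$wavelength_nm, tb$value)))
  }
  if (!is.null(a$preset)) {
    if (a$preset == "hemoglobin") {
      return(list(kind = "basis",
                  basis = hemoglobin_like_basis(wavelengths)))
    }
    return(list(kind = "peaks", peaks = top_absorption_preset(a$preset)))
  }
  list(kind = "peaks",
       peaks = absorption_peaks(a$baseline %||% 0,
                                unlist(a$centers) %||% numeric(0),
                                unlist(a$widths) %||% numeric(0),
                                unlist(a$heights) %||% numeric(0)))
}

config_phantom_spec <- function(cfg, wavelengths) {
  m <- cfg$medium %||% list()
  top <- m$top %||% list()
  bot <- m$bottom %||% list()
  ts <- top$scattering %||% list()
  bs <- bot$scattering %||% list()
  ta <- config_absorption(top$absorption, wavelengths)
  if (ta$kind != "peaks") {
    abort("top-layer absorption must be a peaks spec or preset",
          class = "sfdlayers_io_error")
  }
  ba <- config_absorption(bot$absorption %||% list(preset = "hemoglobin"),
                          wavelengths)
  if (ba$kind != "basis") {
    abort("bottom-layer absorption must be a basis (preset hemoglobin or file)",
          class = "sfdlayers_io_error")
  }
  phantom_spec(
    top_scattering = power_law_scattering(ts$A %||% 1.1, ts$b %||% 1.3,
                                          ts$lambda0 %||% 750),
    top_absorption = ta$peaks,
    bottom_scattering = power_law_scattering(bs$A %||% 1.0, bs$b %||% 1.2,
                                             bs$lambda0 %||% 750),
    beta = (bot$absorption %||% list())$beta %||% 1,
    basis = ba$basis,
    thickness_mm = m$thickness_mm %||% 0.3,
    n = m$n %||% 1.4, n_ambient = m$n_ambient %||% 1, g = m$g %||% 0.8
  )
}

#' Echo an effective run configuration
#'
#' @param cfg A `run_config` (nested list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
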