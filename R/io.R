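#' Read an optical-property table
#'
#' Expects a delimited file with columns `layer`, `wavelength_nm`, `mua`,
#' `mus`, `unit` (`per_mm` or `per_cm`), `g`, `n`, `thickness_mm`.
#' Coefficients given in per-cm are converted: the package stores all
#' coefficients in per-mm internally.
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected from the
#'   extension; `.tsv` is tab-separated).
#' @return A data frame with columns `layer`, `wavelength_nm`, `mu_a`,
#'   `mu_s`, `g`, `n`, `thickness_mm`, coefficients in per-mm.
#' @export
read_optical_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  req <- c("layer", "wavelength_nm", "mua", "mus", "unit", "g", "n",
           "thickness_mm")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("optical-property table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  bad <- !tab$unit %in% c("per_mm", "per_cm")
  if (any(bad))
    stop("unknown unit '", tab$unit[bad][1], "' (expected per_mm or per_cm)")
  fac <- ifelse(tab$unit == "per_cm", 0.1, 1)
  data.frame(layer = tab$layer, wavelength_nm = tab$wavelength_nm,
             mu_a = tab$mua * fac, mu_s = tab$mus * fac,
             g = tab$g, n = tab$n, thickness_mm = tab$thickness_mm)
}

#' Packaged default optical-property table
#'
#' Literature-style near-infrared optical properties for epidermis,
#' dermis, subcutaneous fat and tumor at 808, 852 and 890 nm. These are
#' synthetic defaults with representative magnitudes (tissue `mu_a` of
#' order 0.01-0.03 mm^-1, `mu_s` of order 7-18 mm^-1, `g` = 0.9,
#' `n` = 1.37), not measured values; every entry can be overridden by
#' supplying your own table to [build_tumor_stack()].
#'
#' @return A data frame in the layout of [read_optical_table()].
#' @export
default_tissue_table <- function() {
  read_optical_table(system.file("extdata", "tissue_optical_defaults.csv",
                                 package = "lightheat", mustWork = TRUE))
}

#' Read an absorber spectrum from CSV
#'
#' Columns `wavelength_nm` and `epsilon_per_M_per_cm`.
#'
#' @param path CSV path.
#' @param name Spectrum label; defaults to the file stem.
#' @return An [absorber_spectrum()].
#' @export
read_absorber_spectrum <- function(path, name = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("wavelength_nm", "epsilon_per_M_per_cm")
  if (!all(req %in% names(tab)))
    stop("spectrum file ", path, " must have columns ",
         paste(req, collapse = ", "))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  absorber_spectrum(name, tab$wavelength_nm, tab$epsilon_per_M_per_cm)
}

#' Read a temperature-time trace from CSV
#'
#' Columns `time_s`, `temp_C`, `laser_on` (0/1). Malformed rows are
#' reported with their line number.
#'
#' @param path CSV path.
#' @return A [temperature_trace()].
#' @export
read_trace <- function(path) {
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  req <- c("time_s", "temp_C", "laser_on")
  if (!all(req %in% names(tab)))
    stop("trace file ", path, " must have columns ",
         paste(req, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  t_s <- num(tab$time_s); temp <- num(tab$temp_C); las <- num(tab$laser_on)
  bad <- which(!is.finite(t_s) | !is.finite(temp) | !las %in% c(0, 1))
  if (length(bad) > 0)
    stop("trace file ", path, ": malformed row at line ", bad[1] + 1)
  temperature_trace(t_s, temp, as.integer(las))
}

#' Write a temperature trace to CSV
#'
#' @param trace A [temperature_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times, temp_C = trace$temperatures,
                       laser_on = trace$laser_on),
            path, row.names = FALSE)
  invisible(path)
}

#' Export an impulse response as long-format CSV plus a JSON sidecar
#'
#' The CSV has one row per (radial, depth) bin with columns `ir`, `iz`,
#' `r_mm`, `z_mm`, `A_per_mm3`, `Phi_per_mm2`; the sidecar records the
#' scalar tallies, seed and configuration echo.
#'
#' @param impulse An `impulse_response` from [run_simulation()].
#' @param path Output CSV path; the sidecar is written alongside with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_impulse <- function(impulse, path) {
  g <- impulse$grid
  rc <- (seq_len(g$nr) - 0.5) * g$dr
  zc <- (seq_len(g$nz) - 0.5) * g$dz
  df <- data.frame(ir = rep(seq_len(g$nr), times = g$nz),
                   iz = rep(seq_len(g$nz), each = g$nr),
                   r_mm = rep(rc, times = g$nz),
                   z_mm = rep(zc, each = g$nr),
                   A_per_mm3 = as.vector(impulse$A_rz),
                   Phi_per_mm2 = as.vector(impulse$Phi_rz))
  write.csv(df, path, row.names = FALSE)
  side <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(R_sp = impulse$R_sp, R_d = impulse$R_d, A_total = impulse$A_total,
         T_t = impulse$T_t, overflow_frac = impulse$overflow_frac,
         n_photons = impulse$n_photons, seed = impulse$seed,
         grid = g[c("dz", "dr", "nz", "nr")]),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
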