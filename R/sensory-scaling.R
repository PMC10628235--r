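# Hearing-range estimation from cochlear dimensions, and olfactory /
# semicircular-canal ratio statistics used as regression variables.

#' Hearing-range estimates from cochlear duct dimensions
#'
#' Two scaling chains are computed per taxon, both anchored to the length of
#' the endosseous cochlear duct:
#'
#' * the duct length is scaled against basicranial length (basioccipital +
#'   basisphenoid, excluding the parasphenoid rostrum), log10-transformed
#'   (`ecd_log10`), and used to predict the best-frequency-range bandwidth
#'   `bfr_hz = 6104.3 * ecd_log10 + 6975.2` and the mean best hearing
#'   `mbh_hz = 3311.3 * ecd_log10 + 4000.8` (both in Hz);
#' * the basilar papilla is taken as 2/3 of the duct length (mm) and used to
#'   predict the best frequency `bf = 5.7705 * exp(-0.25 * L)` and maximum
#'   (upper-limit) frequency `mf = 1.8436 * bf + 1.026`. These two equations
#'   operate in kHz; outputs are reported in Hz.
#'
#' A best-hearing interval `mbh_hz +/- bfr_hz / 2` is also reported
#' (interpreting the bandwidth as centred on the mean best hearing). Rows with
#' a missing `basicranial_length_mm` get `NA` for the scaled-duct chain but
#' still get the papilla chain, which needs no basicranial length.
#'
#' @param data Data frame with one row per taxon; required column
#'   `cochlear_duct_length_mm`, optional `basicranial_length_mm` and `taxon`.
#' @return The input tibble with columns `ecd_log10`, `bfr_hz`, `mbh_hz`,
#'   `best_hearing_low_hz`, `best_hearing_high_hz`, `papilla_length_mm`,
#'   `bf_hz`, `mf_hz` appended.
#' @export
#' @examples
#' hearing_range(tibble::tibble(
#'   taxon = "Thescelosaurus neglectus",
#'   cochlear_duct_length_mm = 9.95,
#'   basicranial_length_mm = NA_real_
#' ))
hearing_range <- function(data) {
  data <- tibble::as_tibble(data)
  check_columns(data, "cochlear_duct_length_mm")
  duct <- data$cochlear_duct_length_mm
  check_positive(duct, "cochlear_duct_length_mm")
  basi <- if ("basicranial_length_mm" %in% names(data)) {
    data$basicranial_length_mm
  } else {
    rep(NA_real_, nrow(data))
  }
  check_positive(basi, "basicranial_length_mm", allow_na = TRUE)

  scaled <- duct / basi
  if (any(scaled >= 1, na.rm = TRUE)) {
    inform("Scaled cochlear duct length >= 1 (duct longer than basicranium): unusual but accepted.")
  }
  ecd <- log10(scaled)
  bfr <- 6104.3 * ecd + 6975.2
  mbh <- 3311.3 * ecd + 4000.8
  papilla <- (2 / 3) * duct
  bf_khz <- 5.7705 * exp(-0.25 * papilla)
  mf_khz <- 1.8436 * bf_khz + 1.026

  dplyr::mutate(
    data,
    ecd_log10 = ecd,
    bfr_hz = bfr,
    mbh_hz = mbh,
    best_hearing_low_hz = mbh - bfr / 2,
    best_hearing_high_hz = mbh + bfr / 2,
    papilla_length_mm = papilla,
    bf_hz = 1000 * bf_khz,
    mf_hz = 1000 * mf_khz
  )
}

#' Olfactory ratio
#'
#' Longest diameter of the olfactory bulb divided by longest diameter of the
#' cerebral hemispheres (both in dorsal view), a proxy for olfactory acuity.
#' Dimensionless and scale-invariant: units cancel. Use `log10 = TRUE` for
#' the regression-ready transform.
#'
#' @param bulb_diameter_mm Longest olfactory bulb diameter.
#' @param cerebrum_diameter_mm Longest cerebral hemisphere diameter.
#' @param log10 If `TRUE`, return `log10(ratio)`.
#' @return Numeric vector of ratios (or their log10).
#' @export
#' @examples
#' olfactory_ratio(5, 20)
#' olfactory_ratio(5, 20, log10 = TRUE)
olfactory_ratio <- function(bulb_diameter_mm, cerebrum_diameter_mm,
                            log10 = FALSE) {
  check_positive(bulb_diameter_mm, "bulb_diameter_mm")
  check_positive(cerebrum_diameter_mm, "cerebrum_diameter_mm")
  ratio <- bulb_diameter_mm / cerebrum_diameter_mm
  if (log10) base::log10(ratio) else ratio
}

#' Semicircular-canal ratio metrics
#'
#' Computes the anterior:posterior semicircular canal height ratio
#' (`asc_psc_height_ratio`), the vestibular statistic used in agility
#' comparisons, plus log10 transforms of the canal heights and skull length
#' ready for regression. Heights are maximum vertical diameters measured with
#' the lateral semicircular canal held horizontal; the `lsc_horizontal`
#' column records that provenance and a warning is raised when it is absent
#' or `FALSE`.
#'
#' @param data Data frame with columns `asc_height_mm` and `psc_height_mm`;
#'   optional `skull_length_mm`, `lsc_horizontal` (logical), `taxon`.
#' @return The input tibble with `asc_psc_height_ratio`,
#'   `log10_asc_height`, `log10_psc_height`, `log10_asc_psc_ratio` and (when
#'   skull length is present) `log10_skull_length` appended.
#' @export
#' @examples
#' canal_metrics(tibble::tibble(
#'   taxon = "x", asc_height_mm = 6, psc_height_mm = 3, lsc_horizontal = TRUE
#' ))
canal_metrics <- function(data) {
  data <- tibble::as_tibble(data)
  check_columns(data, c("asc_height_mm", "psc_height_mm"))
  check_positive(data$asc_height_mm, "asc_height_mm")
  check_positive(data$psc_height_mm, "psc_height_mm")
  if (!"lsc_horizontal" %in% names(data) ||
      any(!isTRUE_vec(data$lsc_horizontal))) {
    warn("Canal heights are only comparable when measured with the LSC horizontal; the `lsc_horizontal` flag is missing or FALSE for some rows.")
  }
  out <- dplyr::mutate(
    data,
    asc_psc_height_ratio = .data$asc_height_mm / .data$psc_height_mm,
    log10_asc_height = log10(.data$asc_height_mm),
    log10_psc_height = log10(.data$psc_height_mm),
    log10_asc_psc_ratio = log10(.data$asc_psc_height_ratio)
  )
  if ("skull_length_mm" %in% names(out)) {
    check_positive(out$skull_length_mm, "skull_length_mm", allow_na = TRUE)
    out$log10_skull_length <- log10(out$skull_length_mm)
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read a labyrinth measurement table from CSV
#'
#' One row per taxon; columns follow the measurement field names used across
#' the package (`cochlear_duct_length_mm`, `basicranial_length_mm`,
#' `asc_height_mm`, `asc_width_mm`, `psc_height_mm`, `psc_width_mm`,
#' `skull_length_mm`, `lsc_horizontal`, ...).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_labyrinth_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
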