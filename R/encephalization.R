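# Reptile encephalization quotients from endocast volumes, with
# endocranial-fill and tissue-density conventions and interval propagation.

#' Brain mass from endocast volume
#'
#' Converts an endocast volume to an estimated brain mass by applying an
#' endocranial fill fraction (the share of the endocranial space occupied by
#' brain tissue; 50% is the convention for non-avian dinosaurs, 60% where
#' valleculae suggest a tighter fit) and a brain-tissue density
#' (1.036 g/ml by default).
#'
#' @param volume_ml Endocast volume in ml, excluding the olfactory tract.
#' @param fill_fraction Endocranial fill in (0, 1].
#' @param density_g_per_ml Brain tissue density in g/ml.
#' @return Brain mass in grams. Vectorized over all arguments.
#' @export
#' @examples
#' brain_mass_from_volume(27.25, 0.5)
brain_mass_from_volume <- function(volume_ml, fill_fraction,
                                   density_g_per_ml = 1.036) {
  check_positive(volume_ml, "volume_ml")
  check_fraction(fill_fraction, "fill_fraction")
  check_positive(density_g_per_ml, "density_g_per_ml")
  volume_ml * density_g_per_ml * fill_fraction
}

#' Reptile encephalization quotient
#'
#' Ratio of observed brain mass to the brain mass expected for a non-avian
#' reptile of the same body mass under the scaling law
#' \eqn{0.0155 \, M_{bd}^{0.553}} (both masses in grams):
#' \deqn{REQ = M_{Br} / (0.0155\, M_{bd}^{0.553})}
#'
#' @param brain_mass_g Brain mass in grams.
#' @param body_mass_g Body mass in grams (note: grams, not kg; the tabular
#'   interface [req_table()] owns the kg-to-g conversion).
#' @return Dimensionless REQ. Vectorized.
#' @export
#' @examples
#' req(brain_mass_from_volume(27.25, 0.5), 339 * 1000)
req <- function(brain_mass_g, body_mass_g) {
  check_positive(brain_mass_g, "brain_mass_g")
  check_positive(body_mass_g, "body_mass_g")
  brain_mass_g / (0.0155 * body_mass_g^0.553)
}

#' REQ table with interval propagation
#'
#' Computes REQ intervals for a table of taxa, one output row per taxon and
#' fill fraction. Body-mass and endocast-volume uncertainty propagate by the
#' monotonicity of the REQ formula: the interval lower bound pairs the
#' minimum volume with the maximum mass, the upper bound the maximum volume
#' with the minimum mass. Point inputs collapse to point outputs
#' (`req_min == req_max`).
#'
#' @param records A data frame with columns `taxon`, `body_mass_kg_min`,
#'   `body_mass_kg_max`, `endocast_volume_ml_min`, `endocast_volume_ml_max`,
#'   and `fill_fractions` (a list-column of numeric vectors, a numeric
#'   column, or a semicolon-separated character column such as `"0.5;0.6"`).
#'   Optional columns: `density_g_per_ml` (default 1.036) and `annotation`
#'   (free text carried through, e.g. lower-bound flags).
#' @return A tibble with columns `taxon`, `fill_fraction`,
#'   `brain_mass_g_min`, `brain_mass_g_max`, `req_min`, `req_max`, and
#'   `annotation`.
#' @export
#' @examples
#' req_table(tibble::tibble(
#'   taxon = "Thescelosaurus neglectus",
#'   body_mass_kg_min = 339, body_mass_kg_max = 339,
#'   endocast_volume_ml_min = 27.25, endocast_volume_ml_max = 28.61,
#'   fill_fractions = "0.5;0.6"
#' ))
req_table <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(
      taxon = character(), fill_fraction = numeric(),
      brain_mass_g_min = numeric(), brain_mass_g_max = numeric(),
      req_min = numeric(), req_max = numeric(), annotation = character()
    ))
  }
  check_columns(records, c("taxon", "body_mass_kg_min", "body_mass_kg_max",
                           "endocast_volume_ml_min", "endocast_volume_ml_max",
                           "fill_fractions"))
  if (!"density_g_per_ml" %in% names(records)) {
    records$density_g_per_ml <- 1.036
  }
  records$density_g_per_ml[is.na(records$density_g_per_ml)] <- 1.036
  if (!"annotation" %in% names(records)) records$annotation <- NA_character_
  fills <- parse_fill_fractions(records$fill_fractions)

  purrr::pmap_dfr(
    list(records$taxon,
         records$body_mass_kg_min, records$body_mass_kg_max,
         records$endocast_volume_ml_min, records$endocast_volume_ml_max,
         fills, records$density_g_per_ml, records$annotation),
    function(taxon, m_lo, m_hi, v_lo, v_hi, fill, dens, note) {
      ok <- tryCatch({
        check_positive(c(m_lo, m_hi, v_lo, v_hi), "mass/volume")
        check_fraction(fill, "fill_fractions")
        TRUE
      }, error = function(e) e)
      if (!isTRUE(ok)) {
        abort(sprintf("Invalid record for taxon '%s': %s",
                      taxon, conditionMessage(ok)))
      }
      if (m_lo > m_hi || v_lo > v_hi) {
        abort(sprintf("Invalid record for taxon '%s': interval lower bound exceeds upper bound.",
                      taxon))
      }
      tibble::tibble(
        taxon = taxon,
        fill_fraction = fill,
        brain_mass_g_min = brain_mass_from_volume(v_lo, fill, dens),
        brain_mass_g_max = brain_mass_from_volume(v_hi, fill, dens),
        # kg -> g conversion happens here and nowhere else
        req_min = req(brain_mass_from_volume(v_lo, fill, dens), m_hi * 1000),
        req_max = req(brain_mass_from_volume(v_hi, fill, dens), m_lo * 1000),
        annotation = note
      )
    }
  )
}

parse_fill_fractions <- function(x) {
  if (is.list(x)) return(lapply(x, as.numeric))
  if (is.numeric(x)) return(as.list(x))
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) as.numeric(trimws(v)))
}

#' Read an endocranial record table from CSV
#'
#' Expects the column layout documented in [req_table()]; `fill_fractions`
#' is a semicolon-separated string column (e.g. `"0.5;0.6"`).
#'
#' @param path CSV path.
#' @return A tibble of endocranial records.
#' @export
read_endocranial_csv <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(records, c("taxon", "body_mass_kg_min", "body_mass_kg_max",
                           "endocast_volume_ml_min", "endocast_volume_ml_max",
                           "fill_fractions"))
  records
}

#' Packaged ornithischian endocranial records
#'
#' The endocranial data set distributed with the package: per-taxon body-mass
#' and endocast-volume intervals for 15 ornithischians, with 50% and 60%
#' endocranial fills and brain tissue density 1.036 g/ml. Running it through
#' [req_table()] yields the reference REQ table.
#'
#' @return A tibble of endocranial records.
#' @export
#' @examples
#' req_table(ornithischian_endocranial_data())
ornithischian_endocranial_data <- function() {
  read_endocranial_csv(system.file("extdata", "ornithischian_endocranial.csv",
                                   package = "paleoneuro", mustWork = TRUE))
}
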