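#' @section CSV schemas:
#' The registry reads three comma-separated, UTF-8, header-first tables with
#' "." as the decimal separator:
#' \itemize{
#'   \item `pai_properties.csv`: name, pesticide_class, chemical_class,
#'     molar_mass_g_mol, koc_exp_L_kg, koc_model_L_kg, log_kow, pka,
#'     dt50_soil_days, dt50_water_days
#'   \item `application_rates.csv`: name, product_name, rate_units,
#'     product_rate_min, product_rate_max, ai_fraction, product_density_kg_L,
#'     slow_release_interval_years
#'   \item `etv.csv`: name, limit_umol_L, limit_type, method, percentile,
#'     reliability
#' }
#' @name pai-schemas
NULL

PROPERTY_COLS <- c("name", "pesticide_class", "chemical_class",
                   "molar_mass_g_mol", "koc_exp_L_kg", "koc_model_L_kg",
                   "log_kow", "pka", "dt50_soil_days", "dt50_water_days")
RATE_COLS <- c("name", "product_name", "rate_units", "product_rate_min",
               "product_rate_max", "ai_fraction", "product_density_kg_L",
               "slow_release_interval_years")
ETV_COLS <- c("name", "limit_umol_L", "limit_type", "method", "percentile",
              "reliability")

PESTICIDE_CLASSES <- c("herbicide", "insecticide", "fungicide", "nematicide")
RELIABILITY_LEVELS <- c("very_low", "low", "moderate", "high", "very_high",
                        "unknown")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    pdst_schema_error(sprintf("%s: missing required column(s): %s",
                              what, paste(missing, collapse = ", ")))
  invisible(df)
}

#' Assemble and validate a PAI table
#'
#' Bundles the three registry tables (physicochemical properties, product
#' application rates, ecotoxicity thresholds) into a single validated object.
#' The resolved Koc used downstream prefers the experimental value and falls
#' back to the modelled (OPERA-style) value when no experimental one exists.
#'
#' @param properties data frame of PAI properties (see [pai-schemas]).
#' @param rates data frame of product application rates.
#' @param etvs data frame of ecotoxicity thresholds (one row per PAI).
#' @return An object of class `pai_table`: a list with components
#'   `properties` (with an added resolved `koc_L_kg` and `koc_source`
#'   column), `rates` and `etvs`.
#' @export
pai_table <- function(properties, rates, etvs) {
  check_columns(properties, PROPERTY_COLS, "pai_properties")
  check_columns(rates, RATE_COLS, "application_rates")
  check_columns(etvs, ETV_COLS, "etv")

  properties$koc_L_kg <- ifelse(!is.na(properties$koc_exp_L_kg),
                                properties$koc_exp_L_kg,
                                properties$koc_model_L_kg)
  properties$koc_source <- ifelse(!is.na(properties$koc_exp_L_kg),
                                  "experimental", "modelled")
  x <- structure(list(properties = properties, rates = rates, etvs = etvs),
                 class = "pai_table")
  validate_pai_table(x)
}

#' @export
print.pai_table <- function(x, ...) {
  cat(sprintf("<pai_table> %d PAIs, %d rate entries, %d thresholds\n",
              nrow(x$properties), nrow(x$rates), nrow(x$etvs)))
  invisible(x)
}

require_positive <- function(values, names, what) {
  bad <- !is.na(values) & values <= 0
  nonum <- is.na(values)
  if (any(nonum))
    pdst_validation_error(sprintf("%s: missing value for %s", what,
                                  paste(names[nonum], collapse = ", ")))
  if (any(bad))
    pdst_validation_error(sprintf("%s must be > 0; offending rows: %s", what,
                                  paste(names[bad], collapse = ", ")))
}

validate_pai_table <- function(x) {
  p <- x$properties; r <- x$rates; e <- x$etvs

  if (anyDuplicated(p$name))
    pdst_validation_error(sprintf("duplicate PAI name(s): %s",
      paste(unique(p$name[duplicated(p$name)]), collapse = ", ")))
  bad_class <- !p$pesticide_class %in% PESTICIDE_CLASSES
  if (any(bad_class))
    pdst_validation_error(sprintf("unknown pesticide_class for: %s",
                                  paste(p$name[bad_class], collapse = ", ")))
  require_positive(p$molar_mass_g_mol, p$name, "molar_mass_g_mol")
  require_positive(p$koc_L_kg, p$name, "Koc (experimental or modelled)")
  require_positive(p$dt50_soil_days, p$name, "dt50_soil_days")
  require_positive(p$dt50_water_days, p$name, "dt50_water_days")

  if (nrow(r) == 0)
    pdst_integrity_error("application_rates is empty: no rate for any PAI")
  dangling <- setdiff(r$name, p$name)
  if (length(dangling) > 0)
    pdst_integrity_error(sprintf(
      "application_rates references unknown PAI(s): %s",
      paste(dangling, collapse = ", ")))
  dangling_e <- setdiff(e$name, p$name)
  if (length(dangling_e) > 0)
    pdst_integrity_error(sprintf("etv references unknown PAI(s): %s",
                                 paste(dangling_e, collapse = ", ")))
  if (anyDuplicated(e$name))
    pdst_validation_error("more than one threshold for a single PAI")

  if (any(r$ai_fraction <= 0 | r$ai_fraction > 1))
    pdst_validation_error("ai_fraction must lie in (0, 1]")
  if (any(r$product_rate_min > r$product_rate_max))
    pdst_validation_error("product_rate_min exceeds product_rate_max")
  if (any(r$product_rate_min < 0))
    pdst_validation_error("product rates must be non-negative")
  if (any(!is.na(r$slow_release_interval_years) &
          r$slow_release_interval_years < 1))
    pdst_validation_error("slow_release_interval_years must be >= 1")
  if (any(!r$rate_units %in% c("kg_per_ha", "L_per_ha")))
    pdst_validation_error("rate_units must be kg_per_ha or L_per_ha")

  require_positive(e$limit_umol_L, e$name, "limit_umol_L")
  af <- e$method == "AF"
  if (any(af & !is.na(e$percentile)))
    pdst_validation_error("AF-derived thresholds cannot carry a percentile")
  if (any(af & e$reliability != "unknown"))
    pdst_validation_error("AF-derived thresholds must have reliability 'unknown'")
  if (any(!e$reliability %in% RELIABILITY_LEVELS))
    pdst_validation_error("unknown reliability class in etv table")
  x
}

#' Load a PAI table from CSV files
#'
#' @param properties_path,rates_path,etv_path paths to the three CSV tables
#'   documented in [pai-schemas].
#' @return A validated [pai_table()].
#' @examples
#' paths <- pdst_reference_paths()
#' tab <- load_pai_table(paths["properties"], paths["rates"], paths["etv"])
#' tab
#' @export
load_pai_table <- function(properties_path, rates_path, etv_path) {
  for (f in c(properties_path, rates_path, etv_path))
    if (!file.exists(f)) pdst_schema_error(sprintf("file not found: %s", f))
  read1 <- function(f) read.csv(f, stringsAsFactors = FALSE,
                                fileEncoding = "UTF-8")
  pai_table(read1(properties_path), read1(rates_path), read1(etv_path))
}

#' Write a PAI table back to CSV files
#'
#' Numeric fields are written with full precision so that a
#' write-then-load round trip reproduces the table exactly.
#'
#' @param table a [pai_table()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths written.
#' @export
write_pai_table <- function(table, dir) {
  stopifnot(inherits(table, "pai_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(properties = file.path(dir, "pai_properties.csv"),
             rates = file.path(dir, "application_rates.csv"),
             etv = file.path(dir, "etv.csv"))
  p <- table$properties
  p$koc_L_kg <- NULL; p$koc_source <- NULL   # derived, recomputed on load
  write.csv(format(p, digits = 17, trim = TRUE, scientific = FALSE),
            paths["properties"], row.names = FALSE, na = "")
  write.csv(format(table$rates, digits = 17, trim = TRUE, scientific = FALSE),
            paths["rates"], row.names = FALSE, na = "")
  write.csv(format(table$etvs, digits = 17, trim = TRUE, scientific = FALSE),
            paths["etv"], row.names = FALSE, na = "")
  invisible(paths)
}

#' Paths to the bundled reference dataset
#'
#' @return Named character vector with elements `properties`, `rates`, `etv`
#'   and `measures`.
#' @export
pdst_reference_paths <- function() {
  f <- function(x) system.file("extdata", x, package = "pdst", mustWork = TRUE)
  c(properties = f("pai_properties.csv"), rates = f("application_rates.csv"),
    etv = f("etv.csv"), measures = f("reference_measures.csv"))
}

#' Bundled reference dataset of 47 sugar-cane PAIs
#'
#' Properties, application rates and thresholds for the 47 active ingredients
#' registered for sugar cane or its rotation crops in Queensland (48 rate
#' rows: imidacloprid appears as both a liquid and a slow-release
#' formulation). Thresholds and reference measures are as published for the
#' tool; application rates and half-lives were back-calculated to be
#' consistent with the reference measures and are reconstructions, not
#' label-verbatim values.
#'
#' @return A validated [pai_table()].
#' @export
pdst_reference_data <- function() {
  paths <- pdst_reference_paths()
  load_pai_table(paths["properties"], paths["rates"], paths["etv"])
}

#' Reference measures for the bundled dataset
#'
#' One row per formulation (48 rows) with the reference measure of mobility
#' and persistence, measure of effect at the maximum application rate, their
#' product (`aquatic_risk`), the report-scale value (`aquatic_risk_reported`
#' = risk / 100) and the value as printed in the tool's reference table
#' (`risk_reported_printed`; `"<1"` for sub-unit risks). For six strongly
#' sorbed PAIs with log10 Koc > 4 the runoff model clamps the transported
#' proportion at zero, and the mobility values (~0.01) are stored as given
#' rather than recomputed.
#'
#' @return A data frame of 48 rows.
#' @export
pdst_reference_measures <- function() {
  read.csv(pdst_reference_paths()["measures"], stringsAsFactors = FALSE,
           fileEncoding = "UTF-8")
}

#' Active-ingredient mass application rate
#'
#' Multiplies the product application rate by the AI mass fraction (and the
#' product density when the label rate is volumetric). Slow-release products
#' applied once every `slow_release_interval_years` years are annualized by
#' dividing by the interval.
#'
#' @param rate one or more rows of an `application_rates` table.
#' @param which which label bound to use: `"max"`, `"min"` or `"mean"`
#'   (arithmetic mean of the label bounds).
#' @return kg AI/ha (per year for slow-release products).
#' @export
ai_mass_rate <- function(rate, which = c("max", "min", "mean")) {
  which <- match.arg(which)
  product <- switch(which,
    max = rate$product_rate_max,
    min = rate$product_rate_min,
    mean = (rate$product_rate_min + rate$product_rate_max) / 2)
  density <- rep(1, length(product))
  vol <- rate$rate_units == "L_per_ha"
  if (any(vol)) {
    d <- rate$product_density_kg_L
    if (any(vol & (is.na(d) | d <= 0)))
      pdst_error("volumetric rate without a positive product density",
                 "pdst_configuration_error")
    density[vol] <- d[vol]
  }
  out <- product * density * rate$ai_fraction
  sr <- !is.na(rate$slow_release_interval_years)
  out[sr] <- out[sr] / rate$slow_release_interval_years[sr]
  out
}

#' Convert a mass application rate to a molar rate
#'
#' @param mass_rate kg AI/ha.
#' @param molar_mass g/mol.
#' @return umol AI/ha (`mass_rate * 1e9 / molar_mass`).
#' @export
mass_to_molar_rate <- function(mass_rate, molar_mass) {
  if (any(is.na(molar_mass) | molar_mass <= 0))
    pdst_validation_error("molar mass must be > 0")
  mass_rate * 1e9 / molar_mass
}
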