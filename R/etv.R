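# Ecotoxicity threshold derivation: per-species aggregation, minimum-data
# rule, bimodality handling, percentile selection and reliability classing.

#' Default threshold-derivation configuration
#'
#' Reads the packaged `derivation_config.yaml`: the species-count threshold
#' for automatic distribution selection, the assessment-factor table keyed by
#' endpoint class, the mode-of-action sensitive-group labels and the
#' reliability rubric.
#'
#' @param path optional path to an alternative YAML configuration.
#' @return A named list.
#' @export
default_derivation_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "derivation_config.yaml", package = "pdst",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Single toxicity value per species
#'
#' Aggregates quality-accepted records to one value per species using the
#' geometric mean (or the minimum, if configured).
#'
#' @param records data frame of toxicity records with columns `species`,
#'   `value` (umol/L) and `quality_accepted`.
#' @param aggregate `"geometric_mean"` or `"minimum"`.
#' @return Named numeric vector, one value per species.
#' @export
species_values <- function(records, aggregate = c("geometric_mean",
                                                  "minimum")) {
  aggregate <- match.arg(aggregate)
  acc <- records[records$quality_accepted & records$value > 0, , drop = FALSE]
  if (nrow(acc) == 0)
    pdst_data_error("no quality-accepted toxicity records")
  split_vals <- split(acc$value, acc$species)
  out <- vapply(split_vals, function(v) {
    if (aggregate == "geometric_mean") exp(mean(log(v))) else min(v)
  }, numeric(1))
  out[sort(names(out))]
}

#' Minimum-data rule for an SSD
#'
#' TRUE when toxicity values are available for at least five species from at
#' least four taxonomic groups.
#'
#' @param values named numeric vector (species -> umol/L).
#' @param groups named character vector mapping species to taxonomic group.
#' @return Logical scalar.
#' @export
check_minimum_data <- function(values, groups) {
  sp <- names(values)
  if (!all(sp %in% names(groups)))
    pdst_validation_error("taxonomic group missing for some species")
  length(sp) >= 5 && length(unique(groups[sp])) >= 4
}

#' Restrict bimodal data to the most sensitive group
#'
#' When a toxicity dataset is declared bimodal (by mode-of-action grouping,
#' e.g. phototrophs vs all others for a herbicide), only species belonging to
#' the sensitive group labels are retained; otherwise values pass through
#' unchanged.
#'
#' @param values named numeric vector (species -> umol/L).
#' @param groups named character vector mapping species to taxonomic group.
#' @param sensitive_group_labels character vector of group labels forming the
#'   sensitive mode-of-action group.
#' @param bimodal logical; is the dataset bimodal?
#' @return Filtered named numeric vector.
#' @export
select_sensitive_subset <- function(values, groups, sensitive_group_labels,
                                    bimodal) {
  if (!bimodal) return(values)
  keep <- names(values)[groups[names(values)] %in% sensitive_group_labels]
  if (length(keep) == 0)
    pdst_data_error("no species left after restricting to the sensitive group")
  values[keep]
}

#' Advisory bimodality diagnostic
#'
#' Largest gap between consecutive ordered log10 values relative to the total
#' log10 range. Values near 1 indicate two well-separated modes. Advisory
#' only: bimodality is declared by the caller, not auto-detected.
#'
#' @param values positive numeric vector.
#' @return Gap statistic in `[0, 1]` (0 when fewer than 3 values).
#' @export
bimodality_gap <- function(values) {
  y <- sort(log10(values))
  if (length(y) < 3 || diff(range(y)) == 0) return(0)
  max(diff(y)) / diff(range(y))
}

#' Assessment-factor threshold
#'
#' The fallback when the minimum-data rule fails: the single lowest species
#' value divided by an assessment factor. AF-derived thresholds carry no
#' protection percentile and have unknown reliability.
#'
#' @param values positive numeric vector of species toxicity values (umol/L).
#' @param factor assessment factor (>= 1).
#' @param pai_name name recorded on the result.
#' @return A one-row data frame shaped like an `etv` table row.
#' @export
assessment_factor_etv <- function(values, factor, pai_name = NA_character_) {
  if (length(values) == 0)
    pdst_data_error("no toxicity values for assessment-factor derivation")
  if (factor < 1) pdst_validation_error("assessment factor must be >= 1")
  data.frame(name = pai_name, limit_umol_L = min(values) / factor,
             limit_type = "ETV", method = "AF", percentile = NA_real_,
             reliability = "unknown")
}

#' Protection percentile for a PAI
#'
#' SSD-derived thresholds use the 95% protection level except for potential
#' biomagnifiers (log Kow of 4 or greater), which use 99%. Assessment-factor
#' thresholds carry no percentile.
#'
#' @param log_kow log10 octanol-water partition coefficient.
#' @param ssd_derived was the threshold derived from an SSD?
#' @return 95, 99 or NA.
#' @export
select_percentile <- function(log_kow, ssd_derived) {
  if (!ssd_derived) return(NA_real_)
  if (!is.na(log_kow) && log_kow >= 4) 99 else 95
}

#' Reliability class of a derived threshold
#'
#' Deterministic, monotone lookup in a configurable rubric: points accrue
#' with the number of species, the number of taxonomic groups, the endpoint
#' mix (chronic data scoring highest) and the SSD fit quality, and the total
#' maps to one of very_low, low, moderate, high, very_high.
#'
#' @param n_species,n_groups counts.
#' @param endpoint_mix `"all_chronic"`, `"mixed"` or `"all_converted_acute"`.
#' @param fit_quality `"good"`, `"acceptable"` or `"poor"`.
#' @param rubric rubric list (see `default_derivation_config()$reliability_rubric`).
#' @return Reliability class as a string.
#' @export
classify_reliability <- function(n_species, n_groups,
                                 endpoint_mix = c("all_chronic", "mixed",
                                                  "all_converted_acute"),
                                 fit_quality = c("good", "acceptable",
                                                 "poor"),
                                 rubric = NULL) {
  endpoint_mix <- match.arg(endpoint_mix)
  fit_quality <- match.arg(fit_quality)
  if (is.null(rubric))
    rubric <- default_derivation_config()$reliability_rubric
  stopifnot(n_species >= 0, n_groups >= 0)
  pts <- sum(n_species >= unlist(rubric$species_thresholds)) +
    sum(n_groups >= unlist(rubric$group_thresholds)) +
    rubric$endpoint_points[[endpoint_mix]] +
    rubric$fit_points[[fit_quality]]
  cuts <- unlist(rubric$class_cutoffs)
  names(cuts)[max(which(pts >= cuts))]
}

# fit quality from the Kolmogorov-Smirnov distance between the fitted and
# empirical CDFs; coarse, but monotone in goodness of fit
ssd_fit_quality <- function(fit, values) {
  u <- if (fit$distribution == "burr_iii") {
    pburr3(sort(values), fit$parameters["b"], fit$parameters["c"],
           fit$parameters["k"])
  } else {
    ploglogistic(sort(values), fit$parameters["alpha"],
                 fit$parameters["beta"])
  }
  n <- length(values)
  d <- max(pmax(abs(u - (seq_len(n) - 1) / n), abs(u - seq_len(n) / n)))
  if (d < 0.1) "good" else if (d < 0.2) "acceptable" else "poor"
}

endpoint_mix_of <- function(endpoint_class) {
  if (all(endpoint_class == "chronic")) "all_chronic"
  else if (all(endpoint_class == "converted_acute")) "all_converted_acute"
  else "mixed"
}

#' Derive an ecotoxicity threshold from species toxicity data
#'
#' End-to-end pipeline: aggregate records to one value per species, restrict
#' to the sensitive mode-of-action group if the dataset is declared bimodal,
#' then either fit an SSD and read off the protective concentration at the
#' percentile selected from log Kow (when at least five species from four
#' taxonomic groups are available) or fall back to the assessment-factor
#' method using the factor keyed by the endpoint class of the lowest value.
#'
#' @param records data frame of toxicity records (`species`,
#'   `taxonomic_group`, `endpoint_class`, `value`, `quality_accepted`;
#'   optionally `pai_name`).
#' @param log_kow log10 Kow of the PAI (drives the percentile choice).
#' @param pesticide_class used to look up the sensitive group labels when
#'   `bimodal = TRUE`.
#' @param bimodal logical; declared by the caller.
#' @param config derivation configuration (default:
#'   [default_derivation_config()]).
#' @return A one-row data frame shaped like an `etv` table row, with the
#'   `ssd_fit` attached as attribute `"fit"` when the SSD path was used.
#' @export
derive_etv <- function(records, log_kow = NA, pesticide_class = "herbicide",
                       bimodal = FALSE, config = default_derivation_config()) {
  if (nrow(records) == 0) pdst_data_error("no toxicity records supplied")
  pai <- if ("pai_name" %in% names(records)) records$pai_name[1] else NA
  vals <- species_values(records)
  groups <- setNames(records$taxonomic_group, records$species)
  groups <- groups[!duplicated(names(groups))]
  if (bimodal) {
    labels <- unlist(config$sensitive_groups[[pesticide_class]])
    vals <- select_sensitive_subset(vals, groups, labels, bimodal = TRUE)
  }

  if (!check_minimum_data(vals, groups)) {
    low_sp <- names(vals)[which.min(vals)]
    cls <- records$endpoint_class[match(low_sp, records$species)]
    af <- config$assessment_factors[[cls]]
    if (is.null(af)) af <- max(unlist(config$assessment_factors))
    return(assessment_factor_etv(vals, af, pai))
  }

  fit <- fit_ssd(vals, distribution = "auto",
                 auto_threshold = config$auto_distribution_threshold)
  pct <- select_percentile(log_kow, ssd_derived = TRUE)
  limit <- protective_concentration(fit, pct)
  rel <- classify_reliability(
    n_species = length(vals),
    n_groups = length(unique(groups[names(vals)])),
    endpoint_mix = endpoint_mix_of(records$endpoint_class),
    fit_quality = ssd_fit_quality(fit, vals),
    rubric = config$reliability_rubric)
  out <- data.frame(name = pai, limit_umol_L = limit, limit_type = "ETV",
                    method = "SSD", percentile = pct, reliability = rel)
  attr(out, "fit") <- fit
  out
}

#' Convert a mass concentration to a molar concentration
#'
#' @param value mg/L.
#' @param molar_mass g/mol.
#' @return umol/L (`value * 1000 / molar_mass`).
#' @export
convert_concentration <- function(value, molar_mass) {
  if (any(is.na(molar_mass) | molar_mass <= 0))
    pdst_validation_error("molar mass must be > 0")
  value * 1000 / molar_mass
}
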