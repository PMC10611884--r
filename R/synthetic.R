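#' Generate a synthetic PAI table
#'
#' Draws physicochemical properties, application rates and thresholds from
#' log-uniform ranges spanning the bundled reference dataset: Koc 1 to 1e6
#' L/kg, soil and water half-lives 0.1 to 1e4 days, thresholds 1e-7 to 10
#' umol/L, AI application rates 0.005 to 10 kg/ha. Deterministic for a given
#' seed; every generated table passes the registry validators.
#'
#' @param seed integer seed.
#' @param n_pai number of active ingredients (>= 1).
#' @return A validated [pai_table()].
#' @export
generate_fixture_table <- function(seed, n_pai) {
  stopifnot(n_pai >= 1)
  set.seed(seed)
  rlunif <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))
  name <- sprintf("pai_%03d", seq_len(n_pai))
  classes <- sample(PESTICIDE_CLASSES, n_pai, replace = TRUE)
  koc <- rlunif(n_pai, 1, 1e6)
  has_exp <- runif(n_pai) < 0.66
  props <- data.frame(
    name = name, pesticide_class = classes,
    chemical_class = sample(c("triazine", "organophosphate", "sulfonylurea",
                              "triazole", "carbamate"), n_pai, replace = TRUE),
    molar_mass_g_mol = runif(n_pai, 100, 700),
    koc_exp_L_kg = ifelse(has_exp, koc, NA),
    koc_model_L_kg = signif(koc * rlunif(n_pai, 0.5, 2), 6),
    log_kow = runif(n_pai, -4, 7),
    pka = ifelse(runif(n_pai) < 0.5, runif(n_pai, 1, 12), NA),
    dt50_soil_days = rlunif(n_pai, 0.1, 1e4),
    dt50_water_days = rlunif(n_pai, 0.1, 1e4))
  rate_max <- rlunif(n_pai, 0.005, 10)
  frac <- runif(n_pai, 0.1, 1)
  sr <- runif(n_pai) < 0.05
  rates <- data.frame(
    name = name, product_name = "standard",
    rate_units = sample(c("kg_per_ha", "L_per_ha"), n_pai, replace = TRUE),
    product_rate_min = rate_max / frac * runif(n_pai, 0.25, 1),
    product_rate_max = rate_max / frac,
    ai_fraction = frac, product_density_kg_L = 1,
    slow_release_interval_years = ifelse(sr, sample(2:4, n_pai, TRUE), NA))
  method <- ifelse(runif(n_pai) < 0.1, "AF", "SSD")
  etvs <- data.frame(
    name = name, limit_umol_L = rlunif(n_pai, 1e-7, 10),
    limit_type = sample(c("DGV", "ETV"), n_pai, replace = TRUE),
    method = method,
    percentile = ifelse(method == "AF", NA,
                        ifelse(props$log_kow >= 4, 99, 95)),
    reliability = ifelse(method == "AF", "unknown",
                         sample(setdiff(RELIABILITY_LEVELS, "unknown"),
                                n_pai, replace = TRUE)))
  pai_table(props, rates, etvs)
}

#' Generate a synthetic species toxicity dataset
#'
#' Species sensitivities are drawn from a log10-normal distribution with
#' known parameters, so the true protective concentrations of the generating
#' distribution are available in closed form (e.g. the true 5th percentile is
#' `10^(meanlog10 + qnorm(0.05) * sdlog10)`).
#'
#' @param seed integer seed.
#' @param n_species number of species.
#' @param meanlog10,sdlog10 mean and standard deviation of log10
#'   sensitivity (default -1 and 0.5, i.e. a median of 0.1 umol/L).
#' @param records_per_species replicate toxicity records per species.
#' @param pai_name name attached to the records.
#' @param groups pool of taxonomic group labels to sample from.
#' @return A data frame of toxicity records (`pai_name`, `species`,
#'   `taxonomic_group`, `phylum`, `endpoint_class`, `value` in umol/L,
#'   `quality_accepted`).
#' @export
generate_toxicity_data <- function(seed, n_species, meanlog10 = -1,
                                   sdlog10 = 0.5, records_per_species = 1,
                                   pai_name = "synthetic",
                                   groups = c("fish", "arthropod",
                                              "phototroph", "mollusc",
                                              "amphibian")) {
  stopifnot(n_species >= 1, records_per_species >= 1)
  set.seed(seed)
  species <- sprintf("species_%03d", seq_len(n_species))
  group <- groups[(seq_len(n_species) - 1) %% length(groups) + 1]
  base <- 10^rnorm(n_species, meanlog10, sdlog10)
  rec <- do.call(rbind, lapply(seq_len(records_per_species), function(i) {
    data.frame(pai_name = pai_name, species = species,
               taxonomic_group = group, phylum = group,
               endpoint_class = "chronic",
               value = base * 10^rnorm(n_species, 0, 0.05),
               quality_accepted = TRUE)
  }))
  rec[order(rec$species), ]
}

#' Generate synthetic runoff-trial data
#'
#' Percent loss follows `intercept + slope * log10(Koc)` plus Gaussian noise,
#' truncated at zero, emulating rainfall-simulation trials on a given soil
#' type.
#'
#' @param seed integer seed.
#' @param n number of trials.
#' @param slope,intercept generating line (defaults: the runoff-loss model
#'   coefficients, -10.076 and 39.123).
#' @param sigma noise standard deviation in percent (0 gives exact points).
#' @param soil_type label attached to the trials.
#' @return A data frame with `pai_name`, `soil_type`, `percent_loss`,
#'   `koc_L_kg`.
#' @export
generate_runoff_trials <- function(seed, n, slope = -10.076,
                                   intercept = 39.123, sigma = 5,
                                   soil_type = "hydrosol") {
  stopifnot(n >= 1)
  set.seed(seed)
  koc <- 10^runif(n, 0.5, 3.5)
  loss <- pmax(0, intercept + slope * log10(koc) + rnorm(n, 0, sigma))
  data.frame(pai_name = sprintf("trial_%03d", seq_len(n)),
             soil_type = soil_type, percent_loss = loss, koc_L_kg = koc)
}
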