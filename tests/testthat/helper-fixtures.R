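# A 3-PAI table, built in code, small enough to hand-verify.
make_tiny_table <- function() {
  props <- data.frame(
    name = c("alpha", "beta", "gamma"),
    pesticide_class = c("herbicide", "insecticide", "fungicide"),
    chemical_class = "synthetic",
    molar_mass_g_mol = c(200, 250, 300),
    koc_exp_L_kg = c(100, NA, 1000),
    koc_model_L_kg = c(120, 50, 900),
    log_kow = c(2, 5, 3),
    pka = c(3, NA, NA),
    dt50_soil_days = c(10, 100, 50),
    dt50_water_days = c(5, 20, 2))
  rates <- data.frame(
    name = c("alpha", "beta", "gamma"),
    product_name = "standard",
    rate_units = c("kg_per_ha", "kg_per_ha", "L_per_ha"),
    product_rate_min = c(1, 0.05, 2),
    product_rate_max = c(2, 0.1, 4),
    ai_fraction = c(0.5, 0.8, 0.25),
    product_density_kg_L = c(1, 1, 1.2),
    slow_release_interval_years = c(NA, NA, NA))
  etvs <- data.frame(
    name = c("alpha", "beta", "gamma"),
    limit_umol_L = c(0.01, 1e-5, 0.5),
    limit_type = c("DGV", "ETV", "ETV"),
    method = c("SSD", "SSD", "AF"),
    percentile = c(95, 99, NA),
    reliability = c("high", "moderate", "unknown"))
  pai_table(props, rates, etvs)
}

# toxicity records with explicit values, one row per (species, value)
make_tox_records <- function(species, values, groups,
                             endpoint = "chronic", accepted = TRUE,
                             pai = "test_pai") {
  data.frame(pai_name = pai, species = species, taxonomic_group = groups,
             phylum = groups, endpoint_class = endpoint, value = values,
             quality_accepted = accepted)
}
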