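# The aquatic-risk engine: runoff proportion, measure of effect, measure of
# mobility and persistence, their product, spray regimes and tank mixes.

#' Proportion of an applied PAI transported in runoff
#'
#' Linear model on log10 Koc calibrated against rainfall-simulation runoff
#' trials on a hydrosol soil: percent transported =
#' `-10.076 * log10(Koc) + 39.123`, divided by 100 and clamped to
#' `[floor, 1]`. The line crosses zero at log10 Koc of about 3.883, so
#' strongly sorbed compounds clamp to the floor (0 by default).
#'
#' @param koc organic carbon-water partition coefficient, L/kg (> 0).
#' @param floor lower clamp for the proportion (default 0).
#' @return Proportion in `[floor, 1]`.
#' @export
proportion_transported <- function(koc, floor = 0) {
  if (any(is.na(koc) | koc <= 0))
    pdst_error("Koc must be > 0", "pdst_domain_error")
  stopifnot(floor >= 0, floor <= 1)
  p <- (-10.076 * log10(koc) + 39.123) / 100
  pmin(1, pmax(floor, p))
}

#' Measure of effect
#'
#' Maximum application rate divided by the ecotoxicity threshold, with the
#' threshold converted from umol/L to umol/ML. Interpretable as the
#' megalitres of water per hectare needed to dilute the applied dose to the
#' threshold. Linear in the application rate, inverse in the threshold.
#'
#' @param app_rate_umol_ha application rate, umol PAI/ha (>= 0).
#' @param etv_umol_L threshold (DGV or ETV), umol/L (> 0).
#' @return ML/ha.
#' @export
measure_of_effect <- function(app_rate_umol_ha, etv_umol_L) {
  if (any(is.na(etv_umol_L) | etv_umol_L <= 0))
    pdst_error("threshold must be > 0", "pdst_domain_error")
  if (any(app_rate_umol_ha < 0))
    pdst_error("application rate must be >= 0", "pdst_domain_error")
  app_rate_umol_ha / (etv_umol_L * 1e6)
}

#' Measure of mobility and persistence
#'
#' Soil half-life x water half-life x proportion of the applied PAI
#' transported in runoff.
#'
#' @param dt50_soil,dt50_water half-lives in days (> 0).
#' @param proportion proportion transported, in `[0, 1]`.
#' @return days^2 x proportion; zero iff `proportion` is zero.
#' @export
measure_of_mobility_persistence <- function(dt50_soil, dt50_water,
                                            proportion) {
  if (any(dt50_soil <= 0) || any(dt50_water <= 0))
    pdst_error("half-lives must be > 0", "pdst_domain_error")
  if (any(proportion < 0 | proportion > 1))
    pdst_error("proportion must lie in [0, 1]", "pdst_domain_error")
  dt50_soil * dt50_water * proportion
}

#' Aquatic risk
#'
#' The product of the measure of effect and the measure of mobility and
#' persistence; the report scale divides by 100 (reference tables print
#' risk / 100).
#'
#' @param effect measure of effect (>= 0).
#' @param mobility_persistence measure of mobility and persistence (>= 0).
#' @return List with `risk` and `reported` (= risk / 100).
#' @export
aquatic_risk <- function(effect, mobility_persistence) {
  if (any(effect < 0) || any(mobility_persistence < 0))
    pdst_error("risk inputs must be >= 0", "pdst_domain_error")
  risk <- effect * mobility_persistence
  list(risk = risk, reported = risk / 100)
}

#' Spray regime
#'
#' Broadcast spraying treats the whole field; band or spot spraying treats a
#' fraction of it at the broadcast per-hectare product rate, scaling the
#' effective application rate (and hence the risk) by that fraction.
#'
#' @param mode `"broadcast"`, `"band"` or `"spot"`.
#' @param treated_fraction fraction of the field treated, in `(0, 1]`;
#'   forced to 1 for broadcast.
#' @return An object of class `spray_regime`.
#' @export
spray_regime <- function(mode = c("broadcast", "band", "spot"),
                         treated_fraction = 1) {
  mode <- match.arg(mode)
  if (mode == "broadcast") treated_fraction <- 1
  if (is.na(treated_fraction) || treated_fraction <= 0 ||
      treated_fraction > 1)
    pdst_validation_error("treated_fraction must lie in (0, 1]")
  structure(list(mode = mode, treated_fraction = treated_fraction),
            class = "spray_regime")
}

#' Apply a spray regime to an application rate
#'
#' @param app_rate application rate (any linear unit).
#' @param regime a [spray_regime()].
#' @return `app_rate * treated_fraction` (identity for broadcast).
#' @export
apply_regime <- function(app_rate, regime) {
  stopifnot(inherits(regime, "spray_regime"))
  app_rate * regime$treated_fraction
}

#' Indicative tank-mix risk
#'
#' Sum of the component aquatic risks. The sum assumes a shared mode of
#' action, so it is an indicative, not a definitive, combined risk.
#'
#' @param risks numeric vector of component aquatic risks, or a risk table
#'   from [pdst_compute()] (its `aquatic_risk` column is used).
#' @return List with `components`, `total` and a fixed `label`
#'   `"indicative"`.
#' @export
tank_mix_risk <- function(risks) {
  if (is.data.frame(risks)) risks <- risks$aquatic_risk
  if (length(risks) == 0)
    pdst_validation_error("a tank mix needs at least one component")
  if (any(is.na(risks) | risks < 0))
    pdst_validation_error("component risks must be >= 0")
  list(components = risks, total = sum(risks), label = "indicative")
}

#' Rank PAIs on a risk-table column
#'
#' Descending average ranks (rank 1 = largest value; ties share the mean
#' rank). Formulations of the same PAI rank as separate entries.
#'
#' @param results risk table from [pdst_compute()] (or any data frame with
#'   `label` plus the chosen column).
#' @param key `"risk"`, `"effect"` or `"mobility"`.
#' @return Named numeric vector of ranks.
#' @export
rank_pais <- function(results, key = c("risk", "effect", "mobility")) {
  key <- match.arg(key)
  col <- switch(key, risk = "aquatic_risk", effect = "effect",
                mobility = "mobility_persistence")
  if (nrow(results) == 0) pdst_validation_error("no results to rank")
  setNames(rank(-results[[col]], ties.method = "average"), results$label)
}

#' Compare two PAIs on both risk axes
#'
#' A PAI dominates when it is no worse on both the effect and the
#' mobility-persistence axis and strictly better on at least one (below and
#' to the left on the risk plot). Otherwise the comparison is a trade-off and
#' the scalar aquatic risk decides which is preferable.
#'
#' @param a,b one-row risk results (rows of a [pdst_compute()] table).
#' @return List with `verdict` (`"a_dominates"`, `"b_dominates"` or
#'   `"tradeoff_use_risk"`) and `preferred` (`"a"`, `"b"` or `"tie"`, the
#'   entry with the smaller aquatic risk).
#' @export
compare_pais <- function(a, b) {
  ae <- a$effect; am <- a$mobility_persistence
  be <- b$effect; bm <- b$mobility_persistence
  verdict <- if (ae <= be && am <= bm && (ae < be || am < bm)) {
    "a_dominates"
  } else if (be <= ae && bm <= am && (be < ae || bm < am)) {
    "b_dominates"
  } else {
    "tradeoff_use_risk"
  }
  ra <- a$aquatic_risk; rb <- b$aquatic_risk
  preferred <- if (ra < rb) "a" else if (rb < ra) "b" else "tie"
  list(verdict = verdict, preferred = preferred,
       risk = c(a = ra, b = rb))
}

#' Fold variation of a set of positive values
#'
#' `max / min`, rounded to a given number of significant figures; used to
#' summarise the spread of measure-of-effect or mobility values within a
#' pesticide class.
#'
#' @param values positive numeric vector.
#' @param sig_figs significant figures for the rounded result.
#' @return Dimensionless fold ratio.
#' @export
fold_variation <- function(values, sig_figs = 2) {
  values <- values[!is.na(values)]
  if (length(values) == 0 || any(values <= 0))
    pdst_validation_error("fold variation needs positive values")
  signif(max(values) / min(values), sig_figs)
}

#' Compute the risk table for a PAI table
#'
#' One row per formulation (rate entry): the annualized AI application rate
#' at the chosen label bound, scaled by the spray regime; the measure of
#' effect against the PAI's threshold; the measure of mobility and
#' persistence from the resolved Koc and half-lives; and the aquatic risk
#' with its report-scale value.
#'
#' @param table a [pai_table()].
#' @param rate_bound `"max"` (default), `"min"` or `"mean"`.
#' @param regime a [spray_regime()] (default broadcast).
#' @param mobility_floor lower clamp for the runoff proportion (default 0).
#' @return Data frame with columns `label`, `name`, `product_name`,
#'   `pesticide_class`, `app_rate_kg_ai_ha`, `app_rate_umol_ha`,
#'   `etv_umol_L`, `effect`, `mobility_persistence`, `aquatic_risk`,
#'   `aquatic_risk_reported`, `rank_by_risk`.
#' @examples
#' risk <- pdst_compute(pdst_reference_data())
#' head(risk[order(risk$rank_by_risk), c("label", "aquatic_risk_reported")])
#' @export
pdst_compute <- function(table, rate_bound = c("max", "min", "mean"),
                         regime = spray_regime("broadcast"),
                         mobility_floor = 0) {
  stopifnot(inherits(table, "pai_table"))
  rate_bound <- match.arg(rate_bound)
  r <- table$rates
  p <- table$properties[match(r$name, table$properties$name), ]
  e <- table$etvs[match(r$name, table$etvs$name), ]
  if (any(is.na(e$limit_umol_L)))
    pdst_integrity_error(sprintf("no threshold for: %s",
      paste(unique(r$name[is.na(e$limit_umol_L)]), collapse = ", ")))

  kg <- ai_mass_rate(r, which = rate_bound)
  umol <- apply_regime(mass_to_molar_rate(kg, p$molar_mass_g_mol), regime)
  effect <- measure_of_effect(umol, e$limit_umol_L)
  prop <- proportion_transported(p$koc_L_kg, floor = mobility_floor)
  mobility <- measure_of_mobility_persistence(p$dt50_soil_days,
                                              p$dt50_water_days, prop)
  risk <- aquatic_risk(effect, mobility)

  multi <- r$name %in% r$name[duplicated(r$name)]
  label <- ifelse(multi, paste0(r$name, " (", r$product_name, ")"), r$name)
  out <- data.frame(label = label, name = r$name,
                    product_name = r$product_name,
                    pesticide_class = p$pesticide_class,
                    app_rate_kg_ai_ha = apply_regime(kg, regime),
                    app_rate_umol_ha = umol, etv_umol_L = e$limit_umol_L,
                    effect = effect, mobility_persistence = mobility,
                    aquatic_risk = risk$risk,
                    aquatic_risk_reported = risk$reported)
  out$rank_by_risk <- rank(-out$aquatic_risk, ties.method = "average")
  out
}

#' Look up risk-table rows by PAI label
#'
#' Exact match on `label` first, then on `name`; unknown names raise a
#' lookup error listing near-matches.
#'
#' @param results risk table from [pdst_compute()].
#' @param name PAI label or name.
#' @return The matching rows of `results`.
#' @export
lookup_pai <- function(results, name) {
  hit <- results[results$label == name, , drop = FALSE]
  if (nrow(hit) == 0) hit <- results[results$name == name, , drop = FALSE]
  if (nrow(hit) == 0) {
    near <- results$label[order(utils::adist(tolower(name),
                                             tolower(results$label)))]
    pdst_error(sprintf("unknown PAI '%s'; nearest matches: %s", name,
                       paste(head(near, 3), collapse = ", ")),
               "pdst_lookup_error")
  }
  hit
}
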