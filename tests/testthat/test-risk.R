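test_that("runoff proportion follows the log Koc line and clamps", {
  expect_equal(proportion_transported(1), 0.39123)
  expect_equal(proportion_transported(1e7), 0)
  expect_equal(proportion_transported(813),
               (39.123 - 10.076 * log10(813)) / 100, tolerance = 1e-12)
  expect_equal(proportion_transported(813), 0.0980, tolerance = 1e-3)
  expect_equal(proportion_transported(1e7, floor = 0.001), 0.001)
  expect_error(proportion_transported(0), class = "pdst_domain_error")
  expect_error(proportion_transported(-3), class = "pdst_domain_error")
  # strictly decreasing on the unclamped range
  koc <- 10^seq(0, 3.8, length.out = 40)
  expect_true(all(diff(proportion_transported(koc)) < 0))
})

test_that("measure of effect is the rate over the threshold in umol/ML", {
  expect_equal(measure_of_effect(0, 0.5), 0)
  # diuron: 1.9 kg/ha label at 90% AI, 233.09 g/mol, threshold 0.0030 umol/L
  rate <- mass_to_molar_rate(1.9 * 0.9, 233.09)
  expect_equal(measure_of_effect(rate, 0.0030), 2478, tolerance = 0.02)
  # ametryn: 2.0 kg AI/ha at 227.33 g/mol, threshold 0.00044 umol/L
  rate2 <- mass_to_molar_rate(2.0, 227.33)
  expect_equal(measure_of_effect(rate2, 0.00044), 20000, tolerance = 0.001)
  expect_error(measure_of_effect(1, 0), class = "pdst_domain_error")
  expect_error(measure_of_effect(-1, 1), class = "pdst_domain_error")
})

test_that("mobility-persistence is the plain triple product", {
  expect_equal(measure_of_mobility_persistence(10, 10, 0.5), 50)
  expect_equal(measure_of_mobility_persistence(123, 456, 0), 0)
  expect_equal(measure_of_mobility_persistence(75.5, 8.8, 0.0980), 65.1,
               tolerance = 1e-3)
  expect_error(measure_of_mobility_persistence(-1, 1, 0.5),
               class = "pdst_domain_error")
  expect_error(measure_of_mobility_persistence(1, 1, 1.5),
               class = "pdst_domain_error")
})

test_that("aquatic risk is the product, reported at risk/100", {
  r <- aquatic_risk(480, 1274)
  expect_equal(r$risk, 611520)
  expect_equal(signif(r$risk, 2), 6.1e5)
  expect_equal(r$reported, 6115.2)
  expect_equal(aquatic_risk(20000, 155)$risk, 3.1e6)
  expect_equal(aquatic_risk(0, 42)$risk, 0)
})

test_that("spray regimes scale the rate (and hence risk) linearly", {
  expect_equal(apply_regime(7, spray_regime("broadcast")), 7)
  expect_equal(apply_regime(10, spray_regime("band", 0.10)), 1)
  expect_equal(apply_regime(10, spray_regime("spot", 0.01)), 0.1)
  # broadcast forces treated_fraction to 1
  expect_equal(spray_regime("broadcast", 0.5)$treated_fraction, 1)
  expect_error(spray_regime("band", 0), class = "pdst_validation_error")
  expect_error(spray_regime("band", 1.1), class = "pdst_validation_error")

  tab <- pdst_reference_data()
  broad <- pdst_compute(tab)
  band <- pdst_compute(tab, regime = spray_regime("band", 0.10))
  expect_equal(band$aquatic_risk, broad$aquatic_risk * 0.10,
               tolerance = 1e-12)
})

test_that("tank mixes sum component risks and are order-invariant", {
  expect_equal(tank_mix_risk(42)$total, 42)
  expect_equal(tank_mix_risk(c(1.5, 2.5))$total, 4)
  expect_equal(tank_mix_risk(c(2.5, 1.5))$total, 4)
  expect_error(tank_mix_risk(numeric(0)), class = "pdst_validation_error")
  expect_equal(tank_mix_risk(1)$label, "indicative")
  # diuron + hexazinone from the reference measures
  ref <- pdst_reference_measures()
  mix <- tank_mix_risk(ref$aquatic_risk[ref$label %in%
                                          c("diuron", "hexazinone")])
  expect_equal(mix$total, 337008 + 611520)
})

test_that("ranking uses descending average ranks with shared ties", {
  d <- data.frame(label = c("a", "b", "c"), aquatic_risk = c(3, 1, 2),
                  effect = c(5, 5, 5), mobility_persistence = c(1, 2, 3))
  expect_equal(rank_pais(d, "risk"), c(a = 1, b = 3, c = 2))
  expect_equal(unname(rank_pais(d, "effect")), c(2, 2, 2))
  expect_equal(rank_pais(d, "mobility"), c(a = 3, b = 2, c = 1))
})

test_that("dominance comparison matches the risk-plot geometry", {
  row <- function(e, m) data.frame(effect = e, mobility_persistence = m,
                                   aquatic_risk = e * m)
  expect_equal(compare_pais(row(10, 10), row(20, 20))$verdict, "a_dominates")
  expect_equal(compare_pais(row(20, 20), row(10, 10))$verdict, "b_dominates")
  cmp <- compare_pais(row(10, 30), row(20, 20))
  expect_equal(cmp$verdict, "tradeoff_use_risk")
  expect_equal(cmp$preferred, "a")  # 300 < 400
  expect_equal(compare_pais(row(5, 5), row(5, 5))$preferred, "tie")
  # whenever a dominates, its aquatic risk cannot exceed b's
  set.seed(19)
  for (i in 1:50) {
    a <- row(runif(1, 0, 100), runif(1, 0, 100))
    b <- row(runif(1, 0, 100), runif(1, 0, 100))
    v <- compare_pais(a, b)
    if (v$verdict == "a_dominates")
      expect_lte(a$aquatic_risk, b$aquatic_risk)
    if (v$verdict == "b_dominates")
      expect_lte(b$aquatic_risk, a$aquatic_risk)
  }
})

test_that("fold variation rounds max/min to significant figures", {
  expect_equal(fold_variation(c(1, 2, 4), 2), 4)
  expect_equal(fold_variation(c(0.04, 85366), 1), 2e6)
  expect_error(fold_variation(numeric(0)), class = "pdst_validation_error")
  expect_error(fold_variation(c(1, -1)), class = "pdst_validation_error")
})

test_that("risk is monotone in its drivers", {
  tab <- make_tiny_table()
  base <- pdst_compute(tab)
  up_rate <- tab
  up_rate$rates$product_rate_max <- tab$rates$product_rate_max * 2
  expect_true(all(pdst_compute(up_rate)$aquatic_risk >=
                  base$aquatic_risk - 1e-12))
  up_etv <- tab
  up_etv$etvs$limit_umol_L <- tab$etvs$limit_umol_L * 10
  expect_true(all(pdst_compute(up_etv)$effect < base$effect))
  up_soil <- tab
  up_soil$properties$dt50_soil_days <- tab$properties$dt50_soil_days * 3
  cmp <- pdst_compute(up_soil)$mobility_persistence
  mobile <- base$mobility_persistence > 0
  expect_true(all(cmp[mobile] > base$mobility_persistence[mobile]))
})

test_that("risk table carries the exact composition identity", {
  risk <- pdst_compute(pdst_reference_data())
  expect_equal(risk$aquatic_risk,
               risk$effect * risk$mobility_persistence, tolerance = 0)
  expect_equal(risk$aquatic_risk_reported, risk$aquatic_risk / 100,
               tolerance = 0)
})

test_that("the engine reproduces the stored reference measures", {
  risk <- pdst_compute(pdst_reference_data())
  ref <- pdst_reference_measures()
  m <- merge(risk, ref, by = "label", suffixes = c("", "_ref"))
  expect_equal(nrow(m), 48)
  expect_equal(m$effect, m$effect_max, tolerance = 1e-5)
  # the six strongly sorbed PAIs (stored mobility ~0.01) clamp to zero under
  # the default proportion floor; the other 42 rows are recomputed
  mobile <- m$mobility_persistence_ref != 0.01
  expect_equal(sum(!mobile), 6)
  expect_equal(m$mobility_persistence[mobile],
               m$mobility_persistence_ref[mobile], tolerance = 1e-5)
  expect_true(all(m$mobility_persistence[!mobile] == 0))
})

test_that("lookup finds labels and suggests near-matches", {
  risk <- pdst_compute(pdst_reference_data())
  expect_equal(nrow(lookup_pai(risk, "diuron")), 1)
  expect_equal(nrow(lookup_pai(risk, "imidacloprid")), 2)
  err <- tryCatch(lookup_pai(risk, "diruon"), condition = function(c) c)
  expect_s3_class(err, "pdst_lookup_error")
  expect_match(conditionMessage(err), "diuron")
})
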