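test_that("equivalent annual cost matches annuity arithmetic", {
  # 1295.05/yr discounted 10 years at 5% sums back to the 10000 principal
  eac <- annualize_equivalent_cost(10000, 10, 0.05)
  expect_equal(eac, 1295.05, tolerance = 1e-5)
  expect_equal(sum(eac / (1.05)^(1:10)), 10000, tolerance = 1e-9)

  expect_equal(annualize_equivalent_cost(5000, 8, 0), 5000 / 8)
  expect_equal(annualize_equivalent_cost(1000, 1, 0.05), 1050)
  expect_error(annualize_equivalent_cost(1000, 0, 0.05), "lifespan")

  # monotone: increasing in cost and rate, decreasing in lifespan
  expect_gt(annualize_equivalent_cost(2000, 10, 0.05),
            annualize_equivalent_cost(1000, 10, 0.05))
  expect_gt(annualize_equivalent_cost(1000, 10, 0.08),
            annualize_equivalent_cost(1000, 10, 0.05))
  expect_lt(annualize_equivalent_cost(1000, 15, 0.05),
            annualize_equivalent_cost(1000, 10, 0.05))
})

test_that("survey summary reproduces the published machinery totals", {
  means <- load_rice_budget_means()
  survey <- survey_from_means(means)
  s <- summarize_survey(survey)
  expect_equal(s$machinery_cost_total[["mechanized"]],
               2267.90 + 2312.50, tolerance = 1e-9)  # 4580.40
  expect_equal(s$machinery_cost_total[["non_mechanized"]],
               1794.70 + 2147.73, tolerance = 1e-9)  # 3942.43
  # overall column of a 2+2 fixture is the mean of the two arm means
  expect_equal(s$machinery_cost_total[["overall"]],
               (4580.40 + 3942.43) / 2, tolerance = 1e-9)
  # every overall mean lies between the subsample means
  with(s$means, expect_true(all(
    overall >= pmin(non_mechanized, mechanized) - 1e-9 &
    overall <= pmax(non_mechanized, mechanized) + 1e-9)))

  # single record duplicated into both arms: all means equal that record
  vars <- means$variable
  single <- survey_from_means(means, n_base = 1L, n_mech = 1L)
  single[2, vars] <- single[1, vars]
  s1 <- summarize_survey(single)
  expect_equal(s1$means$non_mechanized, s1$means$mechanized)

  expect_error(summarize_survey(survey[survey$mechanized, ]),
               "non-mechanized")
})

test_that("technology effects equal the printed percentage differences", {
  s <- summarize_survey(survey_from_means(load_rice_budget_means()))
  eff <- tech_effects(s)
  expect_equal(eff$yield_pct, (8085.23 - 7943.18) / 7943.18 * 100,
               tolerance = 1e-9)   # +1.788
  expect_equal(eff$pesticide_pct, (17.87 - 18.75) / 18.75 * 100,
               tolerance = 1e-9)   # -4.693
  expect_equal(eff$labor_pct, (13.37 - 14.83) / 14.83 * 100,
               tolerance = 1e-9)   # -9.845
  expect_equal(eff$machinery_cost_pct,
               (4580.40 - 3942.43) / 3942.43 * 100, tolerance = 1e-9)

  # identical arms give zero effects (and the "unexpected sign" warning
  # stays silent for an exactly-zero difference)
  means <- load_rice_budget_means()
  means$mechanized <- means$non_mechanized
  eff0 <- tech_effects(summarize_survey(survey_from_means(means)))
  expect_equal(unlist(eff0), c(yield_pct = 0, pesticide_pct = 0,
                               labor_pct = 0, machinery_cost_pct = 0))
})

test_that("tech budgets scale the four channels and keep base rows intact", {
  b <- generate_instance(small_config(include_mechanized = FALSE), seed = 9)
  base <- b$budgets
  eff <- list(yield_pct = 1.788, pesticide_pct = -4.693,
              labor_pct = -9.845, machinery_cost_pct = 16.182)

  out <- build_tech_budgets(base, eff, scope = "rice_only",
                            rice_crop = "rice")
  mech <- out[out$tech == "mechanized", ]
  expect_equal(unique(mech$crop), "rice")
  expect_equal(nrow(mech), sum(base$crop == "rice"))
  expect_equal(out[out$tech == "base", ], base, ignore_attr = TRUE)

  rice_base <- base[base$crop == "rice", ][1, ]
  rice_mech <- mech[mech$district == rice_base$district, ]
  expect_equal(rice_mech$yield_kg_per_ha,
               rice_base$yield_kg_per_ha * 1.01788)
  expect_equal(rice_mech$pesticide_kg_per_ha,
               rice_base$pesticide_kg_per_ha * (1 - 0.04693))
  expect_equal(rice_mech$fertilizer_kg_per_ha,
               rice_base$fertilizer_kg_per_ha)   # copied, not scaled

  # the worked numeric example: 8000 kg/ha at +1.788% -> 8143.04
  one <- base[1, ]; one$yield_kg_per_ha <- 8000; one$crop <- "rice"
  out1 <- build_tech_budgets(one, eff, scope = "rice_only")
  expect_equal(out1$yield_kg_per_ha[out1$tech == "mechanized"], 8143.04)

  all_out <- build_tech_budgets(base, eff, scope = "all_crops")
  expect_equal(nrow(all_out), 2L * nrow(base))

  zero <- list(yield_pct = 0, pesticide_pct = 0, labor_pct = 0,
               machinery_cost_pct = 0)
  z <- build_tech_budgets(base, zero, scope = "all_crops")
  zm <- z[z$tech == "mechanized", ]
  zm$tech <- "base"
  expect_equal(zm, base[, names(zm)], ignore_attr = TRUE)

  no_rice <- base[base$crop != "rice", ]
  expect_error(build_tech_budgets(no_rice, eff, scope = "rice_only"),
               "no crop")
})

test_that("injected generator effects are recovered from a large survey", {
  cfg <- generator_config(n_total = 200000L, n_mechanized = 100000L)
  survey <- generate_survey(cfg, seed = 42)
  expect_equal(nrow(survey), 200000L)
  eff <- tech_effects(summarize_survey(survey))
  expect_equal(eff$yield_pct, 1.788, tolerance = 0.1 / 1.788)   # +-0.1 pp
  expect_lt(abs(eff$pesticide_pct - (-4.693)), 0.1)
  expect_lt(abs(eff$labor_pct - (-9.845)), 0.1)
  expect_lt(abs(eff$machinery_cost_pct - 16.182), 0.15)

  # null case: zero injected effects stay within the noise band around 0
  cfg0 <- generator_config(n_total = 200000L, n_mechanized = 100000L,
                           effects = c(yield_pct = 0, pesticide_pct = 0,
                                       labor_pct = 0, machinery_pct = 0,
                                       fertilizer_pct = 0, wage_pct = 0))
  eff0 <- suppressWarnings(
    tech_effects(summarize_survey(generate_survey(cfg0, seed = 7))))
  expect_true(all(abs(unlist(eff0)) < 0.15))
})
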