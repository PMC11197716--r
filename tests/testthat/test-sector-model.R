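# The two-crop oracle instance (see helper-fixtures.R) has a hand-derived
# interior optimum; brute_force_solve provides the independent grid-search
# route on the same instance.

test_that("baseline pesticide usage is the acreage-weighted rate sum", {
  # one district: 100 ha at 10 kg/ha + 50 ha at 2 kg/ha -> 1.1 t
  b <- two_crop_bundle()
  b$observed_district$acreage_ha <- c(100, 50)
  u <- baseline_pesticide_usage(b)
  expect_equal(u$region_total_t, 1.1)
  expect_equal(as.numeric(u$pesticide_t["d1"]), 1.1)

  b$observed_district$acreage_ha <- c(0, 0)
  expect_equal(baseline_pesticide_usage(b)$region_total_t, 0)

  # conservation on a multi-district bundle
  b9 <- generate_instance(small_config(), seed = 5)
  u9 <- baseline_pesticide_usage(b9)
  expect_equal(u9$region_total_t, sum(u9$pesticide_t), tolerance = 1e-9)

  # apportioning by historical shares when district detail is absent
  b9$observed_district <- NULL
  u9b <- baseline_pesticide_usage(b9)
  expect_equal(u9b$region_total_t, u9$region_total_t, tolerance = 1e-6)

  b_miss <- two_crop_bundle()
  b_miss$budgets <- b_miss$budgets[-1, ]
  expect_error(baseline_pesticide_usage(b_miss), "missing base budget")
})

test_that("problem assembly has the stated cap-row structure", {
  b <- generate_instance(small_config(), seed = 8)
  nd <- nrow(b$districts)
  pd <- assemble_problem(b, scenario_spec(0.20, "TechB", "district",
                                          "P_free"))
  expect_equal(sum(pd$row_meta$type == "pesticide_cap"), nd)
  pr <- assemble_problem(b, scenario_spec(0.20, "TechB", "region", "P_free"))
  expect_equal(sum(pr$row_meta$type == "pesticide_cap"), 1L)

  # two-crop instance: 2 acreage + 2 sales variables, cap slack at r = 0
  p0 <- assemble_problem(two_crop_bundle(), scenario_spec(0, "TechB",
                                                          "region",
                                                          "P_free"))
  expect_equal(sum(p0$var_meta$kind == "Q"), 2L)
  expect_equal(sum(p0$var_meta$kind == "Y"), 2L)
  s0 <- solve_problem(p0)
  expect_gt(min(s0$cap_slack_kg), -1e-6)

  # tech restriction errors
  b_nomech <- generate_instance(small_config(include_mechanized = FALSE),
                                seed = 8)
  expect_error(assemble_problem(b_nomech, scenario_spec(0, "TechR", "region",
                                                        "P_free")),
               "TechR")
  expect_error(assemble_problem(b_nomech, scenario_spec(0, "TechA", "region",
                                                        "P_free")),
               "TechA")
})

test_that("solver recovers the hand-derived two-crop optimum", {
  b <- two_crop_bundle()
  sol <- solve_problem(assemble_problem(
    b, scenario_spec(0, "TechB", "region", "P_free")))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$acreage$area_ha,
               as.numeric(TWO_CROP_EXPECTED$acreage), tolerance = 1e-4)
  expect_equal(as.numeric(sol$land_rent_yuan_per_ha),
               TWO_CROP_EXPECTED$land_rent, tolerance = 1e-4)
  expect_equal(sol$welfare$total, TWO_CROP_EXPECTED$welfare,
               tolerance = 1e-6)
  expect_equal(sol$welfare$consumer_surplus,
               TWO_CROP_EXPECTED$consumer_surplus, tolerance = 1e-4)
  # welfare equals the solver objective
  expect_equal(sol$welfare$total, sol$objective,
               tolerance = 1e-6 * abs(sol$objective))
  # duals from the quadprog cross-check backend agree
  sol2 <- solve_problem(assemble_problem(
    b, scenario_spec(0, "TechB", "region", "P_free")), backend = "quadprog")
  expect_equal(sol2$acreage$area_ha, sol$acreage$area_ha, tolerance = 1e-4)
})

test_that("a binding cap shifts acreage to the low-pesticide crop", {
  b <- two_crop_bundle()   # baseline 706.67 kg at rates (10, 2)
  spec <- scenario_spec(0.20, "TechB", "region", "P_free")
  sol <- solve_problem(assemble_problem(b, spec))
  free <- solve_problem(assemble_problem(
    b, scenario_spec(0, "TechB", "region", "P_free")))
  # acreage moves from crop a (10 kg/ha) to crop b (2 kg/ha)
  expect_lt(sol$acreage$area_ha[1], free$acreage$area_ha[1])
  expect_gt(sol$acreage$area_ha[2], free$acreage$area_ha[2])
  # cap binds with a positive shadow price and complementary slackness
  expect_lt(abs(sol$cap_slack_kg), 1e-4)
  expect_gt(sol$pesticide_shadow_yuan_per_kg, 0)
  # use equals (1 - r) x baseline
  expect_equal(sum(sol$pesticide_use_t) * 1000,
               0.8 * TWO_CROP_EXPECTED$baseline_pesticide_kg,
               tolerance = 1e-6)
})

test_that("brute-force oracle and solver agree on small instances", {
  b <- two_crop_bundle()
  # under P_fixed the calibrated prices give both crops equal margins (the
  # equilibrium condition), a flat optimal face; perturb the fixed prices so
  # the linear programs below have unique vertices worth comparing on
  bp <- two_crop_bundle()
  bp$demand$p0_yuan_per_kg <- c(1.5, 2.0)
  cases <- list(
    list(b, scenario_spec(0, "TechB", "region", "P_free")),
    list(b, scenario_spec(0.20, "TechB", "region", "P_free")),
    list(b, scenario_spec(0.20, "TechB", "district", "P_free")),
    list(bp, scenario_spec(0.10, "TechB", "region", "P_fixed")))
  for (case in cases) {
    bundle <- case[[1]]; spec <- case[[2]]
    sol <- solve_problem(assemble_problem(bundle, spec))
    bf <- brute_force_solve(bundle, spec, grid_step_ha = 0.01)
    expect_equal(bf$acreage$area_ha, sol$acreage$area_ha, tolerance = 0.02,
                 label = paste("acreage", spec$id))
    expect_equal(bf$welfare, sol$welfare$total,
                 tolerance = 1e-3 * max(1, abs(sol$welfare$total)),
                 label = paste("welfare", spec$id))
  }

  # oracle refinement: a finer step never lowers the reported welfare
  spec <- scenario_spec(0.20, "TechB", "region", "P_free")
  coarse <- brute_force_solve(b, spec, grid_step_ha = 0.5)
  fine <- brute_force_solve(b, spec, grid_step_ha = 0.01)
  expect_gte(fine$welfare, coarse$welfare - 1e-9)

  # capped grid points are rejected: reported use satisfies the cap
  expect_lte(sum(fine$pesticide_use_t) * 1000,
             0.8 * TWO_CROP_EXPECTED$baseline_pesticide_kg + 1e-6)

  expect_error(
    brute_force_solve(generate_instance(small_config(), seed = 1), spec),
    "more than 3|crop-mix")
})

test_that("fixed-price closure yields the corner allocation", {
  # uniform pesticide rates so the zero-reduction cap (= baseline usage)
  # does not cut the corner; fixed prices perturbed off the equilibrium
  # (where margins tie by construction) to make the corner unique
  b <- two_crop_bundle(pesticide_rates = c(2, 2))
  b$demand$p0_yuan_per_kg <- c(1.5, 2.0)
  spec <- scenario_spec(0, "TechB", "region", "P_fixed")
  sol <- solve_problem(assemble_problem(b, spec))
  # margins: a: 10*1500 - 1000 = 14000 > b: 5*2000 - 500 = 9500 -> all to a
  expect_equal(sol$acreage$area_ha, c(100, 0), tolerance = 1e-3)
  expect_equal(sol$welfare$consumer_surplus, 0)
  expect_equal(sol$welfare$total, sol$welfare$producer_surplus)
  expect_equal(sol$welfare$total, 100 * 14000, tolerance = 1e-6)
  bf <- brute_force_solve(b, spec, grid_step_ha = 0.01)
  expect_equal(bf$welfare, sol$welfare$total, tolerance = 1e-3)

  # degenerate-slope case: prices fixed at the intercepts, all land to the
  # higher-margin crop
  b0 <- two_crop_bundle(pesticide_rates = c(2, 2))
  b0$demand$slope_b <- 0
  b0$demand$intercept_a <- c(2000, 3000)
  sol0 <- solve_problem(assemble_problem(
    b0, scenario_spec(0, "TechB", "region", "P_free")))
  # margins: 10*2000 - 1000 = 19000 vs 5*3000 - 500 = 14500 -> all to a
  expect_equal(sol0$acreage$area_ha, c(100, 0), tolerance = 1e-3)
})

test_that("zero production is feasible and never reported infeasible", {
  # extreme reduction with tiny caps still solves (production shrinks)
  b <- two_crop_bundle()
  spec <- scenario_spec(0.30, "TechB", "district", "P_free")
  sol <- solve_problem(assemble_problem(b, spec))
  expect_equal(sol$status, "optimal")
  expect_lte(sum(sol$pesticide_use_t) * 1000,
             0.7 * TWO_CROP_EXPECTED$baseline_pesticide_kg * (1 + 1e-6))
})

test_that("welfare components are internally consistent", {
  b <- generate_instance(small_config(), seed = 4)
  sol <- solve_problem(assemble_problem(
    b, scenario_spec(0.15, "TechA", "region", "P_free")))
  w <- welfare(sol)
  expect_equal(w$total,
               w$gross_consumer_benefit - w$input_cost - w$activity_cost,
               tolerance = 1e-9 * abs(w$total))
  expect_equal(w$total, w$consumer_surplus + w$producer_surplus,
               tolerance = 1e-9 * abs(w$total))
  expect_equal(w$total, sol$objective, tolerance = 1e-6 * abs(w$total))
})
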