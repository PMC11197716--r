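# Shared fixtures, all built in code.

# Hand-constructed single-district two-crop oracle instance. Interior
# optimum derived from the equal-marginal-net-revenue condition:
#   crop A: 10 t/ha yield, 1000 yuan/ha cost, P_A(y) = 2000 - 1 y
#   crop B:  5 t/ha yield,  500 yuan/ha cost, P_B(y) = 3000 - 2 y
#   100 ha of land, all planted at the optimum:
#   19000 - 100 qA = 9500 + 50 qA  =>  qA = 190/3, qB = 110/3 ha,
#   land rent 38000/3 yuan/ha, welfare 1500833.33..., consumer surplus
#   200555.56 + 33611.11 = 234166.67 yuan.
two_crop_bundle <- function(pesticide_rates = c(10, 2),
                            pesticide_price = 0,
                            monetary_scale = 1) {
  s <- monetary_scale
  crops <- data.frame(id = c("a", "b"), name = c("Crop A", "Crop B"),
                      category = c("grain", "leafy_vegetable"),
                      stringsAsFactors = FALSE)
  districts <- data.frame(id = "d1", name = "District 1", land_ha = 100,
                          stringsAsFactors = FALSE)
  budgets <- data.frame(
    district = "d1", crop = c("a", "b"), tech = "base",
    yield_kg_per_ha = c(10000, 5000),
    pesticide_kg_per_ha = pesticide_rates,
    fertilizer_kg_per_ha = 0, labor_pm_per_ha = 0,
    machinery_cost_yuan_per_ha = 0,
    other_cost_yuan_per_ha = c(1000, 500) * s,
    stringsAsFactors = FALSE)
  # demand constructed so (a, b) = (2000, 1) and (3000, 2) scaled by s:
  # q0/p0/elasticity chosen consistent with those coefficients
  qA <- 190 / 3; qB <- 110 / 3
  YA <- 10 * qA; YB <- 5 * qB
  pA <- 2000 * s - 1 * s * YA; pB <- 3000 * s - 2 * s * YB
  demand <- data.frame(
    crop = c("a", "b"),
    p0_yuan_per_kg = c(pA, pB) / 1000,
    q0_t = c(YA, YB),
    elasticity = c(-pA / (1 * s * YA), -pB / (2 * s * YB)),
    intercept_a = c(2000, 3000) * s, slope_b = c(1, 2) * s,
    stringsAsFactors = FALSE)
  observed_district <- data.frame(district = "d1", crop = c("a", "b"),
                                  acreage_ha = c(qA, qB),
                                  stringsAsFactors = FALSE)
  observed <- data.frame(crop = c("a", "b"), acreage_ha = c(qA, qB),
                         production_t = c(YA, YB),
                         price_yuan_per_kg = c(pA, pB) / 1000,
                         stringsAsFactors = FALSE)
  hist <- data.frame(district = "d1", year = "y1", crop = c("a", "b"),
                     area_ha = c(qA, qB), stringsAsFactors = FALSE)
  ip <- data.frame(input_id = c("pesticide", "fertilizer", "labor"),
                   price = c(pesticide_price, 0, 0),
                   stringsAsFactors = FALSE)
  new_bundle(crops, districts, budgets, ip, demand, hist, observed,
             observed_district = observed_district,
             settings = default_settings(mix_constraint = FALSE))
}

TWO_CROP_EXPECTED <- list(
  acreage = c(a = 190 / 3, b = 110 / 3),
  land_rent = 38000 / 3,
  welfare = 18010000 / 12,      # 1500833.333...
  consumer_surplus = 2810000 / 12,  # 234166.667...
  baseline_pesticide_kg = 10 * 190 / 3 + 2 * 110 / 3)  # 706.67

# survey whose subsample means equal the published citywide rice-budget
# means exactly: two records per arm at mean +- 1% of the mean
survey_from_means <- function(means_df, n_base = 2L, n_mech = 2L) {
  mk_arm <- function(colname, n, mech) {
    rows <- lapply(seq_len(n), function(i) {
      dev <- if (n == 1) 0 else 0.01 * (2 * (i - 1) / (n - 1) - 1)
      vals <- means_df[[colname]] * (1 + dev)
      rec <- as.list(vals)
      names(rec) <- means_df$variable
      c(list(district = "d1", mechanized = mech), rec)
    })
    do.call(rbind, lapply(rows, as.data.frame))
  }
  out <- rbind(mk_arm("non_mechanized", n_base, FALSE),
               mk_arm("mechanized", n_mech, TRUE))
  out$mechanized <- as.logical(out$mechanized)
  out
}

load_rice_budget_means <- function() {
  read.csv(system.file("extdata", "shanghai_rice_budget_means.csv",
                       package = "pasm"), stringsAsFactors = FALSE)
}

load_validation_fixture <- function(which = c("pfixed", "pfree")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("shanghai_validation_%s.csv", which),
                   package = "pasm")
  read.csv(f, stringsAsFactors = FALSE)
}

# small, fast generator configuration for property sweeps
small_config <- function(...) {
  generator_config(n_districts = 3L, n_crops = 5L, land_mean_ha = 4000,
                   n_total = 60L, n_mechanized = 32L, ...)
}
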