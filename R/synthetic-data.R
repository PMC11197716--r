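# Synthetic model-input bundles emulating the structure of the deposited
# regional dataset: 9 districts x 15 crops, budgets whose pesticide rates
# are substantially higher for horticultural than for field crops, negative
# own-price elasticities, several historical crop-mix years, and a paired
# two-subsample technology survey. Everything is deterministic under a seed.

SHANGHAI_CROPS <- data.frame(
  id = c("rice", "wheat", "barley", "melon", "rapeseed", "strawberry",
         "fruit", "leafy", "pekinensis", "cabbage", "root", "cucurbit",
         "beans", "solanaceae", "allium"),
  name = c("Rice", "Wheat", "Barley", "Melon", "Rapeseed", "Strawberry",
           "Fruit", "Leafy greens", "Pekinensis", "Cabbage", "Root",
           "Cucurbit", "Beans", "Solanaceae", "Allium"),
  category = c("grain", "grain", "grain", "fruit", "oilseed", "fruit",
               "fruit", "leafy_vegetable", "other_vegetable",
               "other_vegetable", "other_vegetable", "other_vegetable",
               "other_vegetable", "other_vegetable", "other_vegetable"),
  stringsAsFactors = FALSE)

SHANGHAI_DISTRICTS <- c("chongming", "qingpu", "jinshan", "fengxian",
                        "pudongnew", "songjiang", "jiading", "baoshan",
                        "minhang")

#' Configuration for the synthetic-data generators
#'
#' Defaults state the emulated world once: the nine-district / fifteen-crop
#' regional layout, right-skewed positive agronomic quantities (log-normal
#' yields with district multipliers, gamma pesticide rates), a horticulture
#' to grain pesticide-rate ratio of 5 (the lower end of the 5-10x
#' agrochemical-intensity contrast between horticultural and field crops),
#' own-price elasticities uniform in [-1.2, -0.2], three historical mix
#' years, and a 532-farm survey split 251 non-mechanized / 281 mechanized
#' with technology effects matching the citywide rice budget differences
#' (+1.788% yield, -4.693% pesticide, -9.845% labor, +16.182% machinery
#' cost).
#'
#' @param ... named overrides of any default listed below.
#' @return object of class `pasm_generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_districts = 9L,
    n_crops = 15L,
    category_shares = c(grain = 0.2, leafy_vegetable = 0.1,
                        other_vegetable = 0.4, fruit = 0.2, oilseed = 0.1),
    land_mean_ha = 35000, land_cv = 0.4,
    crop_use_frac = 0.85,
    yield_mean = c(grain = 7000, leafy_vegetable = 26000,
                   other_vegetable = 28000, fruit = 18000, oilseed = 2400),
    yield_cv = 0.15,
    district_multiplier_cv = 0.10,
    pesticide_grain_mean = 5,
    pesticide_hort_ratio = 5,
    pesticide_cv = 0.30,
    fertilizer_mean = c(grain = 1000, leafy_vegetable = 650,
                        other_vegetable = 600, fruit = 500, oilseed = 400),
    fertilizer_cv = 0.20,
    labor_mean = c(grain = 14, leafy_vegetable = 22, other_vegetable = 25,
                   fruit = 30, oilseed = 8),
    labor_cv = 0.20,
    machinery_mean = c(grain = 4000, leafy_vegetable = 1500,
                       other_vegetable = 1500, fruit = 1200, oilseed = 2500),
    machinery_cv = 0.20,
    other_cost_mean = 2500, other_cost_cv = 0.20,
    price_mean = c(grain = 3.0, leafy_vegetable = 2.5, other_vegetable = 4.0,
                   fruit = 8.0, oilseed = 5.5),
    price_cv = 0.10,
    input_prices = c(pesticide = 80, fertilizer = 3, labor = 1200),
    elasticity_range = c(-1.2, -0.2),
    n_mix_years = 3L, mix_perturb_cv = 0.10,
    mix_delta = 0.15,
    acreage_weight = c(grain = 0.45, leafy_vegetable = 0.20,
                       other_vegetable = 0.22, fruit = 0.08, oilseed = 0.05),
    n_total = 532L, n_mechanized = 281L,
    survey_base_means = c(
      yield_kg_per_ha = 7943.18, fertilizer_kg_per_ha = 1009.09,
      pesticide_kg_per_ha = 18.75, labor_wage_yuan_per_pm = 1863.64,
      labor_pm_per_ha = 14.83,
      machinery_purchase_cost_annualized_yuan_per_ha = 1794.70,
      machinery_rent_yuan_per_ha = 2147.73),
    effects = c(yield_pct = 1.788, pesticide_pct = -4.693,
                labor_pct = -9.845, machinery_pct = 16.182,
                fertilizer_pct = -1.352, wage_pct = 3.252),
    survey_cv = 0.08,
    include_mechanized = TRUE,
    seed = 42L
  )
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(cfg$n_districts >= 1, cfg$n_crops >= 1)
  if (cfg$n_mechanized > cfg$n_total) {
    stop("n_mechanized must not exceed n_total")
  }
  if (any(cfg$elasticity_range >= 0)) {
    stop("elasticity_range must lie strictly below zero")
  }
  if (cfg$crop_use_frac > 1) {
    stop("infeasible config: crop_use_frac > 1 puts mix acreage above land")
  }
  cvs <- c(cfg$land_cv, cfg$yield_cv, cfg$pesticide_cv, cfg$fertilizer_cv,
           cfg$labor_cv, cfg$machinery_cv, cfg$other_cost_cv, cfg$price_cv,
           cfg$mix_perturb_cv, cfg$survey_cv, cfg$district_multiplier_cv)
  stopifnot(all(cvs >= 0))
  structure(cfg, class = "pasm_generator_config")
}

# log-normal draw with arithmetic mean `mean` and coefficient of variation
.rlnorm_mean <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

# gamma draw with given mean and coefficient of variation (right-skewed,
# positive support: the natural shape for per-hectare application rates)
.rgamma_mean <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

.make_crops <- function(cfg) {
  if (cfg$n_crops == 15L) return(SHANGHAI_CROPS)
  shares <- cfg$category_shares[CROP_CATEGORIES]
  counts <- round(shares / sum(shares) * cfg$n_crops)
  counts["grain"] <- max(1L, counts["grain"])
  while (sum(counts) > cfg$n_crops) {
    i <- which.max(counts * (names(counts) != "grain" | counts > 1))
    counts[i] <- counts[i] - 1L
  }
  while (sum(counts) < cfg$n_crops) {
    i <- which.max(shares - counts / cfg$n_crops)
    counts[i] <- counts[i] + 1L
  }
  cats <- rep(names(counts), counts)
  ids <- sprintf("crop%02d", seq_len(cfg$n_crops))
  ids[which(cats == "grain")[1]] <- "rice"
  data.frame(id = ids, name = toupper(ids), category = cats,
             stringsAsFactors = FALSE)
}

.make_districts <- function(cfg) {
  ids <- if (cfg$n_districts == 9L) SHANGHAI_DISTRICTS else
    sprintf("district%02d", seq_len(cfg$n_districts))
  data.frame(id = ids, name = tools::toTitleCase(ids),
             land_ha = .rlnorm_mean(cfg$n_districts, cfg$land_mean_ha,
                                    cfg$land_cv),
             stringsAsFactors = FALSE)
}

.pesticide_mean_by_category <- function(cfg) {
  g <- cfg$pesticide_grain_mean
  c(grain = g, oilseed = g,
    leafy_vegetable = g * cfg$pesticide_hort_ratio,
    other_vegetable = g * cfg$pesticide_hort_ratio,
    fruit = g * cfg$pesticide_hort_ratio)
}

#' Generate a complete synthetic model input bundle
#'
#' Produces a bundle that passes [validate_bundle()] and yields a feasible,
#' bounded baseline problem: district land endowments; per-(district, crop)
#' base budgets (log-normal yields around category means with district
#' multipliers, gamma input rates with horticultural pesticide rates a
#' configured multiple of grain rates); a base-year observed acreage /
#' production / price table; demand specs calibrated to that observed
#' baseline; historical mixes containing the base mix plus perturbed copies
#' rescaled to the land endowments; and (by default) mechanized budget
#' variants built from a synthetic technology survey via the budget engine.
#'
#' @param config a `pasm_generator_config`.
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @return a `pasm_bundle`.
#' @export
generate_instance <- function(config = generator_config(),
                              seed = config$seed) {
  cfg <- config
  stopifnot(inherits(cfg, "pasm_generator_config"))
  set.seed(seed)
  crops <- .make_crops(cfg)
  districts <- .make_districts(cfg)
  nd <- nrow(districts); nc <- nrow(crops)
  cat_of <- stats::setNames(crops$category, crops$id)
  dmult <- .rlnorm_mean(nd, 1, cfg$district_multiplier_cv)
  pest_mean <- .pesticide_mean_by_category(cfg)

  grid <- expand.grid(district = districts$id, crop = crops$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$district, districts$id),
                     match(grid$crop, crops$id)), ]
  rownames(grid) <- NULL
  cat_g <- cat_of[grid$crop]
  mult_g <- dmult[match(grid$district, districts$id)]
  budgets <- data.frame(
    district = grid$district, crop = grid$crop, tech = "base",
    yield_kg_per_ha = .rlnorm_mean(nrow(grid),
                                   cfg$yield_mean[cat_g] * mult_g,
                                   cfg$yield_cv),
    pesticide_kg_per_ha = .rgamma_mean(nrow(grid), pest_mean[cat_g],
                                       cfg$pesticide_cv),
    fertilizer_kg_per_ha = .rgamma_mean(nrow(grid), cfg$fertilizer_mean[cat_g],
                                        cfg$fertilizer_cv),
    labor_pm_per_ha = .rgamma_mean(nrow(grid), cfg$labor_mean[cat_g],
                                   cfg$labor_cv),
    machinery_cost_yuan_per_ha = .rgamma_mean(nrow(grid),
                                              cfg$machinery_mean[cat_g],
                                              cfg$machinery_cv),
    other_cost_yuan_per_ha = .rgamma_mean(nrow(grid), cfg$other_cost_mean,
                                          cfg$other_cost_cv),
    stringsAsFactors = FALSE)

  # base-year mix: dirichlet-style crop shares weighted by category
  w <- cfg$acreage_weight[cat_of[crops$id]] /
    pmax(1, table(cat_of)[cat_of[crops$id]])
  base_mix <- do.call(rbind, lapply(seq_len(nd), function(d) {
    draw <- stats::rgamma(nc, shape = 4 * as.numeric(w) /
                            mean(as.numeric(w)), rate = 1)
    share <- draw / sum(draw)
    data.frame(district = districts$id[d], crop = crops$id,
               acreage_ha = share * districts$land_ha[d] * cfg$crop_use_frac,
               stringsAsFactors = FALSE)
  }))
  rownames(base_mix) <- NULL

  # observed baseline from the base mix and base budgets
  bb <- merge(base_mix, budgets[, c("district", "crop", "yield_kg_per_ha")],
              by = c("district", "crop"))
  prod_by_crop <- stats::aggregate(
    cbind(production_t = acreage_ha * yield_kg_per_ha / 1000) ~ crop, bb, sum)
  acr_by_crop <- stats::aggregate(acreage_ha ~ crop, base_mix, sum)
  price0 <- .rlnorm_mean(nc, cfg$price_mean[cat_of[crops$id]], cfg$price_cv)
  observed <- data.frame(
    crop = crops$id,
    acreage_ha = acr_by_crop$acreage_ha[match(crops$id, acr_by_crop$crop)],
    production_t = prod_by_crop$production_t[
      match(crops$id, prod_by_crop$crop)],
    price_yuan_per_kg = price0,
    stringsAsFactors = FALSE)

  demand <- data.frame(
    crop = crops$id,
    p0_yuan_per_kg = observed$price_yuan_per_kg,
    q0_t = observed$production_t,
    elasticity = stats::runif(nc, cfg$elasticity_range[1],
                              cfg$elasticity_range[2]),
    stringsAsFactors = FALSE)

  # historical mixes: the base year plus perturbed, land-rescaled copies
  mixes <- lapply(seq_len(cfg$n_mix_years), function(y) {
    m <- base_mix
    if (y > 1) {
      m$acreage_ha <- m$acreage_ha *
        .rlnorm_mean(nrow(m), 1, cfg$mix_perturb_cv)
      tot <- stats::aggregate(acreage_ha ~ district, m, sum)
      cap <- districts$land_ha[match(tot$district, districts$id)]
      scl <- pmin(1, cap / tot$acreage_ha)
      m$acreage_ha <- m$acreage_ha * scl[match(m$district, tot$district)]
    }
    data.frame(district = m$district, year = sprintf("y%d", y),
               crop = m$crop, area_ha = m$acreage_ha,
               stringsAsFactors = FALSE)
  })
  historical_mix <- do.call(rbind, mixes)

  input_prices <- data.frame(input_id = names(cfg$input_prices),
                             price = as.numeric(cfg$input_prices),
                             stringsAsFactors = FALSE)

  if (cfg$include_mechanized) {
    survey <- generate_survey(cfg, seed = seed + 1L)
    eff <- suppressWarnings(tech_effects(summarize_survey(survey)))
    rice_id <- if ("rice" %in% crops$id) "rice" else crops$id[1]
    budgets <- build_tech_budgets(budgets, eff, scope = "all_crops",
                                  rice_crop = rice_id)
  }

  settings <- default_settings(
    mix_delta = cfg$mix_delta,
    rice_crop = if ("rice" %in% crops$id) "rice" else crops$id[1])
  new_bundle(crops, districts, budgets, input_prices, demand, historical_mix,
             observed, observed_district = base_mix, settings = settings)
}

#' Generate a synthetic paired technology survey
#'
#' `n_total` farm records split into the configured non-mechanized /
#' mechanized subsamples. Mechanized-arm expected values equal the
#' non-mechanized means scaled by the injected percentage effects; each
#' field carries independent multiplicative log-normal noise, so the
#' subsample means recover the injected effects up to sampling error.
#'
#' @param config a `pasm_generator_config`.
#' @param seed integer seed.
#' @return data.frame of survey records (one row per farm) with columns
#'   `district`, `mechanized`, and the survey variables.
#' @export
generate_survey <- function(config = generator_config(),
                            seed = config$seed) {
  cfg <- config
  stopifnot(inherits(cfg, "pasm_generator_config"))
  if (cfg$n_mechanized > cfg$n_total) {
    stop("n_mechanized must not exceed n_total")
  }
  set.seed(seed)
  n <- cfg$n_total
  n_mech <- cfg$n_mechanized
  mech <- sample(rep(c(FALSE, TRUE), c(n - n_mech, n_mech)))
  base <- cfg$survey_base_means
  eff <- cfg$effects
  mult <- c(yield_kg_per_ha = 1 + eff[["yield_pct"]] / 100,
            fertilizer_kg_per_ha = 1 + eff[["fertilizer_pct"]] / 100,
            pesticide_kg_per_ha = 1 + eff[["pesticide_pct"]] / 100,
            labor_wage_yuan_per_pm = 1 + eff[["wage_pct"]] / 100,
            labor_pm_per_ha = 1 + eff[["labor_pct"]] / 100,
            machinery_purchase_cost_annualized_yuan_per_ha =
              1 + eff[["machinery_pct"]] / 100,
            machinery_rent_yuan_per_ha = 1 + eff[["machinery_pct"]] / 100)
  districts <- if (cfg$n_districts == 9L) SHANGHAI_DISTRICTS else
    sprintf("district%02d", seq_len(cfg$n_districts))
  out <- data.frame(district = rep_len(districts, n), mechanized = mech,
                    stringsAsFactors = FALSE)
  for (v in SURVEY_VARIABLES) {
    m <- ifelse(mech, base[[v]] * mult[[v]], base[[v]])
    out[[v]] <- .rlnorm_mean(n, m, cfg$survey_cv)
  }
  out
}

#' Construct an instance whose welfare optimum is known in closed form
#'
#' Builds a closed-economy bundle around a chosen interior optimum: acreage
#' uses all land in every district, and intercepts / activity costs are set
#' so that marginal net revenue per hectare is equalized across planted
#' crops within each district and equals that district's land shadow price.
#' The returned expected solution is exact (Karush-Kuhn-Tucker conditions by
#' construction), making the pair a parameter-recovery oracle for the
#' solver.
#'
#' @param config a `pasm_generator_config`; only `n_districts` (must be 1:
#'   multi-district interior optima have non-unique acreage, see the methods
#'   vignette) and `n_crops` (>= 2) are consumed.
#' @param seed integer seed.
#' @param economy must be `"P_free"`: an interior equalized-margin optimum
#'   requires downward-sloping demand.
#' @return list with `bundle` (a `pasm_bundle`, crop-mix constraint
#'   disabled, pesticide priced at zero so the stated costs are complete)
#'   and `expected` (acreage data.frame, `sales_t`, `prices_yuan_per_kg`,
#'   `land_rent_yuan_per_ha`, `welfare`, `consumer_surplus`,
#'   `producer_surplus`).
#' @export
generate_known_equilibrium_instance <- function(config = generator_config(
                                                  n_districts = 1L,
                                                  n_crops = 2L),
                                                seed = config$seed,
                                                economy = "P_free") {
  cfg <- config
  if (!identical(economy, "P_free")) {
    stop("interior known-equilibrium construction requires the ",
         "closed-economy closure (P_free)")
  }
  stopifnot(cfg$n_crops >= 2, cfg$n_districts >= 1)
  if (cfg$n_districts > 1) {
    # with several districts sharing one demand curve per commodity, sales
    # and land rents are pinned down but the within-district acreage
    # composition is not (the objective is flat along cross-district crop
    # swaps that preserve totals) -- no unique closed-form acreage exists
    stop("known-equilibrium construction requires n_districts = 1: ",
         "multi-district interior optima have non-unique acreage")
  }
  set.seed(seed)
  nd <- cfg$n_districts; nc <- cfg$n_crops
  crops <- data.frame(id = sprintf("c%02d", seq_len(nc)),
                      name = sprintf("Crop %d", seq_len(nc)),
                      category = rep_len(c("grain", "leafy_vegetable"), nc),
                      stringsAsFactors = FALSE)
  land <- stats::runif(nd, 80, 150)
  districts <- data.frame(id = sprintf("d%d", seq_len(nd)),
                          name = sprintf("District %d", seq_len(nd)),
                          land_ha = land, stringsAsFactors = FALSE)
  # chosen optimum: all land planted, interior shares
  share <- matrix(stats::rgamma(nd * nc, 3, 1), nd, nc)
  share <- share / rowSums(share)
  qstar <- share * land                       # ha, district x crop
  cyield <- matrix(stats::runif(nd * nc, 4, 12), nd, nc)   # t/ha
  b <- stats::runif(nc, 0.5, 3)               # yuan/t per t
  p <- stats::runif(nc, 1500, 4000)           # equilibrium prices, yuan/t
  lambda <- stats::runif(nd, 2000, 5000)      # land rents, yuan/ha
  cost <- sweep(cyield * rep(p, each = nd), 1, lambda, "-")  # yuan/ha
  if (any(cost <= 0)) {
    stop("requested configuration yields a corner solution ",
         "(non-positive activity cost); adjust the draw ranges")
  }
  Y <- colSums(cyield * qstar)                # t
  a <- p + b * Y                              # intercepts, yuan/t

  budgets <- data.frame(
    district = rep(districts$id, times = nc),
    crop = rep(crops$id, each = nd),
    tech = "base",
    yield_kg_per_ha = as.numeric(cyield) * 1000,
    pesticide_kg_per_ha = stats::runif(nd * nc, 2, 20),
    fertilizer_kg_per_ha = 0, labor_pm_per_ha = 0,
    machinery_cost_yuan_per_ha = 0,
    other_cost_yuan_per_ha = as.numeric(cost),
    stringsAsFactors = FALSE)
  demand <- data.frame(
    crop = crops$id,
    p0_yuan_per_kg = p / 1000,
    q0_t = Y,
    elasticity = -p / (b * Y),
    intercept_a = a, slope_b = b,
    stringsAsFactors = FALSE)
  observed_district <- data.frame(
    district = rep(districts$id, times = nc),
    crop = rep(crops$id, each = nd),
    acreage_ha = as.numeric(qstar), stringsAsFactors = FALSE)
  observed <- data.frame(
    crop = crops$id, acreage_ha = colSums(qstar), production_t = Y,
    price_yuan_per_kg = p / 1000, stringsAsFactors = FALSE)
  historical_mix <- data.frame(
    district = observed_district$district, year = "y1",
    crop = observed_district$crop, area_ha = observed_district$acreage_ha,
    stringsAsFactors = FALSE)
  input_prices <- data.frame(input_id = INPUT_IDS, price = c(0, 0, 0),
                             stringsAsFactors = FALSE)
  bundle <- new_bundle(crops, districts, budgets, input_prices, demand,
                       historical_mix, observed,
                       observed_district = observed_district,
                       settings = default_settings(mix_constraint = FALSE))
  welfare <- sum(a * Y - b * Y^2 / 2) - sum(cost * qstar)
  cs <- sum(b * Y^2 / 2)
  expected <- list(
    acreage = data.frame(district = rep(districts$id, times = nc),
                         crop = rep(crops$id, each = nd), tech = "base",
                         area_ha = as.numeric(qstar),
                         stringsAsFactors = FALSE),
    sales_t = stats::setNames(Y, crops$id),
    prices_yuan_per_kg = stats::setNames(p / 1000, crops$id),
    land_rent_yuan_per_ha = stats::setNames(lambda, districts$id),
    welfare = welfare, consumer_surplus = cs,
    producer_surplus = welfare - cs)
  list(bundle = bundle, expected = expected)
}
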