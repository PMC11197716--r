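#' @keywords internal
"_PACKAGE"

# Unit conventions used throughout:
#   areas ha; yields kg/ha; production and sales t (1 t = 1000 kg);
#   prices yuan/kg in external files, yuan/t internally for surplus math;
#   pesticide totals t, rates kg/ha; labor person-months/ha.

CROP_CATEGORIES <- c("grain", "leafy_vegetable", "other_vegetable",
                     "fruit", "oilseed")
HORTICULTURAL_CATEGORIES <- c("leafy_vegetable", "other_vegetable", "fruit")
INPUT_IDS <- c("pesticide", "fertilizer", "labor")
TECH_LEVELS <- c("base", "mechanized")

RESULTS_HEADER <- c("scenario_id", "reduction_level", "tech", "imposition",
                    "economy", "metric", "entity", "value")

#' Default bundle settings
#'
#' Settings carried by a model input bundle. `mix_delta` is the flexibility
#' multiplier on the crop-mix convexity cone (acreage may exceed the convex
#' combination of historical mixes by this fraction); `mix_constraint`
#' switches the cone off entirely; `solver` selects the QP backend;
#' `discount_rate` and `machine_lifespan_years` drive machinery-cost
#' annualization; `baseline_from` chooses whether baseline pesticide usage
#' comes from observed base-year acreage (`"observed"`) or from the solved
#' zero-reduction scenario (`"model_r0"`).
#'
#' @param ... named overrides of the defaults.
#' @return named list of settings.
#' @export
default_settings <- function(...) {
  s <- list(
    mix_delta = 0.15,
    mix_constraint = TRUE,
    solver = "ipm",
    solver_tol = 1e-10,
    discount_rate = 0.05,
    machine_lifespan_years = 10,
    rice_crop = NULL,
    baseline_from = "observed"
  )
  utils::modifyList(s, list(...))
}

#' Construct a model input bundle
#'
#' Assembles the plain tables describing one regional sector-model instance
#' into a validated bundle object. Demand coefficients (linear inverse-demand
#' intercept and slope, yuan/t scale) are derived from the calibration points
#' unless already present.
#'
#' @param crops data.frame with columns `id`, `name`, `category`.
#' @param districts data.frame with columns `id`, `name`, `land_ha`.
#' @param budgets data.frame with columns `district`, `crop`, `tech`,
#'   `yield_kg_per_ha`, `pesticide_kg_per_ha`, `fertilizer_kg_per_ha`,
#'   `labor_pm_per_ha`, `machinery_cost_yuan_per_ha`,
#'   `other_cost_yuan_per_ha`.
#' @param input_prices data.frame with columns `input_id`, `price`
#'   (yuan/kg for chemicals, yuan/person-month for labor).
#' @param demand data.frame with columns `crop`, `p0_yuan_per_kg`, `q0_t`,
#'   `elasticity` (negative own-price).
#' @param historical_mix data.frame with columns `district`, `year`, `crop`,
#'   `area_ha`.
#' @param observed data.frame with columns `crop`, `acreage_ha`,
#'   `production_t`, `price_yuan_per_kg` (base-year observations).
#' @param observed_district optional data.frame with columns `district`,
#'   `crop`, `acreage_ha` giving the base-year acreage by district.
#' @param settings list as produced by [default_settings()].
#' @return object of class `pasm_bundle`.
#' @seealso [validate_bundle()], [load_bundle()], [generate_instance()]
#' @export
new_bundle <- function(crops, districts, budgets, input_prices, demand,
                       historical_mix, observed, observed_district = NULL,
                       settings = default_settings()) {
  crops <- as.data.frame(crops)
  districts <- as.data.frame(districts)
  budgets <- as.data.frame(budgets)
  input_prices <- as.data.frame(input_prices)
  demand <- as.data.frame(demand)
  historical_mix <- as.data.frame(historical_mix)
  observed <- as.data.frame(observed)
  if (!is.null(observed_district)) {
    observed_district <- as.data.frame(observed_district)
  }
  if (!all(c("intercept_a", "slope_b") %in% names(demand))) {
    coefs <- calibrate_linear_inverse_demand(
      demand$p0_yuan_per_kg * 1000, demand$q0_t, demand$elasticity)
    demand$intercept_a <- coefs$intercept_a
    demand$slope_b <- coefs$slope_b
  }
  settings <- utils::modifyList(default_settings(), settings)
  structure(
    list(crops = crops, districts = districts, budgets = budgets,
         input_prices = input_prices, demand = demand,
         historical_mix = historical_mix, observed = observed,
         observed_district = observed_district, settings = settings),
    class = "pasm_bundle")
}

#' @export
print.pasm_bundle <- function(x, ...) {
  cat("<pasm_bundle>\n")
  cat(sprintf("  %d districts, %d crops, %d budget rows (%d mechanized)\n",
              nrow(x$districts), nrow(x$crops), nrow(x$budgets),
              sum(x$budgets$tech == "mechanized")))
  cat(sprintf("  %d historical mix years, mix_delta = %g, solver = %s\n",
              length(unique(x$historical_mix$year)),
              x$settings$mix_delta, x$settings$solver))
  invisible(x)
}

BUNDLE_FILES <- list(
  crops = c("id", "name", "category"),
  districts = c("id", "name", "land_ha"),
  budgets = c("district", "crop", "tech", "yield_kg_per_ha",
              "pesticide_kg_per_ha", "fertilizer_kg_per_ha",
              "labor_pm_per_ha", "machinery_cost_yuan_per_ha",
              "other_cost_yuan_per_ha"),
  input_prices = c("input_id", "price"),
  demand = c("crop", "p0_yuan_per_kg", "q0_t", "elasticity"),
  historical_mix = c("district", "year", "crop", "area_ha"),
  observed = c("crop", "acreage_ha", "production_t", "price_yuan_per_kg")
)

#' Load a model input bundle from a directory of CSV files
#'
#' Expects `crops.csv`, `districts.csv`, `budgets.csv`, `input_prices.csv`,
#' `demand.csv`, `historical_mix.csv`, `observed.csv` and `settings.json`
#' (optionally `observed_district.csv`), all UTF-8 comma-separated with "."
#' decimal point.
#'
#' @param path bundle directory.
#' @return a `pasm_bundle` passing [validate_bundle()].
#' @export
load_bundle <- function(path) {
  if (!dir.exists(path)) stop("bundle directory not found: ", path)
  tabs <- lapply(names(BUNDLE_FILES), function(nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing bundle file: ", basename(f))
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    missing_cols <- setdiff(BUNDLE_FILES[[nm]], names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf("file %s.csv: missing column(s) %s", nm,
                   paste(missing_cols, collapse = ", ")))
    }
    df
  })
  names(tabs) <- names(BUNDLE_FILES)
  od_file <- file.path(path, "observed_district.csv")
  od <- if (file.exists(od_file)) {
    utils::read.csv(od_file, stringsAsFactors = FALSE)
  } else NULL
  st_file <- file.path(path, "settings.json")
  settings <- if (file.exists(st_file)) {
    jsonlite::read_json(st_file, simplifyVector = TRUE)
  } else default_settings()
  b <- new_bundle(tabs$crops, tabs$districts, tabs$budgets, tabs$input_prices,
                  tabs$demand, tabs$historical_mix, tabs$observed,
                  observed_district = od, settings = settings)
  issues <- validate_bundle(b)
  if (nrow(issues) > 0) {
    stop("bundle failed validation: ",
         paste(utils::head(issues$rule, 5), collapse = "; "))
  }
  b
}

#' Write a bundle to a directory (inverse of [load_bundle()])
#'
#' @param bundle a `pasm_bundle`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(BUNDLE_FILES)) {
    .write_csv_precise(bundle[[nm]], file.path(path, paste0(nm, ".csv")))
  }
  if (!is.null(bundle$observed_district)) {
    .write_csv_precise(bundle$observed_district,
                       file.path(path, "observed_district.csv"))
  }
  jsonlite::write_json(bundle$settings, file.path(path, "settings.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

# CSV writer preserving >= 15 significant digits on numeric columns
.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) "" else sprintf("%.15g", v)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Validate a model input bundle
#'
#' Checks every type invariant and cross-table reference and returns the
#' violations as a data.frame rather than raising. An empty result means the
#' bundle can be assembled into a solvable baseline problem.
#'
#' @param bundle a `pasm_bundle`.
#' @return data.frame with columns `table`, `key`, `rule`; zero rows if valid.
#' @export
validate_bundle <- function(bundle) {
  issues <- list()
  add <- function(table, key, rule) {
    issues[[length(issues) + 1L]] <<- data.frame(
      table = table, key = key, rule = rule, stringsAsFactors = FALSE)
  }
  cr <- bundle$crops; di <- bundle$districts; bu <- bundle$budgets
  ip <- bundle$input_prices; de <- bundle$demand; hm <- bundle$historical_mix
  ob <- bundle$observed

  if (anyDuplicated(cr$id)) add("crops", "", "id unique")
  bad <- !cr$category %in% CROP_CATEGORIES
  for (i in which(bad)) add("crops", cr$id[i], "category in closed set")
  if (anyDuplicated(di$id)) add("districts", "", "id unique")
  for (i in which(!(di$land_ha > 0))) add("districts", di$id[i], "land_ha > 0")

  key <- paste(bu$district, bu$crop, bu$tech)
  if (anyDuplicated(key)) {
    add("budgets", key[duplicated(key)][1], "(district, crop, tech) unique")
  }
  for (i in which(!(bu$yield_kg_per_ha > 0))) {
    add("budgets", key[i], "yield_kg_per_ha > 0")
  }
  ratecols <- c("pesticide_kg_per_ha", "fertilizer_kg_per_ha",
                "labor_pm_per_ha", "machinery_cost_yuan_per_ha",
                "other_cost_yuan_per_ha")
  for (cc in ratecols) {
    for (i in which(bu[[cc]] < 0)) add("budgets", key[i], paste(cc, ">= 0"))
  }
  for (i in which(!bu$tech %in% TECH_LEVELS)) {
    add("budgets", key[i], "tech in {base, mechanized}")
  }
  for (i in which(!bu$district %in% di$id)) {
    add("budgets", key[i], "district exists")
  }
  for (i in which(!bu$crop %in% cr$id)) add("budgets", key[i], "crop exists")

  for (i in which(ip$price < 0)) add("input_prices", ip$input_id[i], "price >= 0")
  for (nm in setdiff(INPUT_IDS, ip$input_id)) {
    add("input_prices", nm, "input present")
  }

  for (i in which(!(de$p0_yuan_per_kg > 0))) add("demand", de$crop[i], "p0 > 0")
  for (i in which(!(de$q0_t > 0))) add("demand", de$crop[i], "q0 > 0")
  for (i in which(!(de$elasticity < 0))) {
    add("demand", de$crop[i], "elasticity < 0")
  }
  if (!is.null(de$slope_b)) {
    for (i in which(de$slope_b < 0)) add("demand", de$crop[i], "slope_b >= 0")
    for (i in which(de$intercept_a < 1000 * de$p0_yuan_per_kg - 1e-9)) {
      add("demand", de$crop[i], "intercept_a >= p0 (yuan/t)")
    }
  }
  for (nm in setdiff(cr$id, de$crop)) add("demand", nm, "every crop has a demand spec")

  for (i in which(hm$area_ha < 0)) {
    add("historical_mix", paste(hm$district[i], hm$year[i]), "area_ha >= 0")
  }
  agg <- stats::aggregate(area_ha ~ district + year, hm, sum)
  for (i in which(!(agg$area_ha > 0))) {
    add("historical_mix", paste(agg$district[i], agg$year[i]),
        "at least one positive entry per mix vector")
  }

  for (cc in c("acreage_ha", "production_t", "price_yuan_per_kg")) {
    for (i in which(!(ob[[cc]] > 0))) add("observed", ob$crop[i], paste(cc, "> 0"))
  }

  # coverage: base budget behind every positive historical/observed acreage
  pos_hist <- unique(hm[hm$area_ha > 0, c("district", "crop")])
  base_key <- paste(bu$district[bu$tech == "base"], bu$crop[bu$tech == "base"])
  for (i in seq_len(nrow(pos_hist))) {
    k <- paste(pos_hist$district[i], pos_hist$crop[i])
    if (!k %in% base_key) add("budgets", k, "base budget for positive acreage")
  }
  if (!is.null(bundle$observed_district)) {
    od <- bundle$observed_district
    pos <- od[od$acreage_ha > 0, , drop = FALSE]
    for (i in seq_len(nrow(pos))) {
      k <- paste(pos$district[i], pos$crop[i])
      if (!k %in% base_key) add("budgets", k, "base budget for positive acreage")
    }
  }

  if (length(issues) == 0) {
    return(data.frame(table = character(0), key = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Write a long-format results table to CSV
#'
#' The header is exactly
#' `scenario_id,reduction_level,tech,imposition,economy,metric,entity,value`;
#' values are written with 15 significant digits so a read-back reproduces
#' them beyond 12 significant digits.
#'
#' @param results data.frame in results schema (see [run_grid()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(nrow(results) > 0)
  missing_cols <- setdiff(RESULTS_HEADER, names(results))
  if (length(missing_cols) > 0) {
    stop("results table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  .write_csv_precise(results[, RESULTS_HEADER], path)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path CSV file.
#' @return data.frame in results schema.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RESULTS_HEADER, names(df))
  if (length(missing_cols) > 0) {
    stop("results file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

# rounding at the reporting boundary only: half-up, as printed tables use
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
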