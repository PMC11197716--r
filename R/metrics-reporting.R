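# Summary metrics: reduction percentages, Laspeyres/Paasche/Fisher indexes,
# validation-ratio tables with arithmetic and revenue-weighted means,
# pesticide intensity, and district deviations from prescribed cap targets.

#' Percentage reduction between two values
#'
#' `(v_start - v_end) / v_start * 100`, reported half-up at 2 decimals; a
#' positive result is a decrease.
#'
#' @param v_start starting value (> 0).
#' @param v_end ending value.
#' @return signed percent, rounded to 2 decimals.
#' @examples
#' reduction_percent(4415, 2771) # 37.24
#' @export
reduction_percent <- function(v_start, v_end) {
  if (any(v_start <= 0)) stop("v_start must be > 0")
  round_half_up((v_start - v_end) / v_start * 100, 2)
}

#' Laspeyres, Paasche and Fisher indexes
#'
#' Price variant: Laspeyres = `sum(p1*q0)/sum(p0*q0) * 100`, Paasche =
#' `sum(p1*q1)/sum(p0*q1) * 100`, Fisher = geometric mean of the two. The
#' quantity variant swaps the roles of prices and quantities. Under a
#' fixed-price closure the price variant is identically 100, so scenario
#' "price effects" there can only come from the quantity variant.
#'
#' @param p0,q0 base-period prices and quantities (aligned vectors).
#' @param p1,q1 current-period prices and quantities.
#' @param variant `"price"` or `"quantity"`.
#' @return list with `laspeyres`, `paasche`, `fisher`, `variant`
#'   (base = 100).
#' @export
price_index <- function(p0, q0, p1, q1, variant = c("price", "quantity")) {
  variant <- match.arg(variant)
  stopifnot(length(p0) == length(q0), length(p1) == length(q1),
            length(p0) == length(p1))
  if (variant == "quantity") {
    tmp <- p0; p0 <- q0; q0 <- tmp
    tmp <- p1; p1 <- q1; q1 <- tmp
  }
  base_l <- sum(p0 * q0)
  base_p <- sum(p0 * q1)
  if (base_l <= 0 || base_p <= 0) stop("zero base expenditure")
  laspeyres <- sum(p1 * q0) / base_l * 100
  paasche <- sum(p1 * q1) / base_p * 100
  list(laspeyres = laspeyres, paasche = paasche,
       fisher = sqrt(laspeyres * paasche), variant = variant)
}

#' Validation-ratio table against base-year observations
#'
#' Per-crop modeled/observed ratios for acreage, production and price, with
#' two summary rows: the arithmetic mean of the ratios and the
#' revenue-weighted mean, weights being observed production times observed
#' price. Means are reported half-up at 3 decimals; the per-crop table
#' retains full precision.
#'
#' @param observed data.frame with columns `crop`, `acreage_ha`,
#'   `production_t`, `price_yuan_per_kg`.
#' @param modeled data.frame with the same columns giving the modeled
#'   baseline (e.g. from a solved zero-reduction scenario).
#' @return list of class `pasm_validation`: `table` (per-crop observed,
#'   modeled and ratio columns) and `means` (metric x arithmetic /
#'   revenue_weighted, 3 decimals).
#' @export
validation_table <- function(observed, modeled) {
  miss <- setdiff(observed$crop, modeled$crop)
  if (length(miss) > 0) {
    stop("modeled values missing for crop(s): ", paste(miss, collapse = ", "))
  }
  mod <- modeled[match(observed$crop, modeled$crop), ]
  tab <- data.frame(
    crop = observed$crop,
    observed_acreage_ha = observed$acreage_ha,
    modeled_acreage_ha = mod$acreage_ha,
    acreage_ratio = mod$acreage_ha / observed$acreage_ha,
    observed_production_t = observed$production_t,
    modeled_production_t = mod$production_t,
    production_ratio = mod$production_t / observed$production_t,
    observed_price_yuan_per_kg = observed$price_yuan_per_kg,
    modeled_price_yuan_per_kg = mod$price_yuan_per_kg,
    price_ratio = mod$price_yuan_per_kg / observed$price_yuan_per_kg,
    stringsAsFactors = FALSE)
  wt <- observed$production_t * observed$price_yuan_per_kg
  means <- data.frame(
    metric = c("acreage", "production", "price"),
    arithmetic = round_half_up(
      c(mean(tab$acreage_ratio), mean(tab$production_ratio),
        mean(tab$price_ratio)), 3),
    revenue_weighted = round_half_up(
      c(sum(tab$acreage_ratio * wt), sum(tab$production_ratio * wt),
        sum(tab$price_ratio * wt)) / sum(wt), 3),
    stringsAsFactors = FALSE)
  structure(list(table = tab, means = means), class = "pasm_validation")
}

#' @export
print.pasm_validation <- function(x, ...) {
  cat("<pasm_validation>\n")
  print(x$means)
  invisible(x)
}

#' Pesticide use intensity (kg/ha)
#'
#' Intensity per group is `use_t * 1000 / area_ha`; the regional value is
#' total use over total area (the area-weighted mean of the district
#' intensities, not their arithmetic mean).
#'
#' @param pesticide_t named vector of pesticide use by district, t.
#' @param area_ha named vector of planted area by district, ha (same names).
#' @return data.frame with columns `entity`, `intensity_kg_per_ha`,
#'   including a `"region"` row.
#' @export
pesticide_intensity <- function(pesticide_t, area_ha) {
  stopifnot(length(pesticide_t) == length(area_ha))
  if (any(area_ha == 0 & pesticide_t > 0)) {
    stop("zero area with positive pesticide use")
  }
  intensity <- ifelse(area_ha > 0, pesticide_t * 1000 / area_ha, 0)
  data.frame(
    entity = c(names(pesticide_t), "region"),
    intensity_kg_per_ha = c(intensity,
                            sum(pesticide_t) * 1000 / sum(area_ha)),
    stringsAsFactors = FALSE)
}

#' District deviation from prescribed pesticide targets
#'
#' For a reduction rate `r`, the prescribed district target is
#' `(1 - r) * B_n` (baseline usage scaled down). The deviation is
#' `(use_n - target_n) / target_n * 100`: negative means the district cut
#' deeper than prescribed, positive means it stayed above its own target —
#' possible only under region-scale imposition, where districts trade off
#' reductions through the market.
#'
#' @param use_t named vector of scenario pesticide use by district, t.
#' @param baseline list from [baseline_pesticide_usage()].
#' @param r reduction rate in (0, 1).
#' @return named vector of signed percentages.
#' @export
district_target_deviation <- function(use_t, baseline, r) {
  if (!(r > 0 && r < 1)) stop("r must lie in (0, 1)")
  B <- baseline$pesticide_t[names(use_t)]
  if (any(!(B > 0))) stop("baseline district values must be > 0")
  target <- (1 - r) * B
  (use_t - target) / target * 100
}
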