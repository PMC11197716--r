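# Survey -> technology-specific crop budgets. The paired survey (farms using
# vs not using chemicals-application machinery) is summarized to subsample
# means; signed percentage differences between the mechanized and
# non-mechanized means become the technology effect applied to base budgets.

SURVEY_VARIABLES <- c("yield_kg_per_ha", "fertilizer_kg_per_ha",
                      "pesticide_kg_per_ha", "labor_wage_yuan_per_pm",
                      "labor_pm_per_ha",
                      "machinery_purchase_cost_annualized_yuan_per_ha",
                      "machinery_rent_yuan_per_ha")

#' Equivalent annual cost of a machinery purchase
#'
#' The constant annual payment over `lifespan_years` whose discounted sum at
#' `discount_rate` equals `purchase_cost`:
#' \eqn{C r / (1 - (1+r)^{-L})}, with the zero-rate limit \eqn{C / L}.
#'
#' @param purchase_cost purchase price, yuan (vectorized).
#' @param lifespan_years machine life span, years (>= 1).
#' @param discount_rate annual discount rate (>= 0).
#' @return annualized cost, yuan/year.
#' @examples
#' annualize_equivalent_cost(10000, 10, 0.05) # 1295.05
#' @export
annualize_equivalent_cost <- function(purchase_cost, lifespan_years,
                                      discount_rate) {
  stopifnot(all(purchase_cost >= 0), discount_rate >= 0)
  if (any(lifespan_years < 1)) stop("lifespan_years must be >= 1")
  if (discount_rate == 0) return(purchase_cost / lifespan_years)
  r <- discount_rate
  purchase_cost * r / (1 - (1 + r)^(-lifespan_years))
}

#' Summarize a paired technology survey
#'
#' Arithmetic means of every survey variable over all records and over the
#' non-mechanized / mechanized subsamples, plus the machinery-cost totals
#' (annualized purchase mean + rent mean) per column.
#'
#' @param survey data.frame of survey records with a logical `mechanized`
#'   column and the variables in `SURVEY_VARIABLES`.
#' @return object of class `pasm_survey_summary`: list with `means` (a
#'   data.frame variable x overall/non_mechanized/mechanized),
#'   `machinery_cost_total` (named vector), and counts `n_total`, `n_base`,
#'   `n_mech`.
#' @export
summarize_survey <- function(survey) {
  stopifnot(nrow(survey) > 0, is.logical(survey$mechanized))
  n_mech <- sum(survey$mechanized)
  n_base <- sum(!survey$mechanized)
  if (n_base == 0) stop("empty subsample: non-mechanized")
  if (n_mech == 0) stop("empty subsample: mechanized")
  colmeans <- function(rows) {
    vapply(SURVEY_VARIABLES, function(v) mean(survey[[v]][rows]), numeric(1))
  }
  means <- data.frame(
    variable = SURVEY_VARIABLES,
    overall = colmeans(rep(TRUE, nrow(survey))),
    non_mechanized = colmeans(!survey$mechanized),
    mechanized = colmeans(survey$mechanized),
    row.names = NULL, stringsAsFactors = FALSE)
  mt <- means[means$variable == "machinery_purchase_cost_annualized_yuan_per_ha",
              -1] +
        means[means$variable == "machinery_rent_yuan_per_ha", -1]
  structure(list(means = means,
                 machinery_cost_total = unlist(mt),
                 n_total = nrow(survey), n_base = n_base, n_mech = n_mech),
            class = "pasm_survey_summary")
}

#' @export
print.pasm_survey_summary <- function(x, ...) {
  cat(sprintf("<pasm_survey_summary> n = %d (non-mechanized %d, mechanized %d)\n",
              x$n_total, x$n_base, x$n_mech))
  print(x$means, digits = 6)
  cat("machinery cost totals (purchase + rent):\n")
  print(round(x$machinery_cost_total, 2))
  invisible(x)
}

#' Technology effects from a paired survey summary
#'
#' Signed percentage differences of the mechanized subsample means relative
#' to the non-mechanized means, for the four channels propagated into
#' technology budgets: yield, pesticide rate, labor requirement, and total
#' machinery cost (annualized purchase + rent). Mechanization is expected to
#' raise yield and machinery cost and lower pesticide use and labor; an
#' unexpected sign triggers a warning, not an error.
#'
#' @param summary a `pasm_survey_summary`.
#' @return list with `yield_pct`, `pesticide_pct`, `labor_pct`,
#'   `machinery_cost_pct`.
#' @export
tech_effects <- function(summary) {
  stopifnot(inherits(summary, "pasm_survey_summary"))
  m <- summary$means
  base_of <- function(v) m$non_mechanized[m$variable == v]
  mech_of <- function(v) m$mechanized[m$variable == v]
  pct <- function(base, mech, what) {
    if (base == 0) stop("zero non-mechanized mean for ", what)
    (mech - base) / base * 100
  }
  eff <- list(
    yield_pct = pct(base_of("yield_kg_per_ha"), mech_of("yield_kg_per_ha"),
                    "yield"),
    pesticide_pct = pct(base_of("pesticide_kg_per_ha"),
                        mech_of("pesticide_kg_per_ha"), "pesticide"),
    labor_pct = pct(base_of("labor_pm_per_ha"), mech_of("labor_pm_per_ha"),
                    "labor"),
    machinery_cost_pct = pct(summary$machinery_cost_total[["non_mechanized"]],
                             summary$machinery_cost_total[["mechanized"]],
                             "machinery cost"))
  if (eff$yield_pct < 0 || eff$machinery_cost_pct < 0 ||
      eff$pesticide_pct > 0 || eff$labor_pct > 0) {
    warning("technology effect signs differ from the expected pattern ",
            "(yield up, machinery cost up, pesticide down, labor down)")
  }
  eff
}

#' Build mechanized budget variants from a technology effect
#'
#' For each in-scope (district, crop) base budget, adds a `mechanized` row
#' with yield, pesticide rate, labor requirement and machinery cost scaled by
#' the respective percentage effects; fertilizer and other cost are copied
#' unchanged. Base rows are never modified. Scope `rice_only` restricts the
#' technology to the rice crop; `all_crops` applies the rice-derived effect
#' uniformly to every crop.
#'
#' @param base_budgets budgets data.frame (base rows; mechanized rows, if
#'   present, are ignored as templates and retained untouched).
#' @param effect list as returned by [tech_effects()].
#' @param scope `"rice_only"` or `"all_crops"`.
#' @param rice_crop crop id counting as rice when `scope = "rice_only"`.
#' @return budgets data.frame with mechanized rows appended.
#' @export
build_tech_budgets <- function(base_budgets, effect,
                               scope = c("rice_only", "all_crops"),
                               rice_crop = "rice") {
  scope <- match.arg(scope)
  base <- base_budgets[base_budgets$tech == "base", , drop = FALSE]
  in_scope <- if (scope == "all_crops") {
    rep(TRUE, nrow(base))
  } else {
    if (!rice_crop %in% base$crop) {
      stop("scope 'rice_only' but no crop '", rice_crop, "' in the budgets")
    }
    base$crop == rice_crop
  }
  mech <- base[in_scope, , drop = FALSE]
  mech$tech <- "mechanized"
  mech$yield_kg_per_ha <- mech$yield_kg_per_ha * (1 + effect$yield_pct / 100)
  mech$pesticide_kg_per_ha <-
    mech$pesticide_kg_per_ha * (1 + effect$pesticide_pct / 100)
  mech$labor_pm_per_ha <- mech$labor_pm_per_ha * (1 + effect$labor_pct / 100)
  mech$machinery_cost_yuan_per_ha <-
    mech$machinery_cost_yuan_per_ha * (1 + effect$machinery_cost_pct / 100)
  out <- rbind(base_budgets, mech)
  rownames(out) <- NULL
  out
}
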