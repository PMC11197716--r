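# Policy grid: reduction level x technology adoption x imposition scale x
# market closure. At zero reduction the imposition dimension is vacuous, so
# R0 cells collapse to a single "region" entry per (tech, economy); the full
# stated grid is 6 x 3 x 2 x 2 = 72 cells collapsing to 66 scenarios.

.level_index <- function(r) {
  i <- match(r, REDUCTION_LEVELS)
  if (is.na(i)) {
    stop("unknown reduction level ", r, "; allowed: ",
         paste(REDUCTION_LEVELS, collapse = ", "))
  }
  i - 1L
}

#' Construct a scenario specification
#'
#' @param reduction_level one of `r REDUCTION_LEVELS` (fraction of baseline
#'   pesticide use removed).
#' @param tech `"TechB"` (no chemicals-application machinery), `"TechR"`
#'   (machinery for rice only) or `"TechA"` (machinery for all crops).
#' @param imposition `"district"` (cap each district) or `"region"` (cap the
#'   regional total). Normalized to `"region"` when `reduction_level = 0`,
#'   where the dimension is vacuous.
#' @param economy `"P_fixed"` (price taker) or `"P_free"` (closed regional
#'   economy).
#' @return object of class `pasm_scenario` with a stable `id` of the form
#'   `R<level>_<tech>_<imposition>_<economy>`.
#' @export
scenario_spec <- function(reduction_level, tech, imposition, economy) {
  if (!tech %in% TECH_OPTIONS) stop("unknown tech value: ", tech)
  if (!imposition %in% IMPOSITION_OPTIONS) {
    stop("unknown imposition value: ", imposition)
  }
  if (!economy %in% ECONOMY_OPTIONS) stop("unknown economy value: ", economy)
  li <- .level_index(reduction_level)
  if (reduction_level == 0) imposition <- "region"
  structure(list(
    reduction_level = reduction_level, tech = tech, imposition = imposition,
    economy = economy,
    id = sprintf("R%d_%s_%s_%s", li, tech, imposition, economy)),
    class = "pasm_scenario")
}

#' @export
print.pasm_scenario <- function(x, ...) {
  cat(sprintf("<pasm_scenario> %s (r = %g)\n", x$id, x$reduction_level))
  invisible(x)
}

#' Enumerate the policy scenario grid
#'
#' Full cross product of the four dimensions with the zero-reduction
#' collapse, deduplicated and ordered by (reduction level, tech, imposition,
#' economy). The complete grid yields 66 scenarios.
#'
#' @param levels,techs,impositions,economies dimension values (defaults: the
#'   full grid).
#' @return list of `pasm_scenario` objects.
#' @export
enumerate_scenarios <- function(levels = REDUCTION_LEVELS,
                                techs = TECH_OPTIONS,
                                impositions = IMPOSITION_OPTIONS,
                                economies = ECONOMY_OPTIONS) {
  stopifnot(length(levels) > 0, length(techs) > 0, length(impositions) > 0,
            length(economies) > 0)
  grid <- expand.grid(r = levels, tech = techs, imp = impositions,
                      eco = economies, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    scenario_spec(grid$r[i], grid$tech[i], grid$imp[i], grid$eco[i])
  })
  ids <- vapply(specs, `[[`, character(1), "id")
  specs <- specs[!duplicated(ids)]
  ord <- order(vapply(specs, `[[`, numeric(1), "reduction_level"),
               match(vapply(specs, `[[`, character(1), "tech"), TECH_OPTIONS),
               match(vapply(specs, `[[`, character(1), "imposition"),
                     IMPOSITION_OPTIONS),
               match(vapply(specs, `[[`, character(1), "economy"),
                     ECONOMY_OPTIONS))
  specs[ord]
}

# long-format metric rows for one solved scenario
.solution_rows <- function(spec, sol, bundle) {
  row <- function(metric, entity, value) {
    data.frame(scenario_id = spec$id, reduction_level = spec$reduction_level,
               tech = spec$tech, imposition = spec$imposition,
               economy = spec$economy, metric = metric, entity = entity,
               value = as.numeric(value), stringsAsFactors = FALSE)
  }
  out <- list(row("solver_optimal", "region",
                  as.numeric(identical(sol$status, "optimal"))))
  if (!identical(sol$status, "optimal")) return(do.call(rbind, out))

  wf <- sol$welfare
  for (nm in names(wf)) {
    out[[length(out) + 1L]] <- row(paste0("welfare_", nm), "region", wf[[nm]])
  }
  for (crop in names(sol$production_t)) {
    out[[length(out) + 1L]] <- row("production_t", crop,
                                   sol$production_t[[crop]])
    out[[length(out) + 1L]] <- row("price_yuan_per_kg", crop,
                                   sol$prices_yuan_per_kg[[crop]])
  }
  acr_d <- tapply(sol$acreage$area_ha, sol$acreage$district, sum)
  for (d in bundle$districts$id) {
    a <- if (d %in% names(acr_d)) acr_d[[d]] else 0
    out[[length(out) + 1L]] <- row("acreage_ha", d, a)
    out[[length(out) + 1L]] <- row("pesticide_use_t", d,
                                   sol$pesticide_use_t[[d]])
    out[[length(out) + 1L]] <- row(
      "pesticide_intensity_kg_per_ha", d,
      if (a > 0) sol$pesticide_use_t[[d]] * 1000 / a else 0)
    out[[length(out) + 1L]] <- row("land_rent_yuan_per_ha", d,
                                   sol$land_rent_yuan_per_ha[[d]])
  }
  tot_a <- sum(sol$acreage$area_ha)
  tot_p <- sum(sol$pesticide_use_t)
  out[[length(out) + 1L]] <- row("acreage_ha", "region", tot_a)
  out[[length(out) + 1L]] <- row("pesticide_use_t", "region", tot_p)
  out[[length(out) + 1L]] <- row("pesticide_intensity_kg_per_ha", "region",
                                 if (tot_a > 0) tot_p * 1000 / tot_a else 0)
  for (ent in names(sol$pesticide_shadow_yuan_per_kg)) {
    out[[length(out) + 1L]] <- row("pesticide_shadow_yuan_per_kg", ent,
                                   sol$pesticide_shadow_yuan_per_kg[[ent]])
  }
  do.call(rbind, out)
}

#' Run the model across a list of scenarios
#'
#' Solves each scenario and emits a long-format results table: welfare
#' components, per-crop production and prices, per-district acreage,
#' pesticide use, intensity and land rents, regional totals, and pesticide
#' shadow prices. Solver failures are recorded as `solver_optimal = 0`
#' status rows, never dropped.
#'
#' @param bundle a `pasm_bundle`.
#' @param specs list of `pasm_scenario` (e.g. from [enumerate_scenarios()]).
#' @return results data.frame (see `write_results()` for the schema).
#' @export
run_grid <- function(bundle, specs) {
  if (inherits(specs, "pasm_scenario")) specs <- list(specs)
  blocks <- lapply(specs, function(spec) {
    sol <- tryCatch(solve_problem(assemble_problem(bundle, spec)),
                    error = function(e) list(status = conditionMessage(e)))
    .solution_rows(spec, sol, bundle)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

# metrics for which percentage changes against the baseline are meaningful
PCT_CHANGE_METRICS <- c("production_t", "price_yuan_per_kg", "acreage_ha",
                        "pesticide_use_t", "pesticide_intensity_kg_per_ha",
                        "welfare_total")

#' Percentage changes of scenario results against matching baselines
#'
#' For every non-baseline scenario and level metric, appends
#' `(value - base) / base * 100` rows (metric suffix `_pct_change`), where
#' the base is the zero-reduction scenario with the same technology and
#' market closure — pairing within (tech, economy) isolates the policy
#' effect from the technology effect. A zero base with zero value yields 0;
#' a zero base with a nonzero value is flagged undefined (`NA`).
#'
#' @param results results data.frame from [run_grid()].
#' @return data.frame of `_pct_change` rows.
#' @export
percent_change_vs_baseline <- function(results) {
  keyed <- results[results$metric %in% PCT_CHANGE_METRICS, , drop = FALSE]
  out <- list()
  for (pair in unique(paste(keyed$tech, keyed$economy))) {
    parts <- strsplit(pair, " ")[[1]]
    sub <- keyed[keyed$tech == parts[1] & keyed$economy == parts[2], ]
    base <- sub[sub$reduction_level == 0, ]
    if (nrow(base) == 0) {
      stop("missing zero-reduction baseline for ", parts[1], "/", parts[2])
    }
    nonbase <- sub[sub$reduction_level != 0, ]
    if (nrow(nonbase) == 0) next
    m <- merge(nonbase, base[, c("metric", "entity", "value")],
               by = c("metric", "entity"), suffixes = c("", "_base"))
    m$value <- ifelse(
      m$value_base == 0,
      ifelse(m$value == 0, 0, NA_real_),
      (m$value - m$value_base) / m$value_base * 100)
    m$metric <- paste0(m$metric, "_pct_change")
    out[[length(out) + 1L]] <- m[, RESULTS_HEADER]
  }
  if (length(out) == 0) {
    return(results[0, RESULTS_HEADER])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scenario_id, res$metric, res$entity), ]
  rownames(res) <- NULL
  res
}
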