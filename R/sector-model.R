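# The welfare-maximization core. Decision variables: acreage Q per
# (district, crop, tech) budget row, sales Y per commodity, purchased inputs
# X per input, and mix weights lambda per (district, historical year).
# Maximized objective: sum over commodities of the inverse-demand integral
# (a Y - b Y^2/2, yuan) minus input purchase costs (w'X) minus direct
# activity costs (machinery + other, yuan/ha). Constraints: commodity
# balance (sales <= production), input links (use <= purchases), district
# land limits, a convex-cone crop-mix restriction around the historical mix
# vectors with flexibility (1 + delta), and pesticide-use caps at district
# or regional scale. Everything is a concave QP solved by solve_qp().

#' Reduction levels of the policy grid
#' @export
REDUCTION_LEVELS <- c(0, 0.10, 0.15, 0.20, 0.25, 0.30)
#' Technology-adoption dimension values
#' @export
TECH_OPTIONS <- c("TechB", "TechR", "TechA")
#' Imposition-scale dimension values
#' @export
IMPOSITION_OPTIONS <- c("district", "region")
#' Market-closure dimension values
#' @export
ECONOMY_OPTIONS <- c("P_fixed", "P_free")

#' Baseline pesticide usage by district
#'
#' District usage = sum over crops of base-year acreage times the base
#' budget's pesticide rate, in tonnes; the regional total is their sum. Uses
#' the per-(district, crop) observed acreage when the bundle carries it,
#' otherwise apportions the per-crop observed acreage across districts by
#' the first historical mix year's shares.
#'
#' @param bundle a `pasm_bundle`.
#' @return list with `pesticide_t` (named by district) and `region_total_t`.
#' @export
baseline_pesticide_usage <- function(bundle) {
  od <- bundle$observed_district
  if (is.null(od)) {
    hm <- bundle$historical_mix
    y1 <- hm[hm$year == hm$year[1], , drop = FALSE]
    tot <- stats::aggregate(area_ha ~ crop, y1, sum)
    shares <- merge(y1, tot, by = "crop", suffixes = c("", "_total"))
    shares$share <- ifelse(shares$area_ha_total > 0,
                           shares$area_ha / shares$area_ha_total, 0)
    od <- merge(shares[, c("district", "crop", "share")], bundle$observed,
                by = "crop")
    od$acreage_ha <- od$share * od$acreage_ha
    od <- od[, c("district", "crop", "acreage_ha")]
  }
  base_b <- bundle$budgets[bundle$budgets$tech == "base", ]
  m <- merge(od, base_b[, c("district", "crop", "pesticide_kg_per_ha")],
             by = c("district", "crop"), all.x = TRUE)
  miss <- m[is.na(m$pesticide_kg_per_ha) & m$acreage_ha > 0, ]
  if (nrow(miss) > 0) {
    stop("missing base budget for observed acreage: ",
         paste(miss$district[1], miss$crop[1]))
  }
  m$pesticide_kg_per_ha[is.na(m$pesticide_kg_per_ha)] <- 0
  use <- stats::aggregate(
    cbind(kg = acreage_ha * pesticide_kg_per_ha) ~ district, m, sum)
  pest <- stats::setNames(rep(0, nrow(bundle$districts)),
                          bundle$districts$id)
  pest[use$district] <- use$kg / 1000
  list(pesticide_t = pest, region_total_t = sum(pest))
}

# budgets active under a technology-adoption option
.active_budgets <- function(bundle, tech) {
  b <- bundle$budgets
  if (tech == "TechB") return(b[b$tech == "base", , drop = FALSE])
  if (tech == "TechA") {
    if (!any(b$tech == "mechanized")) {
      stop("scenario tech TechA but the bundle has no mechanized budgets")
    }
    return(b)
  }
  rice <- bundle$settings$rice_crop
  if (is.null(rice)) rice <- "rice"
  keep <- b$tech == "base" | (b$tech == "mechanized" & b$crop == rice)
  if (!any(b$tech == "mechanized" & b$crop == rice)) {
    stop("scenario tech TechR but no mechanized budget for crop '",
         rice, "'")
  }
  b[keep, , drop = FALSE]
}

#' Assemble the sector problem for one scenario
#'
#' Applies the scenario's market closure to the demand specs, restricts the
#' budgets to the technologies available under the scenario, and builds the
#' objective and constraint matrices (see the file header for the algebra).
#' The pesticide cap(s) bound use at `(1 - r)` times baseline usage, one row
#' per district under district imposition or a single regional row
#' otherwise.
#'
#' @param bundle a `pasm_bundle`.
#' @param scenario a `pasm_scenario` (see [scenario_spec()]).
#' @return object of class `pasm_problem`.
#' @export
assemble_problem <- function(bundle, scenario) {
  stopifnot(inherits(scenario, "pasm_scenario"))
  demand <- apply_closure(bundle$demand, scenario$economy)
  if (is.null(demand$intercept_a)) stop("uncalibrated demand specs")
  act <- .active_budgets(bundle, scenario$tech)
  crops <- bundle$crops$id
  districts <- bundle$districts$id
  st <- bundle$settings

  nq <- nrow(act)
  ny <- length(crops)
  use_mix <- isTRUE(st$mix_constraint)
  mix_keys <- if (use_mix) {
    unique(bundle$historical_mix[, c("district", "year")])
  } else NULL
  nl <- if (use_mix) nrow(mix_keys) else 0L
  nv <- nq + ny + nl
  iq <- seq_len(nq)
  iy <- nq + seq_len(ny)
  il <- if (nl > 0) nq + ny + seq_len(nl) else integer(0)

  d_idx <- match(demand$crop, crops)
  a_m <- numeric(ny); b_m <- numeric(ny)
  a_m[d_idx] <- demand$intercept_a
  b_m[d_idx] <- demand$slope_b

  w <- stats::setNames(rep(0, 3L), INPUT_IDS)
  ipr <- bundle$input_prices
  for (i in seq_len(nrow(ipr))) {
    if (ipr$input_id[i] %in% INPUT_IDS) w[ipr$input_id[i]] <- ipr$price[i]
  }
  # perfectly elastic input supply: purchases equal use at the optimum, so
  # the X variables are substituted out at assembly (X = A Q) and their
  # cost w'AQ folded into the acreage coefficients; X is reported back in
  # the solution
  input_rates <- rbind(pesticide = act$pesticide_kg_per_ha,
                       fertilizer = act$fertilizer_kg_per_ha,
                       labor = act$labor_pm_per_ha)

  q_min <- numeric(nv)
  q_min[iq] <- act$machinery_cost_yuan_per_ha + act$other_cost_yuan_per_ha +
    as.numeric(w %*% input_rates)
  q_min[iy] <- -a_m
  P_diag <- numeric(nv)
  P_diag[iy] <- b_m

  crop_row <- match(act$crop, crops)
  dist_row <- match(act$district, districts)
  yield_t <- act$yield_kg_per_ha / 1000

  rows <- list(); rhs <- list(); meta <- list()
  add_rows <- function(mat, b, type, key) {
    rows[[length(rows) + 1L]] <<- mat
    rhs[[length(rhs) + 1L]] <<- b
    meta[[length(meta) + 1L]] <<- data.frame(type = type, key = key,
                                             stringsAsFactors = FALSE)
  }

  # commodity balance: Y_m - sum(c Q) <= 0
  bal <- matrix(0, ny, nv)
  bal[cbind(crop_row, iq)] <- -yield_t
  bal[cbind(seq_len(ny), iy)] <- 1
  add_rows(bal, rep(0, ny), "balance", crops)

  # land: sum_k Q_nk <= Z_n
  land <- matrix(0, length(districts), nv)
  land[cbind(dist_row, iq)] <- 1
  add_rows(land, bundle$districts$land_ha, "land", districts)

  # crop-mix convexity cone with flexibility (1 + delta)
  if (use_mix) {
    hm <- bundle$historical_mix
    mix_pairs <- unique(data.frame(district = act$district, crop = act$crop,
                                   stringsAsFactors = FALSE))
    mix <- matrix(0, nrow(mix_pairs), nv)
    for (r in seq_len(nrow(mix_pairs))) {
      sel <- act$district == mix_pairs$district[r] &
        act$crop == mix_pairs$crop[r]
      mix[r, iq[sel]] <- 1
      for (hidx in seq_len(nl)) {
        if (mix_keys$district[hidx] != mix_pairs$district[r]) next
        area <- hm$area_ha[hm$district == mix_pairs$district[r] &
                             hm$year == mix_keys$year[hidx] &
                             hm$crop == mix_pairs$crop[r]]
        if (length(area) == 1 && area > 0) {
          mix[r, il[hidx]] <- -(1 + st$mix_delta) * area
        }
      }
    }
    add_rows(mix, rep(0, nrow(mix_pairs)), "mix",
             paste(mix_pairs$district, mix_pairs$crop))
  }

  # pesticide cap(s)
  baseline <- baseline_pesticide_usage(bundle)
  r <- scenario$reduction_level
  if (scenario$imposition == "district") {
    cap <- matrix(0, length(districts), nv)
    cap[cbind(dist_row, iq)] <- act$pesticide_kg_per_ha
    add_rows(cap, (1 - r) * baseline$pesticide_t * 1000, "pesticide_cap",
             districts)
  } else {
    cap <- matrix(0, 1, nv)
    cap[1, iq] <- act$pesticide_kg_per_ha
    add_rows(cap, (1 - r) * baseline$region_total_t * 1000, "pesticide_cap",
             "region")
  }

  G <- do.call(rbind, rows)
  h <- unlist(rhs, use.names = FALSE)
  row_meta <- do.call(rbind, meta)
  var_meta <- data.frame(
    kind = c(rep("Q", nq), rep("Y", ny), rep("lambda", nl)),
    key = c(paste(act$district, act$crop, act$tech),
            crops,
            if (nl > 0) paste(mix_keys$district, mix_keys$year)),
    stringsAsFactors = FALSE)

  structure(list(
    P_diag = P_diag, q_min = q_min, G = G, h = h,
    row_meta = row_meta, var_meta = var_meta,
    act = act, crops = crops, districts = districts,
    demand = demand, scenario = scenario, baseline = baseline,
    input_prices = w, input_rates = input_rates,
    settings = st, idx = list(q = iq, y = iy, l = il)),
    class = "pasm_problem")
}

#' @export
print.pasm_problem <- function(x, ...) {
  cat(sprintf("<pasm_problem> %s: %d variables (%d acreage), %d constraints\n",
              x$scenario$id, length(x$q_min), length(x$idx$q), nrow(x$G)))
  invisible(x)
}

#' Solve an assembled sector problem
#'
#' Runs the configured QP backend and unpacks the primal and dual optimum:
#' acreage, production and sales, input use, endogenous prices (inverse
#' demand at the optimal sales, or the fixed observed prices under
#' `P_fixed`), pesticide use by district, welfare components, land rents and
#' pesticide shadow prices.
#'
#' @param problem a `pasm_problem`.
#' @param backend overrides the bundle's `solver` setting if given.
#' @return object of class `pasm_solution`.
#' @export
solve_problem <- function(problem, backend = NULL) {
  stopifnot(inherits(problem, "pasm_problem"))
  if (is.null(backend)) backend <- problem$settings$solver
  sol <- solve_qp(problem$P_diag, problem$q_min, problem$G, problem$h,
                  backend = backend,
                  control = list(tol = problem$settings$solver_tol))
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, scenario = problem$scenario),
                     class = "pasm_solution"))
  }
  x <- pmax(sol$x, 0)
  idx <- problem$idx
  act <- problem$act
  Q <- x[idx$q]
  Y <- x[idx$y]
  # purchases equal use under perfectly elastic input supply
  X <- stats::setNames(as.numeric(problem$input_rates %*% Q), INPUT_IDS)

  acreage <- data.frame(district = act$district, crop = act$crop,
                        tech = act$tech, area_ha = Q,
                        stringsAsFactors = FALSE)
  prod_t <- stats::setNames(numeric(length(problem$crops)), problem$crops)
  pq <- tapply(Q * act$yield_kg_per_ha / 1000, act$crop, sum)
  prod_t[names(pq)] <- pq
  sales_t <- stats::setNames(Y, problem$crops)

  dmd <- problem$demand
  a_m <- dmd$intercept_a[match(problem$crops, dmd$crop)]
  b_m <- dmd$slope_b[match(problem$crops, dmd$crop)]
  price_t <- pmax(a_m - b_m * Y, 0)
  prices <- stats::setNames(price_t / 1000, problem$crops)

  pest_kg <- tapply(Q * act$pesticide_kg_per_ha, act$district, sum)
  pest_t <- stats::setNames(numeric(length(problem$districts)),
                            problem$districts)
  pest_t[names(pest_kg)] <- pest_kg / 1000

  gross_benefit <- sum(a_m * Y - b_m * Y^2 / 2)
  input_cost <- sum(problem$input_prices * X)
  activity_cost <- sum((act$machinery_cost_yuan_per_ha +
                          act$other_cost_yuan_per_ha) * Q)
  total <- gross_benefit - input_cost - activity_cost
  fixed <- problem$scenario$economy == "P_fixed"
  cs <- if (fixed) 0 else sum(b_m * Y^2 / 2)

  rm <- problem$row_meta
  land_rent <- stats::setNames(sol$y[rm$type == "land"],
                               rm$key[rm$type == "land"])
  cap_rows <- which(rm$type == "pesticide_cap")
  pesticide_shadow <- stats::setNames(sol$y[cap_rows], rm$key[cap_rows])
  mix_duals <- stats::setNames(sol$y[rm$type == "mix"],
                               rm$key[rm$type == "mix"])
  cap_slack_kg <- stats::setNames(
    problem$h[cap_rows] - as.numeric(problem$G[cap_rows, , drop = FALSE] %*% x),
    rm$key[cap_rows])

  structure(list(
    status = "optimal",
    scenario = problem$scenario,
    acreage = acreage,
    production_t = prod_t,
    sales_t = sales_t,
    input_use = X,
    prices_yuan_per_kg = prices,
    pesticide_use_t = pest_t,
    welfare = list(total = total, gross_consumer_benefit = gross_benefit,
                   input_cost = input_cost, activity_cost = activity_cost,
                   consumer_surplus = cs, producer_surplus = total - cs),
    land_rent_yuan_per_ha = land_rent,
    pesticide_shadow_yuan_per_kg = pesticide_shadow,
    mix_duals = mix_duals,
    cap_slack_kg = cap_slack_kg,
    objective = -sol$objective,
    iterations = sol$iterations),
    class = "pasm_solution")
}

#' @export
print.pasm_solution <- function(x, ...) {
  cat(sprintf("<pasm_solution> %s: status %s\n",
              if (!is.null(x$scenario$id)) x$scenario$id else "?", x$status))
  if (x$status == "optimal") {
    cat(sprintf("  welfare %.2f yuan; pesticide use %.3f t; planted %.1f ha\n",
                x$welfare$total, sum(x$pesticide_use_t),
                sum(x$acreage$area_ha)))
  }
  invisible(x)
}

#' Welfare components of a solved scenario
#'
#' Total welfare = gross consumer benefit minus input purchase costs minus
#' direct activity costs. Under the closed economy this splits into consumer
#' surplus (`sum(b Y^2 / 2)`) and producer surplus; under the price-taker
#' closure consumer surplus is reported as zero (demand is perfectly
#' elastic) and all welfare accrues to producers.
#'
#' @param solution an optimal `pasm_solution`.
#' @return named list of welfare components.
#' @export
welfare <- function(solution) {
  stopifnot(inherits(solution, "pasm_solution"),
            solution$status == "optimal")
  solution$welfare
}

#' Brute-force oracle for small instances
#'
#' Exhaustive search over the feasible acreage grid for instances with at
#' most three acreage variables after the technology restriction, with sales
#' set to production (clipped at the choke quantity) and inputs at their
#' links. The search runs staged refinements of the exhaustive grid; because
#' the objective is concave and the feasible set convex, each refinement
#' brackets the optimum, so the final answer is within one `grid_step_ha` of
#' the true optimizer. Used as an independent check on [solve_problem()].
#'
#' @param bundle a `pasm_bundle` (crop-mix constraint must be disabled).
#' @param scenario a `pasm_scenario`.
#' @param grid_step_ha final acreage resolution, ha.
#' @return list with `acreage`, `welfare`, `pesticide_use_t` and
#'   `status = "optimal"`.
#' @export
brute_force_solve <- function(bundle, scenario, grid_step_ha = 0.01) {
  stopifnot(inherits(scenario, "pasm_scenario"))
  if (isTRUE(bundle$settings$mix_constraint)) {
    stop("brute_force_solve requires bundles with the crop-mix ",
         "constraint disabled")
  }
  act <- .active_budgets(bundle, scenario$tech)
  k <- nrow(act)
  if (k > 3) stop("brute_force_solve refuses instances with more than 3 ",
                  "acreage variables (got ", k, ")")
  demand <- apply_closure(bundle$demand, scenario$economy)
  a_m <- demand$intercept_a[match(act$crop, demand$crop)]
  b_m <- demand$slope_b[match(act$crop, demand$crop)]
  w <- stats::setNames(rep(0, 3), INPUT_IDS)
  w[bundle$input_prices$input_id] <- bundle$input_prices$price
  land <- stats::setNames(bundle$districts$land_ha, bundle$districts$id)
  baseline <- baseline_pesticide_usage(bundle)
  r <- scenario$reduction_level
  cap_district <- scenario$imposition == "district"
  cap_kg <- if (cap_district) (1 - r) * baseline$pesticide_t * 1000 else
    (1 - r) * baseline$region_total_t * 1000

  yield_t <- act$yield_kg_per_ha / 1000
  unit_cost <- act$machinery_cost_yuan_per_ha + act$other_cost_yuan_per_ha +
    act$pesticide_kg_per_ha * w["pesticide"] +
    act$fertilizer_kg_per_ha * w["fertilizer"] +
    act$labor_pm_per_ha * w["labor"]

  eval_points <- function(Qm) {
    # Qm: k x npts matrix of candidate acreages
    ok <- rep(TRUE, ncol(Qm))
    for (d in unique(act$district)) {
      ok <- ok & colSums(Qm[act$district == d, , drop = FALSE]) <=
        land[d] + 1e-9
    }
    pest <- act$pesticide_kg_per_ha * Qm
    if (cap_district) {
      for (d in unique(act$district)) {
        ok <- ok & colSums(pest[act$district == d, , drop = FALSE]) <=
          cap_kg[d] + 1e-9
      }
    } else {
      ok <- ok & colSums(pest) <= cap_kg + 1e-9
    }
    wf <- rep(-Inf, ncol(Qm))
    if (!any(ok)) return(wf)
    Qok <- Qm[, ok, drop = FALSE]
    wv <- -colSums(unit_cost * Qok)
    # aggregate sales per crop, clip at the choke quantity
    for (crop in unique(act$crop)) {
      sel <- act$crop == crop
      y <- colSums((yield_t * Qok)[sel, , drop = FALSE])
      a <- a_m[which(sel)[1]]; b <- b_m[which(sel)[1]]
      if (b > 0) y <- pmin(y, a / b)
      wv <- wv + a * y - b * y^2 / 2
    }
    wf[ok] <- wv
    wf
  }

  ub <- vapply(seq_len(k), function(j) land[act$district[j]], numeric(1))
  lo <- rep(0, k); hi <- ub
  step <- pmax((hi - lo) / 40, grid_step_ha)
  best <- NULL
  repeat {
    grids <- lapply(seq_len(k), function(j) seq(lo[j], hi[j], by = step[j]))
    Qm <- t(as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
    wf <- eval_points(Qm)
    ibest <- which.max(wf)
    best <- list(Q = Qm[, ibest], welfare = wf[ibest])
    if (all(step <= grid_step_ha * (1 + 1e-12))) break
    lo <- pmax(0, best$Q - 2 * step)
    hi <- pmin(ub, best$Q + 2 * step)
    step <- pmax(step / 10, grid_step_ha)
  }
  pest_t <- tapply(best$Q * act$pesticide_kg_per_ha, act$district, sum) / 1000
  list(status = "optimal",
       acreage = data.frame(district = act$district, crop = act$crop,
                            tech = act$tech, area_ha = best$Q,
                            stringsAsFactors = FALSE),
       welfare = best$welfare,
       pesticide_use_t = pest_t)
}
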