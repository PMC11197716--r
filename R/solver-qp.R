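#' Solve a convex quadratic program with non-negative variables
#'
#' Minimizes \eqn{\tfrac12 x'Px + q'x} subject to \eqn{Gx \le h} and
#' \eqn{x \ge 0}, where \eqn{P} is symmetric positive semidefinite (a diagonal
#' here suffices for the sector model, whose only curvature comes from the
#' linear inverse-demand surplus terms). The default backend is a dense
#' Mehrotra predictor-corrector primal-dual interior-point method written for
#' this package; it handles the semidefinite case (including the pure-LP case
#' \eqn{P = 0} that arises under a fixed-price market closure), which rules
#' out off-the-shelf strictly-convex solvers as the primary route.
#'
#' @param P symmetric n x n positive-semidefinite matrix (or a length-n
#'   vector taken as its diagonal).
#' @param q length-n linear cost vector.
#' @param G m x n inequality constraint matrix (may have zero rows).
#' @param h length-m right-hand side.
#' @param backend `"ipm"` (default) or `"quadprog"`. The quadprog backend
#'   adds a small diagonal regularization `reg` so the Goldfarb-Idnani
#'   method applies; it exists as an independent cross-check and requires
#'   the suggested \pkg{quadprog} package.
#' @param control list of solver controls: `tol` (relative KKT tolerance,
#'   default 1e-9), `maxit` (default 200), `reg` (quadprog regularization,
#'   default 1e-9 of the problem scale).
#' @return list with elements `status` ("optimal", "max_iterations" or
#'   "numerical_failure"), `x` (primal solution), `y` (duals of `Gx <= h`,
#'   `>= 0`), `z` (duals of `x >= 0`), `objective` (value of the minimized
#'   objective), and `iterations`.
#' @examples
#' # min (x1-1)^2/2 + (x2-2)^2/2 s.t. x1 + x2 <= 2
#' sol <- solve_qp(diag(2), c(-1, -2), matrix(1, 1, 2), 2)
#' round(sol$x, 6)
#' @export
solve_qp <- function(P, q, G, h, backend = c("ipm", "quadprog"),
                     control = list()) {
  backend <- match.arg(backend)
  n <- length(q)
  if (is.null(dim(P))) {
    stopifnot(length(P) %in% c(1L, n))
    P <- diag(rep_len(as.numeric(P), n), n)
  }
  P <- as.matrix(P)
  if (is.null(G) || length(G) == 0L) {
    G <- matrix(0, 0L, n)
    h <- numeric(0)
  }
  G <- as.matrix(G)
  h <- as.numeric(h)
  stopifnot(nrow(P) == n, ncol(P) == n, ncol(G) == n, nrow(G) == length(h))
  ctl <- utils::modifyList(list(tol = 1e-9, maxit = 200, reg = NULL), control)
  if (backend == "quadprog") {
    return(.qp_quadprog(P, q, G, h, ctl))
  }
  .qp_ipm(P, q, G, h, ctl)
}

# Mehrotra predictor-corrector IPM on the scaled problem.
# KKT system reduced to the condensed normal equations in dx:
#   (P + diag(z/x) + G' diag(y/s) G) dx = rhs
.qp_ipm <- function(P, q, G, h, ctl) {
  n <- length(q)
  m <- length(h)

  # geometric-mean equilibration of variables and rows, then cost scaling;
  # keeps the condensed system well-conditioned when h spans 1e0..1e9
  sc <- .qp_scale(P, q, G, h)
  P <- sc$P; q <- sc$q; G <- sc$G; h <- sc$h

  x <- rep(1, n); z <- rep(1, n)
  s <- rep(1, m); y <- rep(1, m)
  # shift start so slacks are comfortably positive
  if (m > 0) {
    gap0 <- h - as.numeric(G %*% x)
    shift <- max(1, -min(gap0) + 1)
    s <- gap0 + shift
    y <- rep(1, m)
  }
  bnorm <- max(1, abs(h), abs(q))
  status <- "max_iterations"
  it <- 0L
  for (it in seq_len(ctl$maxit)) {
    if (!all(is.finite(x)) || !all(is.finite(z)) ||
        !all(is.finite(s)) || !all(is.finite(y))) {
      status <- "numerical_failure"
      break
    }
    Gx <- if (m > 0) as.numeric(G %*% x) else numeric(0)
    rd <- as.numeric(P %*% x) + q + (if (m > 0) as.numeric(crossprod(G, y)) else 0) - z
    rp <- if (m > 0) Gx + s - h else numeric(0)
    mu <- (sum(x * z) + sum(s * y)) / (n + m)
    res <- max(max(abs(rd)), if (m > 0) max(abs(rp)) else 0) / bnorm
    if (res < ctl$tol && mu < ctl$tol * bnorm) {
      status <- "optimal"
      break
    }
    if (max(x) > 1e12 * bnorm) {
      # zero-curvature improving ray not blocked by any constraint
      status <- "unbounded"
      break
    }

    dxz <- z / x
    M <- P + diag(dxz, n)
    if (m > 0) {
      dys <- y / s
      M <- M + crossprod(G * sqrt(dys))
    }
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(M + diag(1e-10 * max(diag(M)), n)),
                     error = function(e) NULL)
      if (is.null(ch)) { status <- "numerical_failure"; break }
    }
    solveM <- function(r) backsolve(ch, forwardsolve(t(ch), r))

    step_rhs <- function(sig_mu, cxz, csy) {
      # cxz, csy: corrector products (zero on the affine pass)
      rxz <- x * z - sig_mu + cxz
      rsy <- if (m > 0) s * y - sig_mu + csy else numeric(0)
      rhs <- -rd - rxz / x
      if (m > 0) rhs <- rhs + as.numeric(crossprod(G, rsy / s - (y / s) * rp))
      dx <- solveM(rhs)
      ds <- if (m > 0) -(rp + as.numeric(G %*% dx)) else numeric(0)
      dz <- -(rxz + z * dx) / x
      dy <- if (m > 0) -(rsy + y * ds) / s else numeric(0)
      list(dx = dx, ds = ds, dz = dz, dy = dy)
    }
    steplen <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) return(1)
      min(1, 0.9995 * min(-v[neg] / dv[neg]))
    }

    aff <- step_rhs(0, 0, if (m > 0) 0 else numeric(0))
    ap <- min(steplen(x, aff$dx), if (m > 0) steplen(s, aff$ds) else 1)
    ad <- min(steplen(z, aff$dz), if (m > 0) steplen(y, aff$dy) else 1)
    mu_aff <- (sum((x + ap * aff$dx) * (z + ad * aff$dz)) +
               (if (m > 0) sum((s + ap * aff$ds) * (y + ad * aff$dy)) else 0)) / (n + m)
    sigma <- if (mu > 0) min(1, (mu_aff / mu)^3) else 0

    cor <- step_rhs(sigma * mu, aff$dx * aff$dz,
                    if (m > 0) aff$ds * aff$dy else numeric(0))
    if (!all(vapply(cor, function(v) all(is.finite(v)), logical(1)))) {
      status <- "numerical_failure"
      break
    }
    ap <- min(steplen(x, cor$dx), if (m > 0) steplen(s, cor$ds) else 1)
    ad <- min(steplen(z, cor$dz), if (m > 0) steplen(y, cor$dy) else 1)
    x <- x + ap * cor$dx
    z <- z + ad * cor$dz
    if (m > 0) {
      s <- s + ap * cor$ds
      y <- y + ad * cor$dy
    }
  }

  # crossover polish: solve the KKT equalities on the active set guessed
  # from the converged iterate; near-machine-precision on nondegenerate
  # problems, harmless fallback otherwise
  if (status == "optimal") {
    pol <- .qp_polish(P, q, G, h, x, z, s, y)
    if (!is.null(pol)) {
      x <- pol$x; z <- pol$z; s <- pol$s; y <- pol$y
    }
  }

  # undo scaling: x = Dx x~, y = c * E y~ ... see .qp_scale for conventions
  xs <- x * sc$dx
  ys <- if (m > 0) y * sc$dr / sc$cost else numeric(0)
  zs <- z / (sc$dx * sc$cost)
  obj <- 0.5 * sum(xs * as.numeric(sc$P0 %*% xs)) + sum(sc$q0 * xs)
  list(status = status, x = xs, y = ys, z = zs, objective = obj,
       iterations = it)
}

# Active-set crossover on the scaled problem. Variables with x_i < z_i are
# fixed at zero, constraints with s_j < y_j are treated as equalities; the
# resulting KKT system is linear. Returns NULL when the guess is singular or
# violates the sign conditions beyond a small tolerance.
.qp_polish <- function(P, q, G, h, x, z, s, y, tol = 1e-7) {
  n <- length(q); m <- length(h)
  scale_h <- max(1, abs(h))
  fixed <- x < z
  # active: dominated by the dual, or essentially zero slack (covers rows
  # that bind with a (near-)zero multiplier, e.g. a cap that holds exactly)
  active <- if (m > 0) s < pmax(y, 1e-8 * scale_h) else logical(0)
  free <- which(!fixed)
  act <- which(active)
  nf <- length(free)
  if (nf == 0) return(NULL)
  if (length(act) > 0) {
    # drop vacuous and linearly dependent active rows (they make the KKT
    # system singular: e.g. an input-link row whose variable is fixed at 0)
    Gaf <- G[act, free, drop = FALSE]
    nz <- apply(abs(Gaf), 1L, max) > 1e-12
    act <- act[nz]
    if (length(act) > 1) {
      qrg <- qr(t(G[act, free, drop = FALSE]))
      act <- act[sort(qrg$pivot[seq_len(qrg$rank)])]
    }
  }
  na <- length(act)
  K <- rbind(cbind(P[free, free, drop = FALSE],
                   if (na > 0) t(G[act, free, drop = FALSE]) else
                     matrix(0, nf, 0)),
             cbind(if (na > 0) G[act, free, drop = FALSE] else
                     matrix(0, 0, nf),
                   matrix(0, na, na)))
  rhs <- c(-q[free], h[act])
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(NULL)
  x2 <- numeric(n)
  x2[free] <- sol[seq_len(nf)]
  y2 <- numeric(m)
  if (na > 0) y2[act] <- sol[nf + seq_len(na)]
  z2 <- as.numeric(P %*% x2) + q +
    (if (m > 0) as.numeric(crossprod(G, y2)) else 0)
  z2[free] <- 0
  s2 <- if (m > 0) h - as.numeric(G %*% x2) else numeric(0)
  scale <- max(1, abs(h), abs(q))
  ok <- all(x2 >= -tol * scale) && all(s2 >= -tol * scale) &&
    all(y2 >= -tol * scale) && all(z2[fixed] >= -tol * scale)
  if (!ok) return(NULL)
  list(x = pmax(x2, 0), z = pmax(z2, 0), s = pmax(s2, 0), y = pmax(y2, 0))
}

# Diagonal scaling: variables by column norms of [P; G; q], rows of G by row
# norms, objective by its largest coefficient. Returns scaled data plus the
# factors needed to map the solution and duals back.
.qp_scale <- function(P, q, G, h) {
  n <- length(q)
  m <- length(h)
  P0 <- P; q0 <- q
  colmag <- pmax(apply(abs(P), 2L, max),
                 if (m > 0) apply(abs(G), 2L, max) else 0,
                 abs(q) * 0 + 1e-12)
  dx <- 1 / sqrt(pmax(colmag, 1e-8))
  dx <- pmin(pmax(dx, 1e-6), 1e6)
  P <- P * outer(dx, dx)
  q <- q * dx
  if (m > 0) {
    G <- G * rep(dx, each = m)
    rowmag <- pmax(apply(abs(G), 1L, max), 1e-12)
    dr <- 1 / rowmag
    G <- G * dr
    h <- h * dr
  } else {
    dr <- numeric(0)
  }
  cost <- 1 / max(abs(q), max(abs(P)), 1e-12)
  P <- P * cost
  q <- q * cost
  list(P = P, q = q, G = G, h = h, dx = dx, dr = dr, cost = cost,
       P0 = P0, q0 = q0)
}

# Goldfarb-Idnani cross-check backend; requires strictly convex P, so a tiny
# ridge is added to zero-curvature coordinates.
.qp_quadprog <- function(P, q, G, h, ctl) {
  if (!requireNamespace("quadprog", quietly = TRUE)) {
    stop("backend 'quadprog' requires the quadprog package")
  }
  n <- length(q)
  scale <- max(abs(q), max(abs(P)), 1)
  reg <- if (is.null(ctl$reg)) 1e-9 * scale else ctl$reg
  D <- P + diag(reg, n)
  # quadprog: min 1/2 x'Dx - d'x s.t. A'x >= b; fold Gx <= h and x >= 0
  Amat <- cbind(diag(1, n), if (nrow(G) > 0) -t(G) else NULL)
  bvec <- c(rep(0, n), if (nrow(G) > 0) -h else NULL)
  sol <- quadprog::solve.QP(D, -q, Amat, bvec)
  lag <- sol$Lagrangian
  list(status = "optimal", x = sol$solution,
       y = if (nrow(G) > 0) lag[(n + 1):(n + nrow(G))] else numeric(0),
       z = lag[seq_len(n)],
       objective = 0.5 * sum(sol$solution * as.numeric(P %*% sol$solution)) +
         sum(q * sol$solution),
       iterations = NA_integer_)
}
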