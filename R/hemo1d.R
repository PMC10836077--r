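# ---- nonlinear 1D large-vessel hemodynamics (two-step Lax-Wendroff) --------
#
# Cross-sectionally averaged mass and momentum balance in each compliant
# vessel:
#   A_t + q_x = 0
#   q_t + (q^2/A)_x + (A/rho) p_x = -2 pi nu R / delta * q / A
# with a flat velocity profile and a linearly decreasing boundary layer of
# thickness delta = sqrt(nu T / 2 pi), closed by the linearly elastic wall
# law p - p0 = f(r0) (sqrt(A/A0) - 1), f = (4/3)(k1 exp(k2 r0) + k3).
# The pressure-gradient term is written in flux form with
# B = f A^{3/2} / (3 rho sqrt(A0)) plus an analytic geometric source for
# x-dependent r0 (tapering vessels).  Interior points advance by the
# two-step (Richtmyer) Lax-Wendroff scheme; the inlet takes a prescribed
# flow, junctions enforce pressure continuity and flow conservation, and
# outlets couple to an impedance convolution kernel, all closed by damped
# Newton iteration on (A, q) with outgoing-characteristic compatibility
# (Riemann quantities u +/- 4c, quadratic foot-point interpolation).

MMHG <- 1333.22  # g/cm/s^2 per mmHg

#' Large-vessel solver parameters
#'
#' @param T cardiac period (s).
#' @param rho blood density (g/cm^3).
#' @param mu_L large-vessel dynamic viscosity (g/cm/s).
#' @param k1L,k2L,k3L stiffness constants of Eh/r0 = k1 exp(k2 r0) + k3
#'   (g/cm/s^2, 1/cm, g/cm/s^2).
#' @param p0 reference pressure (mmHg) at which A = A0.
#' @param grid spatial points per vessel.
#' @param cycles maximum cardiac cycles to run.
#' @param n_modes frequency modes evaluated for impedance outflow.
#' @param cfl_safety fraction of the CFL bound used for the time step.
#' @param period_tol relative period-to-period change below which the run
#'   stops early (periodic convergence).
#' @param friction_radius use the `"deformed"` radius sqrt(A/pi) (default)
#'   or the rest radius in the friction term.
#' @return list of class `hemo_params`.
#' @export
hemo_params <- function(T = 0.85, rho = 1.055, mu_L = 0.032,
                        k1L = 2.5e6, k2L = -15, k3L = 6.4e4,
                        p0 = 0, grid = 24L, cycles = 10L, n_modes = 128L,
                        cfl_safety = 0.5, period_tol = 1e-3,
                        friction_radius = c("deformed", "rest")) {
  stopifnot(T > 0, rho > 0, mu_L > 0, grid >= 8, cycles >= 1,
            cfl_safety > 0, cfl_safety <= 1)
  structure(list(T = T, rho = rho, mu_L = mu_L, k1L = k1L, k2L = k2L,
                 k3L = k3L, p0 = p0, grid = as.integer(grid),
                 cycles = as.integer(cycles), n_modes = as.integer(n_modes),
                 cfl_safety = cfl_safety, period_tol = period_tol,
                 friction_radius = match.arg(friction_radius)),
            class = "hemo_params")
}

#' Vascular stiffness Eh/r0 as a function of rest radius
#'
#' `Eh/r0 = k1 exp(k2 r0) + k3` — exponentially stiffer at small caliber
#' (k2 < 0), approaching k3 for large vessels.
#'
#' @param r0 rest radius (cm).
#' @param k1,k2,k3 constants.
#' @return Eh/r0 (g/cm/s^2).
#' @export
wall_stiffness <- function(r0, k1, k2, k3) k1 * exp(k2 * r0) + k3

#' Pressure from area under the elastic wall law
#' @param A area (cm^2); `A0` rest area; `f` = (4/3) Eh/r0 (g/cm/s^2);
#'   `p0` reference pressure in CGS units.
#' @return pressure (g/cm/s^2).
#' @export
pressure_from_area <- function(A, A0, f, p0 = 0) p0 + f * (sqrt(A / A0) - 1)

#' Area from pressure under the elastic wall law (inverse of
#' [pressure_from_area()])
#' @param p pressure (g/cm/s^2); other arguments as in
#'   [pressure_from_area()].
#' @return area (cm^2).
#' @export
area_from_pressure <- function(p, A0, f, p0 = 0) A0 * (1 + (p - p0) / f)^2

# per-vessel discrete geometry: grid, rest profile and its derivatives,
# evaluated at nodes and at cell midpoints
.vessel_geometry <- function(r_hat, L, M, hp) {
  x <- seq(0, L, length.out = M)
  xh <- (x[-1] + x[-M]) / 2
  if (length(r_hat) == 1L) {
    r0 <- rep(r_hat, M); r0h <- rep(r_hat, M - 1L)
    dr0 <- rep(0, M); dr0h <- rep(0, M - 1L)
  } else {
    lam <- log(r_hat[2] / r_hat[1]) / L
    r0 <- r_hat[1] * exp(lam * x); r0h <- r_hat[1] * exp(lam * xh)
    dr0 <- lam * r0; dr0h <- lam * r0h
  }
  geom <- function(r0v, dr0v) {
    A0 <- pi * r0v^2
    f <- (4 / 3) * wall_stiffness(r0v, hp$k1L, hp$k2L, hp$k3L)
    fp <- (4 / 3) * hp$k1L * hp$k2L * exp(hp$k2L * r0v) * dr0v
    dA0 <- 2 * pi * r0v * dr0v
    list(r0 = r0v, A0 = A0, f = f, fp = fp, dA0 = dA0,
         cc0 = sqrt(f / (2 * hp$rho)) / A0^0.25)
  }
  list(x = x, dx = x[2] - x[1], M = M, n = geom(r0, dr0), h = geom(r0h, dr0h))
}

# momentum source: friction + geometric (taper) terms
.source2 <- function(A, q, g, hp, delta) {
  nu <- hp$mu_L / hp$rho
  R <- if (hp$friction_radius == "deformed") sqrt(A / pi) else g$r0
  fric <- -2 * pi * nu * R * q / (delta * A)
  sA <- sqrt(A / g$A0)
  geo <- (g$fp * A * (1 - (2 / 3) * sA) + (g$f * g$dA0 / 3) * sA^3) / hp$rho
  fric + geo
}

.fluxB <- function(A, g, hp) g$f * A^1.5 / (3 * hp$rho * sqrt(g$A0))

# quadratic (3-point Lagrange) interpolation of y(x) at x0
.quad_interp <- function(xs, ys, x0) {
  l1 <- (x0 - xs[2]) * (x0 - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3]))
  l2 <- (x0 - xs[1]) * (x0 - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3]))
  l3 <- (x0 - xs[1]) * (x0 - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2]))
  ys[1] * l1 + ys[2] * l2 + ys[3] * l3
}

# precomputed geometry slice for one vessel end (3 nodes nearest the
# boundary, plus the boundary node's wall constants)
.boundary_slice <- function(geo, side) {
  M <- geo$M
  idx <- if (side == "out") (M - 2L):M else 1:3
  g <- geo$n
  gs <- list(r0 = g$r0[idx], A0 = g$A0[idx], f = g$f[idx], fp = g$fp[idx],
             dA0 = g$dA0[idx], cc0 = g$cc0[idx])
  b <- if (side == "out") 3L else 1L
  list(idx = idx, xs = geo$x[idx], gs = gs, b = b, side = side,
       A0 = gs$A0[b], f = gs$f[b], cc0 = gs$cc0[b])
}

# outgoing-characteristic target at a vessel end.
# side = "out": W+ = u + 4c at x = L;  side = "in": W- = u - 4c at x = 0.
# With `new` (an (A, q) estimate of the boundary state at t^{n+1}) the
# characteristic is integrated by the trapezoidal (Heun) rule — foot
# located with the averaged slope, source averaged between the foot and
# the new boundary state — keeping the closure second-order accurate;
# without it the explicit (predictor) target is returned.
.char_target <- function(A, q, bs, hp, delta, dt, new = NULL) {
  Ai <- A[bs$idx]; qi <- q[bs$idx]
  u <- qi / Ai
  cc <- bs$gs$cc0 * Ai^0.25
  sgn <- if (bs$side == "out") 1 else -1
  W <- u + sgn * 4 * cc
  srcA <- .source2(Ai, qi, bs$gs, hp, delta) / Ai
  b <- bs$b
  lam_old <- u[b] + sgn * cc[b]
  if (is.null(new)) {
    x0 <- bs$xs[b] - lam_old * dt
    return(.quad_interp(bs$xs, W, x0) + dt * .quad_interp(bs$xs, srcA, x0))
  }
  gb <- lapply(bs$gs, function(z) z[b])
  lam_new <- new$q / new$A + sgn * bs$gs$cc0[b] * new$A^0.25
  x0 <- bs$xs[b] - 0.5 * (lam_old + lam_new) * dt
  src_new <- .source2(new$A, new$q, gb, hp, delta) / new$A
  .quad_interp(bs$xs, W, x0) +
    dt / 2 * (.quad_interp(bs$xs, srcA, x0) + src_new)
}

#' Solve pulsatile flow in a labeled tree of large vessels
#'
#' Runs the two-step Lax-Wendroff scheme over up to `params$cycles`
#' cardiac cycles (stopping early once the period-to-period change drops
#' below `params$period_tol`) and returns the final period.
#'
#' @param tree a `labeled_tree` whose vessels carry `radius` summaries
#'   (from [extract_tree_radii()]), or constant radii supplied via
#'   `radii`.
#' @param inflow a `flow_waveform` (see [make_inflow_waveform()]) or a
#'   function of time returning the root inflow (cm^3/s); non-periodic
#'   tables are resampled onto the period.
#' @param params a [hemo_params()].
#' @param outflow `"structured"` (structured-tree impedance at every
#'   terminal, using `st_params`), `"resistance"` (constant resistances in
#'   `outflow_R`), or a named list of `impedance_spectrum` functions of
#'   omega per terminal id.
#' @param st_params a [structured_tree_params()] for `"structured"`.
#' @param outflow_R named numeric vector of terminal resistances
#'   (g/cm^4/s) for `"resistance"`.
#' @param radii optional named vector/list overriding each vessel's
#'   radius (scalar, or c(r_in, r_out)).
#' @param lengths optional named vector overriding vessel lengths (cm).
#' @param ramp_frac inflow ramp-up fraction of the first cycle.
#' @return object of class `hemo_solution`: per-vessel `x`, `t`, `p`
#'   (mmHg), `q` (cm^3/s), `A` (cm^2) over the final period, plus
#'   `periodicity` (per-cycle convergence trace), `dt`, `n_t`,
#'   `cycles_run`, and the impedance kernels used.
#' @export
solve_large_vessels <- function(tree, inflow, params = hemo_params(),
                                outflow = "structured",
                                st_params = structured_tree_params(),
                                outflow_R = NULL, radii = NULL, lengths = NULL,
                                ramp_frac = 0.25) {
  hp <- params
  ids <- names(tree$vessels)
  qin <- if (inherits(inflow, "flow_waveform")) inflow$fun
         else if (is.function(inflow)) inflow
         else waveform_function(inflow$t, inflow$q, hp$T)

  # radius/length per vessel
  r_of <- function(id) {
    if (!is.null(radii) && !is.null(radii[[id]])) return(as.numeric(radii[[id]]))
    rs <- tree$vessels[[id]]$radius
    if (!is.null(rs)) return(as.numeric(rs$r_hat))
    mean(tree$vessels[[id]]$points$r)
  }
  L_of <- function(id) {
    if (!is.null(lengths) && !is.null(lengths[[id]])) return(lengths[[id]])
    tree$vessels[[id]]$length
  }

  geos <- lapply(ids, function(id)
    .vessel_geometry(r_of(id), L_of(id), hp$grid, hp))
  names(geos) <- ids
  delta <- sqrt((hp$mu_L / hp$rho) * hp$T / (2 * pi))
  p0c <- hp$p0 * MMHG

  terminals <- ids[vapply(tree$vessels, function(v)
    length(v$daughter_ids) == 0L, TRUE)]
  junction_parents <- ids[vapply(tree$vessels, function(v)
    length(v$daughter_ids) > 0L, TRUE)]

  # time step from the CFL bound on the initial characteristic speed,
  # halved and the run restarted if the bound is violated mid-run
  c0max <- max(vapply(geos, function(g) max(g$n$cc0 * g$n$A0^0.25), 1.0))
  u_est <- max(abs(qin(seq(0, hp$T, length.out = 200)))) /
    min(vapply(geos, function(g) min(g$n$A0), 1.0))
  dxmin <- min(vapply(geos, function(g) g$dx, 1.0))
  for (attempt in 1:4) {
    dt0 <- hp$cfl_safety * dxmin / ((c0max * 1.15 + u_est) * 2^(attempt - 1))
    n_t <- as.integer(ceiling(hp$T / dt0))
    dt <- hp$T / n_t

    # outflow kernels on this time grid
    kernels <- list()
    for (tid in terminals) {
      rh <- r_of(tid)
      r_out <- if (length(rh) > 1L) rh[2] else rh
      kernels[[tid]] <- if (identical(outflow, "structured")) {
        impedance_kernel(function(om)
          root_impedance(r_out, st_params, hp, om)$Z,
          hp$T, n_t, hp$n_modes)
      } else if (identical(outflow, "resistance")) {
        if (is.null(outflow_R[[tid]])) stop("missing outflow resistance for ", tid)
        c(outflow_R[[tid]], rep(0, n_t - 1L))
      } else {
        impedance_kernel(outflow[[tid]], hp$T, n_t, hp$n_modes)
      }
    }

    res <- tryCatch(
      .run_lw(tree, geos, kernels, qin, hp, dt, n_t, delta, p0c,
              terminals, junction_parents, ramp_frac),
      error = function(e) {
        if (grepl("CFL", conditionMessage(e))) {
          message("CFL bound violated; halving the time step and restarting")
          NULL
        } else stop(e)
      })
    if (!is.null(res)) return(res)
  }
  stop("solver blow-up: CFL bound could not be satisfied")
}

.run_lw <- function(tree, geos, kernels, qin, hp, dt, n_t, delta, p0c,
                    terminals, junction_parents, ramp_frac) {
  ids <- names(geos)
  M <- hp$grid
  # state
  A <- lapply(geos, function(g) g$n$A0)
  q <- lapply(geos, function(g) rep(0, M))
  # recording arrays: current and previous cycle
  rec <- lapply(geos, function(g) list(A = matrix(NA_real_, M, n_t),
                                       q = matrix(NA_real_, M, n_t)))
  prev <- NULL
  qbuf <- lapply(terminals, function(t) rep(0, n_t))
  names(qbuf) <- terminals
  bin <- lapply(geos, .boundary_slice, side = "in")
  bout <- lapply(geos, .boundary_slice, side = "out")
  periodicity <- numeric(0)
  ramp_T <- ramp_frac * hp$T
  gstep <- 0L
  cycles_run <- 0L

  for (cyc in seq_len(hp$cycles)) {
    for (n in seq_len(n_t)) {
      t_old <- (cyc - 1L) * hp$T + (n - 1L) * dt
      t_new <- t_old + dt
      ramp <- function(tt) if (tt < ramp_T) tt / ramp_T else 1
      q_in_new <- qin(t_new) * ramp(t_new)

      halfA <- vector("list", length(ids)); names(halfA) <- ids
      halfq <- halfA
      newA <- halfA; newq <- halfA
      # interior update per vessel
      for (id in ids) {
        g <- geos[[id]]
        Av <- A[[id]]; qv <- q[[id]]
        if (any(Av <= 0)) stop("solver blow-up: negative area in ", id)
        dx <- g$dx
        F2 <- qv^2 / Av + .fluxB(Av, g$n, hp)
        Amid <- (Av[-1] + Av[-M]) / 2
        Ah <- Amid - dt / (2 * dx) * (qv[-1] - qv[-M])
        qmid <- (qv[-1] + qv[-M]) / 2
        Sh <- .source2(Amid, qmid, g$h, hp, delta)
        qh <- qmid - dt / (2 * dx) * (F2[-1] - F2[-M]) + dt / 2 * Sh
        if (any(Ah <= 0)) stop("solver blow-up: negative area in ", id)
        F2h <- qh^2 / Ah + .fluxB(Ah, g$h, hp)
        Sn <- .source2((Ah[-1] + Ah[-(M - 1L)]) / 2,
                       (qh[-1] + qh[-(M - 1L)]) / 2,
                       lapply(g$n, function(z) if (length(z) > 1) z[2:(M - 1L)] else z),
                       hp, delta)
        Anew <- Av; qnew <- qv
        Mm <- M - 1L
        Anew[2:Mm] <- Av[2:Mm] - dt / dx * (qh[-1] - qh[-Mm])
        qnew[2:Mm] <- qv[2:Mm] - dt / dx * (F2h[-1] - F2h[-Mm]) + dt * Sn
        halfA[[id]] <- Ah; halfq[[id]] <- qh
        newA[[id]] <- Anew; newq[[id]] <- qnew
      }

      # inlet of the root: prescribed flow + outgoing W- characteristic
      rid <- tree$root_id
      WmT0 <- .char_target(A[[rid]], q[[rid]], bin[[rid]], hp, delta, dt)
      Ain <- .newton_A_inlet(q_in_new, WmT0, bin[[rid]], A[[rid]][1])
      WmT0 <- .char_target(A[[rid]], q[[rid]], bin[[rid]], hp, delta, dt,
                           new = list(A = Ain, q = q_in_new))
      Ain <- .newton_A_inlet(q_in_new, WmT0, bin[[rid]], Ain)
      newA[[rid]][1] <- Ain
      newq[[rid]][1] <- q_in_new

      # junctions: parent outlet + daughter inlets
      for (pid in junction_parents) {
        dids <- tree$vessels[[pid]]$daughter_ids
        WpT <- .char_target(A[[pid]], q[[pid]], bout[[pid]], hp, delta, dt)
        WmT <- vapply(dids, function(d)
          .char_target(A[[d]], q[[d]], bin[[d]], hp, delta, dt), 1.0)
        egp <- bout[[pid]]
        egd <- bin[dids]
        sol <- .newton_junction(WpT, WmT, egp, egd,
                                A[[pid]][M], q[[pid]][M],
                                vapply(dids, function(d) A[[d]][1], 1.0),
                                vapply(dids, function(d) q[[d]][1], 1.0),
                                p0c)
        WpT <- .char_target(A[[pid]], q[[pid]], bout[[pid]], hp, delta, dt,
                            new = list(A = sol$Ap, q = sol$qp))
        WmT <- vapply(seq_along(dids), function(j)
          .char_target(A[[dids[j]]], q[[dids[j]]], bin[[dids[j]]], hp, delta,
                       dt, new = list(A = sol$Ad[j], q = sol$qd[j])), 1.0)
        sol <- .newton_junction(WpT, WmT, egp, egd, sol$Ap, sol$qp,
                                sol$Ad, sol$qd, p0c)
        newA[[pid]][M] <- sol$Ap; newq[[pid]][M] <- sol$qp
        for (j in seq_along(dids)) {
          newA[[dids[j]]][1] <- sol$Ad[j]
          newq[[dids[j]]][1] <- sol$qd[j]
        }
      }

      # terminal outlets: impedance convolution
      gnew <- gstep + 1L
      conv_idx <- if (n_t > 1L) ((gnew - seq_len(n_t - 1L)) %% n_t) + 1L else integer()
      for (tid in terminals) {
        WpT <- .char_target(A[[tid]], q[[tid]], bout[[tid]], hp, delta, dt)
        eg <- bout[[tid]]
        z <- kernels[[tid]]
        buf <- qbuf[[tid]]
        hist <- if (n_t > 1L) sum(z[2:n_t] * buf[conv_idx]) else 0
        sol <- .newton_outlet(WpT, z[1], hist, eg, p0c,
                              A[[tid]][M], q[[tid]][M])
        WpT <- .char_target(A[[tid]], q[[tid]], bout[[tid]], hp, delta, dt,
                            new = list(A = sol$A, q = sol$q))
        sol <- .newton_outlet(WpT, z[1], hist, eg, p0c, sol$A, sol$q)
        newA[[tid]][M] <- sol$A; newq[[tid]][M] <- sol$q
        buf[(gnew %% n_t) + 1L] <- sol$q
        qbuf[[tid]] <- buf
      }

      # commit + CFL check
      maxco <- 0
      for (id in ids) {
        Av <- newA[[id]]
        if (any(!is.finite(Av)) || any(Av <= 0))
          stop("solver blow-up: negative area in ", id)
        A[[id]] <- Av; q[[id]] <- newq[[id]]
        sp <- max(abs(newq[[id]] / Av) + geos[[id]]$n$cc0 * Av^0.25)
        maxco <- max(maxco, sp * dt / geos[[id]]$dx)
        rec[[id]]$A[, n] <- Av
        rec[[id]]$q[, n] <- newq[[id]]
      }
      if (maxco > 1) stop("CFL bound violated")
      gstep <- gstep + 1L
    }
    cycles_run <- cyc
    if (!is.null(prev)) {
      periodicity <- c(periodicity, .cycle_change(rec, prev))
      if (periodicity[length(periodicity)] < hp$period_tol && cyc >= 3L) break
    }
    prev <- lapply(rec, function(r) list(A = r$A, q = r$q))
  }

  vessels <- lapply(ids, function(id) {
    g <- geos[[id]]
    pmat <- (pressure_from_area(rec[[id]]$A,
                                matrix(g$n$A0, M, n_t),
                                matrix(g$n$f, M, n_t), p0c)) / MMHG
    list(x = g$x, t = seq_len(n_t) * dt, p = pmat, q = rec[[id]]$q,
         A = rec[[id]]$A)
  })
  names(vessels) <- ids
  structure(list(vessels = vessels, dt = dt, n_t = n_t,
                 cycles_run = cycles_run, periodicity = periodicity,
                 kernels = kernels, params = hp, root_id = tree$root_id,
                 terminals = terminals),
            class = "hemo_solution")
}

.cycle_change <- function(rec, prev) {
  mx <- 0
  for (id in names(rec)) {
    for (f in c("A", "q")) {
      dn <- sqrt(sum((rec[[id]][[f]] - prev[[id]][[f]])^2))
      rn <- sqrt(sum(prev[[id]][[f]]^2))
      # absolute floor keeps the metric meaningful for fields at rest
      mx <- max(mx, dn / (rn + 1e-6 * sqrt(length(prev[[id]][[f]]))))
    }
  }
  mx
}

# Newton solves ---------------------------------------------------------------

.newton_A_inlet <- function(qn, Wm, eg, A_start) {
  A <- A_start
  for (it in 1:60) {
    cc <- eg$cc0 * A^0.25
    r <- qn / A - 4 * cc - Wm
    dr <- -qn / A^2 - cc / A
    step <- r / dr
    A_new <- A - step
    if (A_new <= 0) A_new <- A / 2
    A <- A_new
    if (abs(step) < 1e-12 * max(1, A)) break
  }
  A
}

.newton_outlet <- function(WpT, z0, hist, eg, p0c, A_start, q_start) {
  A <- A_start; q <- q_start
  for (it in 1:60) {
    cc <- eg$cc0 * A^0.25
    r1 <- q / A + 4 * cc - WpT
    r2 <- pressure_from_area(A, eg$A0, eg$f, p0c) - (z0 * q + hist)
    J11 <- -q / A^2 + cc / A;            J12 <- 1 / A
    J21 <- eg$f / (2 * sqrt(A * eg$A0)); J22 <- -z0
    det <- J11 * J22 - J12 * J21
    dA <- (r1 * J22 - r2 * J12) / det
    dq <- (J11 * r2 - J21 * r1) / det
    lam <- 1
    while (A - lam * dA <= 0) lam <- lam / 2
    A <- A - lam * dA; q <- q - lam * dq
    if (max(abs(dA) / max(A, 1e-12), abs(dq)) < 1e-12) break
  }
  list(A = A, q = q)
}

.newton_junction <- function(WpT, WmT, egp, egd, Ap, qp, Ad, qd, p0c) {
  k <- length(WmT)
  u <- c(Ap, qp, rbind(Ad, qd))             # (Ap,qp,A1,q1,A2,q2,...)
  scale_p <- egp$f
  resid <- function(u) {
    Ap <- u[1]; qp <- u[2]
    Ad <- u[2 + 2 * seq_len(k) - 1]; qd <- u[2 + 2 * seq_len(k)]
    ccp <- egp$cc0 * Ap^0.25
    r <- numeric(2 * k + 2)
    r[1] <- qp / Ap + 4 * ccp - WpT
    pp <- pressure_from_area(Ap, egp$A0, egp$f, p0c)
    for (i in seq_len(k)) {
      ccd <- egd[[i]]$cc0 * Ad[i]^0.25
      r[1 + i] <- qd[i] / Ad[i] - 4 * ccd - WmT[i]
      r[1 + k + i] <- (pp - pressure_from_area(Ad[i], egd[[i]]$A0,
                                               egd[[i]]$f, p0c)) / scale_p
    }
    r[2 * k + 2] <- qp - sum(qd)
    r
  }
  jac <- function(u) {
    Ap <- u[1]; qp <- u[2]
    Ad <- u[2 + 2 * seq_len(k) - 1]; qd <- u[2 + 2 * seq_len(k)]
    J <- matrix(0, 2 * k + 2, 2 * k + 2)
    ccp <- egp$cc0 * Ap^0.25
    J[1, 1] <- -qp / Ap^2 + ccp / Ap
    J[1, 2] <- 1 / Ap
    dppdA <- egp$f / (2 * sqrt(Ap * egp$A0))
    for (i in seq_len(k)) {
      ai <- 2 + 2 * i - 1; qi <- 2 + 2 * i
      ccd <- egd[[i]]$cc0 * Ad[i]^0.25
      J[1 + i, ai] <- -qd[i] / Ad[i]^2 - ccd / Ad[i]
      J[1 + i, qi] <- 1 / Ad[i]
      J[1 + k + i, 1] <- dppdA / scale_p
      J[1 + k + i, ai] <- -egd[[i]]$f / (2 * sqrt(Ad[i] * egd[[i]]$A0)) / scale_p
      J[2 * k + 2, qi] <- -1
    }
    J[2 * k + 2, 2] <- 1
    J
  }
  r <- resid(u)
  for (it in 1:60) {
    if (max(abs(r)) < 1e-11) break
    du <- tryCatch(solve(jac(u), r), error = function(e) NULL)
    if (is.null(du)) stop("junction Newton: singular Jacobian")
    lam <- 1
    repeat {
      u_try <- u - lam * du
      if (all(u_try[c(1, 2 + 2 * seq_len(k) - 1)] > 0)) {
        r_try <- resid(u_try)
        if (max(abs(r_try)) <= max(abs(r)) || lam < 1 / 64) {
          u <- u_try; r <- r_try; break
        }
      }
      lam <- lam / 2
      if (lam < 1e-6) { u <- u - lam * du; r <- resid(u); break }
    }
  }
  list(Ap = u[1], qp = u[2],
       Ad = u[2 + 2 * seq_len(k) - 1], qd = u[2 + 2 * seq_len(k)])
}

# ---- solution utilities -----------------------------------------------------

#' Midpoint pressure/flow time series of one vessel
#'
#' @param sol a `hemo_solution`.
#' @param id vessel id.
#' @return data.frame with t (s), p (mmHg), q (cm^3/s).
#' @export
midpoint_series <- function(sol, id) {
  v <- sol$vessels[[id]]
  j <- ceiling(length(v$x) / 2)
  data.frame(t = v$t, p = v$p[j, ], q = v$q[j, ])
}

#' Maximum relative period-to-period change of a run
#'
#' The convergence trace recorded by [solve_large_vessels()]: for each
#' pair of consecutive cycles, the maximum over vessels of the relative
#' L2 difference between the two periods.  Returns the trace; the last
#' entry is the achieved periodicity.
#'
#' @param sol a `hemo_solution` run for at least 2 cycles.
#' @return numeric vector of per-cycle changes.
#' @export
periodicity_check <- function(sol) {
  if (!length(sol$periodicity))
    stop("periodicity requires at least 2 computed cycles")
  sol$periodicity
}

#' @export
print.hemo_solution <- function(x, ...) {
  cat("hemo_solution:", length(x$vessels), "vessels,", x$cycles_run,
      "cycles, dt =", format(x$dt, digits = 4), "s,",
      "periodicity =", format(utils::tail(x$periodicity, 1), digits = 3), "\n")
  invisible(x)
}
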