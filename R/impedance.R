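# ---- frequency-domain impedance of structured trees ------------------------
#
# In vessels below image resolution viscous forces dominate; the 1D
# equations are linearized and solved per frequency, giving each vessel a
# transmission-line relation between its inlet impedance Z(0, w) and its
# outlet impedance Z(L, w).  Junctions combine daughters in parallel
# admittance, so the impedance at the root of a structured tree is
# computed by a recursion from the leaves, and serves as the outflow
# boundary condition of the large-vessel solver.

#' Ratio J1(z)/J0(z) of Bessel functions at complex argument
#'
#' Evaluated by the modified Lentz continued fraction derived from the
#' three-term recurrence (robust for all arguments away from zeros of J0,
#' no overflow), vectorized over `z`.  Used for the oscillatory viscous
#' (Womersley) term of the linearized momentum equation; no installed
#' package evaluates Bessel J at complex argument.
#'
#' @param z complex vector.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return complex vector J1(z)/J0(z).
#' @export
bessel_j1_over_j0 <- function(z, tol = 1e-14, max_iter = 10000L) {
  # r0 = J1/J0 with r_{nu-1} = 1/(2*nu/z - r_nu):
  # continued fraction r0 = 1/(2/z - 1/(4/z - 1/(6/z - ...)))
  n <- length(z)
  tiny <- 1e-30 + 0i
  f <- rep(tiny, n)
  C <- f
  D <- rep(0 + 0i, n)
  done <- rep(FALSE, n)
  zero <- which(z == 0)
  for (it in seq_len(max_iter)) {
    b <- 2 * it / z
    a <- if (it == 1L) 1 + 0i else -1 + 0i
    D <- b + a * D
    D[D == 0] <- tiny
    C <- b + a / C
    C[C == 0] <- tiny
    D <- 1 / D
    delta <- C * D
    f <- f * delta
    done <- done | abs(delta - 1) < tol
    if (all(done)) break
  }
  f[zero] <- 0 + 0i
  f
}

#' Womersley viscous term F_J
#'
#' `F_J = 2 J1(w0) / (w0 J0(w0))` with `w0^2 = i^3 r0^2 w / nu`
#' (equivalently `w0 = i^{3/2} r0 sqrt(w/nu)`).
#'
#' @param r0 vessel radius (cm).
#' @param omega angular frequency vector (rad/s), all > 0.
#' @param nu kinematic viscosity (cm^2/s).
#' @return complex vector F_J(omega).
#' @export
womersley_fj <- function(r0, omega, nu) {
  w0 <- exp(3i * pi / 4) * r0 * sqrt(omega / nu)
  2 * bessel_j1_over_j0(w0) / w0
}

# inlet impedance of a single small vessel given its outlet impedance ZL
# (vectors over the omega grid; omega = 0 entries take the Poiseuille limit)
.vessel_inlet_impedance <- function(r0, omega, ZL, st, hemo) {
  mu <- small_vessel_viscosity(r0, hemo$mu_L)
  l <- st$lrr * r0
  A0 <- pi * r0^2
  Ehr <- st$k1S * exp(st$k2S * r0) + st$k3S
  CA <- 1.5 * A0 / Ehr                     # area compliance dA/dp
  Z <- complex(length(omega))
  i0 <- omega == 0
  if (any(i0)) Z[i0] <- 8 * mu * l / (pi * r0^4) + ZL[i0]
  if (any(!i0)) {
    w <- omega[!i0]
    FJ <- womersley_fj(r0, w, mu / hemo$rho)
    cc <- sqrt(A0 * (1 - FJ) / (hemo$rho * CA))
    g <- cc * CA
    th <- w * l / cc
    Zl <- ZL[!i0]
    Z[!i0] <- (1i * sin(th) / g + Zl * cos(th)) /
              (cos(th) + 1i * g * Zl * sin(th))
  }
  Z
}

#' Root impedance spectrum of a structured tree
#'
#' Computes Z(0, w) at the root of the asymmetric structured tree grown
#' from `r_root`, over the angular frequencies `omega`.  Leaves carry the
#' terminal impedance `z_terminal` (0 = pure outflow, the default);
#' junctions combine daughters by parallel admittance; each vessel maps
#' its outlet impedance to its inlet through the transmission-line
#' solution of the linearized system, with wave speed
#' `c = sqrt(A0 (1 - F_J) / (rho C_A))` and admittance `g = c C_A`.
#' At w = 0 the exact limit is the Poiseuille resistance
#' `8 mu_S l / (pi r0^4)` in series per vessel.  The self-similar tree is
#' traversed once per distinct scale pair (j applications of alpha, k of
#' beta), with memoization.
#'
#' @param r_root structured-tree root radius (cm).
#' @param st a [structured_tree_params()].
#' @param hemo a list with at least `rho` and `mu_L` (see [hemo_params()]).
#' @param omega angular frequency vector (rad/s), >= 0.
#' @param z_terminal impedance at the structured-tree leaves
#'   (g/cm^4/s; scalar, default 0).
#' @return object of class `impedance_spectrum`: list with `omega`, `Z`
#'   (complex), `r_root`.
#' @export
root_impedance <- function(r_root, st, hemo, omega, z_terminal = 0) {
  stopifnot(all(omega >= 0), r_root >= st$r_min)
  memo <- new.env(parent = emptyenv())
  zterm <- rep(z_terminal + 0i, length(omega))
  recurse <- function(j, k) {
    key <- paste0(j, "_", k)
    if (exists(key, envir = memo, inherits = FALSE)) return(memo[[key]])
    r <- r_root * st$alpha^j * st$beta^k
    ra <- r * st$alpha
    rb <- r * st$beta
    ZL <- if (ra >= st$r_min && rb >= st$r_min) {
      Za <- recurse(j + 1, k)
      Zb <- recurse(j, k + 1)
      1 / (1 / Za + 1 / Zb)
    } else if (ra >= st$r_min) {
      recurse(j + 1, k)
    } else zterm
    Z <- .vessel_inlet_impedance(r, omega, ZL, st, hemo)
    memo[[key]] <- Z
    Z
  }
  Z <- recurse(0, 0)
  structure(list(omega = omega, Z = Z, r_root = r_root), class = "impedance_spectrum")
}

#' Constant (purely resistive) impedance spectrum
#'
#' @param R resistance (g/cm^4/s).
#' @param omega angular frequency vector.
#' @return an `impedance_spectrum`.
#' @export
resistive_impedance <- function(R, omega) {
  structure(list(omega = omega, Z = rep(R + 0i, length(omega)), r_root = NA),
            class = "impedance_spectrum")
}

#' Periodic time-domain impedance kernel
#'
#' Inverse DFT of the spectrum onto the solver's time grid of `n_t` steps
#' per period: `z_m` such that `p^n = sum_m z_m q^{n-m}` reproduces
#' `P = Z Q` mode by mode.  The spectrum is evaluated at
#' `omega_k = 2 pi k / T` for k = 0..min(n_modes, n_t/2); modes above
#' `n_modes` are held at the plateau value Z(n_modes) (the spectrum of a
#' structured tree flattens at high frequency), and negative frequencies
#' are the complex conjugates, so the kernel is real.
#'
#' @param zfun function(omega) returning the complex impedance vector, or
#'   an `impedance_spectrum` evaluated on exactly the needed grid.
#' @param T period (s).
#' @param n_t time steps per period.
#' @param n_modes number of explicitly evaluated modes (default 128).
#' @return numeric kernel vector of length `n_t` (index m = 0..n_t-1).
#' @export
impedance_kernel <- function(zfun, T, n_t, n_modes = 128L) {
  kmax <- floor(n_t / 2)
  keval <- 0:min(n_modes, kmax)
  omega <- 2 * pi * keval / T
  Zk <- if (is.function(zfun)) zfun(omega) else {
    stopifnot(length(zfun$Z) >= length(keval))
    zfun$Z[seq_along(keval)]
  }
  Zfull <- complex(n_t)
  Zfull[keval + 1L] <- Zk
  # tail band above n_modes: a transmission line tends to its (real)
  # characteristic impedance at high frequency, so the unevaluated modes
  # take the real part of the last evaluated one; carrying its reactive
  # part across the whole tail band would make the discrete boundary
  # condition non-passive
  if (max(keval) < kmax)
    Zfull[(max(keval) + 2L):(kmax + 1L)] <- Re(Zk[length(Zk)])
  # conjugate symmetry for k = n_t - 1 .. kmax+1
  for (k in seq_len(n_t - kmax - 1L))
    Zfull[n_t - k + 1L] <- Conj(Zfull[k + 1L])
  z <- Re(stats::fft(Zfull, inverse = TRUE)) / n_t
  z
}
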