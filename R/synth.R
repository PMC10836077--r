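# ---- seeded synthetic centerline generators --------------------------------
#
# These emulate what maximally-inscribed-sphere centerline extraction
# produces on real vascular surfaces: inflated radii in the ostium region,
# piecewise radius structure along the vessel, resolution noise, and
# junction split-points placed upstream of the true ostium with
# near-coincident daughter prefixes.  Every generator is pure given its
# seed and returns the ground truth needed to score downstream stages.

#' Generate a synthetic radius sequence with known ground truth
#'
#' The profile is (optionally) an ostium bump over the first
#' `ostium_frac` of the nodes held flat at `ostium_scale` times the plateau,
#' followed by a short linear transition ramp down to the plateau, then the
#' plateau itself (constant, or decaying exponentially when
#' `taper_ratio < 1`), with iid Gaussian noise of sd `noise_sd` added.
#'
#' @param n node count.
#' @param base_radius plateau radius (cm).
#' @param taper_ratio r_out/r_in over the plateau region; 1 = no taper.
#' @param ostium_frac fraction of initial nodes carrying junction-inflated
#'   radii (0 disables the bump).
#' @param ostium_scale multiplicative bump height (e.g. 1.5).
#' @param transition_frac fraction of nodes in the bump-to-plateau ramp.
#' @param noise_sd radius noise sd (cm).
#' @param seed integer seed.
#' @return list with `r` (radius sequence), and ground truth fields:
#'   `truth_radius` (plateau value, or c(r_in, r_out) when tapering),
#'   `breakpoints` (true change indices), `plateau_range` (node interval of
#'   uncontaminated plateau), `noise_sd`.
#' @export
make_synthetic_vessel <- function(n, base_radius = 0.5, taper_ratio = 1,
                                  ostium_frac = 0, ostium_scale = 1.5,
                                  transition_frac = 0.05,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(n >= 4, ostium_frac >= 0, ostium_frac < 1, noise_sd >= 0,
            base_radius > 0, taper_ratio > 0)
  set.seed(as.integer(seed))
  b <- if (ostium_frac > 0) max(2L, round(ostium_frac * n)) else 0L
  trans <- if (ostium_frac > 0) max(2L, round(transition_frac * n)) else 0L
  if (b + trans >= n - 2L) stop("inconsistent spec: ostium occupies the vessel")
  prof <- numeric(n)
  plateau_start <- b + trans + 1L
  idx_pl <- plateau_start:n
  s <- (idx_pl - plateau_start) / max(1L, (n - plateau_start))
  plateau <- base_radius * exp(s * log(taper_ratio))
  prof[idx_pl] <- plateau
  if (b > 0L) {
    prof[1:b] <- ostium_scale * base_radius
    # linear ramp from bump level down to the first plateau value
    prof[(b + 1L):(b + trans)] <-
      seq(ostium_scale * base_radius, plateau[1L],
          length.out = trans + 2L)[2:(trans + 1L)]
  }
  r <- prof + rnorm(n, 0, noise_sd)
  r[r <= 0] <- 1e-6
  bp <- if (b > 0L) c(b, b + trans) else integer()
  list(r = r,
       truth_radius = if (taper_ratio == 1) base_radius
                      else c(r_in = base_radius,
                             r_out = base_radius * taper_ratio),
       breakpoints = bp,
       plateau_range = c(plateau_start, n),
       noise_sd = noise_sd)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic bifurcating network with an injected junction flaw
#'
#' Builds a binary network `levels` deep whose true radii follow the
#' asymmetric scaling (daughters alpha*r and beta*r).  Each vessel is a
#' straight polyline with node spacing `spacing`.  The centerline-extraction
#' flaw is emulated by shifting each junction split-point `junction_offset`
#' nodes upstream: the parent polyline is truncated early and each daughter
#' is prepended with `junction_offset` near-coincident nodes (lateral
#' jitter `jitter`) tracing the parent's remaining path, carrying inflated
#' ostium-like radii.  Beyond the true junction the daughters separate
#' quickly over `div_len` nodes and then continue at a gentler mutual
#' divergence, which is what centerlines of branching vessels look like.
#'
#' @param levels number of generations (1 = single vessel).
#' @param root_radius root vessel radius (cm).
#' @param alpha,beta daughter radius scale factors.
#' @param n_nodes nodes per vessel (beyond any prepended flaw nodes).
#' @param spacing node spacing along each vessel (cm); default 0.05.
#' @param junction_offset number of nodes the junction is shifted upstream.
#' @param jitter lateral half-distance between near-coincident daughter
#'   prefix nodes (cm).
#' @param div_len nodes over which daughters separate rapidly.
#' @param fast_step,slow_step lateral separation gained per node during and
#'   after the rapid-divergence phase (cm).
#' @param noise_sd radius noise sd (cm).
#' @param trifurcate id of one internal vessel to turn into a trifurcation
#'   (adds a third daughter with radius beta*r), or `NULL`.
#' @param seed integer seed.
#' @return list with `centerlines` (named list of x/y/z/r data.frames,
#'   flaw included), `true_radii` (named), `true_junctions` (data.frame of
#'   parent id and true junction x/y/z), `offset` and the generation ids.
#' @export
make_synthetic_network <- function(levels, root_radius = 0.5,
                                   alpha = 0.88, beta = 0.697,
                                   n_nodes = 30L, spacing = 0.05,
                                   junction_offset = 0L, jitter = 0.002,
                                   div_len = 4L, fast_step = 0.08,
                                   slow_step = 0.01,
                                   noise_sd = 0, trifurcate = NULL,
                                   seed = 1L) {
  stopifnot(levels >= 1)
  set.seed(as.integer(seed))
  centerlines <- list()
  true_r <- c()
  junctions <- list()

  noisy_r <- function(r, n) {
    x <- r + rnorm(n, 0, noise_sd)
    x[x <= 0] <- 1e-6
    x
  }

  # daughters share their first node with the parent's end node (how
  # centerline software reports junctions); they then separate quickly
  # over div_len nodes and drift apart gently afterwards
  build_children <- function(id, end, dir, r, level) {
    nd <- if (!is.null(trifurcate) && identical(id, trifurcate)) 3L else 2L
    ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    lat <- pracma_cross(dir, ref); lat <- lat / sqrt(sum(lat^2))
    scales <- c(alpha, beta, beta)[seq_len(nd)]
    sides <- c(1, -1, 0.35)[seq_len(nd)]
    junctions[[id]] <<- data.frame(parent = id, x = end[1], y = end[2],
                                   z = end[3])
    for (j in seq_len(nd)) {
      did <- paste0(id, ".", j)
      rd <- scales[j] * r
      s <- 0:(n_nodes - 1L)                 # s = 0 is the shared junction node
      lat_off <- sides[j] * 0.5 *
        (fast_step * pmin(s, div_len) + slow_step * pmax(s - div_len, 0))
      fwd <- spacing * s
      pts_d <- data.frame(
        x = end[1] + dir[1] * fwd + lat[1] * lat_off,
        y = end[2] + dir[2] * fwd + lat[2] * lat_off,
        z = end[3] + dir[3] * fwd + lat[3] * lat_off,
        r = noisy_r(rd, n_nodes))
      centerlines[[did]] <<- pts_d
      true_r[did] <<- rd
      if (level + 1 < levels) {
        m <- n_nodes
        dend <- as.numeric(pts_d[m, c("x", "y", "z")])
        dird <- dend - as.numeric(pts_d[m - 1, c("x", "y", "z")])
        dird <- dird / sqrt(sum(dird^2))
        build_children(did, dend, dird, rd, level + 1)
      }
    }
  }

  root_dir <- c(1, 0, 0)
  s <- 0:(n_nodes - 1L)
  pts <- data.frame(x = spacing * s, y = 0 * s, z = 0 * s,
                    r = noisy_r(root_radius, n_nodes))
  centerlines[["R"]] <- pts
  true_r["R"] <- root_radius
  if (levels > 1) {
    endR <- as.numeric(pts[n_nodes, c("x", "y", "z")])
    build_children("R", endR, root_dir, root_radius, 1L)
  }

  # inject the junction flaw: truncate each parent junction_offset nodes
  # early and prepend the removed span to every daughter as a
  # near-coincident (laterally jittered) prefix with inflated radii
  off <- as.integer(junction_offset)
  if (off > 0L) {
    for (pid in names(junctions)) {
      par <- centerlines[[pid]]
      np <- nrow(par)
      if (np <= off + 3L) next
      keep <- np - off
      span <- par[keep:(np - 1L), , drop = FALSE]   # keep..np-1 prepended
      centerlines[[pid]] <- par[1:keep, , drop = FALSE]
      dirp <- as.numeric(par[keep, c("x", "y", "z")]) -
        as.numeric(par[keep - 1L, c("x", "y", "z")])
      dirp <- dirp / sqrt(sum(dirp^2))
      ref <- if (abs(dirp[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      lat <- pracma_cross(dirp, ref); lat <- lat / sqrt(sum(lat^2))
      kids <- names(centerlines)[startsWith(names(centerlines), paste0(pid, ".")) &
        nchar(gsub("[^.]", "", names(centerlines))) ==
        nchar(gsub("[^.]", "", pid)) + 1L]
      for (k in seq_along(kids)) {
        did <- kids[k]
        side <- c(1, -1, 0.35)[k]
        pre <- span
        jit <- c(0, rep(side * jitter, nrow(pre) - 1L))  # first node shared
        pre$x <- pre$x + jit * lat[1]
        pre$y <- pre$y + jit * lat[2]
        pre$z <- pre$z + jit * lat[3]
        pre$r <- pre$r * 1.1                # ostium-like inflation
        d <- centerlines[[did]]
        centerlines[[did]] <- rbind(pre, d)
      }
    }
  }

  list(centerlines = centerlines,
       true_radii = true_r,
       true_junctions = if (length(junctions)) do.call(rbind, junctions)
                        else NULL,
       offset = off,
       spacing = spacing)
}

#' Periodic inflow waveform with a prescribed stroke volume
#'
#' Half-sine systole over `systole_frac * T` followed by zero diastole
#' (shape `"halfsine"`), a constant flow (`"constant"`), or an infinitely
#' smooth biased sinusoid (`"sine"`, used for grid-convergence studies
#' where a waveform with discontinuous derivatives would degrade the
#' observable order); the integral over one period equals `stroke_volume`
#' exactly.
#'
#' @param T cardiac period (s).
#' @param stroke_volume integral of q over one period (cm^3).
#' @param shape `"halfsine"`, `"constant"` or `"sine"`.
#' @param systole_frac systolic fraction of the period for `"halfsine"`.
#' @param n_samples number of samples in the returned table.
#' @return list of class `flow_waveform` with `t`, `q`, `T`, and `fun`, a
#'   periodic interpolating function of time.
#' @export
make_inflow_waveform <- function(T, stroke_volume,
                                 shape = c("halfsine", "constant", "sine"),
                                 systole_frac = 1 / 3, n_samples = 401L) {
  shape <- match.arg(shape)
  stopifnot(T > 0)
  ts <- systole_frac * T
  fun <- switch(shape,
    halfsine = {
      qmax <- stroke_volume * pi / (2 * ts)
      function(t) {
        tt <- t %% T
        ifelse(tt < ts, qmax * sin(pi * tt / ts), 0)
      }
    },
    constant = function(t) rep(stroke_volume / T, length(t)),
    sine = function(t) (stroke_volume / T) * (1 + 0.5 * sin(2 * pi * t / T))
  )
  tgrid <- seq(0, T, length.out = n_samples)
  structure(list(t = tgrid, q = fun(tgrid), T = T, fun = fun,
                 stroke_volume = stroke_volume, shape = shape),
            class = "flow_waveform")
}

#' Periodic interpolating flow function from a sampled waveform
#'
#' Used when an inflow is read from a two-column (t, q) table rather than
#' generated; linear interpolation, wrapped periodically.
#'
#' @param t,q sample times (s) and flows (cm^3/s) covering one period.
#' @param T the period (s); default `max(t)`.
#' @return function of time.
#' @export
waveform_function <- function(t, q, T = max(t)) {
  f <- stats::approxfun(t, q, rule = 2)
  function(tt) f(tt %% T)
}
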