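# ---- representative radius extraction (optimal segment r_opt) --------------
#
# The raw per-node radii of a vessel include ostium values (which mix
# parent and daughter lumens), surface-irregularity oscillations and
# near-resolution noise.  The representative radius is therefore estimated
# only from an optimal segment r_opt chosen by case rules on the
# change-point structure, then summarized as a constant (mean) or a
# decaying exponential taper, with a root-mean-square residual as its
# standard deviation.

#' Parameters of the optimal-segment selection rules
#'
#' @param min_frac minimum fraction of the vessel's nodes a single segment
#'   must contain to be selected outright (default 0.25).
#' @param mid_frac threshold on the position of the second change point in
#'   the start rule (default 0.5).
#' @param long_frac minimum node fraction for the longest-segment rule of
#'   tapering vessels (default 0.4).
#' @param xi slope-ratio threshold comparing the last two segments
#'   (default 2.8).
#' @param invert_sa_branch invert the end rule branch chosen by the slope
#'   ratio (sensitivity switch; default FALSE, as printed).
#' @param sa_absolute use absolute slopes in the slope ratio (default TRUE).
#' @return list of class `selection_params`.
#' @export
selection_params <- function(min_frac = 0.25, mid_frac = 0.5, long_frac = 0.4,
                             xi = 2.8, invert_sa_branch = FALSE,
                             sa_absolute = TRUE) {
  stopifnot(min_frac > 0, min_frac < mid_frac, mid_frac < 1, xi > 0)
  structure(list(min_frac = min_frac, mid_frac = mid_frac,
                 long_frac = long_frac, xi = xi,
                 invert_sa_branch = invert_sa_branch,
                 sa_absolute = sa_absolute),
            class = "selection_params")
}

#' Slope ratio comparing the last two segments
#'
#' `sa = |slp_{m+1} - slp_m| / |slp_m|`.  Absolute values make the ratio a
#' usable threshold statistic; set `absolute = FALSE` for the raw signed
#' ratio.
#'
#' @param slp_m slope of the second-to-last segment.
#' @param slp_m1 slope of the last segment.
#' @param absolute take absolute values (default TRUE).
#' @return `sa`; `+Inf` (flagged via attribute) when `slp_m` is 0.
#' @export
slope_ratio <- function(slp_m, slp_m1, absolute = TRUE) {
  if (slp_m == 0) {
    out <- Inf
    attr(out, "flag") <- "zero reference slope"
    return(out)
  }
  if (absolute) abs(slp_m1 - slp_m) / abs(slp_m)
  else (slp_m1 - slp_m) / slp_m
}

# start index of r_opt for Case 2 (shared by both algorithms)
.case2_start <- function(psi, n, params) {
  q1 <- n * params$min_frac
  if (psi[1] >= q1) return(psi[1])
  if (length(psi) >= 2L) {
    if (psi[2] > n * params$mid_frac) ceiling(q1) else psi[2]
  } else ceiling(q1)
}

# end index of r_opt for Case 2
.case2_end <- function(sf, psi, n, params) {
  m <- length(psi)
  slp_m <- sf$slope[m]        # second-to-last segment
  slp_m1 <- sf$slope[m + 1]   # last segment
  sa <- slope_ratio(slp_m, slp_m1, params$sa_absolute)
  take_psi <- (sa <= params$xi)
  if (params$invert_sa_branch) take_psi <- !take_psi
  if (take_psi) psi[m] else n
}

#' Optimal radius segment for non-tapering vessels
#'
#' Case 1: among the sections after the first change point, the one with
#' the smallest absolute slope, if it holds more than `min_frac` of the
#' nodes.  Case 2: start and end chosen from the change-point locations
#' (start at psi1 if beyond the 25% mark, else psi2 unless that lies past
#' the 50% mark, in which case the 25% mark; end at psi_m or n depending
#' on the slope ratio against xi).  Case 3: no change points — the whole
#' vessel.  The section before the first change point is never selected
#' (ostium exclusion).
#'
#' @param r radius sequence.
#' @param cp a `changepoint_result` computed on `r`.
#' @param params a [selection_params()].
#' @return list with `range` (c(first, last) node indices) and
#'   `case_label`.
#' @export
select_ropt_nontapering <- function(r, cp, params = selection_params()) {
  n <- length(r)
  if (cp$m == 0L || n < 4L)
    return(list(range = c(1L, n), case_label = "case3"))
  psi <- cp$psi
  sf <- cp$segment_fits
  # Case 1: smallest |slope| among sections 2..m+1
  cand <- 2:(cp$m + 1L)
  imin <- cand[which.min(abs(sf$slope[cand]))]
  npts <- sf$last[imin] - sf$first[imin] + 1L
  if (npts > params$min_frac * n)
    return(list(range = c(sf$first[imin], sf$last[imin]), case_label = "case1"))
  # Case 2
  lo <- .case2_start(psi, n, params)
  hi <- .case2_end(sf, psi, n, params)
  if (hi - lo + 1L < 2L) hi <- n          # degenerate interval guard
  if (hi - lo + 1L < 2L) return(list(range = c(1L, n), case_label = "case3"))
  list(range = c(as.integer(lo), as.integer(hi)), case_label = "case2")
}

#' Optimal radius segment for tapering vessels
#'
#' Case 1: the longest section after the first change point, if it holds
#' more than `long_frac` of the nodes.  Case 2: as the non-tapering rule.
#' Case 3: no change points — whole vessel, flagged non-tapering.
#' Case 4: anything else — exponential anchored at r(1) and r(n) over the
#' whole vessel.
#'
#' @inheritParams select_ropt_nontapering
#' @return list with `range`, `case_label`, and `taper` (FALSE for Case 3).
#' @export
select_ropt_tapering <- function(r, cp, params = selection_params()) {
  n <- length(r)
  if (cp$m == 0L || n < 4L)
    return(list(range = c(1L, n), case_label = "case3", taper = FALSE))
  sf <- cp$segment_fits
  cand <- 2:(cp$m + 1L)                    # ostium exclusion
  len <- sf$last[cand] - sf$first[cand] + 1L
  imax <- cand[which.max(len)]
  if (max(len) > params$long_frac * n)
    return(list(range = c(sf$first[imax], sf$last[imax]),
                case_label = "case1", taper = TRUE))
  lo <- .case2_start(cp$psi, n, params)
  hi <- .case2_end(sf, cp$psi, n, params)
  if (hi - lo + 1L >= 3L)
    return(list(range = c(as.integer(lo), as.integer(hi)),
                case_label = "case2", taper = TRUE))
  list(range = c(1L, n), case_label = "case4", taper = TRUE)
}

#' Constant representative radius over the optimal segment
#'
#' @param r radius sequence.
#' @param range c(first, last) node interval.
#' @return the mean radius over the interval (assigned to every node of
#'   the vessel by the callers).
#' @export
constant_radius <- function(r, range) {
  mean(r[range[1]:range[2]])
}

#' Fit a decaying exponential taper over the optimal segment
#'
#' Model `r(s) = r_in * exp(s * log(r_out/r_in))` with s the normalized
#' position in [0, 1] across the segment, so r(0) = r_in and r(1) = r_out.
#' Parameters minimize the mean squared error by Nelder-Mead started at
#' the segment's endpoint radii; non-positive iterates are rejected.
#'
#' @param r radius sequence.
#' @param range c(first, last), at least 3 nodes.
#' @return list with `r_in`, `r_out`, `se` (approximate standard errors
#'   from the Gauss-Newton normal equations), `converged`, `flag`.
#' @export
fit_exponential_taper <- function(r, range) {
  idx <- range[1]:range[2]
  k <- length(idx)
  if (k < 3L) stop("taper fit needs at least 3 nodes")
  y <- r[idx]
  s <- (idx - idx[1]) / (idx[k] - idx[1])
  obj <- function(p) {
    if (any(p <= 0)) return(Inf)
    mean((p[1] * exp(s * log(p[2] / p[1])) - y)^2)
  }
  p0 <- c(max(y[1], 1e-8), max(y[k], 1e-8))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  flag <- ""
  p <- opt$par
  if (opt$convergence != 0 || any(p <= 0)) {
    p <- p0                              # endpoint anchoring fallback
    flag <- "non-convergence: endpoint anchoring"
  }
  # delta-method SEs from the Jacobian of the fitted curve
  rin <- p[1]; rout <- p[2]
  fitv <- rin * exp(s * log(rout / rin))
  J <- cbind(fitv * (1 - s) / rin, fitv * s / rout)
  sigma2 <- sum((fitv - y)^2) / max(k - 2, 1)
  JtJ <- crossprod(J)
  se <- tryCatch(sqrt(diag(solve(JtJ)) * sigma2),
                 error = function(e) c(NA_real_, NA_real_))
  list(r_in = rin, r_out = rout, se = se,
       converged = opt$convergence == 0, flag = flag)
}

#' Standard deviation of the radius over the optimal segment
#'
#' Root-mean-square residual of the observed radii against the
#' representative model (constant value or fitted taper).
#'
#' @param r radius sequence.
#' @param range c(first, last).
#' @param r_hat_model either a single constant or a numeric vector of
#'   model values along the segment.
#' @return sigma (cm).
#' @export
radius_sd <- function(r, range, r_hat_model) {
  idx <- range[1]:range[2]
  sqrt(mean((r[idx] - r_hat_model)^2))
}

#' Extract the representative radius of one vessel
#'
#' Runs the full chain on a radius sequence: change-point detection,
#' optimal-segment selection (non-tapering or tapering rules), the
#' constant or exponential summary, and the RMS standard deviation.
#'
#' @param r radius sequence.
#' @param taper fit a tapering (exponential) radius when the rules allow.
#' @param params a [selection_params()].
#' @param max_cp change-point cap.
#' @return list of class `radius_summary`: `ropt_range`, `case_label`,
#'   `taper`, `r_hat` (constant, or c(r_in, r_out)), `sigma`, `m`, `psi`,
#'   `reassigned` (FALSE), `flag`.
#' @export
extract_radius <- function(r, taper = FALSE, params = selection_params(),
                           max_cp = 3L) {
  cp <- detect_changepoints(r, max_cp)
  if (!taper) {
    sel <- select_ropt_nontapering(r, cp, params)
    rng <- sel$range
    rh <- constant_radius(r, rng)
    sg <- radius_sd(r, rng, rh)
    out <- list(ropt_range = rng, case_label = sel$case_label, taper = FALSE,
                r_hat = rh, sigma = sg, m = cp$m, psi = cp$psi,
                reassigned = FALSE, flag = cp$flag)
  } else {
    sel <- select_ropt_tapering(r, cp, params)
    rng <- sel$range
    if (!isTRUE(sel$taper)) {                     # Case 3: constant
      rh <- constant_radius(r, rng)
      sg <- radius_sd(r, rng, rh)
      out <- list(ropt_range = rng, case_label = sel$case_label, taper = FALSE,
                  r_hat = rh, sigma = sg, m = cp$m, psi = cp$psi,
                  reassigned = FALSE, flag = cp$flag)
    } else if (sel$case_label == "case4") {
      idx <- rng[1]:rng[2]
      rin <- r[rng[1]]; rout <- r[rng[2]]
      s <- (idx - idx[1]) / (idx[length(idx)] - idx[1])
      model <- rin * exp(s * log(rout / rin))
      sg <- radius_sd(r, rng, model)
      out <- list(ropt_range = rng, case_label = "case4", taper = TRUE,
                  r_hat = c(r_in = rin, r_out = rout), sigma = sg,
                  m = cp$m, psi = cp$psi, reassigned = FALSE, flag = cp$flag)
    } else {
      ft <- fit_exponential_taper(r, rng)
      idx <- rng[1]:rng[2]
      s <- (idx - idx[1]) / (idx[length(idx)] - idx[1])
      model <- ft$r_in * exp(s * log(ft$r_out / ft$r_in))
      sg <- radius_sd(r, rng, model)
      out <- list(ropt_range = rng, case_label = sel$case_label, taper = TRUE,
                  r_hat = c(r_in = ft$r_in, r_out = ft$r_out), sigma = sg,
                  m = cp$m, psi = cp$psi, reassigned = FALSE,
                  flag = paste0(cp$flag, ft$flag))
    }
  }
  structure(out, class = "radius_summary")
}

#' Extract radii for every vessel of a tree
#'
#' @param tree a `labeled_tree`.
#' @param taper logical, or a named logical vector per vessel id.
#' @param params a [selection_params()].
#' @return the tree with a `radius` field (a `radius_summary`) on every
#'   vessel.
#' @export
extract_tree_radii <- function(tree, taper = FALSE, params = selection_params()) {
  tp <- taper
  for (id in names(tree$vessels)) {
    t_i <- if (length(tp) > 1L) isTRUE(tp[[id]]) else isTRUE(tp)
    tree$vessels[[id]]$radius <-
      extract_radius(tree$vessels[[id]]$points$r, taper = t_i, params = params)
  }
  tree
}

# scalar radius used in consistency comparisons (inlet value for tapering)
.vessel_rhat <- function(v) {
  rh <- v$radius$r_hat
  if (length(rh) > 1L) unname(rh[1]) else unname(rh)
}

#' Network consistency check on extracted radii
#'
#' In healthy networks a parent is wider than each daughter (r_p > r_d)
#' and the combined daughter cross-section exceeds the parent's
#' (sum A_d > A_p).  At bifurcations, a violating *terminal* daughter is
#' reassigned to `alpha * r_p` (one violator) or the pair to
#' `(alpha, beta) * r_p` (two violators), with the reassigned flag and the
#' parent-daughter scale kappa recorded for the uncertainty sampler.
#' Violations by internal vessels or at trifurcations are only reported
#' (manual assignment); daughter-area violations are reported, not fixed.
#'
#' @param tree a `labeled_tree` whose vessels carry `radius` summaries.
#' @param alpha,beta reassignment scale factors (e.g. 0.88 and 0.697 for
#'   pulmonary networks).
#' @return list with `tree` (radii adjusted) and `report` data.frame
#'   (junction, vessel, rule violated, action taken).
#' @export
consistency_check <- function(tree, alpha = 0.88, beta = 0.697) {
  rows <- list()
  for (pid in names(tree$vessels)) {
    dids <- tree$vessels[[pid]]$daughter_ids
    if (!length(dids)) next
    rp <- .vessel_rhat(tree$vessels[[pid]])
    rd <- vapply(dids, function(d) .vessel_rhat(tree$vessels[[d]]), 1.0)
    viol <- which(rd >= rp)
    if (length(viol)) {
      term <- vapply(dids[viol], function(d)
        tree$vessels[[d]]$kind == "terminal", TRUE)
      if (length(dids) == 2L && all(term)) {
        scale <- c(alpha, beta)[seq_along(viol)]
        for (j in seq_along(viol)) {
          d <- dids[viol[j]]
          kappa <- scale[j]
          old <- .vessel_rhat(tree$vessels[[d]])
          rs <- tree$vessels[[d]]$radius
          if (length(rs$r_hat) > 1L) {
            ratio <- rs$r_hat / rs$r_hat[1]
            rs$r_hat <- kappa * rp * ratio    # keep the taper ratio
          } else rs$r_hat <- kappa * rp
          rs$reassigned <- TRUE
          rs$kappa <- kappa
          rs$parent_id <- pid
          tree$vessels[[d]]$radius <- rs
          rows[[length(rows) + 1L]] <- data.frame(
            junction = pid, vessel = d, rule = "radius r_d >= r_p",
            action = sprintf("reassigned %.4g -> %.4g (kappa=%.3g)",
                             old, kappa * rp, kappa))
        }
      } else {
        for (d in dids[viol])
          rows[[length(rows) + 1L]] <- data.frame(
            junction = pid, vessel = d, rule = "radius r_d >= r_p",
            action = if (length(dids) == 3L)
              "flagged: trifurcation, manual assignment required"
            else "flagged: internal vessel, manual assignment required")
      }
    }
    # area rule uses post-reassignment radii
    rd2 <- vapply(dids, function(d) .vessel_rhat(tree$vessels[[d]]), 1.0)
    if (sum(pi * rd2^2) <= pi * rp^2)
      rows[[length(rows) + 1L]] <- data.frame(
        junction = pid, vessel = paste(dids, collapse = "+"),
        rule = "area sum(A_d) <= A_p", action = "flagged")
  }
  list(tree = tree,
       report = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
                else data.frame(junction = character(), vessel = character(),
                                rule = character(), action = character()))
}

#' Per-vessel radius report table
#'
#' @param tree a tree whose vessels carry `radius` summaries.
#' @return data.frame: id, m, psi, case_label, taper, r_hat (or
#'   r_in/r_out), sigma, reassigned.
#' @export
radius_report <- function(tree) {
  rows <- lapply(names(tree$vessels), function(id) {
    v <- tree$vessels[[id]]
    rs <- v$radius
    if (is.null(rs)) return(NULL)
    data.frame(id = id, m = rs$m,
               psi = paste(rs$psi, collapse = ";"),
               case_label = rs$case_label, taper = rs$taper,
               r_hat = if (rs$taper) NA_real_ else unname(rs$r_hat),
               r_in = if (rs$taper) unname(rs$r_hat[1]) else NA_real_,
               r_out = if (rs$taper) unname(rs$r_hat[2]) else NA_real_,
               sigma = rs$sigma,
               reassigned = isTRUE(rs$reassigned))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
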