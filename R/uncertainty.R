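# ---- propagation of radius uncertainty and descriptive statistics ----------

#' Sample radius ensembles from per-vessel normal laws
#'
#' Each vessel's representative radius carries a fitted normal law
#' N(r_hat, sigma^2); for vessels whose radius was reassigned by the
#' consistency check the law is the kappa-scaled
#' N(kappa * r_hat_p, kappa * sigma_p^2) with kappa = r_hat_d / r_hat_p
#' (variance scaled by kappa as printed; set `kappa_sd_scaling = TRUE`
#' to scale the sd instead, i.e. variance kappa^2 sigma^2).  Draws are
#' independent across vessels and samples; non-positive draws are
#' rejected and redrawn.  Tapering vessels are perturbed by one
#' multiplicative factor applied jointly to (r_in, r_out), preserving the
#' taper ratio.
#'
#' @param tree a `labeled_tree` with `radius` summaries (post
#'   [consistency_check()]).
#' @param n_samples number of ensemble members.
#' @param seed integer seed (sampling is reproducible bit-for-bit).
#' @param kappa_sd_scaling scale sd rather than variance by kappa.
#' @return list with `draws` (matrix n_samples x vessels of sampled
#'   constant radii, or inlet radii for tapering vessels), `rejections`
#'   (count per vessel), and `apply_sample(tree, i)` is left to callers
#'   via [sampled_radii()].
#' @export
sample_radii <- function(tree, n_samples, seed = 1L, kappa_sd_scaling = FALSE) {
  stopifnot(n_samples >= 1)
  set.seed(as.integer(seed))
  ids <- names(tree$vessels)
  draws <- matrix(NA_real_, n_samples, length(ids),
                  dimnames = list(NULL, ids))
  rejections <- setNames(integer(length(ids)), ids)
  for (id in ids) {
    rs <- tree$vessels[[id]]$radius
    if (is.null(rs)) stop("vessel ", id, " has no radius summary")
    if (isTRUE(rs$reassigned)) {
      kap <- rs$kappa
      pr <- tree$vessels[[rs$parent_id]]$radius
      mu <- kap * (if (length(pr$r_hat) > 1) pr$r_hat[1] else pr$r_hat)
      sdv <- if (kappa_sd_scaling) kap * pr$sigma else sqrt(kap) * pr$sigma
    } else {
      mu <- if (length(rs$r_hat) > 1) unname(rs$r_hat[1]) else unname(rs$r_hat)
      sdv <- rs$sigma
    }
    x <- stats::rnorm(n_samples, mu, sdv)
    bad <- which(x <= 0)
    tries <- 0L
    while (length(bad)) {
      tries <- tries + 1L
      if (tries > 100L) stop("degenerate distribution for vessel ", id)
      rejections[id] <- rejections[id] + length(bad)
      x[bad] <- stats::rnorm(length(bad), mu, sdv)
      bad <- which(x <= 0)
    }
    draws[, id] <- x
  }
  list(draws = draws, rejections = rejections)
}

#' Radii of one ensemble member
#'
#' Converts row `i` of a [sample_radii()] draw matrix into the named
#' radius list accepted by [solve_large_vessels()]'s `radii` argument
#' (tapering vessels keep their taper ratio).
#'
#' @param tree the tree the ensemble was drawn for.
#' @param samples result of [sample_radii()].
#' @param i sample index.
#' @return named list of radii.
#' @export
sampled_radii <- function(tree, samples, i) {
  out <- list()
  for (id in colnames(samples$draws)) {
    rs <- tree$vessels[[id]]$radius
    v <- samples$draws[i, id]
    out[[id]] <- if (!is.null(rs) && length(rs$r_hat) > 1L)
      unname(v * rs$r_hat / rs$r_hat[1]) else unname(v)
  }
  out
}

#' Count parent/daughter order violations in an ensemble
#'
#' Independent per-vessel sampling can draw a daughter wider than its
#' parent; such draws are surfaced, not corrected.
#'
#' @param tree a `labeled_tree`.
#' @param samples result of [sample_radii()].
#' @return integer vector: violations per sample.
#' @export
sampling_violations <- function(tree, samples) {
  d <- samples$draws
  viol <- integer(nrow(d))
  for (pid in names(tree$vessels)) {
    dids <- tree$vessels[[pid]]$daughter_ids
    for (did in dids)
      viol <- viol + (d[, did] >= d[, pid])
  }
  viol
}

#' Coefficient of variation of a representative radius
#'
#' `CV = sigma / r_hat`.
#'
#' @param r_hat representative radius (> 0).
#' @param sigma its standard deviation (>= 0).
#' @return CV (dimensionless).
#' @export
coefficient_of_variation <- function(r_hat, sigma) {
  if (any(r_hat <= 0)) stop("r_hat must be positive")
  sigma / r_hat
}

#' Kernel density estimate of vessel radii
#'
#' Gaussian-kernel density of a radius sample (used to compare the radius
#' distributions of different segmentations of the same image).
#'
#' @param radii numeric vector (>= 2 values).
#' @param bw bandwidth rule or value, passed to [stats::density()]
#'   (default "nrd0").
#' @param n grid size.
#' @return data.frame with `radius` and `density` columns; integrates to
#'   1 over the grid to within numerical quadrature error.
#' @export
kde_radii <- function(radii, bw = "nrd0", n = 512L) {
  stopifnot(length(radii) >= 2L)
  d <- stats::density(radii, bw = bw, n = n)
  data.frame(radius = d$x, density = d$y)
}

#' One-way analysis of variance across segmentations
#'
#' Classical one-way decomposition (via [stats::aov()]) testing whether a
#' vessel's dimension differs between repeated segmentations of the same
#' image.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `SSE` (error/within sum of squares), `SSB` (between),
#'   `F`, `p`, `df`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2L, all(vapply(groups, length, 1L) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  tab <- stats::anova(stats::aov(y ~ g))
  list(SSE = tab$`Sum Sq`[2], SSB = tab$`Sum Sq`[1],
       F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = tab$Df)
}

#' Midpoint pressure/flow extrema per vessel and ensemble envelope
#'
#' For each solution and vessel, the range, minimum and maximum over time
#' of pressure and flow at the vessel midpoint; plus the envelope
#' (min of minima, max of maxima) across the ensemble.
#'
#' @param solutions list of `hemo_solution` objects over the same tree.
#' @return list with `per_solution` (data.frame: solution, vessel,
#'   p_range/p_min/p_max, q_range/q_min/q_max) and `envelope` (per
#'   vessel).
#' @export
ensemble_summaries <- function(solutions) {
  stopifnot(length(solutions) >= 1L)
  rows <- list()
  for (s in seq_along(solutions)) {
    sol <- solutions[[s]]
    for (id in names(sol$vessels)) {
      ms <- midpoint_series(sol, id)
      rows[[length(rows) + 1L]] <- data.frame(
        solution = s, vessel = id,
        p_min = min(ms$p), p_max = max(ms$p), p_range = diff(range(ms$p)),
        q_min = min(ms$q), q_max = max(ms$q), q_range = diff(range(ms$q)))
    }
  }
  per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  env <- do.call(rbind, lapply(split(per, per$vessel), function(d) data.frame(
    vessel = d$vessel[1],
    p_min = min(d$p_min), p_max = max(d$p_max),
    p_range = max(d$p_max) - min(d$p_min),
    q_min = min(d$q_min), q_max = max(d$q_max),
    q_range = max(d$q_max) - min(d$q_min))))
  rownames(env) <- NULL
  list(per_solution = per, envelope = env)
}
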