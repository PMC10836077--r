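# Independent brute-force oracles used to check the package's
# implementations.  Each is deliberately the simplest possible
# re-derivation of the rule it checks and shares no code with R/.

# exhaustive least-squares search for the continuous broken-line model
# (r = b0 + b1 x + sum d_i (x - psi_i)+): global optimum over all integer
# breakpoint placements with a minimum gap
oracle_broken_line <- function(r, m, min_gap = 2L) {
  n <- length(r)
  x <- seq_len(n)
  rss_of <- function(psi) {
    X <- cbind(1, x)
    for (p in psi) X <- cbind(X, pmax(x - p, 0))
    sum(stats::lm.fit(X, r)$residuals^2)
  }
  if (m == 1L) {
    cand <- min_gap:(n - min_gap)
    rss <- vapply(cand, rss_of, 1.0)
    return(list(psi = cand[which.min(rss)], rss = min(rss)))
  }
  best <- NULL; best_rss <- Inf
  for (p1 in min_gap:(n - 2L * min_gap)) {
    for (p2 in (p1 + min_gap):(n - min_gap)) {
      v <- rss_of(c(p1, p2))
      if (v < best_rss) { best_rss <- v; best <- c(p1, p2) }
    }
  }
  list(psi = best, rss = best_rss)
}

# continuous piecewise-linear test signal with known breakpoints
make_broken_signal <- function(n, psi, slopes, intercept = 1, noise_sd = 0,
                               seed = 1L) {
  set.seed(seed)
  x <- seq_len(n)
  y <- intercept + slopes[1] * x
  for (i in seq_along(psi)) {
    y <- y + (slopes[i + 1] - slopes[i]) * pmax(x - psi[i], 0)
  }
  y + rnorm(n, 0, noise_sd)
}

# recursive structured-tree oracle: returns leaf radii and vessel count
oracle_structured_tree <- function(r_root, alpha, beta, r_min) {
  count <- 0L
  leaves <- numeric()
  rec <- function(r) {
    count <<- count + 1L
    ra <- alpha * r; rb <- beta * r
    kids <- c(ra, rb)[c(ra, rb) >= r_min]
    if (!length(kids)) { leaves[length(leaves) + 1L] <<- r; return(invisible()) }
    for (k in kids) rec(k)
  }
  if (r_root >= r_min) rec(r_root)
  list(count = count, leaves = sort(leaves))
}

# series/parallel Poiseuille resistance of a structured tree
oracle_tree_resistance <- function(r_root, st, mu_L) {
  rec <- function(r) {
    mu <- vasctrees::small_vessel_viscosity(r, mu_L)
    R <- 8 * mu * (st$lrr * r) / (pi * r^4)
    ra <- st$alpha * r; rb <- st$beta * r
    if (ra >= st$r_min && rb >= st$r_min) R + 1 / (1 / rec(ra) + 1 / rec(rb))
    else if (ra >= st$r_min) R + rec(ra)
    else R
  }
  rec(r_root)
}

# independent re-implementation of the pruning rule: returns removal
# units (pair at bifurcation, single at trifurcation) in order
oracle_prune_order <- function(tree, target, stat = mean) {
  vs <- lapply(tree$vessels, function(v)
    list(kind = v$kind, parent = v$parent_id, daughters = v$daughter_ids,
         rad = stat(v$points$r)))
  removed <- list()
  while (length(vs) > target) {
    elig <- character()
    for (id in names(vs)) {
      v <- vs[[id]]
      if (v$kind != "terminal" || is.na(v$parent)) next
      sibs <- setdiff(vs[[v$parent]]$daughters, id)
      if (any(vapply(sibs, function(s) vs[[s]]$kind == "terminal", TRUE)))
        elig <- c(elig, id)
    }
    if (!length(elig)) break
    rad <- vapply(elig, function(id) vs[[id]]$rad, 1.0)
    pick <- elig[order(rad, elig)][1]
    par <- vs[[pick]]$parent
    sibs <- vs[[par]]$daughters
    drop <- if (length(sibs) == 2L) sibs else pick
    removed[[length(removed) + 1L]] <- sort(drop)
    vs[drop] <- NULL
    vs[[par]]$daughters <- setdiff(sibs, drop)
    if (!length(vs[[par]]$daughters)) vs[[par]]$kind <- "terminal"
  }
  removed
}

# brute-force one-way ANOVA sums of squares
oracle_anova <- function(groups) {
  y <- unlist(groups); gm <- mean(y)
  ni <- vapply(groups, length, 1L)
  mi <- vapply(groups, mean, 1.0)
  ssb <- sum(ni * (mi - gm)^2)
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  k <- length(groups); N <- length(y)
  Fv <- (ssb / (k - 1)) / (sse / (N - k))
  list(SSE = sse, SSB = ssb, F = Fv,
       p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

# small helper: solver settings sized for tests
test_hemo <- function(...) {
  vasctrees::hemo_params(T = 0.85, p0 = 0, grid = 12L, cycles = 6L,
                         period_tol = 1e-3, ...)
}

# perfect binary tree built directly from the data model (no geometry
# needed): heap-indexed ids, radii follow the alpha/beta scaling, each
# vessel carrying a hand-set radius summary
make_heap_tree <- function(levels, root_radius = 0.8, alpha = 0.88,
                           beta = 0.697, sigma_frac = 0.08) {
  nv <- 2L^levels - 1L
  rad <- numeric(nv); rad[1] <- root_radius
  if (nv > 1) for (i in 2:nv)
    rad[i] <- rad[i %/% 2] * if (i %% 2 == 0) alpha else beta
  vessels <- list()
  for (i in seq_len(nv)) {
    dts <- if (2 * i + 1 <= nv) paste0("V", c(2 * i, 2 * i + 1)) else character()
    par <- if (i == 1) NA_character_ else paste0("V", i %/% 2)
    v <- vasctrees::new_vessel(paste0("V", i),
                               data.frame(x = c(0, 1), y = 0, z = i, r = rad[i]),
                               parent_id = par, daughter_ids = dts)
    v$radius <- structure(list(
      ropt_range = c(1L, 2L), case_label = "case3", taper = FALSE,
      r_hat = rad[i], sigma = sigma_frac * rad[i], m = 0L, psi = integer(),
      reassigned = FALSE, flag = ""), class = "radius_summary")
    vessels[[paste0("V", i)]] <- v
  }
  tree <- structure(list(vessels = vessels, root_id = "V1",
                         connectivity = NULL), class = "labeled_tree")
  tree <- vasctrees::classify_vessels(tree)
  con <- lapply(tree$vessels, function(v) v$daughter_ids)
  tree$connectivity <- con[vapply(con, length, 1L) > 0]
  vasctrees::validate_tree(tree)
  tree
}

# draw structured-tree parameters whose materialized size stays at desk
# scale (redraw using the current RNG stream when the count explodes)
draw_st_params <- function(max_count = 20000L) {
  repeat {
    alpha <- runif(1, 0.75, 0.95)
    beta <- runif(1, 0.55, alpha)
    r_root <- runif(1, 0.005, 0.02)
    r_min <- r_root / runif(1, 3, 15)
    cnt <- 0L
    ok <- TRUE
    stack <- r_root
    while (length(stack)) {
      r <- stack[length(stack)]; stack <- stack[-length(stack)]
      cnt <- cnt + 1L
      if (cnt > max_count) { ok <- FALSE; break }
      for (rd in c(alpha * r, beta * r)) if (rd >= r_min)
        stack <- c(stack, rd)
    }
    if (ok) return(list(alpha = alpha, beta = beta, r_root = r_root,
                        r_min = r_min, count = cnt))
  }
}
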