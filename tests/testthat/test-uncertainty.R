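# builds a small tree with hand-set radius summaries
fixture_tree_with_radii <- function(sigma_frac = 0.05, seed = 1) {
  net <- make_synthetic_network(levels = 3, root_radius = 0.5, seed = seed)
  tr <- build_labeled_tree(net$centerlines)
  for (id in names(tr$vessels)) {
    rh <- net$true_radii[[id]]
    tr$vessels[[id]]$radius <- structure(list(
      ropt_range = c(1L, 30L), case_label = "case3", taper = FALSE,
      r_hat = rh, sigma = sigma_frac * rh, m = 0L, psi = integer(),
      reassigned = FALSE, flag = ""), class = "radius_summary")
  }
  tr
}

test_that("sampling is reproducible, unbiased and respects sigma = 0", {
  tr <- fixture_tree_with_radii()
  s1 <- sample_radii(tr, 200, seed = 7)
  s2 <- sample_radii(tr, 200, seed = 7)
  expect_identical(s1$draws, s2$draws)
  # sigma = 0: all draws equal the mean tree
  tr0 <- fixture_tree_with_radii(sigma_frac = 0)
  s0 <- sample_radii(tr0, 10, seed = 1)
  for (id in colnames(s0$draws))
    expect_true(all(s0$draws[, id] == tr0$vessels[[id]]$radius$r_hat))
  # CLT bound on the sample means
  mh <- colMeans(s1$draws)
  for (id in names(tr$vessels)) {
    rh <- tr$vessels[[id]]$radius$r_hat
    expect_lt(abs(mh[[id]] - rh), 4 * (0.05 * rh) / sqrt(200))
  }
})

test_that("reassigned vessels draw from the kappa-scaled parent law", {
  tr <- fixture_tree_with_radii()
  kap <- 0.88
  pr <- tr$vessels$R$radius
  tr$vessels$R.1$radius$reassigned <- TRUE
  tr$vessels$R.1$radius$kappa <- kap
  tr$vessels$R.1$radius$parent_id <- "R"
  s <- sample_radii(tr, 4000, seed = 3)
  x <- s$draws[, "R.1"]
  expect_equal(mean(x), kap * pr$r_hat, tolerance = 0.01)
  # variance scaled by kappa (as printed): var = kappa * sigma_p^2
  expect_equal(stats::var(x), kap * pr$sigma^2, tolerance = 0.1)
  # sd-scaling switch: var = (kappa * sigma_p)^2
  s2 <- sample_radii(tr, 4000, seed = 3, kappa_sd_scaling = TRUE)
  expect_equal(stats::var(s2$draws[, "R.1"]), (kap * pr$sigma)^2,
               tolerance = 0.1)
})

test_that("parent/daughter order violations are counted, not corrected", {
  tr <- fixture_tree_with_radii(sigma_frac = 0.3)   # wide laws force overlaps
  s <- sample_radii(tr, 200, seed = 5)
  v <- sampling_violations(tr, s)
  expect_length(v, 200L)
  expect_gt(sum(v), 0)
})

test_that("CV matches its definition including the CV > 1 regime", {
  expect_equal(coefficient_of_variation(0.5, 0), 0)
  expect_equal(coefficient_of_variation(0.5, 0.1), 0.2)
  expect_gt(coefficient_of_variation(0.04, 0.05), 1)  # near-resolution vessels
  expect_error(coefficient_of_variation(0, 0.1), "positive")
})

test_that("kernel density integrates to 1 and resolves bimodality", {
  set.seed(18)
  x <- rnorm(400, 0.25, 0.02)
  kd <- kde_radii(x)
  area <- sum(diff(kd$radius) * (kd$density[-1] + kd$density[-nrow(kd)]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_lt(abs(kd$radius[which.max(kd$density)] - 0.25), 0.01)
  # well-separated mixture (aorta-like bimodal radii) has two modes
  y <- c(rnorm(300, 0.25, 0.02), rnorm(150, 0.6, 0.03))
  kdy <- kde_radii(y)
  dens <- kdy$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  modes <- kdy$radius[peaks[dens[peaks] > 0.1 * max(dens)]]
  expect_gte(length(modes), 2L)
})

test_that("one-way ANOVA matches the brute-force decomposition", {
  ident <- list(c(1, 2, 3), c(1, 2, 3))
  res <- anova_oneway(ident)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # two groups: F equals the squared pooled t statistic
  set.seed(19)
  g1 <- rnorm(12, 1); g2 <- rnorm(15, 1.4)
  res2 <- anova_oneway(list(g1, g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  # random fixture vs sums-of-squares oracle
  groups <- lapply(1:4, function(i) rnorm(sample(5:12, 1), i * 0.1))
  res3 <- anova_oneway(groups)
  orc <- oracle_anova(groups)
  expect_equal(res3$SSE, orc$SSE, tolerance = 1e-10)
  expect_equal(res3$F, orc$F, tolerance = 1e-10)
  expect_equal(res3$p, orc$p, tolerance = 1e-10)
})

test_that("ensemble summaries report midpoint extrema and envelopes", {
  mk_sol <- function(pshift) {
    tt <- seq(0.01, 1, length.out = 100)
    p <- matrix(rep(10 + pshift + 5 * sin(2 * pi * tt), each = 3), nrow = 3,
                byrow = FALSE)
    structure(list(vessels = list(V = list(x = c(0, 1, 2), t = tt, p = p,
                                           q = p * 0.1, A = p * 0 + 1))),
              class = "hemo_solution")
  }
  one <- ensemble_summaries(list(mk_sol(0)))
  expect_equal(one$per_solution$p_range, 10, tolerance = 1e-3)
  expect_equal(one$per_solution$p_min, 5, tolerance = 1e-3)
  expect_equal(one$per_solution$p_max, 15, tolerance = 1e-3)
  # two identical solutions: envelope equals either
  two <- ensemble_summaries(list(mk_sol(0), mk_sol(0)))
  expect_equal(two$envelope$p_range, one$per_solution$p_range)
  # shifted member widens the envelope
  three <- ensemble_summaries(list(mk_sol(0), mk_sol(3)))
  expect_gt(three$envelope$p_range, one$per_solution$p_range)
})
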