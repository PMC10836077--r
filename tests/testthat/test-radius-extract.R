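test_that("slope ratio follows the absolute-value convention", {
  expect_equal(slope_ratio(0.01, 0.05), 4)
  expect_equal(slope_ratio(0.02, 0.02), 0)
  expect_equal(slope_ratio(-0.02, 0.02), 2)
  inf <- slope_ratio(0, 1)
  expect_true(is.infinite(inf))
  expect_match(attr(inf, "flag"), "zero")
})

test_that("non-tapering segment selection follows the case rules", {
  # constructed Case 1: flat middle segment holding 70% of the nodes
  # (the short trailing section keeps a slight slope so the middle is the
  # unambiguous flattest)
  n <- 100
  r <- c(seq(0.8, 0.5, length.out = 10), rep(0.5, 70),
         seq(0.5, 0.3, length.out = 12), seq(0.3, 0.29, length.out = 8))
  cp <- structure(list(
    psi = c(10L, 80L, 92L), m = 3L, n = n,
    segment_fits = segment_fits(r, c(10L, 80L, 92L))), class = "changepoint_result")
  sel <- select_ropt_nontapering(r, cp)
  expect_identical(sel$case_label, "case1")
  expect_equal(sel$range, c(10L, 80L))
  # no change points: whole vessel (Case 3)
  cp0 <- detect_changepoints(rep(0.4, 30))
  sel0 <- select_ropt_nontapering(rep(0.4, 30), cp0)
  expect_identical(sel0$case_label, "case3")
  expect_equal(sel0$range, c(1L, 30L))
})

test_that("Case 2 start rule uses psi1/psi2 and the 25%/50% marks", {
  n <- 100
  mk_cp <- function(r, psi) structure(list(
    psi = psi, m = length(psi), n = length(r),
    segment_fits = segment_fits(r, psi)), class = "changepoint_result")
  # the flattest section is the short trailing one (21 nodes <= 25%), so
  # Case 1 fails and the start/end rules of Case 2 decide
  r <- c(seq(1, 0.9, length.out = 5), 0.9 - 0.004 * (1:35),
         0.76 - 0.002 * (1:40), rep(0.68, 20))
  # psi1 at 5%, psi2 at 40% (<= 50%): start at psi2
  sel <- select_ropt_nontapering(r, mk_cp(r, c(5L, 40L, 80L)))
  expect_identical(sel$case_label, "case2")
  expect_equal(sel$range[1], 40L)
  # psi1 past 25%: start at psi1
  sel2 <- select_ropt_nontapering(r, mk_cp(r, c(30L, 60L, 80L)))
  expect_identical(sel2$case_label, "case2")
  expect_equal(sel2$range[1], 30L)
  # psi1 at 5%, psi2 past 50%: start at the 25% mark
  sel3 <- select_ropt_nontapering(r, mk_cp(r, c(5L, 60L, 80L)))
  expect_equal(sel3$range[1], 25L)
})

test_that("constant radius, taper fit and sigma match their definitions", {
  expect_equal(constant_radius(c(0.5, 0.5, 0.5), c(1, 3)), 0.5)
  expect_equal(constant_radius(c(0.4, 0.6), c(1, 2)), 0.5)
  # plateau with noise: CLT-scale accuracy
  set.seed(12)
  r <- rep(0.5, 50) + rnorm(50, 0, 0.01)
  expect_lt(abs(constant_radius(r, c(1, 50)) - 0.5), 3 * 0.01 / sqrt(50))
  # exponential recovery on noiseless data
  s <- seq(0, 1, length.out = 20)
  rexp <- 1.0 * exp(s * log(0.5))
  ft <- fit_exponential_taper(rexp, c(1, 20))
  expect_equal(ft$r_in, 1.0, tolerance = 1e-6)
  expect_equal(ft$r_out, 0.5, tolerance = 1e-6)
  # model identity at s = 1 and the constant-data limit
  expect_equal(ft$r_in * exp(1 * log(ft$r_out / ft$r_in)), ft$r_out)
  ftc <- fit_exponential_taper(rep(0.3, 10), c(1, 10))
  expect_equal(ftc$r_in, 0.3, tolerance = 1e-5)
  expect_equal(ftc$r_out, 0.3, tolerance = 1e-5)
  # sigma: RMS residual
  expect_equal(radius_sd(c(0.4, 0.6), c(1, 2), 0.5), 0.1)
  expect_equal(radius_sd(rexp, c(1, 20), rexp), 0)
  set.seed(3)
  rr <- rnorm(30, 1, 0.1)
  expect_equal(radius_sd(rr, c(5, 25), 1),
               sqrt(mean((rr[5:25] - 1)^2)), tolerance = 1e-14)
})

test_that("tapering selection prefers long segments and anchors Case 4", {
  # one segment holding 60% of nodes
  r <- c(seq(0.9, 0.6, length.out = 20), seq(0.6, 0.4, length.out = 60),
         rep(0.4, 20))
  cp <- structure(list(psi = c(20L, 80L), m = 2L, n = 100L,
                       segment_fits = segment_fits(r, c(20L, 80L))),
                  class = "changepoint_result")
  sel <- select_ropt_tapering(r, cp)
  expect_identical(sel$case_label, "case1")
  expect_equal(sel$range, c(20L, 80L))
  # no change points: constant radius flag
  sel0 <- select_ropt_tapering(rep(0.4, 30), detect_changepoints(rep(0.4, 30)))
  expect_identical(sel0$case_label, "case3")
  expect_false(sel0$taper)
  # Case 4 via extract_radius on a short degenerate selection
  rs <- extract_radius(c(0.9, 0.8, 0.7, 0.65, 0.6), taper = TRUE)
  expect_true(rs$case_label %in% c("case1", "case2", "case3", "case4"))
})

test_that("ostium exclusion: r_hat beats the naive all-node mean", {
  wins <- 0L
  for (seed in 1:20) {
    v <- make_synthetic_vessel(100, base_radius = 0.5, ostium_frac = 0.15,
                               ostium_scale = 1.5, noise_sd = 0.01,
                               seed = seed)
    rs <- extract_radius(v$r)
    err <- abs(rs$r_hat - v$truth_radius)
    err_naive <- abs(mean(v$r) - v$truth_radius)
    if (err < err_naive) wins <- wins + 1L
    if (rs$m >= 1)
      expect_gte(rs$ropt_range[1], 2L)      # never starts in the first section
  }
  expect_gte(wins, 19L)
})

test_that("r_hat lies within the observed radius range of r_opt", {
  for (seed in 1:5) {
    v <- make_synthetic_vessel(80, 0.4, ostium_frac = 0.12, noise_sd = 0.02,
                               seed = seed)
    rs <- extract_radius(v$r)
    rng <- rs$ropt_range
    expect_gte(rs$r_hat, min(v$r[rng[1]:rng[2]]))
    expect_lte(rs$r_hat, max(v$r[rng[1]:rng[2]]))
  }
})

test_that("consistency check reassigns terminal daughters and reports areas", {
  net <- make_synthetic_network(levels = 2, root_radius = 0.5, seed = 1)
  tr <- build_labeled_tree(net$centerlines)
  tr <- extract_tree_radii(tr)
  # healthy by construction: no radius violations
  res <- consistency_check(tr, alpha = 0.88, beta = 0.697)
  expect_false(any(grepl("radius", res$report$rule)))
  # force a violating terminal daughter: r_d > r_p
  tr$vessels$R.1$radius$r_hat <- 0.6
  tr$vessels$R$radius$r_hat <- 0.5
  fix <- consistency_check(tr, alpha = 0.88, beta = 0.697)
  expect_equal(fix$tree$vessels$R.1$radius$r_hat, 0.88 * 0.5)
  expect_true(fix$tree$vessels$R.1$radius$reassigned)
  expect_equal(fix$tree$vessels$R.1$radius$kappa, 0.88)
  # all bifurcations with terminal daughters now satisfy r_p > r_d
  for (d in fix$tree$vessels$R$daughter_ids)
    expect_lt(fix$tree$vessels[[d]]$radius$r_hat,
              fix$tree$vessels$R$radius$r_hat)
  # area rule: pi r^2 arithmetic (0.3^2 + 0.3^2 < 0.5^2)
  tr2 <- tr
  tr2$vessels$R$radius$r_hat <- 0.5
  tr2$vessels$R.1$radius$r_hat <- 0.3
  tr2$vessels$R.2$radius$r_hat <- 0.3
  res2 <- consistency_check(tr2, 0.88, 0.697)
  expect_true(any(grepl("area", res2$report$rule)))
})
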