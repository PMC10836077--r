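test_that("first-generation radii and lengths follow the scaling law", {
  st <- structured_tree_params(alpha = 0.88, beta = 0.697, lrr = 15.75)
  tr <- build_structured_tree(1.0, structured_tree_params(
    alpha = 0.88, beta = 0.697, lrr = 15.75, r_min = 0.5))
  g1 <- tr$radius[tr$generation == 1]
  expect_equal(sort(g1), sort(c(0.88, 0.697)))
  expect_equal(tr$length, st$lrr * tr$radius)
})

test_that("pure-alpha and pure-beta path depths match the geometric bound", {
  st <- structured_tree_params(alpha = 0.88, beta = 0.697, r_min = 0.001)
  tr <- build_structured_tree(0.01, st)
  depth_a <- max(nchar(gsub("[^a]", "", tr$id)))
  depth_b <- max(nchar(gsub("[^b]", "", tr$id)))
  expect_equal(depth_a, 18L)   # 0.01 * 0.88^18 >= 0.001 > 0.01 * 0.88^19
  expect_equal(depth_b, 6L)    # 0.01 * 0.697^6 >= 0.001 > 0.01 * 0.697^7
  # closed-form check
  expect_equal(depth_a, floor(log(st$r_min / 0.01) / log(st$alpha)))
  expect_equal(depth_b, floor(log(st$r_min / 0.01) / log(st$beta)))
})

test_that("tree structure matches a recursive oracle for random parameters", {
  set.seed(14)
  for (i in 1:20) {
    alpha <- runif(1, 0.75, 0.95)
    beta <- runif(1, 0.55, alpha)
    r_root <- runif(1, 0.005, 0.02)
    r_min <- r_root / runif(1, 3, 12)
    st <- structured_tree_params(alpha = alpha, beta = beta, r_min = r_min)
    tr <- build_structured_tree(r_root, st)
    orc <- oracle_structured_tree(r_root, alpha, beta, r_min)
    expect_equal(nrow(tr), orc$count)
    expect_equal(sort(tr$radius[tr$is_leaf]), orc$leaves, tolerance = 1e-14)
    # self-similarity holds exactly at every internal vessel
    for (row in which(!tr$is_leaf)[seq_len(min(10, sum(!tr$is_leaf)))]) {
      kids <- tr[!is.na(tr$parent) & tr$parent == tr$id[row], ]
      expect_true(all(sort(kids$radius) %in%
                      sort(tr$radius[row] * c(beta, alpha))))
    }
  }
})

test_that("cross-sectional area grows with generation when alpha^2+beta^2 >= 1", {
  st <- structured_tree_params(alpha = 0.9, beta = 0.6, r_min = 0.01)
  tr <- build_structured_tree(0.1, st)
  # compare full generations only (all vessels still above r_min)
  gens <- structured_tree_generations(tr)
  full <- gens$generation[gens$count == 2^gens$generation]
  area <- vapply(full, function(g)
    sum(tr$radius[tr$generation == g]^2), 1.0)
  expect_true(all(diff(area) >= -1e-12))
})

test_that("root below r_min yields a flagged single leaf", {
  st <- structured_tree_params(r_min = 0.01)
  tr <- build_structured_tree(0.005, st)
  expect_equal(nrow(tr), 1L)
  expect_match(attr(tr, "flag"), "below r_min")
})

test_that("small-vessel viscosity has the Fahraeus-Lindqvist shape", {
  mu_L <- 0.032
  r <- seq(2e-4, 0.05, length.out = 200)      # 2 um - 500 um radii
  mu <- small_vessel_viscosity(r, mu_L)
  expect_true(all(mu > 0))
  # direct evaluation of the law at d = 100 um (r = 50 um)
  r50 <- 50
  D <- 100 / (100 - 1.12)
  eta <- 6 * exp(-0.17 * r50) + 3.2 - 2.44 * exp(-0.12 * r50^0.645)
  expect_equal(small_vessel_viscosity(50e-4, mu_L),
               mu_L / 3.2 * D * (1 + D * (eta - 1)), tolerance = 1e-14)
  # monotone recovery toward the bulk value above d = 50 um, and a
  # plateau within 0.2% of mu_L for millimetre-scale vessels and larger
  big <- small_vessel_viscosity(seq(25e-4, 0.05, length.out = 100), mu_L)
  expect_true(all(diff(big) > 0))
  plateau <- small_vessel_viscosity(seq(0.1, 10, length.out = 50), mu_L)
  expect_true(all(abs(plateau / mu_L - 1) < 2e-3))
  expect_equal(small_vessel_viscosity(10, mu_L), mu_L, tolerance = 1e-3)
  expect_error(small_vessel_viscosity(0.5e-4 / 2), "plasma-layer")
})
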