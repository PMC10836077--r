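test_that("daughter distances reproduce hand and brute-force values", {
  a <- data.frame(x = c(1, 1), y = c(0, 1), z = 0, r = 1)
  expect_equal(daughter_distances(a, a), c(0, 0))
  d1 <- data.frame(x = 1, y = 0, z = 0, r = 1)
  d2 <- data.frame(x = 0, y = 1, z = 0, r = 1)
  expect_equal(daughter_distances(d1, d2), sqrt(2))
  set.seed(8)
  p1 <- data.frame(x = cumsum(runif(12)), y = rnorm(12), z = rnorm(12), r = 1)
  p2 <- data.frame(x = cumsum(runif(15)), y = rnorm(15), z = rnorm(15), r = 1)
  D <- daughter_distances(p1, p2)
  expect_length(D, 12L)
  brute <- vapply(1:12, function(i)
    sqrt(sum((p1[i, 1:3] - p2[i, 1:3])^2)), 1.0)
  expect_equal(D, brute, tolerance = 1e-15)
  expect_error(daughter_distances(p1[0, ], p2), "empty daughter")
})

test_that("daughter pair selection minimizes mean distance", {
  expect_error(select_daughter_pair(list(data.frame(x = 1, y = 1, z = 1, r = 1))),
               "not a junction")
  two <- list(data.frame(x = 1, y = 0, z = 0, r = 1),
              data.frame(x = 0, y = 1, z = 0, r = 1))
  expect_equal(select_daughter_pair(two), c(1L, 2L))
  # coincident first nodes win at a trifurcation
  base <- data.frame(x = c(0, 1), y = c(0, 0), z = 0, r = 1)
  far <- data.frame(x = c(0, 5), y = c(5, 9), z = 0, r = 1)
  expect_equal(sort(select_daughter_pair(list(base, far, base))), c(1L, 3L))
  # random trifurcation: enumerate all 3 pairs
  set.seed(11)
  tri <- replicate(3, data.frame(x = cumsum(runif(8)), y = rnorm(8),
                                 z = rnorm(8), r = 1), simplify = FALSE)
  pairs <- utils::combn(3, 2)
  means <- apply(pairs, 2, function(p)
    mean(daughter_distances(tri[[p[1]]], tri[[p[2]]])))
  expect_equal(sort(select_daughter_pair(tri)),
               sort(pairs[, which.min(means)]))
})

test_that("new junction index follows the divergence-ratio rule", {
  # normalized profiles: first ratio above the 0.1 cutoff wins
  expect_equal(find_new_junction(c(0.02, 0.05, 0.12, 0.4), Dmax = 1)$k, 3L)
  expect_equal(find_new_junction(c(0.2, 0.5, 1), 0.1)$k, 1L)
  # linear-scan oracle on a random profile
  set.seed(13)
  D <- cumsum(runif(20, 0, 0.1))
  expect_equal(find_new_junction(D)$k, min(which(D / max(D) > 0.1)))
  # never diverging past the cutoff: flagged
  flat <- find_new_junction(rep(0, 5), 0.1)
  expect_false(flat$diverged)
  expect_false(find_new_junction(c(0.01, 0.05, 0.08), Dmax = 1)$diverged)
})

test_that("parent extension averages daughters (positions and radii)", {
  d1 <- data.frame(x = 1, y = 0, z = 0, r = 0.2)
  d2 <- data.frame(x = 3, y = 0, z = 0, r = 0.4)
  expect_equal(as.numeric(extend_parent(list(d1, d2), 1)), c(2, 0, 0, 0.3))
  e1 <- data.frame(x = 1, y = 0, z = 0, r = 1)
  e2 <- data.frame(x = 0, y = 1, z = 0, r = 1)
  e3 <- data.frame(x = 0, y = 0, z = 1, r = 1)
  expect_equal(as.numeric(extend_parent(list(e1, e2, e3), 1))[1:3],
               rep(1 / 3, 3))
  expect_error(extend_parent(list(d1, d2), 5), "index overflow")
})

test_that("smoothing weights daughters against the parent extension", {
  # w = 2: (2*xd + xp)/3
  d <- list(data.frame(x = c(0, 0), y = c(0, 3), z = 0, r = 1),
            data.frame(x = c(0, 6), y = c(0, -3), z = 0, r = 1))
  D <- daughter_distances(d[[1]], d[[2]])
  params <- junction_adjust_params(w = 2)
  sm <- smooth_daughters(d, D, 2L, params)
  xp <- (c(0, 3, 0) + c(6, -3, 0)) / 2          # parent extension at i = 2
  expect_equal(as.numeric(sm[[1]][2, 1:3]), (2 * c(0, 3, 0) + xp) / 3)
  # w -> infinity leaves daughters unchanged
  sm_inf <- smooth_daughters(d, D, 2L, junction_adjust_params(w = 1e9))
  expect_equal(as.numeric(sm_inf[[1]][2, 1:3]), c(0, 3, 0), tolerance = 1e-8)
  # w = 100 stays within 1% of the daughter position
  sm100 <- smooth_daughters(d, D, 2L, junction_adjust_params(w = 100))
  shift <- sqrt(sum((sm100[[1]][2, 1:3] - c(0, 3, 0))^2))
  expect_lt(shift, 0.01 * sqrt(sum((c(0, 3, 0) - xp)^2)) * 3.1)
})

test_that("junction adjustment recovers the true ostium and conserves nodes", {
  for (off in c(3L, 5L, 8L)) {
    net <- make_synthetic_network(levels = 2, junction_offset = off, seed = off)
    tr <- build_labeled_tree(net$centerlines)
    n_before <- vapply(tr$vessels, function(v) nrow(v$points), 1L)
    adj <- adjust_all_junctions(tr)
    rep1 <- adj$report[1, ]
    truth <- net$true_junctions[1, c("x", "y", "z")]
    dist <- sqrt(sum((c(rep1$new_x, rep1$new_y, rep1$new_z) - truth)^2))
    expect_lt(dist, net$spacing * 1.0001)   # within one node of ground truth
    # bookkeeping: parent gains k nodes, each daughter drops k-1
    k <- rep1$k
    n_after <- vapply(adj$tree$vessels, function(v) nrow(v$points), 1L)
    expect_equal(n_after[["R"]], n_before[["R"]] + k)
    expect_equal(n_after[["R.1"]], n_before[["R.1"]] - (k - 1L))
    expect_equal(n_after[["R.2"]], n_before[["R.2"]] - (k - 1L))
    # parent length grew, daughters shrank
    expect_gt(adj$tree$vessels$R$length, tr$vessels$R$length)
    expect_lt(adj$tree$vessels$R.1$length, tr$vessels$R.1$length)
  }
})

test_that("coincident-nowhere junctions are flagged, not moved", {
  net <- make_synthetic_network(levels = 2, junction_offset = 0, seed = 2)
  tr <- build_labeled_tree(net$centerlines)
  adj <- adjust_all_junctions(tr)
  # k = 1 everywhere: parent gains a single (averaged first) node
  expect_lte(adj$report$k[1], 2L)
  expect_true(validate_tree(adj$tree))
})

test_that("re-adjustment moves the junction by at most one node spacing", {
  net <- make_synthetic_network(levels = 2, junction_offset = 5, seed = 9)
  tr <- build_labeled_tree(net$centerlines)
  a1 <- adjust_all_junctions(tr)
  a2 <- adjust_all_junctions(a1$tree)
  d <- sqrt(sum((a2$report[1, c("new_x", "new_y", "new_z")] -
                 a1$report[1, c("new_x", "new_y", "new_z")])^2))
  expect_lt(d, net$spacing * 1.5)
})
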