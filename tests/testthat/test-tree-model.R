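test_that("vessel_length matches hand values and a brute-force sum", {
  expect_equal(vessel_length(data.frame(x = c(0, 3), y = c(0, 4),
                                        z = c(0, 0), r = 1)), 5)
  expect_equal(vessel_length(data.frame(x = 0:2, y = 0, z = 0, r = 1)), 2)
  set.seed(42)
  pts <- data.frame(x = rnorm(50), y = rnorm(50), z = rnorm(50), r = 1)
  brute <- sum(vapply(2:50, function(i)
    sqrt(sum((pts[i, 1:3] - pts[i - 1, 1:3])^2)), 1.0))
  expect_equal(vessel_length(pts), brute, tolerance = 1e-12)
  expect_error(vessel_length(pts[1, , drop = FALSE]), "degenerate")
})

test_that("build_labeled_tree handles degenerate, Y and 3-level networks", {
  single <- list(A = data.frame(x = 0:5, y = 0, z = 0, r = 0.5))
  tr <- build_labeled_tree(single)
  expect_length(tr$vessels, 1L)
  expect_identical(tr$vessels$A$kind, "root")

  net <- make_synthetic_network(levels = 2, seed = 1)
  tr2 <- build_labeled_tree(net$centerlines)
  kinds <- table(vapply(tr2$vessels, function(v) v$kind, ""))
  expect_equal(as.integer(kinds[c("root", "terminal")]), c(1L, 2L))
  expect_equal(tr2$connectivity$R, c("R.1", "R.2"))

  net3 <- make_synthetic_network(levels = 3, seed = 2)
  tr3 <- build_labeled_tree(net3$centerlines)
  expect_length(tr3$vessels, 7L)
  kinds3 <- table(vapply(tr3$vessels, function(v) v$kind, ""))
  expect_equal(as.integer(kinds3[c("root", "central", "terminal")]),
               c(1L, 2L, 4L))
  expect_true(validate_tree(tr3))
})

test_that("build_labeled_tree rejects malformed networks", {
  a <- data.frame(x = 0:3, y = 0, z = 0, r = 1)
  b <- data.frame(x = 10:13, y = 5, z = 0, r = 1)
  expect_error(build_labeled_tree(list(a, b)), "disconnected")
  # cycle: two polylines each starting at the other's end
  c1 <- data.frame(x = c(0, 1), y = 0, z = 0, r = 1)
  c2 <- data.frame(x = c(1, 0), y = 0, z = 0, r = 1)
  expect_error(build_labeled_tree(list(c1, c2)), "cycle|disconnected")
})

test_that("total length is invariant under vessel re-ordering", {
  net <- make_synthetic_network(levels = 3, seed = 5)
  tr <- build_labeled_tree(net$centerlines)
  perm <- rev(names(net$centerlines))
  tr2 <- build_labeled_tree(net$centerlines[perm])
  expect_equal(total_tree_length(tr), total_tree_length(tr2), tolerance = 1e-12)
})

test_that("pruning removes smallest terminal pairs and is idempotent", {
  net <- make_synthetic_network(levels = 3, root_radius = 0.5, seed = 3)
  tr <- build_labeled_tree(net$centerlines)
  pr <- prune_to_size(tr, 5)
  expect_length(pr$vessels, 5L)
  # the removed pair has the smallest mean radii among terminals
  removed <- setdiff(names(tr$vessels), names(pr$vessels))
  term_ids <- names(tr$vessels)[vapply(tr$vessels, function(v)
    v$kind == "terminal", TRUE)]
  rads <- vapply(term_ids, function(id) mean(tr$vessels[[id]]$points$r), 1.0)
  expect_true(names(which.min(rads)) %in% removed)
  # the pair's parent became terminal
  par <- tr$vessels[[removed[1]]]$parent_id
  expect_identical(pr$vessels[[par]]$kind, "terminal")
  expect_true(validate_tree(pr))
  # identity at the reached size; warning above current size
  expect_identical(names(prune_to_size(pr, 5)$vessels), names(pr$vessels))
  expect_warning(prune_to_size(pr, 99), "nothing to prune")
})

test_that("pruning a trifurcation removes a single daughter", {
  net <- make_synthetic_network(levels = 2, trifurcate = "R", seed = 4)
  tr <- build_labeled_tree(net$centerlines)
  expect_length(tr$vessels$R$daughter_ids, 3L)
  pr <- prune_to_size(tr, 3)
  expect_length(pr$vessels, 3L)
  expect_length(pr$vessels$R$daughter_ids, 2L)
  # removed: the single smallest terminal daughter (beta-scaled ones tie on
  # truth; noise-free so smallest mean radius decides, ties by id)
  removed <- setdiff(names(tr$vessels), names(pr$vessels))
  expect_length(removed, 1L)
  expect_true(validate_tree(pr))
})
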