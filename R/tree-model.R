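# ---- labeled directed trees of vessels -------------------------------------
#
# A vessel is an ordered sequence of centerline points (x, y, z in cm) each
# carrying the maximally-inscribed-sphere radius r (cm).  A labeled tree is a
# rooted directed tree of vessels: one root (starts at the inlet), central
# vessels (junction to junction) and terminal vessels (junction to outlet).

#' Create a vessel record
#'
#' A vessel is the atomic geometry record of a labeled tree: an ordered
#' centerline point sequence with per-point inscribed-sphere radii.
#'
#' @param id character identifier, unique within a tree.
#' @param points data.frame with columns `x`, `y`, `z` (cm) and `r` (cm),
#'   at least two rows, radii strictly positive.
#' @param parent_id identifier of the parent vessel or `NA`.
#' @param daughter_ids character vector of daughter identifiers.
#' @return list of class `vessel` with fields `id`, `kind`, `points`,
#'   `length`, `parent_id`, `daughter_ids`.  `kind` is filled in by
#'   [build_labeled_tree()] / [classify_vessels()].
#' @export
new_vessel <- function(id, points, parent_id = NA_character_,
                       daughter_ids = character()) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "z", "r") %in% names(points)))
  if (nrow(points) < 2L) stop("degenerate vessel: fewer than 2 points")
  if (!all(is.finite(as.matrix(points[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(!is.finite(points$r)) || any(points$r <= 0))
    stop("radii must be positive and finite")
  structure(list(
    id = as.character(id),
    kind = NA_character_,
    points = points[, c("x", "y", "z", "r")],
    length = vessel_length(points),
    parent_id = parent_id,
    daughter_ids = as.character(daughter_ids)
  ), class = "vessel")
}

#' Arc length of a centerline polyline
#'
#' Sum of Euclidean distances between consecutive points.
#'
#' @param points data.frame (or matrix) with columns `x`, `y`, `z`.
#' @return length in cm.
#' @examples
#' vessel_length(data.frame(x = c(0, 3), y = c(0, 4), z = c(0, 0), r = 1))
#' @export
vessel_length <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  if (nrow(pts) < 2L) stop("degenerate vessel: fewer than 2 points")
  d <- diff(pts)
  sum(sqrt(rowSums(d * d)))
}

#' Build a labeled directed tree from centerline polylines
#'
#' Polylines become vessels (edges); junctions are the nodes where a
#' polyline's first point coincides (within `tol`) with another polyline's
#' last point.  Vessels are classified as root / central / terminal and
#' assigned their arc length.
#'
#' @param centerlines list of data.frames with columns `x`, `y`, `z`, `r`;
#'   names, if present, become vessel ids (otherwise `V1`, `V2`, ...).
#' @param junctions optional matrix/data.frame of junction node positions
#'   used only to sanity-check that each declared junction coincides with a
#'   polyline endpoint.
#' @param tol merge tolerance (cm) when matching endpoints; default 1e-6.
#' @return object of class `labeled_tree`: list with `vessels` (named list
#'   of `vessel`), `root_id`, `connectivity` (named list parent -> daughters).
#' @export
build_labeled_tree <- function(centerlines, junctions = NULL, tol = 1e-6) {
  n <- length(centerlines)
  stopifnot(n >= 1L)
  ids <- names(centerlines)
  if (is.null(ids) || any(!nzchar(ids))) ids <- paste0("V", seq_len(n))
  for (cl in centerlines)
    if (nrow(as.data.frame(cl)) < 2L) stop("degenerate vessel: fewer than 2 points")

  starts <- t(vapply(centerlines, function(p) as.numeric(p[1L, c("x", "y", "z")]),
                     numeric(3)))
  ends <- t(vapply(centerlines, function(p) {
    p <- as.data.frame(p); as.numeric(p[nrow(p), c("x", "y", "z")])
  }, numeric(3)))

  # parent of i = polyline whose end coincides with i's start
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    d2 <- rowSums((ends - matrix(starts[i, ], n, 3, byrow = TRUE))^2)
    d2[i] <- Inf
    hit <- which(d2 <= tol^2)
    if (length(hit) > 1L) stop("ambiguous connectivity: multiple parents match")
    if (length(hit) == 1L) parent[i] <- hit
  }
  roots <- which(is.na(parent))
  if (length(roots) == 0L) stop("not a tree: cycle detected")
  if (length(roots) > 1L) stop("disconnected network")

  # cycle / reachability check
  seen <- rep(FALSE, n)
  stack <- roots
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) stop("not a tree: cycle detected")
    seen[v] <- TRUE
    stack <- c(stack, which(parent == v))
  }
  if (!all(seen)) stop("disconnected network")

  if (!is.null(junctions)) {
    jm <- as.matrix(as.data.frame(junctions))[, 1:3, drop = FALSE]
    endpts <- rbind(starts, ends)
    for (j in seq_len(nrow(jm))) {
      d2 <- rowSums((endpts - matrix(as.numeric(jm[j, ]), nrow(endpts), 3,
                                     byrow = TRUE))^2)
      if (min(d2) > tol^2)
        warning("junction ", j, " does not coincide with any polyline endpoint")
    }
  }

  vessels <- vector("list", n)
  names(vessels) <- ids
  for (i in seq_len(n)) {
    dts <- ids[which(parent == i)]
    if (length(dts) > 3L) stop("unsupported junction degree")
    if (length(dts) == 1L) stop("unsupported junction degree: single daughter")
    vessels[[i]] <- new_vessel(ids[i], centerlines[[i]],
                               parent_id = if (is.na(parent[i])) NA_character_ else ids[parent[i]],
                               daughter_ids = dts)
  }
  tree <- structure(list(
    vessels = vessels,
    root_id = ids[roots],
    connectivity = NULL
  ), class = "labeled_tree")
  tree <- classify_vessels(tree)
  tree$connectivity <- connectivity_map(tree)
  validate_tree(tree)
  tree
}

#' Assign root / central / terminal labels
#' @param tree a `labeled_tree`.
#' @return the tree with `kind` set on every vessel.
#' @export
classify_vessels <- function(tree) {
  for (id in names(tree$vessels)) {
    v <- tree$vessels[[id]]
    tree$vessels[[id]]$kind <-
      if (is.na(v$parent_id)) "root"
      else if (length(v$daughter_ids) == 0L) "terminal"
      else "central"
  }
  tree
}

connectivity_map <- function(tree) {
  con <- lapply(tree$vessels, function(v) v$daughter_ids)
  con[vapply(con, length, 1L) > 0L]
}

#' Validate labeled-tree invariants
#'
#' Checks: exactly one root, acyclic, parent/daughter fields mutually
#' consistent with the connectivity map, daughter counts in {0, 2, 3},
#' vessel lengths equal to polyline arc length, positive radii.
#'
#' @param tree a `labeled_tree`.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_tree <- function(tree) {
  vs <- tree$vessels
  ids <- names(vs)
  stopifnot(length(ids) >= 1L, !anyDuplicated(ids))
  roots <- ids[vapply(vs, function(v) is.na(v$parent_id), TRUE)]
  if (length(roots) != 1L || roots != tree$root_id)
    stop("tree must have exactly one root matching root_id")
  for (id in ids) {
    v <- vs[[id]]
    nd <- length(v$daughter_ids)
    if (!nd %in% c(0L, 2L, 3L)) stop("unsupported junction degree at ", id)
    for (d in v$daughter_ids) {
      if (!d %in% ids) stop("unknown daughter ", d)
      if (!identical(vs[[d]]$parent_id, id))
        stop("parent/daughter fields disagree at ", id, " -> ", d)
    }
    if (!is.na(v$parent_id) && !(id %in% vs[[v$parent_id]]$daughter_ids))
      stop("parent/daughter fields disagree at ", v$parent_id, " -> ", id)
    if (abs(v$length - vessel_length(v$points)) > 1e-8 * max(1, v$length))
      stop("stored length differs from arc length at ", id)
    if (any(v$points$r <= 0)) stop("non-positive radius in ", id)
    if (v$kind == "terminal" && nd > 0L) stop("terminal vessel with daughters: ", id)
    if (v$kind == "root" && !is.na(v$parent_id)) stop("root with parent: ", id)
  }
  # acyclicity via walk from root
  seen <- character()
  stack <- tree$root_id
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v %in% seen) stop("not a tree: cycle detected")
    seen <- c(seen, v)
    stack <- c(stack, vs[[v]]$daughter_ids)
  }
  if (length(seen) != length(ids)) stop("disconnected network")
  con <- connectivity_map(tree)
  if (!is.null(tree$connectivity) &&
      !identical(con[order(names(con))],
                 tree$connectivity[order(names(tree$connectivity))]))
    stop("connectivity map out of step with vessel fields")
  invisible(TRUE)
}

#' @export
print.labeled_tree <- function(x, ...) {
  kinds <- vapply(x$vessels, function(v) v$kind, "")
  cat("labeled_tree:", length(x$vessels), "vessels (",
      sum(kinds == "root"), "root,", sum(kinds == "central"), "central,",
      sum(kinds == "terminal"), "terminal ), total length",
      format(total_tree_length(x), digits = 5), "cm\n")
  invisible(x)
}

#' Total arc length of all vessels in a tree
#' @param tree a `labeled_tree`.
#' @return total length (cm).
#' @export
total_tree_length <- function(tree)
  sum(vapply(tree$vessels, function(v) v$length, 1.0))

#' Vessel-level summary table
#' @param tree a `labeled_tree`.
#' @return data.frame with id, kind, length_cm, n_points, mean_radius_cm.
#' @export
tree_summary <- function(tree) {
  data.frame(
    id = names(tree$vessels),
    kind = vapply(tree$vessels, function(v) v$kind, ""),
    length_cm = vapply(tree$vessels, function(v) v$length, 1.0),
    n_points = vapply(tree$vessels, function(v) nrow(v$points), 1L),
    mean_radius_cm = vapply(tree$vessels, function(v) mean(v$points$r), 1.0),
    row.names = NULL
  )
}

vessel_depths <- function(tree) {
  depth <- setNames(rep(NA_integer_, length(tree$vessels)), names(tree$vessels))
  depth[tree$root_id] <- 0L
  stack <- tree$root_id
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (d in tree$vessels[[v]]$daughter_ids) {
      depth[d] <- depth[v] + 1L
      stack <- c(stack, d)
    }
  }
  depth
}

representative_radius <- function(vessel, stat = c("mean", "min", "tip")) {
  stat <- match.arg(stat)
  r <- vessel$points$r
  switch(stat, mean = mean(r), min = min(r), tip = r[length(r)])
}

#' Prune a tree to a standard vessel count
#'
#' Iteratively removes the smallest terminal vessel that has a terminal
#' sibling, ordered by ascending representative radius (ties broken
#' lexicographically by id).  At a bifurcation whose daughters are both
#' terminal the pair is removed and the parent becomes terminal; at a
#' trifurcation a single terminal daughter is removed, leaving a
#' bifurcation.  Stops at the first vessel count that does not exceed
#' `target`.
#'
#' @param tree a `labeled_tree`.
#' @param target desired vessel count (>= 1).
#' @param radius_stat which per-point radius summary orders removal:
#'   `"mean"` (default), `"min"` or `"tip"`.
#' @return the pruned `labeled_tree`.  If `target` is not below the current
#'   count a warning ("nothing to prune") is raised and the tree returned
#'   unchanged.
#' @export
prune_to_size <- function(tree, target, radius_stat = "mean") {
  stopifnot(target >= 1)
  if (target >= length(tree$vessels)) {
    if (target > length(tree$vessels)) warning("nothing to prune")
    return(tree)
  }
  removed <- list()
  repeat {
    if (length(tree$vessels) <= target) break
    vs <- tree$vessels
    # eligible: terminal vessels with at least one terminal sibling
    elig <- character()
    for (id in names(vs)) {
      v <- vs[[id]]
      if (v$kind != "terminal" || is.na(v$parent_id)) next
      sibs <- setdiff(vs[[v$parent_id]]$daughter_ids, id)
      if (any(vapply(sibs, function(s) vs[[s]]$kind == "terminal", TRUE)))
        elig <- c(elig, id)
    }
    if (!length(elig)) {
      warning("no terminal sibling pairs left; stopping at ",
              length(tree$vessels), " vessels")
      break
    }
    rad <- vapply(elig, function(id)
      representative_radius(vs[[id]], radius_stat), 1.0)
    pick <- elig[order(rad, elig)][1L]
    par <- vs[[pick]]$parent_id
    sibs <- vs[[par]]$daughter_ids
    if (length(sibs) == 2L) {
      drop_ids <- sibs                       # remove the terminal pair
    } else {
      drop_ids <- pick                       # trifurcation: single removal
    }
    tree$vessels[drop_ids] <- NULL
    tree$vessels[[par]]$daughter_ids <- setdiff(sibs, drop_ids)
    tree <- classify_vessels(tree)
    removed <- c(removed, list(sort(drop_ids)))
  }
  tree$connectivity <- connectivity_map(tree)
  validate_tree(tree)
  attr(tree, "removed") <- removed   # removal units, in order of removal
  tree
}
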