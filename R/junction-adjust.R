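# ---- junction relocation into the ostium -----------------------------------
#
# Centerline software places junction nodes where maximally inscribed
# spheres first intersect, often upstream of the ostium; the daughter
# centerlines then run nearly coincident until the true split.  The fix:
# (1) find the first node index k at which the inter-daughter distance
# exceeds a fraction of its maximum, (2) replace the coincident daughter
# prefixes by their average, appended to the parent, and (3) smooth the
# daughter nodes in the 10-20% divergence band by a weighted average with
# the extended parent path.

#' Parameters for junction adjustment
#'
#' @param cutoff_low divergence ratio defining the new junction (default 0.1).
#' @param cutoff_high upper ratio of the smoothing band (default 0.2).
#' @param w smoothing weight: 2 suits rapidly branching (pulmonary-like)
#'   networks, 100 suits aorta-like geometries.
#' @param weight_target which path the weight `w` multiplies in the
#'   smoothing average: the printed formula weights the `"daughter"` nodes;
#'   `"parent"` inverts it for sensitivity analysis.
#' @return list of class `junction_adjust_params`.
#' @export
junction_adjust_params <- function(cutoff_low = 0.1, cutoff_high = 0.2,
                                   w = 2, weight_target = c("daughter", "parent")) {
  stopifnot(cutoff_low > 0, cutoff_low < cutoff_high, cutoff_high <= 1, w > 0)
  structure(list(cutoff_low = cutoff_low, cutoff_high = cutoff_high, w = w,
                 weight_target = match.arg(weight_target)),
            class = "junction_adjust_params")
}

#' Node-wise distance between two daughter centerlines
#'
#' `D(i)` is the Euclidean distance between the i-th nodes of the two
#' daughters, for i = 1..N where N is the node count of the shorter
#' daughter.
#'
#' @param d1_points,d2_points data.frames with columns x, y, z.
#' @return numeric vector of length N.
#' @export
daughter_distances <- function(d1_points, d2_points) {
  if (nrow(d1_points) == 0L || nrow(d2_points) == 0L)
    stop("empty daughter vessel")
  N <- min(nrow(d1_points), nrow(d2_points))
  a <- as.matrix(d1_points[1:N, c("x", "y", "z")])
  b <- as.matrix(d2_points[1:N, c("x", "y", "z")])
  unname(sqrt(rowSums((a - b)^2)))
}

#' Select the daughter pair that defines the junction geometry
#'
#' For a bifurcation this is the only pair; for a trifurcation, the pair
#' with the smallest mean node-wise distance.
#'
#' @param daughters list of 2 or 3 point data.frames.
#' @return integer vector of length 2: indices of the selected pair.
#' @export
select_daughter_pair <- function(daughters) {
  nd <- length(daughters)
  if (nd < 2L) stop("not a junction")
  if (nd == 2L) return(c(1L, 2L))
  pairs <- utils::combn(nd, 2)
  score <- apply(pairs, 2, function(p)
    mean(daughter_distances(daughters[[p[1]]], daughters[[p[2]]])))
  as.integer(pairs[, which.min(score)])
}

#' Locate the new junction index from the divergence profile
#'
#' The new junction is placed at the smallest index i for which
#' `D(i)/max(D) > cutoff_low`.
#'
#' @param D node-wise daughter distances.
#' @param cutoff_low divergence threshold ratio.
#' @param Dmax normalization; by default the maximum of `D` over the
#'   compared span (an endpoint-anchored value may be supplied instead).
#' @return list with `k` (index, or NA when the daughters never diverge
#'   past the threshold — flagged, junction left at the vessel end) and
#'   `diverged` logical.
#' @export
find_new_junction <- function(D, cutoff_low = 0.1, Dmax = max(D)) {
  if (!(Dmax > 0)) return(list(k = NA_integer_, diverged = FALSE))
  hit <- which(D / Dmax > cutoff_low)
  if (!length(hit)) return(list(k = NA_integer_, diverged = FALSE))
  list(k = min(hit), diverged = TRUE)
}

#' Average daughter prefixes into new parent nodes
#'
#' Nodes i = 1..k of the parent extension are the arithmetic mean of the
#' daughters' i-th node positions; radii are averaged the same way (they
#' lie in the ostium and are later excluded by the optimal-radius segment).
#'
#' @param daughters list of point data.frames (x, y, z, r).
#' @param k number of prefix nodes to average.
#' @return data.frame of k new parent nodes.
#' @export
extend_parent <- function(daughters, k) {
  stopifnot(k >= 1)
  for (d in daughters)
    if (nrow(d) < k) stop("index overflow: daughter shorter than k")
  out <- 0
  for (d in daughters) out <- out + as.matrix(d[1:k, c("x", "y", "z", "r")])
  as.data.frame(out / length(daughters))
}

#' Smooth daughter nodes in the divergence band
#'
#' For nodes i = k..m (where m is the first index with
#' `D(i)/Dmax >= cutoff_high`, or N if none), each daughter's node is
#' replaced by the weighted average `(w*xd + xp)/(w + 1)` with the parent
#' extension `xp` (the running mean of the daughters' positions, i = k..N).
#' Radii are left unchanged.  Nodes beyond m are untouched.
#'
#' @param daughters list of point data.frames.
#' @param D node-wise distances of the defining pair.
#' @param k junction index from [find_new_junction()].
#' @param params a `junction_adjust_params`.
#' @return list of adjusted daughter data.frames (full length).
#' @export
smooth_daughters <- function(daughters, D, k, params) {
  N <- length(D)
  Dmax <- max(D)
  hit <- which(D / Dmax >= params$cutoff_high)
  m <- if (length(hit)) min(hit) else N
  if (m < k) return(daughters)
  Nall <- min(vapply(daughters, nrow, 1L))
  m <- min(m, Nall)
  ext <- extend_parent(daughters, min(N, Nall))  # parent path over i = 1..N
  w <- params$w
  for (j in seq_along(daughters)) {
    d <- daughters[[j]]
    for (i in k:m) {
      if (i > nrow(d)) break
      xd <- as.numeric(d[i, c("x", "y", "z")])
      xp <- as.numeric(ext[i, c("x", "y", "z")])
      newpt <- if (params$weight_target == "daughter")
        (w * xd + xp) / (w + 1) else (xd + w * xp) / (w + 1)
      d[i, c("x", "y", "z")] <- as.list(newpt)
    }
    daughters[[j]] <- d
  }
  daughters
}

#' Relocate every junction of a tree into the ostium
#'
#' Junctions are processed from the terminal-most junctions toward the
#' root.  At each junction the defining daughter pair is selected, the new
#' junction index k located, the averaged daughter prefix (nodes 1..k)
#' appended to the parent, the daughters trimmed to start at node k, and
#' the divergence band smoothed.  Connectivity is unchanged; vessel point
#' lists and lengths are updated.
#'
#' @param tree a `labeled_tree`.
#' @param params a [junction_adjust_params()].
#' @return list with `tree` (adjusted) and `report`, a data.frame with one
#'   row per junction (parent id, k, m, old/new junction coordinates, flag).
#' @export
adjust_all_junctions <- function(tree, params = junction_adjust_params()) {
  depth <- vessel_depths(tree)
  parents <- names(tree$vessels)[vapply(tree$vessels, function(v)
    length(v$daughter_ids) > 0, TRUE)]
  parents <- parents[order(-depth[parents])]  # terminal-most junctions first
  rows <- list()
  for (pid in parents) {
    did <- tree$vessels[[pid]]$daughter_ids
    daughters <- lapply(did, function(d) tree$vessels[[d]]$points)
    old_j <- as.numeric(tree$vessels[[pid]]$points[
      nrow(tree$vessels[[pid]]$points), c("x", "y", "z")])
    res <- tryCatch(
      adjust_one_junction(daughters, params),
      error = function(e) stop("junction at ", pid, ": ", conditionMessage(e)))
    if (!res$diverged) {
      rows[[pid]] <- data.frame(parent = pid, k = NA, m = NA,
                                old_x = old_j[1], old_y = old_j[2], old_z = old_j[3],
                                new_x = old_j[1], new_y = old_j[2], new_z = old_j[3],
                                flag = "daughters never diverge; junction left at vessel end")
      next
    }
    pv <- tree$vessels[[pid]]
    pv$points <- rbind(pv$points, res$parent_nodes)
    pv$length <- vessel_length(pv$points)
    tree$vessels[[pid]] <- pv
    for (j in seq_along(did)) {
      dv <- tree$vessels[[did[j]]]
      dv$points <- res$daughters[[j]]
      dv$length <- vessel_length(dv$points)
      tree$vessels[[did[j]]] <- dv
    }
    new_j <- as.numeric(res$parent_nodes[nrow(res$parent_nodes), c("x", "y", "z")])
    rows[[pid]] <- data.frame(parent = pid, k = res$k, m = res$m,
                              old_x = old_j[1], old_y = old_j[2], old_z = old_j[3],
                              new_x = new_j[1], new_y = new_j[2], new_z = new_j[3],
                              flag = "")
  }
  validate_tree(tree)
  list(tree = tree, report = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

# core per-junction geometry; daughters is a list of point data.frames
adjust_one_junction <- function(daughters, params) {
  pair <- select_daughter_pair(daughters)
  D <- daughter_distances(daughters[[pair[1]]], daughters[[pair[2]]])
  loc <- find_new_junction(D, params$cutoff_low)
  if (!loc$diverged) return(list(diverged = FALSE))
  k <- loc$k
  # every daughter must retain at least 2 nodes after trimming at k
  k <- min(k, min(vapply(daughters, nrow, 1L)) - 1L)
  if (k < 1L) return(list(diverged = FALSE))
  parent_nodes <- extend_parent(daughters, k)
  sm <- smooth_daughters(daughters, D, k, params)
  trimmed <- lapply(sm, function(d) {
    d <- d[k:nrow(d), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  Dmax <- max(D)
  hit <- which(D / Dmax >= params$cutoff_high)
  m <- if (length(hit)) min(hit) else length(D)
  list(diverged = TRUE, k = k, m = m, parent_nodes = parent_nodes,
       daughters = trimmed)
}
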