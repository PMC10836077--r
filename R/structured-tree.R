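# ---- asymmetric self-similar structured trees ------------------------------
#
# Vessels below image resolution are represented by fractal trees appended
# to each terminal vessel: every parent of radius r_p has daughters of
# radius alpha*r_p and beta*r_p, every vessel has length lrr * r, and the
# recursion stops when a would-be daughter radius falls below r_min.

#' Structured-tree parameters
#'
#' @param alpha,beta daughter radius scale factors, 0 < beta <= alpha < 1,
#'   alpha + beta >= 1.
#' @param lrr length-to-radius ratio.
#' @param r_min termination radius (cm); default 0.001 cm, a red blood
#'   cell's diameter.
#' @param k1S,k2S,k3S small-vessel stiffness constants (g/cm/s^2, 1/cm,
#'   g/cm/s^2) in Eh/r0 = k1S exp(k2S r0) + k3S.
#' @param pre_check a vessel is generated only if its radius >= r_min
#'   (default TRUE); FALSE generates the first sub-threshold daughter as a
#'   leaf before stopping.
#' @return list of class `structured_tree_params`.
#' @export
structured_tree_params <- function(alpha = 0.88, beta = 0.697, lrr = 15.75,
                                   r_min = 0.001, k1S = 2.5e7, k2S = -15,
                                   k3S = 8e5, pre_check = TRUE) {
  stopifnot(beta > 0, beta <= alpha, alpha < 1, alpha + beta >= 1, r_min > 0,
            lrr > 0)
  structure(list(alpha = alpha, beta = beta, lrr = lrr, r_min = r_min,
                 k1S = k1S, k2S = k2S, k3S = k3S, pre_check = pre_check),
            class = "structured_tree_params")
}

#' Materialize a structured tree
#'
#' Builds the binary tree rooted at `r_root`.  Daughters take radii
#' alpha*r and beta*r; lengths are `lrr * r`.  With the default pre-check
#' semantics a vessel exists only if its radius >= r_min, so a parent
#' whose would-be daughters both fall below r_min is a leaf.
#'
#' @param r_root root radius (cm).
#' @param params a [structured_tree_params()].
#' @param max_vessels safety cap on tree size.
#' @return data.frame with one row per vessel: `id`, `parent`,
#'   `generation` (root = 0), `radius`, `length`, `is_leaf`.  A root below
#'   r_min yields a single-leaf tree, flagged via attribute `flag`.
#' @export
build_structured_tree <- function(r_root, params = structured_tree_params(),
                                  max_vessels = 5e5) {
  flag <- ""
  if (r_root < params$r_min) flag <- "root below r_min: single-leaf tree"
  ids <- character(); parent <- character(); gen <- integer()
  rad <- numeric(); leaf <- logical()
  # iterative DFS over (id, parent, generation, radius)
  stack <- list(list(id = "1", parent = NA_character_, g = 0L, r = r_root))
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- length(ids) + 1L
    if (i > max_vessels) stop("structured tree exceeds max_vessels")
    ids[i] <- nd$id; parent[i] <- nd$parent; gen[i] <- nd$g; rad[i] <- nd$r
    rd <- nd$r * c(params$alpha, params$beta)
    keep <- if (nd$r < params$r_min) c(FALSE, FALSE)
            else if (params$pre_check) rd >= params$r_min
            else c(TRUE, TRUE)   # post-check: sub-threshold daughters are leaves
    leaf[i] <- !any(keep)
    for (j in which(keep))
      stack[[length(stack) + 1L]] <-
        list(id = paste0(nd$id, c("a", "b")[j]), parent = nd$id, g = nd$g + 1L,
             r = rd[j])
  }
  out <- data.frame(id = ids, parent = parent, generation = gen,
                    radius = rad, length = params$lrr * rad, is_leaf = leaf)
  attr(out, "flag") <- flag
  out
}

#' Summarize a structured tree by generation
#'
#' @param st data.frame from [build_structured_tree()].
#' @return data.frame: generation, count, min/max radius, total length.
#' @export
structured_tree_generations <- function(st) {
  sp <- split(st, st$generation)
  do.call(rbind, lapply(sp, function(g) data.frame(
    generation = g$generation[1], count = nrow(g),
    r_min = min(g$radius), r_max = max(g$radius),
    total_length = sum(g$length))))
}

#' Diameter-dependent apparent blood viscosity in small vessels
#'
#' The apparent viscosity of blood drops in microvessels
#' (Fahraeus-Lindqvist effect) before recovering toward the bulk value.
#' The law used here evaluates, for a vessel of radius `r0`,
#' `mu_S = (mu_L / 3.2) * D * (1 + D * (eta(r) - 1))` with
#' `eta(r) = 6 exp(-0.17 r) + 3.2 - 2.44 exp(-0.12 r^0.645)` the relative
#' viscosity at a hematocrit of 0.45 and `D = 2r/(2r - 1.12)` the
#' plasma-layer correction, where r is the radius in micrometres (the
#' 1.12 um constant is the plasma-layer scale, so radii are converted from
#' cm internally).  As the diameter grows, D -> 1 and eta -> 3.2, so
#' mu_S -> mu_L.
#'
#' @param r0 vessel radius (cm).
#' @param mu_L large-vessel (bulk) viscosity (g/cm/s).
#' @return apparent viscosity mu_S (g/cm/s).
#' @export
small_vessel_viscosity <- function(r0, mu_L = 0.032) {
  stopifnot(all(r0 > 0))
  r_um <- r0 * 1e4
  d_um <- 2 * r_um
  if (any(d_um <= 1.12)) stop("below plasma-layer scale: 2*r0 <= 1.12 um")
  D <- d_um / (d_um - 1.12)
  eta <- 6 * exp(-0.17 * r_um) + 3.2 - 2.44 * exp(-0.12 * r_um^0.645)
  (mu_L / 3.2) * D * (1 + D * (eta - 1))
}
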