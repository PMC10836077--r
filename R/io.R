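# ---- readers and writers ----------------------------------------------------
#
# Centerlines come from centerline-extraction software as VTK XML polydata
# (points + polyline connectivity + a per-point inscribed-sphere radius
# array) or as a flat CSV table; labeled trees round-trip through a
# versioned JSON schema plus a flat CSV summary.  Coordinates are cm
# throughout.

#' Read centerlines from VTK XML polydata or CSV
#'
#' The VTK dialect expects an ASCII XML PolyData file with a `Points`
#' array, a `Lines` connectivity/offsets pair and a per-point radius
#' array (name configurable).  The CSV dialect expects columns
#' `vessel_id`, `point_index` (1-based), `x`, `y`, `z`, `r`.
#' Connectivity is inferred downstream from shared endpoints by
#' [build_labeled_tree()].
#'
#' @param path file path.
#' @param dialect "vtk-polydata" or "csv"; guessed from the extension by
#'   default.
#' @param radius_array name of the VTK point-data radius array.
#' @return named list of centerline data.frames (x, y, z, r).
#' @export
read_centerlines <- function(path, dialect = c("auto", "vtk-polydata", "csv"),
                             radius_array = "MaximumInscribedSphereRadius") {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vtp$|\\.xml$", path, ignore.case = TRUE))
      "vtk-polydata" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    d <- utils::read.csv(path)
    need <- c("vessel_id", "point_index", "x", "y", "z", "r")
    if (!all(need %in% names(d)))
      stop("malformed centerline CSV: need columns ",
           paste(need, collapse = ", "))
    if (!"r" %in% names(d) || all(is.na(d$r))) stop("no radius data")
    sp <- split(d, d$vessel_id)
    out <- lapply(sp, function(v) {
      v <- v[order(v$point_index), ]
      data.frame(x = v$x, y = v$y, z = v$z, r = v$r)
    })
    return(out[unique(as.character(d$vessel_id))])
  }
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("malformed polydata: no Piece node")
  num <- function(node) {
    if (inherits(node, "xml_missing")) return(numeric())
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- num(xml2::xml_find_first(piece, ".//Points/DataArray"))
  if (!length(pts)) stop("malformed polydata: no points")
  P <- matrix(pts, ncol = 3, byrow = TRUE)
  rad_node <- xml2::xml_find_first(piece, sprintf(
    ".//PointData/DataArray[@Name='%s']", radius_array))
  if (inherits(rad_node, "xml_missing")) stop("no radius data")
  r <- num(rad_node)
  if (length(r) != nrow(P)) stop("malformed polydata: radius length mismatch")
  conn <- num(xml2::xml_find_first(piece, ".//Lines/DataArray[@Name='connectivity']"))
  offs <- num(xml2::xml_find_first(piece, ".//Lines/DataArray[@Name='offsets']"))
  if (!length(offs)) stop("malformed polydata: no line offsets")
  out <- list()
  lo <- 1L
  nm <- xml2::xml_attr(xml2::xml_find_all(piece, ".//Lines"), "Name")
  for (i in seq_along(offs)) {
    idx <- conn[lo:offs[i]] + 1L           # VTK indices are 0-based
    out[[paste0("V", i)]] <- data.frame(x = P[idx, 1], y = P[idx, 2],
                                        z = P[idx, 3], r = r[idx])
    lo <- offs[i] + 1L
  }
  out
}

#' Write centerlines as VTK XML polydata or CSV
#'
#' @param centerlines named list of x/y/z/r data.frames.
#' @param path output path.
#' @param dialect as in [read_centerlines()].
#' @param radius_array VTK radius array name.
#' @return invisibly `path`.
#' @export
write_centerlines <- function(centerlines, path,
                              dialect = c("auto", "vtk-polydata", "csv"),
                              radius_array = "MaximumInscribedSphereRadius") {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vtp$|\\.xml$", path, ignore.case = TRUE))
      "vtk-polydata" else "csv"
  if (dialect == "csv") {
    rows <- lapply(names(centerlines), function(id) {
      v <- centerlines[[id]]
      data.frame(vessel_id = id, point_index = seq_len(nrow(v)),
                 x = v$x, y = v$y, z = v$z, r = v$r)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    return(invisible(path))
  }
  np <- vapply(centerlines, nrow, 1L)
  P <- do.call(rbind, lapply(centerlines, function(v)
    as.matrix(v[, c("x", "y", "z")])))
  r <- unlist(lapply(centerlines, function(v) v$r), use.names = FALSE)
  offs <- cumsum(np)
  conn <- seq_len(sum(np)) - 1L
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    "  <PolyData>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="0">',
            sum(np), length(np)),
    "      <Points>",
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste0("          ", fmt(t(P))),
    "        </DataArray>",
    "      </Points>",
    "      <PointData>",
    sprintf('        <DataArray type="Float64" Name="%s" format="ascii">',
            radius_array),
    paste0("          ", fmt(r)),
    "        </DataArray>",
    "      </PointData>",
    "      <Lines>",
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste0("          ", paste(conn, collapse = " ")),
    "        </DataArray>",
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste0("          ", paste(offs, collapse = " ")),
    "        </DataArray>",
    "      </Lines>",
    "    </Piece>",
    "  </PolyData>",
    "</VTKFile>")
  writeLines(xml, path)
  invisible(path)
}

#' Write a labeled tree to JSON
#'
#' Versioned schema: vessels (id, kind, parent, daughters, length,
#' per-point arrays, radius summary when present), root id, connectivity.
#'
#' @param tree a `labeled_tree`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(
    schema = "vasctrees/tree/1",
    root_id = tree$root_id,
    connectivity = tree$connectivity,
    vessels = lapply(tree$vessels, function(v) {
      out <- list(id = v$id, kind = v$kind, parent_id = v$parent_id,
                  daughter_ids = I(v$daughter_ids), length = v$length,
                  points = as.list(v$points))
      if (!is.null(v$radius)) out$radius <- unclass(v$radius)
      out
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a labeled tree from JSON
#'
#' @param path file written by [write_tree_json()].
#' @return a `labeled_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  vessels <- lapply(obj$vessels, function(v) {
    vv <- new_vessel(v$id, as.data.frame(v$points),
                     parent_id = if (is.null(v$parent_id)) NA_character_ else v$parent_id,
                     daughter_ids = unlist(v$daughter_ids))
    if (!is.null(v$radius)) {
      rs <- v$radius
      rs$psi <- as.integer(unlist(rs$psi))
      rs$r_hat <- unlist(rs$r_hat)
      rs$ropt_range <- unlist(rs$ropt_range)
      vv$radius <- structure(rs, class = "radius_summary")
    }
    vv
  })
  names(vessels) <- vapply(vessels, function(v) v$id, "")
  tree <- structure(list(vessels = vessels, root_id = obj$root_id,
                         connectivity = NULL), class = "labeled_tree")
  tree <- classify_vessels(tree)
  tree$connectivity <- connectivity_map(tree)
  validate_tree(tree)
  tree
}

#' Flat CSV summary of a tree
#' @param tree a `labeled_tree`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_tree_csv <- function(tree, path) {
  utils::write.csv(tree_summary(tree), path, row.names = FALSE)
  invisible(path)
}
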