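# Simplicial mesh containers ---------------------------------------------
#
# A mesh is a list with class "surface_mesh" or "volume_mesh":
#   vertices : n x 3 numeric matrix, Cartesian coordinates (mm or cm)
#   cells    : m x 3 (triangles) or m x 4 (tetrahedra) integer matrix,
#              1-based vertex indices
#   vertex_normals : optional n x 3 matrix of unit outward normals
#   fields   : named list; each entry is a numeric vector of length n
#              (per-vertex) or m (per-element)
# File formats exchange 0-based indices; in memory everything is 1-based.

#' Construct a triangulated surface mesh
#'
#' @param vertices numeric matrix with 3 columns of Cartesian coordinates.
#' @param triangles integer matrix with 3 columns of 1-based vertex indices.
#' @param vertex_normals optional matrix of per-vertex unit outward normals.
#' @param fields named list of scalar arrays, one value per vertex or per
#'   triangle.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, vertex_normals = NULL,
                         fields = list()) {
  m <- structure(list(
    vertices = as_coord_matrix(vertices),
    cells = as_cell_matrix(triangles, 3L),
    vertex_normals = if (!is.null(vertex_normals)) as_coord_matrix(vertex_normals),
    fields = fields
  ), class = c("surface_mesh", "dotmap_mesh"))
  validate_mesh(m)
  m
}

#' Construct a tetrahedral volume mesh
#'
#' @param vertices numeric matrix with 3 columns of Cartesian coordinates.
#' @param tetrahedra integer matrix with 4 columns of 1-based vertex indices.
#' @param fields named list of scalar arrays, one value per vertex or per
#'   tetrahedron.
#' @return an object of class `volume_mesh`.
#' @export
volume_mesh <- function(vertices, tetrahedra, fields = list()) {
  m <- structure(list(
    vertices = as_coord_matrix(vertices),
    cells = as_cell_matrix(tetrahedra, 4L),
    vertex_normals = NULL,
    fields = fields
  ), class = c("volume_mesh", "dotmap_mesh"))
  validate_mesh(m)
  m
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  dimnames(x) <- NULL
  x
}

as_cell_matrix <- function(x, k) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (ncol(x) != k) stop(sprintf("cells must have %d columns", k))
  dimnames(x) <- NULL
  x
}

validate_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  cells <- mesh$cells
  if (nrow(cells) > 0) {
    if (any(cells < 1L) || any(cells > nv))
      stop("cell indices out of range")
    dup <- apply(cells, 1L, anyDuplicated) > 0L
    if (any(dup))
      stop(sprintf("cell %d repeats a vertex index", which(dup)[1]))
  }
  if (!is.null(mesh$vertex_normals)) {
    if (nrow(mesh$vertex_normals) != nv)
      stop("vertex_normals length does not match vertex count")
    len <- sqrt(rowSums(mesh$vertex_normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("vertex_normals must have unit length (1e-6)")
  }
  for (nm in names(mesh$fields)) {
    f <- mesh$fields[[nm]]
    if (!(length(f) %in% c(nv, nrow(cells))))
      stop(sprintf("field '%s' has length %d; expected %d (vertices) or %d (elements)",
                   nm, length(f), nv, nrow(cells)))
  }
  invisible(mesh)
}

#' @export
print.dotmap_mesh <- function(x, ...) {
  kind <- if (inherits(x, "surface_mesh")) "surface_mesh (triangles)"
          else "volume_mesh (tetrahedra)"
  cat(sprintf("%s: %d vertices, %d elements\n", kind,
              nrow(x$vertices), nrow(x$cells)))
  if (length(x$fields))
    cat("fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

#' Number of elements (triangles or tetrahedra) in a mesh
#' @param mesh a `surface_mesh` or `volume_mesh`.
#' @export
n_elements <- function(mesh) nrow(mesh$cells)

#' Geometric centroid of a mesh (mean vertex position)
#' @param mesh a mesh object.
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Per-element area or volume
#'
#' Triangle area is half the magnitude of the edge cross product; tetrahedron
#' volume is |det|/6 of the edge matrix.  Degenerate elements yield 0 and are
#' retained (they receive a zero Poisson mean downstream, hence no dots).
#'
#' @param mesh a `surface_mesh` (returns mm^2) or `volume_mesh` (mm^3).
#' @return numeric vector of non-negative element measures.
#' @export
element_measure <- function(mesh) {
  v <- mesh$vertices
  c1 <- mesh$cells
  if (inherits(mesh, "surface_mesh")) {
    ab <- v[c1[, 2], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
    ac <- v[c1[, 3], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
    cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
    0.5 * sqrt(rowSums(cx^2))
  } else {
    ab <- v[c1[, 2], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
    ac <- v[c1[, 3], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
    ad <- v[c1[, 4], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
    det <- ab[, 1] * (ac[, 2] * ad[, 3] - ac[, 3] * ad[, 2]) -
           ab[, 2] * (ac[, 1] * ad[, 3] - ac[, 3] * ad[, 1]) +
           ab[, 3] * (ac[, 1] * ad[, 2] - ac[, 2] * ad[, 1])
    abs(det) / 6
  }
}

# Element data ------------------------------------------------------------

#' Per-element scalar field with a normalization window
#'
#' @param values numeric vector, one scalar per element (physical units,
#'   e.g. mV or LGE signal intensity).
#' @param window length-2 numeric `c(lo, hi)`, lo < hi: the clip-then-scale
#'   window mapped onto \[0, 1\] before the field enters the dot weight.
#'   Defaults to the data range, widened to include 0 for constant fields.
#' @param name label used in exports and rendering.
#' @return an object of class `element_field`.
#' @export
element_field <- function(values, window = default_window(values),
                          name = "S") {
  values <- as.numeric(values)
  window <- as.numeric(window)
  if (length(window) != 2L || !(window[1] < window[2]))
    stop("window must be c(lo, hi) with lo < hi")
  structure(list(values = values, window = window, name = name),
            class = "element_field")
}

# Data range as a window; constant fields get an anchored window so they
# normalize to a well-defined level (a constant-1 field stays at S = 1).
default_window <- function(values) {
  r <- range(values)
  if (r[1] < r[2]) r
  else if (r[2] > 0) c(0, r[2])
  else if (r[2] < 0) c(r[2], 0)
  else c(0, 1)
}

#' @export
print.element_field <- function(x, ...) {
  cat(sprintf("element_field '%s': n=%d, range [%g, %g], window [%g, %g]\n",
              x$name, length(x$values), min(x$values), max(x$values),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Convert per-vertex data to per-element data
#'
#' Each element's value is the arithmetic mean of its 3 (triangle) or 4
#' (tetrahedron) vertex values — the conventional conversion for
#' electroanatomic shells where measurements live on map points.
#'
#' @param mesh a mesh object.
#' @param vertex_field numeric vector of length `nrow(mesh$vertices)`, or the
#'   name of a per-vertex field attached to `mesh`.
#' @param window,name passed to [element_field()]; window defaults to the
#'   range of the vertex data.
#' @return an [element_field()].
#' @export
vertex_to_element_field <- function(mesh, vertex_field,
                                    window = NULL, name = "S") {
  if (is.character(vertex_field) && length(vertex_field) == 1L) {
    name <- vertex_field
    vertex_field <- mesh$fields[[vertex_field]]
    if (is.null(vertex_field)) stop("no such field on mesh: ", name)
  }
  if (length(vertex_field) == n_elements(mesh) &&
      length(vertex_field) != nrow(mesh$vertices)) {
    # already per-element
    return(element_field(vertex_field, window %||% default_window(vertex_field), name))
  }
  if (length(vertex_field) != nrow(mesh$vertices))
    stop("vertex_field length does not match vertex count")
  vals <- matrix(vertex_field[mesh$cells], nrow = nrow(mesh$cells))
  element_field(rowMeans(vals), window %||% default_window(vertex_field), name)
}

#' Normalize an element field to \[0, 1\]
#'
#' Values are clipped to the window then linearly mapped, mirroring clinical
#' voltage/LGE thresholding (e.g. a 0.05–0.5 mV atrial scar window).  The dot
#' weight requires a non-negative scalar, which normalization guarantees.
#'
#' @param field an [element_field()] or numeric vector.
#' @param window optional override of the field's own window.
#' @return an `element_field` with values in \[0, 1\] and window `c(0, 1)`.
#' @export
normalize_field <- function(field, window = NULL) {
  if (is.numeric(field)) field <- element_field(field, window %||% default_window(field))
  w <- window %||% field$window
  if (length(w) != 2L || !(w[1] < w[2])) stop("degenerate window")
  v <- pmin(pmax(field$values, w[1]), w[2])
  element_field((v - w[1]) / (w[2] - w[1]), c(0, 1), field$name)
}

# Normals ------------------------------------------------------------------

#' Per-element unit normals of a surface mesh
#' @param mesh a `surface_mesh`.
#' @export
element_normals <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; c1 <- mesh$cells
  ab <- v[c1[, 2], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
  ac <- v[c1[, 3], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
  cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  normalize_rows(cx)
}

#' Area-weighted per-vertex normals
#'
#' Accumulates (unnormalized) face normals onto incident vertices and
#' renormalizes.  Outward orientation follows the winding of the triangles.
#'
#' @param mesh a `surface_mesh`.
#' @return the mesh with `vertex_normals` set.
#' @export
compute_vertex_normals <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; c1 <- mesh$cells
  ab <- v[c1[, 2], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
  ac <- v[c1[, 3], , drop = FALSE] - v[c1[, 1], , drop = FALSE]
  fn <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  acc <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    idx <- c1[, j]
    s <- rowsum(fn, idx)
    acc[as.integer(rownames(s)), ] <- acc[as.integer(rownames(s)), ] + s
  }
  mesh$vertex_normals <- normalize_rows(acc)
  validate_mesh(mesh)
  mesh
}

# Barycentric coordinates of points w.r.t. their source elements; used by the
# containment invariants and by dot offsetting.  Returns a matrix with one
# column per non-reference vertex (2 for triangles, 3 for tets): the weights
# of B, C(, D); the A-weight is 1 - rowSums.
barycentric_in_element <- function(mesh, points, element_index) {
  v <- mesh$vertices; c1 <- mesh$cells
  k <- ncol(c1) - 1L
  out <- matrix(NA_real_, nrow(points), k)
  for (el in unique(element_index)) {
    sel <- which(element_index == el)
    A <- v[c1[el, 1], ]
    E <- t(v[c1[el, -1], , drop = FALSE]) - A  # 3 x k edge matrix
    rel <- t(points[sel, , drop = FALSE]) - A  # 3 x n
    # least-squares barycentric solve (exact for in-plane/in-volume points)
    G <- crossprod(E)
    out[sel, ] <- t(solve(G, crossprod(E, rel)))
  }
  out
}
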