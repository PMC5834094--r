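# Dot-mapping sampler -----------------------------------------------------
#
# Pipeline per element i of a mesh with measure V_i (area or volume) and
# normalized scalar S_i in [0, 1]:
#
#   lambda_i     = V_i * S_i * (D / D')^2        distance-corrected weight
#   lambda_adj,i = b * lambda_i ^ c              brightness b, contrast c
#   x_i          ~ min(Poisson(lambda_adj,i), N_i),  N_i = ceil(q * V_i)
#
# then x_i dots are placed uniformly at random inside element i.  The D^2/D'^2
# factor makes the expected number of dots scale with the projected screen
# area of the model under a scaled-orthographic camera, so screen dot density
# is zoom-invariant in expectation.

#' View state: reference and current viewpoint-to-model distance
#'
#' `D` is the viewpoint-to-model-centroid distance captured at scene start;
#' `D_prime` the current one.  Both are global scalars — density is kept
#' uniform across the model rather than corrected per element.
#'
#' @param D reference distance (> 0, same length unit as the mesh).
#' @param D_prime current distance (> 0); defaults to `D`.
#' @export
view_state <- function(D, D_prime = D) {
  if (!(D > 0) || !(D_prime > 0)) stop("distances must be positive")
  structure(list(D = D, D_prime = D_prime), class = "view_state")
}

#' Dot-map tuning parameters
#'
#' @param b brightness constant (> 0): scales every element weight.
#' @param c contrast power (> 0): bends the weight-vs-value response.
#' @param q density-cap constant in dots per unit measure (mm^-2 for surfaces,
#'   mm^-3 for volumes); `Inf` disables the cap.
#' @param seed integer RNG seed; the whole dot cloud is a deterministic
#'   function of (mesh, field, view, config).
#' @param offset elevation of surface dots above the shell along the outward
#'   normal (same unit as the mesh).  Default 0.5: a small lift that keeps
#'   dots from z-fighting with the colour-shaded surface.
#' @param dot_color,dot_px rendering hints (marker colour and pixel size).
#' @export
dot_map_config <- function(b = 1, c = 1, q = Inf, seed = 1L, offset = 0.5,
                           dot_color = "black", dot_px = 1L) {
  if (!(b > 0) || !(c > 0)) stop("b and c must be positive")
  if (!(q > 0)) stop("q must be positive (or Inf for no cap)")
  if (offset < 0) stop("offset must be non-negative")
  structure(list(b = b, c = c, q = q, seed = as.integer(seed),
                 offset = offset, dot_color = dot_color,
                 dot_px = as.integer(dot_px)),
            class = "dot_map_config")
}

#' Distance-corrected element weight
#'
#' lambda = V * S * (D/D')^2.  Computed as the squared ratio so that halving
#' `D_prime` quadruples the weight exactly in floating point.
#'
#' @param V element measure(s), >= 0.
#' @param S normalized scalar value(s) in \[0, 1\].
#' @param D,D_prime reference and current viewpoint distances (> 0).
#' @return numeric vector of weights, recycled over elements.
#' @export
compute_weight <- function(V, S, D, D_prime) {
  if (any(D <= 0) || any(D_prime <= 0)) stop("distances must be positive")
  if (any(V < 0)) stop("element measures must be non-negative")
  if (any(S < 0 | S > 1)) stop("scalar values must be normalized to [0, 1]")
  V * S * (D / D_prime)^2
}

#' Brightness/contrast adjustment of element weights
#'
#' lambda_adj = b * lambda^c, with 0^c defined as 0 for every c > 0.
#'
#' @param lambda non-negative weight(s).
#' @param b brightness constant (> 0).
#' @param c contrast power (> 0).
#' @export
adjust_weight <- function(lambda, b, c) {
  if (!(b > 0) || !(c > 0)) stop("b and c must be positive")
  if (any(lambda < 0)) stop("weights must be non-negative")
  out <- b * lambda^c
  out[lambda == 0] <- 0
  out
}

#' Per-element dot-count cap
#'
#' N = ceil(q * measure).  The ceiling keeps every positive-measure element
#' eligible for at least one dot however small it is.
#'
#' @param measure element measure(s), >= 0.
#' @param q cap constant (dots per unit measure); `Inf` means no cap.
#' @return integer-valued vector (Inf entries when uncapped).
#' @export
dot_cap <- function(measure, q) {
  if (!(q > 0)) stop("q must be positive (or Inf)")
  if (any(measure < 0)) stop("measures must be non-negative")
  if (is.infinite(q)) rep(Inf, length(measure)) else ceiling(q * measure)
}

#' Draw capped Poisson dot counts
#'
#' Independent Poisson(lambda_adj) draws, truncated from above at the cap
#' (truncation, not resampling: a draw above the cap is clamped to it).
#'
#' @param lambda_adj non-negative Poisson means, one per element.
#' @param caps per-element maxima from [dot_cap()] (may be `Inf`).
#' @return integer vector of realized counts.
#' @export
draw_dot_counts <- function(lambda_adj, caps = Inf) {
  if (any(lambda_adj < 0)) stop("Poisson means must be non-negative")
  caps <- rep_len(caps, length(lambda_adj))
  x <- rpois(length(lambda_adj), lambda_adj)
  as.integer(pmin(x, caps))
}

#' Uniform random point in a triangle
#'
#' Folded parametrization P = (1-s)A + s(1-r2)B + s r2 C with s = sqrt(r1),
#' which places points uniformly over the triangle (the square root
#' compensates the area element of the (r1, r2) chart; without it density
#' would pile up near A).
#'
#' @param A,B,C triangle vertex coordinates (length-3 vectors, or n x 3
#'   matrices to vectorize over triangles).
#' @param r1,r2 uniform variates on \[0, 1\] (scalars or length-n vectors).
#' @return an n x 3 matrix of points.
#' @export
sample_point_triangle <- function(A, B, C, r1, r2) {
  n <- max(length(r1), length(r2))
  A <- to_point_matrix(A, n); B <- to_point_matrix(B, n)
  C <- to_point_matrix(C, n)
  s <- sqrt(r1)
  (1 - s) * A + (s * (1 - r2)) * B + (s * r2) * C
}

#' Uniform random point in a tetrahedron
#'
#' Two-stage folding of the unit cube onto the unit simplex:
#' fold 1 — if r1 + r2 > 1, (r1, r2, r3) -> (1-r1, 1-r2, r3);
#' fold 2 — if the components then sum above 1, fold through
#' (r1', 1-r3', 1-r1'-r2') when r2' + r3' > 1, or
#' (1-r2'-r3', r2', r1'+r2'+r3'-1) otherwise.  The folded triple R'' gives
#' barycentric weights: P = (1 - sum(R''))A + r1'' B + r2'' C + r3'' D.
#' Branch boundaries use <= exactly as stated (measure-zero sets).
#'
#' @param A,B,C,D tetrahedron vertex coordinates (length-3 vectors or n x 3
#'   matrices).
#' @param r1,r2,r3 uniform variates on \[0, 1\].
#' @return an n x 3 matrix of points.
#' @export
sample_point_tetrahedron <- function(A, B, C, D, r1, r2, r3) {
  n <- max(length(r1), length(r2), length(r3))
  A <- to_point_matrix(A, n); B <- to_point_matrix(B, n)
  C <- to_point_matrix(C, n); D <- to_point_matrix(D, n)
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); r3 <- rep_len(r3, n)
  f1 <- r1 + r2 > 1
  p1 <- ifelse(f1, 1 - r1, r1)
  p2 <- ifelse(f1, 1 - r2, r2)
  p3 <- r3
  tot <- p1 + p2 + p3
  over <- tot > 1
  caseA <- over & (p2 + p3 > 1)
  caseB <- over & (p2 + p3 <= 1)
  q1 <- p1; q2 <- p2; q3 <- p3
  q1[caseA] <- p1[caseA]
  q2[caseA] <- 1 - p3[caseA]
  q3[caseA] <- 1 - p1[caseA] - p2[caseA]
  q1[caseB] <- 1 - p2[caseB] - p3[caseB]
  q2[caseB] <- p2[caseB]
  q3[caseB] <- p1[caseB] + p2[caseB] + p3[caseB] - 1
  w0 <- 1 - (q1 + q2 + q3)
  w0 * A + q1 * B + q2 * C + q3 * D
}

to_point_matrix <- function(x, n) {
  if (is.matrix(x)) {
    if (nrow(x) == n) x else matrix(x, n, 3, byrow = TRUE)
  } else matrix(x, n, 3, byrow = TRUE)
}

#' Generate a dot cloud for one scalar dataset on a mesh
#'
#' Runs the full pipeline: weight, brightness/contrast, capped Poisson counts,
#' then uniform placement inside each triangle or tetrahedron.  Counts are
#' drawn before placements, and uniform variates are consumed in element
#' order, so the result is a deterministic function of its inputs.
#'
#' @param mesh a `surface_mesh` or `volume_mesh`.
#' @param field an [element_field()] on the mesh's elements (normalized via
#'   its window before weighting) or the name of an attached field (per-vertex
#'   fields are converted by vertex averaging).
#' @param view a [view_state()].
#' @param config a [dot_map_config()].
#' @param frame regeneration counter; each distinct frame (e.g. after a zoom
#'   change) uses a derived substream of `config$seed`.
#' @return an object of class `dot_cloud` with `points` (n x 3), per-dot
#'   `element_index`, per-element realized `counts` and `caps`.
#' @export
generate_dot_map <- function(mesh, field, view, config = dot_map_config(),
                             frame = 0L) {
  if (is.character(field)) field <- vertex_to_element_field(mesh, field)
  if (!inherits(field, "element_field")) field <- element_field(field)
  if (length(field$values) != n_elements(mesh))
    stop("field length ", length(field$values),
         " does not match element count ", n_elements(mesh))
  S <- normalize_field(field)$values
  V <- element_measure(mesh)
  lam <- compute_weight(V, S, view$D, view$D_prime)
  lam_adj <- adjust_weight(lam, config$b, config$c)
  caps <- dot_cap(V, config$q)
  with_seed(frame_seed(config$seed, frame), {
    counts <- draw_dot_counts(lam_adj, caps)
    total <- sum(counts)
    el <- rep.int(seq_len(n_elements(mesh)), counts)
    if (total == 0) {
      pts <- matrix(numeric(0), 0, 3)
    } else if (inherits(mesh, "surface_mesh")) {
      r1 <- runif(total); r2 <- runif(total)
      cells <- mesh$cells[el, , drop = FALSE]
      pts <- sample_point_triangle(mesh$vertices[cells[, 1], , drop = FALSE],
                                   mesh$vertices[cells[, 2], , drop = FALSE],
                                   mesh$vertices[cells[, 3], , drop = FALSE],
                                   r1, r2)
    } else {
      r1 <- runif(total); r2 <- runif(total); r3 <- runif(total)
      cells <- mesh$cells[el, , drop = FALSE]
      pts <- sample_point_tetrahedron(mesh$vertices[cells[, 1], , drop = FALSE],
                                      mesh$vertices[cells[, 2], , drop = FALSE],
                                      mesh$vertices[cells[, 3], , drop = FALSE],
                                      mesh$vertices[cells[, 4], , drop = FALSE],
                                      r1, r2, r3)
    }
    structure(list(points = pts, element_index = el, counts = counts,
                   caps = caps, field_name = field$name,
                   surface = inherits(mesh, "surface_mesh"),
                   seed = config$seed, frame = as.integer(frame)),
              class = "dot_cloud")
  })
}

#' @export
print.dot_cloud <- function(x, ...) {
  cat(sprintf("dot_cloud: %d dots over %d elements (%s), seed %d frame %d\n",
              nrow(x$points), length(x$counts),
              if (x$surface) "surface" else "volumetric", x$seed, x$frame))
  invisible(x)
}

#' Export a dot cloud as CSV or PLY point cloud
#'
#' CSV has header `x,y,z,element_id` with 0-based element ids; PLY is an
#' ascii 1.0 vertex-only file with an `element_id` property.
#'
#' @param cloud a `dot_cloud`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"csv"` or `"ply"`.
#' @export
write_dot_cloud <- function(cloud, path, format = c("auto", "csv", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("csv", "ply")) ext else
      stop("cannot guess dot-cloud format from extension: ", path)
  }
  p <- cloud$points; el <- cloud$element_index - 1L
  lines <- if (format == "csv") {
    c("x,y,z,element_id",
      sprintf("%s,%s,%s,%d", fmt_num(p[, 1]), fmt_num(p[, 2]),
              fmt_num(p[, 3]), el))
  } else {
    c("ply", "format ascii 1.0", "comment dotmapr dot cloud",
      sprintf("element vertex %d", nrow(p)),
      "property double x", "property double y", "property double z",
      "property int element_id", "end_header",
      sprintf("%s %s %s %d", fmt_num(p[, 1]), fmt_num(p[, 2]),
              fmt_num(p[, 3]), el))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
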