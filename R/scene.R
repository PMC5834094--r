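# Scene, camera and rendering --------------------------------------------
#
# The renderer is a small deterministic software rasterizer: a scaled
# orthographic camera, per-triangle z-buffer fill, and 1-px (configurable)
# dot splats depth-tested against the surface.  Orthographic projection with
# screen scale proportional to D/D' is what makes the D^2/D'^2 weight law
# translate into exactly zoom-invariant expected screen dot density.

#' Camera for an orthographic scene
#' @param position camera position (world units).
#' @param target look-at point; defaults to the origin.
#' @param up approximate up direction.
#' @export
scene_camera <- function(position, target = c(0, 0, 0), up = c(0, 1, 0)) {
  position <- as.numeric(position); target <- as.numeric(target)
  if (vnorm(position - target) == 0) stop("camera coincident with target")
  structure(list(position = position, target = target, up = as.numeric(up)),
            class = "scene_camera")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Standard look-at frame: `back` points toward the viewer, `right`/`up` span
# the screen; depth increases along -back (into the scene).
camera_basis <- function(camera) {
  back <- camera$position - camera$target
  back <- back / vnorm(back)
  right <- cross3(camera$up, back)
  if (vnorm(right) == 0) stop("camera up vector parallel to view direction")
  right <- right / vnorm(right)
  up2 <- cross3(back, right)
  list(fwd = -back, right = right, up = up2)
}

#' Derive a view state from a camera
#'
#' The current distance D' is the camera-to-model-centroid distance; the
#' reference D is frozen the first time a scene is built (pass the previous
#' `view_state` as `reference` to keep it).
#'
#' @param camera a [scene_camera()].
#' @param mesh the displayed mesh.
#' @param reference optional earlier [view_state()] whose `D` is retained.
#' @export
view_from_camera <- function(camera, mesh, reference = NULL) {
  d <- vnorm(camera$position - mesh_centroid(mesh))
  if (d == 0) stop("camera coincident with model centroid")
  view_state(D = if (is.null(reference)) d else reference$D, D_prime = d)
}

#' Assemble a renderable scene
#'
#' @param mesh a `surface_mesh` (colour layer + dots) or `volume_mesh`
#'   (dots only).
#' @param color_field name of the field shown as surface shading (NULL for
#'   none).
#' @param dot_field name of the field shown as dots, or an [element_field()].
#' @param camera a [scene_camera()]; default looks down +z from 3 bounding
#'   radii away.
#' @param colormap palette name understood by [grDevices::hcl.colors()], or
#'   `"rainbow"` for classic isochrone colours.
#' @param window normalization window for the colour field (default: its
#'   range).
#' @param image `c(width, height)` in pixels.
#' @param background background colour.
#' @param show_color,show_dots layer visibility toggles.
#' @param fill_fraction fraction of the image the model's bounding radius
#'   fills at the reference distance.
#' @param shading `"flat"` (per-element colour) or `"gouraud"` (per-vertex
#'   interpolation).
#' @param config a [dot_map_config()].
#' @return a `scene_spec` carrying a frozen reference view.
#' @export
scene_spec <- function(mesh, color_field = NULL, dot_field = NULL,
                       camera = NULL, colormap = "viridis", window = NULL,
                       image = c(400L, 400L), background = "white",
                       show_color = TRUE, show_dots = TRUE,
                       fill_fraction = 0.8, shading = c("flat", "gouraud"),
                       config = dot_map_config()) {
  shading <- match.arg(shading)
  ctr <- mesh_centroid(mesh)
  rad <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
  if (is.null(camera))
    camera <- scene_camera(ctr + c(0, 0, 3 * rad), target = ctr)
  for (nm in c(color_field, if (is.character(dot_field)) dot_field))
    if (!nm %in% names(mesh$fields)) stop("no such field on mesh: ", nm)
  if (any(image <= 0)) stop("image dimensions must be positive")
  view <- view_from_camera(camera, mesh)
  structure(list(mesh = mesh, color_field = color_field,
                 dot_field = dot_field, camera = camera, colormap = colormap,
                 window = window, image = as.integer(image),
                 background = background, show_color = show_color,
                 show_dots = show_dots,
                 scale0 = fill_fraction * min(image) / (2 * rad),
                 view = view, shading = shading, config = config),
            class = "scene_spec")
}

# Current pixels-per-world-unit scale: zooming in (smaller D') magnifies.
scene_scale <- function(spec, view = spec$view) {
  spec$scale0 * view$D / view$D_prime
}

#' Project world points through a scene's orthographic camera
#'
#' @param points n x 3 world coordinates.
#' @param spec a [scene_spec()].
#' @param view current [view_state()]; defaults to the reference view.
#' @return data.frame with `x`, `y` (pixels; origin top-left, y down) and
#'   `depth` (distance along the view direction).
#' @export
project_points <- function(points, spec, view = spec$view) {
  b <- camera_basis(spec$camera)
  s <- scene_scale(spec, view)
  rel <- sweep(points, 2, spec$camera$target)
  data.frame(
    x = spec$image[1] / 2 + (rel %*% b$right)[, 1] * s,
    y = spec$image[2] / 2 - (rel %*% b$up)[, 1] * s,
    depth = (sweep(points, 2, spec$camera$position) %*% b$fwd)[, 1])
}

colormap_colors <- function(name, n = 256L) {
  if (identical(name, "rainbow"))
    grDevices::rainbow(n, end = 0.7)
  else grDevices::hcl.colors(n, palette = name)
}

# Rasterize the colour-shaded surface into rgb (H x W x 3 in [0,1]) and a
# z-buffer (H x W), in place via environment. Flat shading colours each
# triangle by its (element) field value; gouraud interpolates vertex values.
rasterize_surface <- function(spec, view, rgb, zbuf) {
  mesh <- spec$mesh
  W <- spec$image[1]; H <- spec$image[2]
  pr <- project_points(mesh$vertices, spec, view)
  lut <- grDevices::col2rgb(colormap_colors(spec$colormap)) / 255
  fv <- mesh$fields[[spec$color_field]]
  w <- spec$window %||% range(fv)
  if (!(w[1] < w[2])) stop("degenerate colour window")
  fn <- pmin(pmax((fv - w[1]) / (w[2] - w[1]), 0), 1)
  per_vertex <- length(fv) == nrow(mesh$vertices)
  if (spec$shading == "flat" && per_vertex)
    fe <- rowMeans(matrix(fn[mesh$cells], nrow = n_elements(mesh)))
  else if (spec$shading == "flat") fe <- fn
  else if (!per_vertex) stop("gouraud shading needs a per-vertex field")
  cells <- mesh$cells
  for (i in seq_len(nrow(cells))) {
    tri <- cells[i, ]
    x <- pr$x[tri]; y <- pr$y[tri]; z <- pr$depth[tri]
    x0 <- max(1L, floor(min(x))); x1 <- min(W, ceiling(max(x)))
    y0 <- max(1L, floor(min(y))); y1 <- min(H, ceiling(max(y)))
    if (x0 > x1 || y0 > y1) next
    det <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
    if (abs(det) < 1e-12) next
    px <- rep(x0:x1, times = y1 - y0 + 1L)
    py <- rep(y0:y1, each = x1 - x0 + 1L)
    l2 <- ((px - x[1]) * (y[3] - y[1]) - (py - y[1]) * (x[3] - x[1])) / det
    l3 <- ((py - y[1]) * (x[2] - x[1]) - (px - x[1]) * (y[2] - y[1])) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    px <- px[inside]; py <- py[inside]
    zi <- l1[inside] * z[1] + l2[inside] * z[2] + l3[inside] * z[3]
    idx <- cbind(py, px)
    closer <- zi < zbuf[idx]
    if (!any(closer)) next
    px <- px[closer]; py <- py[closer]; zi <- zi[closer]
    idx <- cbind(py, px)
    val <- if (spec$shading == "flat") rep(fe[i], length(px))
           else l1[inside][closer] * fn[tri[1]] +
                l2[inside][closer] * fn[tri[2]] +
                l3[inside][closer] * fn[tri[3]]
    ci <- pmin(pmax(1L, 1L + as.integer(round(val * 255))), 256L)
    zbuf[idx] <- zi
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[idx] <- lut[ch, ci]
      rgb[, , ch] <- plane
    }
  }
  list(rgb = rgb, zbuf = zbuf)
}

splat_dots <- function(spec, view, cloud, rgb, zbuf, depth_bias) {
  if (nrow(cloud$points) == 0) return(rgb)
  W <- spec$image[1]; H <- spec$image[2]
  pr <- project_points(cloud$points, spec, view)
  col <- grDevices::col2rgb(spec$config$dot_color)[, 1] / 255
  half <- (spec$config$dot_px - 1L) %/% 2L
  xs <- as.integer(round(pr$x)); ys <- as.integer(round(pr$y))
  for (dx in -half:(spec$config$dot_px - 1L - half))
    for (dy in -half:(spec$config$dot_px - 1L - half)) {
      px <- xs + dx; py <- ys + dy
      ok <- px >= 1L & px <= W & py >= 1L & py <= H
      idx <- cbind(py[ok], px[ok])
      vis <- pr$depth[ok] - depth_bias <= zbuf[idx] + 1e-9
      idx <- idx[vis, , drop = FALSE]
      if (!nrow(idx)) next
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[idx] <- col[ch]
        rgb[, , ch] <- plane
      }
    }
  rgb
}

#' Render a scene to PNG
#'
#' Draws the colour-shaded surface (if enabled and a `color_field` is set),
#' then the dot layer depth-tested against the surface with a depth bias
#' equal to the configured dot offset.  Output is written with
#' [png::writePNG()], which is byte-deterministic: identical scene + seed
#' gives byte-identical files.
#'
#' @param spec a [scene_spec()].
#' @param cloud optional precomputed `dot_cloud`; by default one is generated
#'   from `spec$dot_field` at the scene's current view.
#' @param path output PNG path (8-bit RGB).
#' @param view current [view_state()]; defaults to the scene's reference.
#' @return `path`, invisibly.
#' @export
render_scene <- function(spec, cloud = NULL, path, view = spec$view) {
  W <- spec$image[1]; H <- spec$image[2]
  bg <- grDevices::col2rgb(spec$background)[, 1] / 255
  rgb <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  zbuf <- matrix(Inf, H, W)
  if (spec$show_color && !is.null(spec$color_field) &&
      inherits(spec$mesh, "surface_mesh")) {
    rs <- rasterize_surface(spec, view, rgb, zbuf)
    rgb <- rs$rgb; zbuf <- rs$zbuf
  }
  if (spec$show_dots) {
    if (is.null(cloud) && !is.null(spec$dot_field))
      cloud <- generate_dot_map(spec$mesh, spec$dot_field, view, spec$config)
    if (!is.null(cloud))
      rgb <- splat_dots(spec, view, cloud, rgb, zbuf,
                        depth_bias = spec$config$offset)
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Lift surface dots off the shell along interpolated outward normals
#'
#' Each dot is displaced by `offset` along the unit normal interpolated (from
#' the mesh's per-vertex normals) at its barycentric position in its source
#' element.  This is how a second surface dataset — e.g. epicardial voltage
#' over an endocardial colour map — is kept visually separable from the
#' shaded surface underneath.
#'
#' @param cloud a surface `dot_cloud`.
#' @param mesh the generating `surface_mesh`; must carry vertex normals
#'   (see [compute_vertex_normals()]).
#' @param offset displacement in mesh units (>= 0).
#' @return the displaced `dot_cloud` (element indices preserved).
#' @export
offset_dots <- function(cloud, mesh, offset) {
  if (!isTRUE(cloud$surface))
    stop("offset_dots applies to surface dot clouds only")
  if (!inherits(mesh, "surface_mesh")) stop("mesh must be a surface_mesh")
  if (is.null(mesh$vertex_normals))
    stop("mesh has no vertex normals; call compute_vertex_normals() first")
  if (offset < 0) stop("offset must be non-negative")
  if (offset == 0 || nrow(cloud$points) == 0) return(cloud)
  bc <- barycentric_in_element(mesh, cloud$points, cloud$element_index)
  w1 <- 1 - rowSums(bc)
  cells <- mesh$cells[cloud$element_index, , drop = FALSE]
  nrm <- w1 * mesh$vertex_normals[cells[, 1], , drop = FALSE] +
    bc[, 1] * mesh$vertex_normals[cells[, 2], , drop = FALSE] +
    bc[, 2] * mesh$vertex_normals[cells[, 3], , drop = FALSE]
  nrm <- normalize_rows(nrm)
  cloud$points <- cloud$points + offset * nrm
  cloud
}

#' Screen dot density across zoom levels
#'
#' Regenerates the dot cloud at each zoom (distance multiplier applied to the
#' reference distance), projects it, counts dots falling in a fixed screen
#' rectangle and divides by the rectangle's area.  With unbounded `q` and a
#' uniform field the densities are equal in expectation at every zoom; with a
#' finite `q` the per-element caps saturate at close zoom and density drops.
#'
#' @param spec a [scene_spec()] with a `dot_field`.
#' @param zooms numeric distance multipliers (e.g. `c(0.5, 1, 2, 4)`; 0.5
#'   means the camera moved to half the reference distance).
#' @param region screen rectangle `c(x0, y0, x1, y1)` in pixels; must lie
#'   within the projected model at every zoom.  Default: the largest centred
#'   square inside the model at the farthest zoom.
#' @param reps independent regenerations per zoom (counts are pooled).
#' @return data.frame with one row per zoom: `zoom`, `D_prime`, `n_dots`
#'   (pooled over reps), `area_px` and `density` (dots per pixel^2 per rep).
#' @export
density_sweep <- function(spec, zooms = c(0.5, 1, 2, 4), region = NULL,
                          reps = 1L) {
  if (is.null(spec$dot_field)) stop("scene has no dot_field")
  mesh <- spec$mesh
  if (is.null(region)) {
    far <- max(zooms)
    vfar <- view_state(spec$view$D, spec$view$D * far)
    pr <- project_points(mesh$vertices, spec, vfar)
    half <- 0.45 * min(max(pr$x) - min(pr$x), max(pr$y) - min(pr$y)) / sqrt(2)
    cx <- spec$image[1] / 2; cy <- spec$image[2] / 2
    region <- c(cx - half, cy - half, cx + half, cy + half)
  }
  if (region[3] <= region[1] || region[4] <= region[2])
    stop("empty region")
  area <- (region[3] - region[1]) * (region[4] - region[2])
  frame <- 0L
  out <- lapply(zooms, function(m) {
    v <- view_state(spec$view$D, spec$view$D * m)
    pr <- project_points(mesh$vertices, spec, v)
    if (region[1] < min(pr$x) || region[3] > max(pr$x) ||
        region[2] < min(pr$y) || region[4] > max(pr$y))
      stop("region extends outside the projected model at zoom ", m)
    n <- 0
    for (r in seq_len(reps)) {
      frame <<- frame + 1L
      cl <- generate_dot_map(mesh, spec$dot_field, v, spec$config,
                             frame = frame)
      if (nrow(cl$points)) {
        pd <- project_points(cl$points, spec, v)
        n <- n + sum(pd$x >= region[1] & pd$x <= region[3] &
                     pd$y >= region[2] & pd$y <= region[4])
      }
    }
    data.frame(zoom = m, D_prime = v$D_prime, n_dots = n, area_px = area,
               density = n / (area * reps))
  })
  do.call(rbind, out)
}
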