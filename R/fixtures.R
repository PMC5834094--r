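# Synthetic test geometries and fields ------------------------------------
#
# Emulates the data the method is used on, since no clinical meshes are
# deposited: the 2 cm perception-test geometries (disc with a linear
# gradient, square with a focal bump), nested endo/epi voltage shells,
# a volumetric wedge with a partial-thickness scar, and paired activation /
# voltage fields on closed surfaces.  Everything is deterministic under a
# fixed seed; geometry units are cm for the 2D perception tasks and mm for
# the anatomical fixtures.

#' Triangulated disc with a linear scalar gradient
#'
#' A planar polar-grid disc (default diameter 2 cm, the gradient perception
#' task geometry) with a per-vertex field rising linearly from 0 to 1 along
#' the axis at angle `theta` (degrees, counterclockwise from +x), plus a
#' constant per-element field `uniform` used for density sweeps and an
#' isochrone-style field `lat` along the perpendicular axis.
#'
#' @param diameter disc diameter (cm).
#' @param theta gradient direction in degrees, `0 <= theta < 360`.
#' @param resolution number of radial rings (segments = 6 x resolution);
#'   elements = `6 * resolution * (2 * resolution - 1)`.
#' @param seed unused (geometry is deterministic); kept for a uniform
#'   fixture signature.
#' @return a `surface_mesh` with vertex normals and fields `gradient`
#'   (per-vertex), `lat` (per-vertex, ms) and `uniform` (per-element).
#' @export
make_disc_gradient <- function(diameter = 2, theta = 0, resolution = 8L,
                               seed = 1L) {
  if (theta < 0 || theta >= 360) stop("theta must be in [0, 360)")
  if (diameter <= 0) stop("diameter must be positive")
  R <- diameter / 2
  nr <- max(2L, as.integer(resolution)); ns <- 6L * nr
  ang <- 2 * pi * (seq_len(ns) - 1L) / ns
  verts <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(seq_len(nr), function(k)
                   cbind(R * k / nr * cos(ang), R * k / nr * sin(ang), 0))))
  ring <- function(k) 1L + (k - 1L) * ns + seq_len(ns)  # vertex ids of ring k
  nxt <- c(seq_len(ns)[-1], 1L)
  tris <- cbind(1L, ring(1L), ring(1L)[nxt])
  for (k in seq_len(nr - 1L)) {
    a <- ring(k); b <- ring(k + 1L)
    tris <- rbind(tris,
                  cbind(a, b, b[nxt]),
                  cbind(a, b[nxt], a[nxt]))
  }
  th <- theta * pi / 180
  u <- c(cos(th), sin(th))
  grad <- 0.5 + (verts[, 1] * u[1] + verts[, 2] * u[2]) / diameter
  lat <- 100 * (0.5 + (-verts[, 1] * u[2] + verts[, 2] * u[1]) / diameter)
  mesh <- surface_mesh(verts, tris,
                       vertex_normals = matrix(rep(c(0, 0, 1), nrow(verts)),
                                               ncol = 3, byrow = TRUE),
                       fields = list(gradient = grad, lat = lat))
  mesh$fields$uniform <- rep(1, n_elements(mesh))
  mesh
}

#' Triangulated square with a focal scalar bump
#'
#' The focal-source perception task geometry: a 2 cm square with a smooth
#' radial bump field (raised-cosine), peak 1 at `center`, baseline 0 beyond
#' `radius`.
#'
#' @param edge square edge length (cm); domain is centred on the origin.
#' @param center bump centre `c(x, y)` (cm).
#' @param radius bump radius (cm); the bump disc must intersect the square.
#' @param resolution grid cells per side (elements = `2 * resolution^2`).
#' @param seed unused; kept for a uniform fixture signature.
#' @return a `surface_mesh` with fields `scar` (per-vertex bump) and
#'   `uniform` (per-element).
#' @export
make_square_scar <- function(edge = 2, center = c(0, 0), radius = 0.5,
                             resolution = 24L, seed = 1L) {
  if (edge <= 0 || radius <= 0) stop("edge and radius must be positive")
  h <- edge / 2
  if (any(abs(center) > h + radius))
    stop("scar disc lies fully outside the square")
  n <- max(4L, as.integer(resolution))
  xs <- seq(-h, h, length.out = n + 1L)
  g <- expand.grid(x = xs, y = xs)
  verts <- cbind(g$x, g$y, 0)
  vid <- function(i, j) (j - 1L) * (n + 1L) + i
  tris <- do.call(rbind, lapply(seq_len(n), function(j) {
    i <- seq_len(n)
    rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
          cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  }))
  d <- sqrt((verts[, 1] - center[1])^2 + (verts[, 2] - center[2])^2)
  bump <- ifelse(d < radius, (1 + cos(pi * d / radius)) / 2, 0)
  mesh <- surface_mesh(verts, tris,
                       vertex_normals = matrix(rep(c(0, 0, 1), nrow(verts)),
                                               ncol = 3, byrow = TRUE),
                       fields = list(scar = bump))
  mesh$fields$uniform <- rep(1, n_elements(mesh))
  mesh
}

# Subdivided icosahedron on a sphere of given radius; watertight,
# outward-wound, with radial vertex normals.
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    cache <- new.env(hash = TRUE)
    vlist <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- cache[[key]]
      if (!is.null(id)) return(id)
      m <- vlist[a, ] + vlist[b, ]
      m <- m / vnorm(m)
      vlist <<- rbind(vlist, m)
      cache[[key]] <- nrow(vlist)
      nrow(vlist)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    v <- vlist; f <- nf
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f, vertex_normals = v)
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Bimodal "voltage" field on a sphere-like shell: healthy plateau with one
# low-voltage cap around `axis`, smooth edge, optional Gaussian noise.
voltage_field_on_shell <- function(mesh, axis, angle_deg, healthy, scar,
                                   edge_deg = 10, noise_sd = 0) {
  ctr <- mesh_centroid(mesh)
  dirs <- normalize_rows(sweep(mesh$vertices, 2, ctr))
  if (angle_deg <= 0) {
    v <- rep(healthy, nrow(mesh$vertices))
  } else {
    axis <- axis / vnorm(axis)
    ang <- acos(pmin(pmax(dirs %*% axis, -1), 1)) * 180 / pi
    w <- smoothstep((ang - angle_deg) / edge_deg)  # 0 inside cap, 1 outside
    v <- scar + (healthy - scar) * w
  }
  if (noise_sd > 0) v <- pmax(v + rnorm(length(v), 0, noise_sd), 0)
  as.numeric(v)
}

#' Nested endocardial/epicardial shells with bimodal voltage fields
#'
#' Two concentric icospheres carrying "bipolar voltage" vertex fields: a
#' healthy plateau with one smooth low-voltage patch per shell.  `overlap`
#' rotates the outer patch axis relative to the inner one: 1 puts both
#' patches on the same axis (transmural scar), 0 makes them antipodal.
#'
#' @param inner_radius,outer_radius shell radii (mm), inner < outer.
#' @param resolution icosphere subdivision level (3 gives 1280 triangles).
#' @param scar_params list with any of `angle_deg` (cap half-angle, default
#'   40; 0 disables the patch), `axis` (inner patch axis), `overlap`
#'   (default 1), `healthy` (mV, default 4), `scar` (mV, default 0.2),
#'   `edge_deg` (transition width, default 10), `noise_sd` (mV, default 0).
#' @param seed RNG seed for the noise.
#' @return list with `endo` and `epi` surface meshes, each with a per-vertex
#'   `voltage` field (mV).
#' @export
make_shell_pair <- function(inner_radius = 40, outer_radius = 45,
                            resolution = 3L, scar_params = list(),
                            seed = 1L) {
  if (!(inner_radius > 0 && outer_radius > inner_radius))
    stop("need 0 < inner_radius < outer_radius")
  p <- modifyList(list(angle_deg = 40, axis = c(1, 0, 0), overlap = 1,
                       healthy = 4, scar = 0.2, edge_deg = 10,
                       noise_sd = 0), scar_params)
  endo <- icosphere(inner_radius, resolution)
  epi <- icosphere(outer_radius, resolution)
  axis_in <- p$axis / vnorm(p$axis)
  # rotate the outer axis by (1 - overlap) * 180 degrees in a fixed plane
  rot <- (1 - p$overlap) * pi
  perp <- if (abs(axis_in[1]) < 0.9) cross3(axis_in, c(1, 0, 0))
          else cross3(axis_in, c(0, 1, 0))
  perp <- perp / vnorm(perp)
  axis_out <- cos(rot) * axis_in + sin(rot) * perp
  with_seed(seed, {
    endo$fields$voltage <- voltage_field_on_shell(
      endo, axis_in, p$angle_deg, p$healthy, p$scar, p$edge_deg, p$noise_sd)
    epi$fields$voltage <- voltage_field_on_shell(
      epi, axis_out, p$angle_deg, p$healthy, p$scar, p$edge_deg, p$noise_sd)
  })
  list(endo = endo, epi = epi)
}

#' Curved tetrahedral wedge with a partial-thickness scar
#'
#' A cylindrically curved slab of "myocardium" meshed with tetrahedra (Kuhn
#' subdivision of a structured hex grid) carrying an LGE-like per-element
#' intensity field: high signal within the subendocardial
#' `scar_transmurality` fraction of the wall thickness over a central patch,
#' baseline elsewhere, plus Gaussian noise.
#'
#' @param dimensions `c(arc, height, thickness)` in mm; the wall curves
#'   around a cylinder so the endocardial surface is the inner face.
#' @param scar_transmurality fraction of wall thickness, `0 <` value `<= 1`,
#'   measured from the endocardium (0.75 emulates a 75% subendocardial scar).
#' @param resolution `c(nu, nv, nw)` grid cells (or one integer for all);
#'   elements = `6 * nu * nv * nw`.
#' @param seed RNG seed for the noise.
#' @param noise_sd Gaussian noise sd on the intensity (signal units).
#' @param patch_fraction in-plane extent of the scar patch as a fraction of
#'   the wall's (arc, height) extent, centred.
#' @return a `volume_mesh` with per-element fields `lge` (intensity) and
#'   `scar_mask` (0/1 before noise).
#' @export
make_lv_wedge <- function(dimensions = c(40, 40, 10), scar_transmurality = 0.75,
                          resolution = c(10L, 10L, 4L), seed = 1L,
                          noise_sd = 0.1, patch_fraction = 0.5) {
  if (!(scar_transmurality > 0 && scar_transmurality <= 1))
    stop("scar_transmurality must be in (0, 1]")
  if (length(resolution) == 1L) resolution <- rep(resolution, 3L)
  nu <- resolution[1]; nv <- resolution[2]; nw <- resolution[3]
  arc <- dimensions[1]; ht <- dimensions[2]; th <- dimensions[3]
  Rc <- 30  # endocardial radius of curvature (mm)
  us <- seq(-arc / 2, arc / 2, length.out = nu + 1L) / Rc  # azimuth (rad)
  vs <- seq(-ht / 2, ht / 2, length.out = nv + 1L)
  ws <- seq(0, th, length.out = nw + 1L)                   # depth from endo
  g <- expand.grid(u = us, v = vs, w = ws)
  verts <- cbind((Rc + g$w) * sin(g$u), g$v, (Rc + g$w) * cos(g$u))
  vid <- function(i, j, k)
    as.integer((k - 1L) * (nu + 1L) * (nv + 1L) + (j - 1L) * (nu + 1L) + i)
  # Kuhn 6-tet decomposition of each hex cell along the main diagonal
  corner <- function(di, dj, dk, i, j, k) vid(i + di, j + dj, k + dk)
  paths <- rbind(c(1, 2, 4), c(1, 3, 4), c(1, 3, 7), c(1, 5, 7),
                 c(1, 5, 6), c(1, 2, 6))  # vertex orders 1..8 (binary corners)
  cidx <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  cellgrid <- expand.grid(i = seq_len(nu), j = seq_len(nv), k = seq_len(nw))
  tets <- matrix(0L, 6L * nrow(cellgrid), 4L)
  row <- 0L
  for (cc in seq_len(nrow(cellgrid))) {
    i <- cellgrid$i[cc]; j <- cellgrid$j[cc]; k <- cellgrid$k[cc]
    ids <- vapply(seq_len(8), function(m)
      corner(cidx[m, 1], cidx[m, 2], cidx[m, 3], i, j, k), 0L)
    for (t in seq_len(6)) {
      row <- row + 1L
      tets[row, ] <- ids[c(paths[t, 1], paths[t, 2], paths[t, 3], 8L)]
    }
  }
  mesh <- volume_mesh(verts, tets)
  # per-element parametric centroid
  cells <- mesh$cells
  cx <- (verts[cells[, 1], ] + verts[cells[, 2], ] +
         verts[cells[, 3], ] + verts[cells[, 4], ]) / 4
  rad <- sqrt(cx[, 1]^2 + cx[, 3]^2)
  wdep <- rad - Rc
  uarc <- atan2(cx[, 1], cx[, 3]) * Rc
  in_patch <- abs(uarc) <= patch_fraction * arc / 2 &
              abs(cx[, 2]) <= patch_fraction * ht / 2
  mask <- as.numeric(in_patch & wdep <= scar_transmurality * th)
  baseline <- 1; enhanced <- 5
  lge <- baseline + (enhanced - baseline) * mask
  if (noise_sd > 0)
    lge <- with_seed(seed, lge + rnorm(length(lge), 0, noise_sd))
  mesh$fields$lge <- lge
  mesh$fields$scar_mask <- mask
  mesh
}

# TRUE when every edge of the surface is shared by exactly two triangles.
mesh_is_closed <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  e <- rbind(mesh$cells[, c(1, 2)], mesh$cells[, c(2, 3)],
             mesh$cells[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# Geodesic (edge-graph shortest path) distances from one vertex, mm.
geodesic_distance <- function(mesh, from) {
  e <- unique(rbind(mesh$cells[, c(1, 2)], mesh$cells[, c(2, 3)],
                    mesh$cells[, c(3, 1)]))
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  as.numeric(igraph::distances(g, v = from, weights = len))
}

#' Paired activation-time and voltage fields on a closed surface
#'
#' The activation analogue of a focal rhythm: local activation time grows
#' with geodesic distance from a source vertex at a fixed conduction
#' velocity, wrapped over the cycle length.  The voltage field is an
#' independent healthy plateau with one smooth low-voltage patch.
#'
#' @param mesh a closed `surface_mesh`.
#' @param circuit_params list with any of `source_vertex` (default 1),
#'   `cv` (conduction velocity, mm/ms, default 1), `cycle_length` (ms,
#'   default 250).
#' @param scar_params list as in [make_shell_pair()] (patch axis/size,
#'   plateau and scar voltages, noise).
#' @param seed RNG seed for the voltage noise.
#' @return list of two [element_field()]s, `lat` (ms) and `voltage` (mV),
#'   plus `lat_vertex` / `voltage_vertex` vertex fields.
#' @export
make_activation_voltage_pair <- function(mesh, circuit_params = list(),
                                         scar_params = list(), seed = 1L) {
  if (!mesh_is_closed(mesh)) stop("mesh must be a closed surface")
  cp <- modifyList(list(source_vertex = 1L, cv = 1, cycle_length = 250),
                   circuit_params)
  sp <- modifyList(list(angle_deg = 40, axis = c(1, 0, 0), healthy = 4,
                        scar = 0.2, edge_deg = 10, noise_sd = 0),
                   scar_params)
  lat_v <- (geodesic_distance(mesh, cp$source_vertex) / cp$cv) %%
    cp$cycle_length
  volt_v <- with_seed(seed, voltage_field_on_shell(
    mesh, sp$axis, sp$angle_deg, sp$healthy, sp$scar, sp$edge_deg,
    sp$noise_sd))
  list(lat = vertex_to_element_field(mesh, lat_v,
                                     window = c(0, cp$cycle_length),
                                     name = "lat"),
       voltage = vertex_to_element_field(mesh, volt_v,
                                         window = c(sp$scar, sp$healthy),
                                         name = "voltage"),
       lat_vertex = lat_v, voltage_vertex = volt_v)
}

#' Build a named fixture from a parameter list (CLI backend)
#'
#' @param kind one of `disc_gradient`, `square_scar`, `shell_pair`
#'   (`sphere_pair` is an accepted alias) or `lv_wedge`.
#' @param params named list forwarded to the matching `make_*` function.
#' @param seed RNG seed.
#' @export
make_fixture <- function(kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, c("disc_gradient", "square_scar", "sphere_pair",
                            "shell_pair", "lv_wedge"))
  if (kind == "sphere_pair") kind <- "shell_pair"
  fn <- switch(kind, disc_gradient = make_disc_gradient,
               square_scar = make_square_scar, shell_pair = make_shell_pair,
               lv_wedge = make_lv_wedge)
  do.call(fn, c(params, list(seed = seed)))
}
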