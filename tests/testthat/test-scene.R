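disc_spec <- function(n_dots = 3000, seed = 5L, q = Inf, ...) {
  d <- make_disc_gradient()
  scene_spec(d, color_field = "gradient", dot_field = "uniform",
             config = dot_map_config(b = n_dots / sum(element_measure(d)),
                                     q = q, seed = seed), ...)
}

test_that("view_from_camera freezes D and tracks D'", {
  d <- make_disc_gradient()
  cam0 <- scene_camera(c(0, 0, 3))
  v0 <- view_from_camera(cam0, d)
  expect_equal(v0$D, v0$D_prime)
  v_half <- view_from_camera(scene_camera(c(0, 0, 1.5)), d, reference = v0)
  expect_equal((v_half$D / v_half$D_prime)^2, 4)
  v_double <- view_from_camera(scene_camera(c(0, 0, 6)), d, reference = v0)
  expect_equal((v_double$D / v_double$D_prime)^2, 0.25)
  expect_error(view_from_camera(scene_camera(mesh_centroid(d),
                                             target = c(1, 1, 1)), d),
               "centroid")
})

test_that("orthographic projection scales with D/D' and centres the model", {
  spec <- disc_spec()
  pr1 <- project_points(spec$mesh$vertices, spec)
  v2 <- view_state(spec$view$D, spec$view$D * 2)
  pr2 <- project_points(spec$mesh$vertices, spec, v2)
  cx <- spec$image[1] / 2
  expect_equal(max(pr1$x) - cx, 2 * (max(pr2$x) - cx), tolerance = 1e-12)
  expect_equal(mean(range(pr1$x)), cx, tolerance = 1e-9)
  expect_equal(mean(range(pr1$y)), spec$image[2] / 2, tolerance = 1e-9)
})

test_that("offset_dots lifts dots along sphere normals, additively", {
  s <- dotmapr:::icosphere(1, 3)
  s$fields$uniform <- rep(1, n_elements(s))
  cl <- generate_dot_map(s, "uniform", view_state(10),
                         dot_map_config(b = 2000 / sum(element_measure(s)),
                                        seed = 9))
  r0 <- sqrt(rowSums(cl$points^2))
  lifted <- offset_dots(cl, s, 0.1)
  r1 <- sqrt(rowSums(lifted$points^2))
  # interpolated facet normals deviate slightly from the exact radial ones
  expect_true(all(abs((r1 - r0) - 0.1) < 0.02 * 0.1 + 0.01))
  expect_identical(lifted$element_index, cl$element_index)
  twice <- offset_dots(offset_dots(cl, s, 0.05), s, 0.05)
  once <- offset_dots(cl, s, 0.1)
  expect_lt(max(abs(twice$points - once$points)), 1e-3)
  expect_identical(offset_dots(cl, s, 0), cl)
  s2 <- s; s2$vertex_normals <- NULL
  expect_error(offset_dots(cl, s2, 0.1), "normals")
  vm <- unit_tet_mesh()
  clv <- generate_dot_map(vm, "S", view_state(10), dot_map_config(b = 60))
  expect_error(offset_dots(clv, s, 0.1), "surface")
})

test_that("renders are deterministic and layers compose independently", {
  spec <- disc_spec()
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_scene(spec, path = p1)
  render_scene(spec, path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1) + 1),
                   readBin(p2, "raw", file.size(p2) + 1))

  # dots off -> identical to a colour-only spec
  spec_nodots <- disc_spec(show_dots = FALSE)
  spec_coloronly <- disc_spec()
  spec_coloronly$show_dots <- FALSE
  pa <- withr::local_tempfile(fileext = ".png")
  pb <- withr::local_tempfile(fileext = ".png")
  render_scene(spec_nodots, path = pa)
  render_scene(spec_coloronly, path = pb)
  expect_identical(readBin(pa, "raw", file.size(pa) + 1),
                   readBin(pb, "raw", file.size(pb) + 1))

  # zero field with dots-only layer -> pure background
  d <- make_disc_gradient()
  d$fields$zero <- rep(0, n_elements(d))
  spec0 <- scene_spec(d, dot_field = "zero", show_color = FALSE,
                      image = c(64L, 64L),
                      config = dot_map_config(b = 5, seed = 1))
  pz <- withr::local_tempfile(fileext = ".png")
  render_scene(spec0, path = pz)
  img <- png::readPNG(pz)
  expect_true(all(img == 1))
})

test_that("gouraud and flat shading both render the colour layer", {
  for (sh in c("flat", "gouraud")) {
    spec <- disc_spec(shading = sh, image = c(96L, 96L))
    spec$show_dots <- FALSE
    p <- withr::local_tempfile(fileext = ".png")
    render_scene(spec, path = p)
    img <- png::readPNG(p)
    expect_gt(sum(img < 1), 500)  # a painted disc, not background
  }
})

test_that("density_sweep is flat for unbounded q and sags when caps bind", {
  spec <- disc_spec(n_dots = 2e4, seed = 77)
  ds <- density_sweep(spec, zooms = c(0.5, 1, 2, 4), reps = 3)
  expect_identical(nrow(ds), 4L)
  expect_lt(max(ds$density) / min(ds$density), 1.10)

  b <- spec$config$b
  specq <- disc_spec(n_dots = 2e4, seed = 77, q = 2.5 * b)
  dq <- density_sweep(specq, zooms = c(0.5, 1, 2, 4), reps = 3)
  expect_lt(dq$density[dq$zoom == 0.5], 0.8 * ds$density[ds$zoom == 0.5])
  far <- dq$zoom >= 2
  expect_lt(max(abs(dq$density[far] / ds$density[far] - 1)), 0.05)

  # zero field -> zero density everywhere
  d <- make_disc_gradient()
  d$fields$zero <- rep(0, n_elements(d))
  s0 <- scene_spec(d, dot_field = "zero", show_color = FALSE,
                   config = dot_map_config(b = 5, seed = 1))
  expect_true(all(density_sweep(s0, zooms = c(1, 2))$density == 0))
  expect_error(density_sweep(spec, region = c(10, 10, 5, 20)), "empty region")
  expect_error(density_sweep(spec, zooms = 1, region = c(0, 0, 400, 400)),
               "outside the projected model")
})
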