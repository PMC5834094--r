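test_that("disc gradient fixture matches its stated geometry and field", {
  d <- make_disc_gradient(diameter = 2, theta = 0)
  bb <- apply(d$vertices, 2, function(v) diff(range(v)))
  expect_equal(bb[1:2], c(2, 2), tolerance = 1e-12)
  g <- d$fields$gradient
  left <- which.min(d$vertices[, 1]); right <- which.max(d$vertices[, 1])
  expect_equal(g[left], 0)
  expect_equal(g[right], 1)
  expect_true(all(g >= 0 & g <= 1))
  expect_gte(n_elements(d), 32)

  # theta = 90: the theta = 0 field evaluated on -90-degree-rotated positions
  d90 <- make_disc_gradient(theta = 90)
  expect_equal(d90$vertices, d$vertices)  # same geometry, rotated field axis
  # rotating positions by -90 deg maps the theta=90 axis onto +x, i.e. the
  # field becomes the y-ramp on the original coordinates
  expect_equal(d90$fields$gradient, 0.5 + d$vertices[, 2] / 2,
               tolerance = 1e-12)
  expect_error(make_disc_gradient(theta = 360), "theta")
})

test_that("square scar fixture peaks at the requested centre", {
  s <- make_square_scar(edge = 2, center = c(0, 0), radius = 0.5)
  expect_equal(diff(range(s$vertices[, 1])), 2)
  pk <- which.max(s$fields$scar)
  expect_equal(unname(s$vertices[pk, 1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(max(s$fields$scar), 1)
  d <- sqrt(rowSums(s$vertices[, 1:2]^2))
  expect_true(all(s$fields$scar[d > 0.5] == 0))
  s2 <- make_square_scar(center = c(0.4, -0.2), radius = 0.3)
  pk2 <- which.max(s2$fields$scar)
  expect_lt(vnorm_t(s2$vertices[pk2, 1:2] - c(0.4, -0.2)), 2 / 24)
  expect_error(make_square_scar(center = c(5, 5), radius = 0.3), "outside")
})

test_that("shell pair is watertight with the configured scar relationship", {
  sp <- make_shell_pair(inner_radius = 40, outer_radius = 45,
                        scar_params = list(overlap = 1))
  expect_true(dotmapr:::mesh_is_closed(sp$endo))
  expect_true(dotmapr:::mesh_is_closed(sp$epi))
  expect_equal(sum(element_measure(sp$endo)), 4 * pi * 40^2,
               tolerance = 0.01)
  # voltage is bimodal: plateau high, patch low
  expect_equal(max(sp$endo$fields$voltage), 4)
  expect_equal(min(sp$endo$fields$voltage), 0.2)
  # identical axes -> patch centres (low-voltage centroids) coincide
  patch_dir <- function(m) {
    v <- colMeans(m$vertices[m$fields$voltage < 1, , drop = FALSE])
    v / vnorm_t(v)
  }
  expect_gt(sum(patch_dir(sp$endo) * patch_dir(sp$epi)), 0.95)
  # overlap 0 -> antipodal patches
  sp0 <- make_shell_pair(scar_params = list(overlap = 0))
  expect_lt(sum(patch_dir(sp0$endo) * patch_dir(sp0$epi)), -0.95)
  # zero-size scar -> uniform plateau on both shells
  spu <- make_shell_pair(scar_params = list(angle_deg = 0))
  expect_true(all(spu$endo$fields$voltage == 4))
  expect_true(all(spu$epi$fields$voltage == 4))
  expect_error(make_shell_pair(inner_radius = 50, outer_radius = 45), "inner")
})

test_that("wedge scar respects transmurality from the endocardium", {
  for (tm in c(0.75, 1)) {
    w <- make_lv_wedge(scar_transmurality = tm, noise_sd = 0,
                       resolution = c(8L, 8L, 4L))
    cells <- w$cells
    cx <- (w$vertices[cells[, 1], ] + w$vertices[cells[, 2], ] +
           w$vertices[cells[, 3], ] + w$vertices[cells[, 4], ]) / 4
    depth <- sqrt(cx[, 1]^2 + cx[, 3]^2) - 30  # wall depth from endo (mm)
    thick <- 10
    scar <- w$fields$scar_mask == 1
    expect_true(any(scar))
    # enhanced centroids lie within the inner tm fraction (one element slack)
    expect_lt(max(depth[scar]), tm * thick + thick / 4)
    if (tm < 1) expect_gt(max(depth[!scar]), tm * thick)
    # noise-free field is piecewise constant at two levels
    expect_identical(sort(unique(w$fields$lge)), c(1, 5))
  }
  expect_error(make_lv_wedge(scar_transmurality = 0), "transmurality")
})

test_that("activation/voltage pair is geodesic, wrapped and seeded", {
  s <- dotmapr:::icosphere(20, 2)
  av <- make_activation_voltage_pair(
    s, circuit_params = list(source_vertex = 5L, cv = 0.5,
                             cycle_length = 80),
    scar_params = list(noise_sd = 0.05), seed = 3)
  expect_equal(av$lat_vertex[5], 0)
  expect_true(all(av$lat_vertex >= 0 & av$lat_vertex < 80))
  # LAT grows with straight-line distance from the source nearby
  dd <- sqrt(rowSums(sweep(s$vertices, 2, s$vertices[5, ])^2))
  near <- dd < 10
  expect_gt(cor(dd[near], av$lat_vertex[near]), 0.95)
  # scar patch centre below plateau
  expect_lt(min(av$voltage_vertex), 1)
  expect_gt(max(av$voltage_vertex), 3)
  av2 <- make_activation_voltage_pair(
    s, circuit_params = list(source_vertex = 5L, cv = 0.5,
                             cycle_length = 80),
    scar_params = list(noise_sd = 0.05), seed = 3)
  expect_identical(av, av2)
  # open meshes are rejected
  open <- surface_mesh(s$vertices[1:3, ], rbind(1:3))
  expect_error(make_activation_voltage_pair(open), "closed")
})

test_that("fixtures are bit-reproducible and refine toward the analytic field", {
  expect_identical(make_shell_pair(scar_params = list(noise_sd = 0.2),
                                   seed = 11),
                   make_shell_pair(scar_params = list(noise_sd = 0.2),
                                   seed = 11))
  expect_identical(make_lv_wedge(seed = 4), make_lv_wedge(seed = 4))
  # element means converge to the generating linear function on refinement
  for (res in c(6L, 12L)) {
    d <- make_disc_gradient(resolution = res, theta = 0)
    fe <- vertex_to_element_field(d, "gradient")$values
    cells <- d$cells
    ctr <- (d$vertices[cells[, 1], ] + d$vertices[cells[, 2], ] +
            d$vertices[cells[, 3], ]) / 3
    analytic <- 0.5 + ctr[, 1] / 2
    rms <- sqrt(mean((fe - analytic)^2))
    expect_lt(rms, 0.02)
  }
})
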