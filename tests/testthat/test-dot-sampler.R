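test_that("compute_weight follows the V*S*(D/D')^2 law", {
  expect_identical(compute_weight(1, 1, 10, 10), 1)
  expect_identical(compute_weight(2, 0.5, 10, 5), 4)
  expect_identical(compute_weight(7.3, 0, 10, 2), 0)
  # exact quadrupling when the distance halves, over random parameters
  set.seed(11)
  V <- runif(1000, 0, 50); S <- runif(1000); D <- runif(1000, 1, 200)
  expect_identical(compute_weight(V, S, D, D / 2),
                   4 * compute_weight(V, S, D, D))
  expect_error(compute_weight(1, 1, 0, 1), "positive")
  expect_error(compute_weight(1, 2, 1, 1), "normalized")
})

test_that("adjust_weight applies b * lambda^c with 0^c = 0", {
  lam <- c(0, 0.3, 1, 4, 9)
  expect_identical(adjust_weight(lam, 1, 1), lam)
  expect_equal(adjust_weight(4, 2, 0.5), 4)
  expect_identical(adjust_weight(0, 5, 0.2), 0)
  expect_error(adjust_weight(-1, 1, 1), "non-negative")
})

test_that("dot_cap ceilings q * measure and honours the unbounded case", {
  expect_equal(dot_cap(0.35, 10), 4)
  expect_identical(dot_cap(c(1, 2), Inf), c(Inf, Inf))
  expect_identical(dot_cap(0, 10), 0)
})

test_that("draw_dot_counts matches Poisson moments and respects caps", {
  n <- 1e4
  for (lam in c(0.5, 2, 10)) {
    x <- withr::with_seed(99L + as.integer(10 * lam),
                          draw_dot_counts(rep(lam, n)))
    se_mean <- sqrt(lam / n)
    se_var <- sqrt((2 * lam^2 + lam) / n)  # Var(s^2) ~ (mu4 - sigma^4)/n
    expect_lt(abs(mean(x) - lam), 3 * se_mean)
    expect_lt(abs(var(x) - lam), 3 * se_var)
  }
  x0 <- draw_dot_counts(rep(0, 1000))
  expect_identical(x0, rep(0L, 1000))
  xc <- withr::with_seed(7, draw_dot_counts(rep(10, 1e4), caps = 3))
  expect_true(all(xc <= 3))
})

test_that("triangle sampling hits the collapse points and the centroid", {
  A <- ref_tri$A; B <- ref_tri$B; C <- ref_tri$C
  expect_equal(drop(sample_point_triangle(A, B, C, 0, 0.73)), A)
  expect_equal(drop(sample_point_triangle(A, B, C, 1, 0)), B)
  expect_equal(drop(sample_point_triangle(A, B, C, 1, 1)), C)
  n <- 1e5
  p <- withr::with_seed(5, sample_point_triangle(A, B, C, runif(n), runif(n)))
  ctr <- (A + B + C) / 3
  # SE per coordinate from the oracle sampler's empirical spread
  o <- withr::with_seed(6, reject_sample_triangle(A, B, C, n))
  se <- apply(o, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(p) - ctr) < 3 * se))
  expect_true(all(abs(colMeans(o) - ctr) < 3 * se))  # oracle sanity
})

test_that("tetrahedron folding reproduces the hand traces", {
  A <- ref_tet$A; B <- ref_tet$B; C <- ref_tet$C; D <- ref_tet$D
  expect_equal(drop(sample_point_tetrahedron(A, B, C, D, 0, 0, 0)), A)
  expect_equal(drop(sample_point_tetrahedron(A, B, C, D, 1, 0, 0)), B)
  # (0.5, 0.5, 0.5): fold 2 third branch -> R'' = (0, 0.5, 0.5),
  # the midpoint of C and D
  expect_equal(drop(sample_point_tetrahedron(A, B, C, D, 0.5, 0.5, 0.5)),
               (C + D) / 2)
  n <- 1e5
  p <- withr::with_seed(8, sample_point_tetrahedron(A, B, C, D, runif(n),
                                                    runif(n), runif(n)))
  expect_true(all(abs(colMeans(p) - (A + B + C + D) / 4) < 0.01))
})

test_that("simplex samples are contained and uniform against the rejection oracle", {
  n <- 5e4
  tri <- ref_tri
  p <- withr::with_seed(21, sample_point_triangle(tri$A, tri$B, tri$C,
                                                  runif(n), runif(n)))
  bc <- bary_coords(p, tri)
  expect_true(all(bc >= -1e-9) && all(rowSums(bc) <= 1 + 1e-9))
  cells <- table(subtri_cell(p, tri))
  expect_gt(chisq_p(cells), 0.001)
  o <- withr::with_seed(22, reject_sample_triangle(tri$A, tri$B, tri$C, n))
  expect_gt(homogeneity_p(cells, table(subtri_cell(o, tri))), 0.001)

  tet <- ref_tet
  pt <- withr::with_seed(23, sample_point_tetrahedron(tet$A, tet$B, tet$C,
                                                      tet$D, runif(n),
                                                      runif(n), runif(n)))
  bct <- bary_coords(pt, tet)
  expect_true(all(bct >= -1e-9) && all(rowSums(bct) <= 1 + 1e-9))
  sub <- subdivide_tet_twice(tet)
  cellt <- table(subtet_cell(pt, sub))
  expect_gt(chisq_p(cellt), 0.001)
  ot <- withr::with_seed(24, reject_sample_tetrahedron(tet$A, tet$B, tet$C,
                                                       tet$D, n))
  expect_gt(homogeneity_p(cellt, table(subtet_cell(ot, sub))), 0.001)
})

test_that("generate_dot_map runs the full pipeline with its invariants", {
  sq <- unit_square_mesh()
  view <- view_state(10)
  # zero field -> empty cloud
  z <- generate_dot_map(sq, element_field(c(0, 0), c(0, 1)), view)
  expect_identical(nrow(z$points), 0L)
  expect_identical(z$counts, c(0L, 0L))

  # counts sum to points; containment in source elements
  d <- make_disc_gradient(resolution = 4)
  cl <- generate_dot_map(d, "gradient", view,
                         dot_map_config(b = 2000 / sum(element_measure(d)),
                                        seed = 31))
  expect_identical(sum(cl$counts), nrow(cl$points))
  expect_identical(length(cl$element_index), nrow(cl$points))
  bc <- dotmapr:::barycentric_in_element(d, cl$points, cl$element_index)
  expect_true(all(bc >= -1e-9) && all(rowSums(bc) <= 1 + 1e-9))
  expect_true(all(cl$counts <= cl$caps))

  # caps bind when q is small
  cfg <- dot_map_config(b = 5e4, q = 1, seed = 4)
  clq <- generate_dot_map(sq, element_field(c(1, 1), c(0, 1)), view, cfg)
  expect_true(all(clq$counts <= ceiling(element_measure(sq))))

  # field/mesh mismatch
  expect_error(generate_dot_map(sq, element_field(1:3, c(0, 3)), view),
               "does not match")
})

test_that("dot clouds are seed-deterministic and seed-sensitive", {
  d <- make_disc_gradient(resolution = 4)
  view <- view_state(10)
  cfg <- dot_map_config(b = 1000 / sum(element_measure(d)), seed = 42)
  c1 <- generate_dot_map(d, "gradient", view, cfg)
  c2 <- generate_dot_map(d, "gradient", view, cfg)
  expect_identical(c1, c2)
  cfg2 <- dot_map_config(b = cfg$b, seed = 43)
  c3 <- generate_dot_map(d, "gradient", view, cfg2)
  expect_gt(nrow(c1$points), 100)
  expect_false(isTRUE(all.equal(c1$points, c3$points)))
  # distinct frames give distinct reproducible substreams
  f1 <- generate_dot_map(d, "gradient", view, cfg, frame = 1L)
  expect_false(identical(c1$points, f1$points))
  expect_identical(f1, generate_dot_map(d, "gradient", view, cfg, frame = 1L))
})

test_that("expected dot count is monotone in S, b and V and proportional to area", {
  # deterministic monotonicity through the weight pipeline
  set.seed(12)
  for (i in 1:50) {
    V <- runif(1, 0.1, 10); S <- runif(1); D <- 10; b <- runif(1, 0.1, 5)
    c_ <- runif(1, 0.2, 3)
    base <- adjust_weight(compute_weight(V, S, D, D), b, c_)
    expect_gte(adjust_weight(compute_weight(V, min(1, S + 0.1), D, D), b, c_),
               base)
    expect_gte(adjust_weight(compute_weight(V + 1, S, D, D), b, c_), base)
    expect_gte(adjust_weight(compute_weight(V, S, D, D), b + 0.5, c_), base)
  }
  # realized counts on a two-element mesh with areas 1 and 3 under uniform S
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(-3, 0, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(element_measure(m), c(1, 3))
  f <- element_field(c(1, 1), c(0, 1))
  tot <- c(0, 0)
  for (r in 1:400) {
    cl <- generate_dot_map(m, f, view_state(10),
                           dot_map_config(b = 10, seed = r))
    tot <- tot + cl$counts
  }
  # expected 4000 and 12000; ratio within 3 SE of 1:3
  se_ratio <- sqrt(1 / 4000 + 1 / 12000) / 4
  expect_lt(abs(tot[1] / tot[2] - 1 / 3), 3 * se_ratio)
})
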