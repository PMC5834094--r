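# Independent oracles and small reference geometry used across tests.
# These deliberately avoid the package's own sampling code paths.

# Non-degenerate reference simplices (no axis alignment, unequal edges).
ref_tri <- list(A = c(0.2, -0.1, 0.3), B = c(2.1, 0.4, -0.2),
                C = c(0.6, 1.9, 0.8))
ref_tet <- list(A = c(0, 0, 0), B = c(1.7, 0.2, -0.1),
                C = c(0.3, 1.4, 0.2), D = c(-0.2, 0.4, 1.6))

# Uniform points in a triangle by rejection from the parallelogram chart:
# (v, w) uniform in the unit square, accepted when v + w <= 1.
reject_sample_triangle <- function(A, B, C, n) {
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    m <- 2 * (n - nrow(pts)) + 16
    v <- runif(m); w <- runif(m)
    keep <- v + w <= 1
    v <- v[keep]; w <- w[keep]
    new <- outer(rep(1, length(v)), A) + outer(v, B - A) + outer(w, C - A)
    pts <- rbind(pts, new)
  }
  pts[seq_len(n), , drop = FALSE]
}

# Uniform points in a tetrahedron by rejection from the unit cube chart.
reject_sample_tetrahedron <- function(A, B, C, D, n) {
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    m <- 7 * (n - nrow(pts)) + 16
    x <- runif(m); y <- runif(m); z <- runif(m)
    keep <- x + y + z <= 1
    x <- x[keep]; y <- y[keep]; z <- z[keep]
    new <- outer(rep(1, length(x)), A) + outer(x, B - A) +
      outer(y, C - A) + outer(z, D - A)
    pts <- rbind(pts, new)
  }
  pts[seq_len(n), , drop = FALSE]
}

# Barycentric coordinates (weights of B, C[, D]) of points in one simplex.
bary_coords <- function(pts, verts) {
  A <- verts[[1]]
  E <- do.call(cbind, lapply(verts[-1], function(v) v - A))
  G <- crossprod(E)
  t(solve(G, crossprod(E, t(pts) - A)))
}

# Assign triangle points to one of n^2 congruent sub-triangles of the
# 1/n barycentric grid (index by floor of scaled B/C weights + orientation).
subtri_cell <- function(pts, tri, n = 10L) {
  bc <- bary_coords(pts, tri)
  x <- n * bc[, 1]; y <- n * bc[, 2]
  i <- pmin(floor(x), n - 1); j <- pmin(floor(y), n - 1)
  up <- (x - i) + (y - j) <= 1
  # "up" cells exist when i + j <= n - 1, "down" cells when i + j <= n - 2;
  # together n^2 congruent cells of equal area
  g <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), up = c(TRUE, FALSE))
  ok <- ifelse(g$up, g$i + g$j <= n - 1, g$i + g$j <= n - 2)
  factor(paste(i, j, up), levels = paste(g$i, g$j, g$up)[ok])
}

# Recursive midpoint subdivision of a tetrahedron into 8 equal-volume
# sub-tets (4 corner tets + octahedron split along the AB-CD diagonal).
subdivide_tet <- function(tet) {
  A <- tet[[1]]; B <- tet[[2]]; C <- tet[[3]]; D <- tet[[4]]
  e1 <- (A + B) / 2; e2 <- (A + C) / 2; e3 <- (A + D) / 2
  e4 <- (B + C) / 2; e5 <- (B + D) / 2; e6 <- (C + D) / 2
  list(list(A, e1, e2, e3), list(e1, B, e4, e5),
       list(e2, e4, C, e6), list(e3, e5, e6, D),
       list(e1, e6, e2, e3), list(e1, e6, e3, e5),
       list(e1, e6, e5, e4), list(e1, e6, e4, e2))
}

subdivide_tet_twice <- function(tet) {
  unlist(lapply(subdivide_tet(tet), subdivide_tet), recursive = FALSE)
}

# Assign each point to the first containing sub-tet (1e-9 tolerance).
subtet_cell <- function(pts, subtets) {
  cell <- rep(NA_integer_, nrow(pts))
  for (k in seq_along(subtets)) {
    todo <- which(is.na(cell))
    if (!length(todo)) break
    bc <- bary_coords(pts[todo, , drop = FALSE], subtets[[k]])
    inside <- bc[, 1] >= -1e-9 & bc[, 2] >= -1e-9 & bc[, 3] >= -1e-9 &
      rowSums(bc) <= 1 + 1e-9
    cell[todo[inside]] <- k
  }
  factor(cell, levels = seq_along(subtets))
}

# Pearson chi-square p-value against given expected proportions.
chisq_p <- function(counts, prop = rep(1 / length(counts), length(counts))) {
  e <- sum(counts) * prop
  stat <- sum((counts - e)^2 / e)
  pchisq(stat, df = length(counts) - 1, lower.tail = FALSE)
}

# Chi-square homogeneity of two count vectors over the same cells.
homogeneity_p <- function(c1, c2) {
  tot <- c1 + c2
  keep <- tot > 0
  c1 <- c1[keep]; c2 <- c2[keep]; tot <- tot[keep]
  n1 <- sum(c1); n2 <- sum(c2); n <- n1 + n2
  e1 <- tot * n1 / n; e2 <- tot * n2 / n
  stat <- sum((c1 - e1)^2 / e1) + sum((c2 - e2)^2 / e2)
  pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
}

# Random rigid transform (rotation + translation) for invariance tests.
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(pts, tr) sweep(pts %*% t(tr$R), 2, tr$t, "+")

# A tiny two-triangle square and one-tet mesh used by I/O and sampler tests.
unit_square_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3), c(1, 3, 4)),
               vertex_normals = matrix(rep(c(0, 0, 1), 4), ncol = 3,
                                       byrow = TRUE),
               fields = list(S = c(0, 1, 2, 3)))
}

unit_tet_mesh <- function() {
  volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
              rbind(1:4), fields = list(S = 1))
}

# Unit icosphere via the package fixture machinery (radius 1, origin).
icosphere_for_test <- function(subdivisions = 2L)
  dotmapr:::icosphere(1, subdivisions)

vnorm_t <- function(x) sqrt(sum(x^2))
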