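# Independent brute-force oracles and small fixture builders.

# Field of a uniformly charged triangle by brute-force quadrature: the
# triangle is cut into a k x k uniform triangular grid of equal-area cells,
# each contributing a centroid monopole (O(1/k^2) error, even expansion),
# and Richardson extrapolation over k and 2k removes the leading term.
# Shares no code with the closed-form evaluation it checks.
quad_tri_field_grid <- function(tri, p, k) {
  # centroid barycentric coordinates of upward and downward cells
  ij <- expand.grid(i = 0:(k - 1L), j = 0:(k - 1L))
  up <- ij[ij$i + ij$j <= k - 1L, ]
  l2 <- (3 * up$i + 1) / (3 * k)
  l3 <- (3 * up$j + 1) / (3 * k)
  if (k > 1L) {
    dn <- ij[ij$i + ij$j <= k - 2L, ]
    l2 <- c(l2, (3 * dn$i + 2) / (3 * k))
    l3 <- c(l3, (3 * dn$j + 2) / (3 * k))
  }
  l1 <- 1 - l2 - l3
  pts <- cbind(l1, l2, l3) %*% tri
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  dA <- 0.5 * sqrt(sum(cr^2)) / k^2
  d <- cbind(p[1] - pts[, 1], p[2] - pts[, 2], p[3] - pts[, 3])
  w <- dA / (4 * pi * rowSums(d^2)^1.5)
  colSums(d * w)
}

quad_tri_field <- function(tri, p, k = 256L) {
  f1 <- quad_tri_field_grid(tri, p, k)
  f2 <- quad_tri_field_grid(tri, p, 2L * k)
  (4 * f2 - f1) / 3
}

# single-interface sphere fixture (scalp-in-air), modest resolution
single_sphere <- function(subdivisions = 2L, radius = 0.09, sigma = 0.33,
                          probe_n = 100L) {
  make_sphere_model(radius, sigma, subdivisions = subdivisions,
                    probe_n = probe_n)
}

three_layer <- function(subdivisions = 2L, probe_n = 200L) {
  make_sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.01, 0.33),
                    subdivisions = subdivisions, probe_n = probe_n)
}

test_coil <- function(didt = 9.4e7) {
  make_figure8(didt = didt, height = 0.095)
}

# tiny ASCII STL of a single unit right triangle
write_unit_triangle_stl <- function(path) {
  writeLines(c(
    "solid tri",
    " facet normal 0 0 1",
    "  outer loop",
    "   vertex 0 0 0",
    "   vertex 1 0 0",
    "   vertex 0 1 0",
    "  endloop",
    " endfacet",
    "endsolid tri"), path)
  path
}
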