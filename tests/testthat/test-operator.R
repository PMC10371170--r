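test_that("conductivity contrast follows its definition and bounds", {
  expect_equal(conductivity_contrast(0.33, 0.33), 0)
  expect_equal(conductivity_contrast(0.33, 0), 1)
  expect_equal(conductivity_contrast(1, 3), -0.5)
  expect_error(conductivity_contrast(0, 0), "zero")
  expect_error(conductivity_contrast(-1, 2), "non-negative")
  set.seed(1)
  s <- matrix(runif(40, 0, 2), ncol = 2)
  k <- conductivity_contrast(s[, 1], s[, 2])
  expect_true(all(abs(k) <= 1))
})

test_that("analytic triangle field matches the quadrature oracle", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  # generic point above the triangle, 1e-8 relative against brute force
  p <- c(0.25, 0.25, 0.5)
  fa <- drop(triangle_field_integral(tri, p))
  fq <- quad_tri_field(tri, p)
  expect_lt(max(abs(fa - fq)) / max(abs(fq)), 1e-8)
  # below the triangle, and for a skewed triangle
  tri2 <- rbind(c(0.1, -0.2, 0.3), c(0.7, 0.1, 0.25), c(0.2, 0.6, 0.9))
  for (pp in list(c(0.25, 0.25, -0.4), c(1.2, -0.3, 0.8))) {
    fa2 <- drop(triangle_field_integral(tri2, pp))
    fq2 <- quad_tri_field(tri2, pp)
    expect_lt(max(abs(fa2 - fq2)) / max(abs(fq2)), 1e-7)
  }
})

test_that("triangle field limits: point-charge far field, planar PV", {
  tri <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0))
  ctr <- colMeans(tri)
  A <- 0.5 * 0.01^2
  # at 100 triangle diameters the monopole approximation holds to 1e-4
  p <- ctr + c(0.3, 0.8, 0.52) / sqrt(0.3^2 + 0.8^2 + 0.52^2) * 1.4
  fa <- drop(triangle_field_integral(tri, p))
  d <- p - ctr
  mono <- A * d / (4 * pi * sum(d^2)^1.5)
  expect_lt(max(abs(fa - mono)) / max(abs(mono)), 1e-4)
  # in-plane interior point: principal-value field has no normal component
  pin <- c(0.002, 0.003, 0)
  fin <- drop(triangle_field_integral(tri, pin))
  expect_lt(abs(fin[3]), 1e-12 * max(abs(fin)))
  expect_error(triangle_field_integral(tri, tri[1, ]), "vertex")
})

test_that("dense assembly: exact half diagonal, K = 0 identity, oracle", {
  sm <- single_sphere(1)         # 80 facets
  op <- assemble_operator(sm$model)
  expect_equal(diag(op$dense), rep(0.5, op$n))
  # zero contrast annihilates the integral term
  m0 <- head_model(list(interface(make_icosphere(0.09, 1), 0.33, 0.33)))
  op0 <- assemble_operator(m0)
  expect_equal(op0$dense, diag(0.5, 80), tolerance = 1e-15)
  # centroid-collocation assembly against the per-pair quadrature oracle
  s20 <- head_model(list(interface(make_icosphere(0.09, 0), 0.33, 0)))
  opc <- assemble_operator(s20, near_threshold = Inf, outer_rule = 1L)
  g <- tmsbem:::model_geometry(s20)
  Aref <- diag(0.5, 20)
  for (m in 1:20) for (n in 1:20) {
    if (m == n) next
    tri <- g$vertices[g$triangles[n, ], ]
    f <- quad_tri_field(tri, g$centroids[m, ], k = 128L)
    Aref[m, n] <- -g$contrast[m] * sum(g$normals[m, ] * f)
  }
  expect_lt(max(abs(opc$dense - Aref)), 1e-8)
})

test_that("facet-averaged near entries agree with double-quadrature oracle", {
  # two adjacent facets of a coarse icosphere: average the analytic inner
  # integral over the collocation facet by dense 1:4-subdivision midpoints
  s20 <- head_model(list(interface(make_icosphere(0.09, 0), 0.33, 0)))
  g <- tmsbem:::model_geometry(s20)
  op <- assemble_operator(s20, near_threshold = Inf, outer_rule = 7L)
  subdiv_points <- function(tri, depth) {
    if (depth == 0L)
      return(list(list(p = colMeans(tri), tri = tri)))
    m12 <- (tri[1, ] + tri[2, ]) / 2
    m23 <- (tri[2, ] + tri[3, ]) / 2
    m31 <- (tri[3, ] + tri[1, ]) / 2
    c(subdiv_points(rbind(tri[1, ], m12, m31), depth - 1L),
      subdiv_points(rbind(tri[2, ], m23, m12), depth - 1L),
      subdiv_points(rbind(tri[3, ], m31, m23), depth - 1L),
      subdiv_points(rbind(m12, m23, m31), depth - 1L))
  }
  # facet 13 shares no vertex with facet 1 (tight agreement); facet 2
  # shares an edge, where the exact facet average has a log singularity the
  # fixed rule only approximates (checked at its measured ~15 % level)
  for (pair in list(list(m = 1L, n = 13L, tol = 1e-3, depth = 4L),
                    list(m = 1L, n = 2L, tol = 0.15, depth = 5L))) {
    trim <- g$vertices[g$triangles[pair$m, ], ]
    trin <- g$vertices[g$triangles[pair$n, ], ]
    cells <- subdiv_points(trim, pair$depth)
    acc <- 0
    for (cell in cells) {
      f <- drop(triangle_field_integral(trin, cell$p))
      acc <- acc + sum(g$normals[pair$m, ] * f) / length(cells)
    }
    ref <- -g$contrast[pair$m] * acc
    expect_equal(op$dense[pair$m, pair$n], ref, tolerance = pair$tol)
  }
})

test_that("operator application: linearity, columns, dense vs matrix-free", {
  sm <- single_sphere(2)        # 320 facets
  opd <- assemble_operator(sm$model)
  opf <- assemble_operator(sm$model, mode = "matrix-free")
  expect_equal(apply_operator(opd, numeric(opd$n)), numeric(opd$n))
  set.seed(11)
  x <- rnorm(opd$n); y <- rnorm(opd$n)
  # linearity
  expect_equal(apply_operator(opd, 2 * x + 3 * y),
               2 * apply_operator(opd, x) + 3 * apply_operator(opd, y),
               tolerance = 1e-12)
  # basis vector extracts a column
  e5 <- numeric(opd$n); e5[5] <- 1
  expect_equal(apply_operator(opd, e5), opd$dense[, 5], tolerance = 1e-14)
  # the two storage modes agree
  scale <- max(abs(x))
  expect_lt(max(abs(apply_operator(opd, x) - apply_operator(opf, x))) /
              scale, 1e-10)
  expect_error(apply_operator(opd, numeric(3)), "length")
})

test_that("Gauss sanity: operator on constants, K = 1 closed surface", {
  # uniformly charged closed surface: interior field ~ 0, so A 1 ~ 0 within
  # discretization error, shrinking under refinement
  r1 <- apply_operator(assemble_operator(single_sphere(2)$model),
                       rep(1, 320))
  r2 <- apply_operator(assemble_operator(single_sphere(3)$model),
                       rep(1, 1280))
  expect_lt(mean(abs(r1)), 0.02)
  expect_lt(mean(abs(r2)), mean(abs(r1)))
})

test_that("right-hand side: contrast gating, linearity, cosine pattern", {
  sm <- single_sphere(2)
  op <- assemble_operator(sm$model)
  cl <- test_coil()
  b <- assemble_rhs(op, cl)
  # linear in didt
  b2 <- assemble_rhs(op, make_figure8(didt = 2 * 9.4e7, height = 0.095))
  expect_equal(as.numeric(b2), 2 * as.numeric(b), tolerance = 1e-12)
  # didt = 0 -> zero
  expect_equal(max(abs(assemble_rhs(op, make_figure8(didt = 0,
                                                     height = 0.095)))), 0)
  # K = 0 interface gives zero rows regardless of the coil
  m0 <- head_model(list(interface(make_icosphere(0.09, 2), 0.33, 0.33)))
  expect_equal(max(abs(assemble_rhs(m0, cl))), 0)
  # uniform E0 z-hat with K = 1: b = E0 cos(theta) at facet normals
  src <- uniform_field_source(c(0, 0, 2.5))
  bu <- assemble_rhs(op, src)
  expect_equal(as.numeric(bu),
               2.5 * sm$model$interfaces[[1]]$surface$normals[, 3],
               tolerance = 1e-12)
})
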