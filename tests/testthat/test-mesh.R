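test_that("icosphere construction: counts, radii, closure, area deficit", {
  s0 <- make_icosphere(1, 0)
  expect_equal(nrow(s0$triangles), 20L)
  s3 <- make_icosphere(1, 3)
  expect_equal(nrow(s3$triangles), 1280L)
  # all vertices on the sphere
  expect_lt(max(abs(sqrt(rowSums(s3$vertices^2)) - 1)), 1e-12)
  s4 <- make_icosphere(0.1, 4, center = c(1, 2, 3))
  d <- sweep(s4$vertices, 2, c(1, 2, 3))
  expect_lt(max(abs(sqrt(rowSums(d^2)) - 0.1)), 1e-13)
  # inscribed-polyhedron area deficit under 1.5 % at 1280 facets
  expect_lt(abs(sum(s3$areas) - 4 * pi) / (4 * pi), 0.015)
  # divergence-theorem closure and outward orientation
  expect_lt(closure_defect(s3), 1e-10)
  expect_gt(signed_volume(s3), 0)
  expect_error(make_icosphere(-1), "radius")
})

test_that("surface validation rejects degenerate and malformed facets", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(triangle_surface(v, rbind(c(1, 2, 2))), "repeated")
  expect_error(triangle_surface(v, rbind(c(1, 2, 9))), "out of range")
  # zero-area facet (collinear vertices)
  vz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(triangle_surface(vz, rbind(1:3)), "degenerate")
})

test_that("1:4 subdivision preserves area, multiplies facets, stays closed", {
  s <- make_icosphere(1, 0)
  r1 <- subdivide_1to4(s)
  expect_equal(nrow(r1$triangles), 80L)
  expect_equal(sum(r1$areas), sum(s$areas), tolerance = 1e-12)
  r2 <- subdivide_1to4(r1)
  expect_equal(nrow(r2$triangles), 320L)
  expect_lt(closure_defect(r2), 1e-10)
  # Euler: closed triangulated sphere has V = F/2 + 2
  expect_equal(nrow(r2$vertices), nrow(r2$triangles) / 2L + 2L)
  # projected refinement approaches the true sphere area monotonically
  p1 <- subdivide_1to4(s, project = list(center = c(0, 0, 0), radius = 1))
  def0 <- abs(sum(s$areas) - 4 * pi)
  def1 <- abs(sum(p1$areas) - 4 * pi)
  expect_lt(def1, def0)
  # an open (non-manifold-boundary) surface is rejected
  expect_error(
    subdivide_1to4(triangle_surface(rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(0, 1, 0)), rbind(1:3))),
    "non-manifold|boundary")
})

test_that("STL round trip: binary and ASCII, welding, unit conversion", {
  s <- make_icosphere(0.05, 1)   # 80 facets
  tf <- withr::local_tempfile(fileext = ".stl")
  write_stl(s, tf, binary = TRUE)
  r <- read_stl(tf)
  expect_equal(nrow(r$triangles), 80L)
  expect_equal(nrow(r$vertices), 42L)   # welded: V = F/2 + 2
  expect_equal(sort(r$areas), sort(s$areas), tolerance = 1e-6)
  expect_equal(sum(abs(r$vertices)) / sum(abs(s$vertices)), 1,
               tolerance = 1e-6)
  ta <- withr::local_tempfile(fileext = ".stl")
  write_stl(s, ta, binary = FALSE)
  ra <- read_stl(ta)
  expect_equal(sort(ra$areas), sort(s$areas), tolerance = 1e-6)
  # millimeter STL scales on read
  tm <- withr::local_tempfile(fileext = ".stl")
  write_stl(s, tm, binary = TRUE, units = "mm")
  rm_ <- read_stl(tm, units = "mm")
  expect_equal(sum(rm_$areas), sum(s$areas), tolerance = 1e-6)
  # single ASCII triangle: right triangle with legs 1 has area 1/2
  t1 <- withr::local_tempfile(fileext = ".stl")
  write_unit_triangle_stl(t1)
  tr <- read_stl(t1)
  expect_equal(nrow(tr$triangles), 1L)
  expect_equal(tr$areas, 0.5, tolerance = 1e-12)
  expect_error(read_stl(withr::local_tempfile(fileext = ".stl")), "read")
})

test_that("model validation flags orientation and conductivity defects", {
  sm <- three_layer(1)
  rep_ <- validate_model(sm$model, fatal = FALSE)
  expect_true(all(rep_$outward))
  expect_true(all(rep_$sigma_ok))
  expect_length(attr(rep_, "problems"), 0L)
  # flipped surface -> orientation error
  s <- make_icosphere(0.09, 1)
  flipped <- triangle_surface(s$vertices, s$triangles[, c(1, 3, 2)])
  bad <- head_model(list(interface(flipped, 0.33, 0)))
  expect_error(validate_model(bad), "inward")
  # inconsistent nesting conductivities
  m2 <- head_model(list(interface(make_icosphere(0.09, 1), 0.33, 0),
                        interface(make_icosphere(0.08, 1), 0.5, 0.1)))
  expect_error(validate_model(m2), "conductivity")
  # both conductivities zero is rejected at interface construction
  expect_error(interface(s, 0, 0), "zero")
})

test_that("facet indexing maps bijectively across interfaces", {
  sm <- three_layer(1)
  loc <- facet_location(sm$model, seq_len(sm$model$total_facets))
  expect_equal(nrow(unique(loc)), sm$model$total_facets)
  expect_equal(range(loc$interface), c(1L, 3L))
  expect_true(all(loc$facet >= 1L & loc$facet <= 80L))
  expect_error(facet_location(sm$model, 0L), "range")
})
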