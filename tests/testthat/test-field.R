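test_that("off-surface field: zero charge, monopole limit, shell theorem", {
  sm <- single_sphere(2)
  cl <- test_coil()
  op <- assemble_operator(sm$model)
  n <- op$n
  # rho* = 0: total field equals the primary field
  z <- tmsbem:::charge_solution(numeric(n), NA_real_, "test")
  f <- field_off_surface(sm$model, z, cl, sm$probes)
  expect_equal(f$e_total, f$e_primary)
  # single charged facet far away acts as a point charge A rho*/(4 pi r^2)
  rho1 <- numeric(n); rho1[17] <- 2.3
  s1 <- tmsbem:::charge_solution(rho1, NA_real_, "test")
  g <- tmsbem:::model_geometry(sm$model)
  p <- g$centroids[17, ] + c(1.3, -0.4, 2.2)
  fs <- field_off_surface(sm$model, s1, NULL, rbind(p))
  d <- p - g$centroids[17, ]
  mono <- 2.3 * g$areas[17] * d / (4 * pi * sum(d^2)^1.5)
  expect_lt(max(abs(fs$e_total - rbind(mono))) / max(abs(mono)), 1e-4)
  # uniformly charged sphere: field at the center vanishes (shell theorem)
  su <- tmsbem:::charge_solution(rep(1, n), NA_real_, "test")
  fc <- field_off_surface(sm$model, su, NULL, rbind(c(0, 0, 0)))
  expect_lt(max(abs(fc$e_total)), 1e-13 * max(abs(su$rho)))
  # guard: points essentially on the surface are rejected
  expect_error(field_off_surface(sm$model, z, cl,
                                 rbind(g$centroids[1, ] + 1e-6)),
               "guard")
})

test_that("one-sided fields: exact jump identity and zero-charge limit", {
  sm <- single_sphere(2)
  cl <- test_coil()
  fit <- tms_fit(sm$model, cl, tol = 1e-8)
  ein <- predict(fit, side = "in")
  eout <- predict(fit, side = "out")
  g <- tmsbem:::model_geometry(sm$model)
  jump <- eout$e_total - ein$e_total
  expect_equal(jump, g$normals * coef(fit),
               tolerance = 1e-14 * max(abs(coef(fit))))
  # rho* = 0: both sides equal the primary field
  z <- tmsbem:::charge_solution(numeric(fit$model$total_facets), NA, "test")
  e0 <- field_one_sided(sm$model, z, cl, side = "out")
  expect_equal(e0$e_total, e0$e_primary)
  expect_error(field_one_sided(sm$model, z, cl, facets = 10^6, side = "in"),
               "range")
})

test_that("off-surface evaluation converges to the one-sided limit", {
  sm <- single_sphere(2)
  cl <- test_coil()
  fit <- tms_fit(sm$model, cl, tol = 1e-8)
  g <- tmsbem:::model_geometry(sm$model)
  m <- 42L
  h <- sqrt(g$areas[m])
  eout <- predict(fit, side = "out")$e_total[m, ]
  errs <- sapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    p <- g$centroids[m, ] + eps * h * g$normals[m, ]
    f <- field_off_surface(sm$model, fit$solution, cl, rbind(p), guard = 0)
    sqrt(sum((f$e_total - eout)^2)) / sqrt(sum(eout^2))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("boundary-condition residual is small and shrinks on refinement", {
  cl <- test_coil()
  res <- sapply(2:3, function(sub) {
    fit <- tms_fit(single_sphere(sub)$model, cl, tol = 1e-8)
    attr(residuals(fit), "area_weighted_mean")
  })
  expect_lt(res[2], 2e-2)
  expect_lt(res[2], res[1])
  # unsolved rho* = 0 with a live coil violates the condition grossly
  sm <- single_sphere(2)
  z <- tmsbem:::charge_solution(numeric(320), NA, "test")
  r0 <- bc_residual(sm$model, z, cl)
  expect_gt(attr(r0, "area_weighted_mean"), 0.3)
})

test_that("charge neutrality per closed interface for inductive drive", {
  sm <- three_layer(2)
  fit <- tms_fit(sm$model, test_coil(), tol = 1e-8)
  g <- tmsbem:::model_geometry(sm$model)
  loc <- facet_location(sm$model, seq_len(sm$model$total_facets))
  for (i in 1:3) {
    idx <- loc$interface == i
    net <- abs(sum(g$areas[idx] * coef(fit)[idx]))
    expect_lt(net, 1e-6 * sum(g$areas[idx] * abs(coef(fit)[idx])))
  }
})

test_that("field TSV and observation point files round trip", {
  sm <- single_sphere(1)
  fit <- tms_fit(sm$model, test_coil())
  f <- predict(fit, points = sm$probes)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_field_tsv(f, tf)
  r <- read_field_tsv(tf)
  expect_equal(r$e, unname(f$e_total), tolerance = 1e-15)
  tp <- withr::local_tempfile(fileext = ".txt")
  write_points(sm$probes, tp)
  expect_equal(read_points(tp), sm$probes, tolerance = 1e-15)
})
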