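test_that("sphere model construction: contrasts, nesting, probes", {
  sm1 <- make_sphere_model(0.09, 0.33, 1)
  expect_equal(sm1$model$interfaces[[1]]$contrast, 1)
  sm3 <- make_sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.01, 0.33), 1)
  k <- vapply(sm3$model$interfaces, `[[`, 1, "contrast")
  expect_equal(k, c(1, (0.01 - 0.33) / 0.34, (0.33 - 0.01) / 0.34))
  # equal adjacent conductivities: middle interface K = 0
  sm0 <- make_sphere_model(c(0.09, 0.08), c(0.33, 0.33), 1)
  expect_equal(sm0$model$interfaces[[2]]$contrast, 0)
  expect_silent(validate_model(sm3$model))
  expect_error(make_sphere_model(c(0.08, 0.09), c(1, 1), 1), "decreasing")
  # probe shell sits at 0.8 x innermost radius
  expect_equal(unique(round(sqrt(rowSums(sm3$probes^2)), 12)), 0.8 * 0.08)
})

test_that("uniform-field oracle: rho* = 3 E0 cos(theta), interior null", {
  src <- uniform_field_source(c(0, 0, 1))
  errs <- sapply(2:3, function(sub) {
    sm <- single_sphere(sub)
    fit <- tms_fit(sm$model, src, tol = 1e-10)
    ana <- analytic_uniform_field_case(sm$model$interfaces[[1]]$surface, 1)
    rho_err <- sqrt(sum((coef(fit) - ana$rho)^2) / sum(ana$rho^2))
    f <- predict(fit, points = sm$probes)
    c(rho = rho_err, int = max(sqrt(rowSums(f$e_total^2))))
  })
  # within 2 % at 1280 facets, improving under refinement
  expect_lt(errs["rho", 2], 0.02)
  expect_lt(errs["int", 2], 0.02)
  expect_lt(errs["rho", 2], errs["rho", 1])
  expect_lt(errs["int", 2], errs["int", 1])
  # E0 = 0 gives exactly zero charge
  sm <- single_sphere(1)
  fit0 <- tms_fit(sm$model, uniform_field_source(c(0, 0, 0)))
  expect_equal(coef(fit0), numeric(80))
})

test_that("conservative vs inductive excitation differ qualitatively", {
  # uniform (conservative) drive cancels interior fields; a coil (inductive)
  # drive does not - the solver must distinguish the two regimes
  sm <- single_sphere(3)
  fu <- predict(tms_fit(sm$model, uniform_field_source(c(0, 0, 1)),
                        tol = 1e-8), points = sm$probes)
  ratio_u <- max(sqrt(rowSums(fu$e_total^2)))  # vs |E0| = 1
  cl <- test_coil()
  fitc <- tms_fit(sm$model, cl, tol = 1e-8)
  fc <- predict(fitc, points = sm$probes)
  ratio_c <- max(sqrt(rowSums(fc$e_total^2))) /
    max(sqrt(rowSums(fc$e_primary^2)))
  expect_lt(ratio_u, 0.02)
  expect_gt(ratio_c, 0.3)
})

test_that("interior field is profile-independent and non-radial", {
  rep_ <- profile_independence_check(
    list(radii = 0.09, conductivities = 0.33, subdivisions = 3,
         probe_n = 400, probe_frac = 0.8 * 0.08 / 0.09),
    list(radii = c(0.09, 0.085, 0.08), conductivities = c(0.33, 0.01, 0.33),
         subdivisions = 3, probe_n = 400),
    test_coil())
  expect_lt(rep_$error_total, 0.02)
  expect_lt(rep_$radial_fraction_single, 0.02)
  expect_lt(rep_$radial_fraction_multi, 0.02)
  # identical specs agree to solver tolerance
  spec <- list(radii = 0.09, conductivities = 0.33, subdivisions = 2,
               probe_n = 100)
  same <- profile_independence_check(spec, spec, test_coil(), tol = 1e-10)
  expect_lt(same$error_total, 1e-6)
})

test_that("refined ground truth: K = 0 passthrough and provenance", {
  m0 <- head_model(list(interface(make_icosphere(0.09, 1), 0.33, 0.33,
                                  sphere = list(center = c(0, 0, 0),
                                                radius = 0.09))))
  cl <- test_coil()
  pts <- fibonacci_sphere(50, 0.05)
  gt <- refined_ground_truth(m0, cl, pts, levels = 1)
  # zero contrast: the field is the primary field at any refinement
  expect_equal(gt$e_total, primary_field(cl, pts), tolerance = 1e-12)
  expect_true(gt$provenance$ground_truth)
  expect_equal(gt$provenance$facets, 320L)
  expect_error(refined_ground_truth(m0, cl, pts, levels = 3), "levels")
})
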