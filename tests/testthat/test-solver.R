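test_that("GMRES: trivial systems and independent cross-check", {
  # b = 0 solves in 0 iterations
  r0 <- gmres(function(x) x, numeric(10))
  expect_equal(r0$x, numeric(10))
  expect_equal(r0$iterations, 0L)
  # scaled identity (K = 0 model): converges in one iteration to x = 2b
  m0 <- head_model(list(interface(make_icosphere(0.09, 1), 0.33, 0.33)))
  op0 <- assemble_operator(m0)
  b <- rnorm(80)
  sol <- solve_iterative(op0, b, tol = 1e-10)
  expect_equal(sol$iterations, 1L)
  expect_equal(sol$rho, 2 * b, tolerance = 1e-10)
  # cross-check against pracma::gmres on a dense nonsymmetric system
  skip_if_not_installed("pracma")
  set.seed(5)
  A <- diag(30) + 0.1 * matrix(rnorm(900), 30)
  bb <- rnorm(30)
  ours <- gmres(function(x) drop(A %*% x), bb, tol = 1e-10, max_iter = 60)
  theirs <- pracma::gmres(A, bb, errtol = 1e-10)
  expect_equal(ours$x, drop(theirs$x), tolerance = 1e-8)
  # non-convergence raises with history attached
  err <- tryCatch(solve_iterative(assemble_operator(single_sphere(1)$model),
                                  rnorm(80), tol = 1e-12, max_iter = 2L),
                  error = identity)
  expect_s3_class(err, "error")
  expect_true(length(err$history) == 2L)
})

test_that("factorization: exactness, fingerprint binding, build counter", {
  m0 <- head_model(list(interface(make_icosphere(0.09, 1), 0.33, 0.33)))
  op0 <- assemble_operator(m0)
  factorization_builds(reset = TRUE)
  f0 <- factorize(op0)
  b <- rnorm(80)
  expect_equal(solve_direct(f0, b)$rho, 2 * b, tolerance = 1e-13)
  expect_equal(factorization_builds(), 1L)
  # many right-hand sides reuse the single factorization
  sols <- solve_direct(f0, lapply(1:100, function(i) rnorm(80)), op = op0)
  expect_length(sols, 100L)
  expect_equal(factorization_builds(), 1L)
  # linearity: b and 2b
  s1 <- solve_direct(f0, b)
  s2 <- solve_direct(f0, 2 * b)
  expect_equal(s2$rho, 2 * s1$rho, tolerance = 1e-12)
  # fingerprint mismatch on a different model
  op_other <- assemble_operator(single_sphere(1)$model)
  expect_error(solve_direct(f0, b, op = op_other), "fingerprint")
  expect_error(factorize(assemble_operator(single_sphere(2)$model,
                                           mode = "matrix-free")), "dense")
})

test_that("direct and iterative solutions agree on a sphere model", {
  sm <- single_sphere(2)
  cl <- test_coil()
  op <- assemble_operator(sm$model)
  b <- assemble_rhs(op, cl)
  it <- solve_iterative(op, b, tol = 1e-10)
  dr <- solve_direct(factorize(op), b, op = op)
  expect_lt(sqrt(sum((it$rho - dr$rho)^2) / sum(dr$rho^2)), 1e-8)
})

test_that("solution superposition across coils", {
  sm <- single_sphere(2)
  op <- assemble_operator(sm$model)
  c1 <- test_coil()
  c2 <- transform_coil(test_coil(), rbind(c(0, -1, 0), c(1, 0, 0),
                                          c(0, 0, 1)), c(0.01, 0, 0.002))
  fact <- factorize(op)
  s1 <- solve_direct(fact, assemble_rhs(op, c1), op = op)
  s2 <- solve_direct(fact, assemble_rhs(op, c2), op = op)
  s12 <- solve_direct(fact, assemble_rhs(op, c1) + assemble_rhs(op, c2),
                      op = op)
  expect_equal(s12$rho, s1$rho + s2$rho,
               tolerance = 1e-10 * max(abs(s12$rho)))
})

test_that("factorization save/load round trip gives bitwise solves", {
  sm <- single_sphere(1)
  op <- assemble_operator(sm$model)
  fact <- factorize(op)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_factorization(fact, tf)
  re <- load_factorization(tf)
  b <- assemble_rhs(op, test_coil())
  expect_identical(solve_direct(re, b, op = op)$rho,
                   solve_direct(fact, b, op = op)$rho)
  tf2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, tf2)
  expect_error(load_factorization(tf2), "factorization")
})
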