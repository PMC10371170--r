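# package-local instrumentation (factorization build counter)
.tmsbem_state <- new.env(parent = emptyenv())
.tmsbem_state$factorization_builds <- 0L

#' Number of factorizations built in this session
#'
#' Instrumentation for the factor-once/solve-many contract: [factorize()]
#' increments this counter, [solve_direct()] never does.
#'
#' @param reset reset the counter to zero.
#' @return the current (pre-reset) count.
#' @export
factorization_builds <- function(reset = FALSE) {
  n <- .tmsbem_state$factorization_builds
  if (reset) .tmsbem_state$factorization_builds <- 0L
  n
}

#' Unrestarted GMRES for a matrix-free operator
#'
#' Arnoldi with modified Gram-Schmidt and Givens rotations, zero initial
#' guess, relative-residual stopping. Kept matrix-free so the dense and
#' on-the-fly operator modes share one code path.
#'
#' @param matvec function computing `A x`.
#' @param b right-hand side.
#' @param tol relative residual tolerance in (0, 1).
#' @param max_iter maximum Krylov dimension.
#' @return list `x`, `iterations`, `residual`, `history`, `converged`.
#' @export
gmres <- function(matvec, b, tol = 1e-6, max_iter = 200L) {
  if (tol <= 0 || tol >= 1) stop("tol must be in (0, 1)")
  n <- length(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0)
    return(list(x = numeric(n), iterations = 0L, residual = 0,
                history = numeric(0), converged = TRUE))
  V <- matrix(0, n, max_iter + 1L)
  H <- matrix(0, max_iter + 1L, max_iter)
  cs <- numeric(max_iter)
  sn <- numeric(max_iter)
  g <- numeric(max_iter + 1L)
  g[1] <- bnorm
  V[, 1] <- b / bnorm
  history <- numeric(0)
  k <- 0L
  for (j in seq_len(max_iter)) {
    w <- matvec(V[, j])
    for (i in seq_len(j)) {           # modified Gram-Schmidt
      H[i, j] <- sum(w * V[, i])
      w <- w - H[i, j] * V[, i]
    }
    H[j + 1L, j] <- sqrt(sum(w^2))
    if (H[j + 1L, j] > 0) V[, j + 1L] <- w / H[j + 1L, j]
    for (i in seq_len(j - 1L)) {      # previous Givens rotations
      t <- cs[i] * H[i, j] + sn[i] * H[i + 1L, j]
      H[i + 1L, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1L, j]
      H[i, j] <- t
    }
    r <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
    if (r == 0) { cs[j] <- 1; sn[j] <- 0 } else {
      cs[j] <- H[j, j] / r
      sn[j] <- H[j + 1L, j] / r
    }
    H[j, j] <- r
    H[j + 1L, j] <- 0
    g[j + 1L] <- -sn[j] * g[j]
    g[j] <- cs[j] * g[j]
    relres <- abs(g[j + 1L]) / bnorm
    history <- c(history, relres)
    k <- j
    if (relres <= tol) break
  }
  y <- backsolve(H[seq_len(k), seq_len(k), drop = FALSE], g[seq_len(k)])
  x <- drop(V[, seq_len(k), drop = FALSE] %*% y)
  list(x = x, iterations = k, residual = history[k], history = history,
       converged = history[k] <= tol)
}

#' Iterative (GMRES) solution of the surface-charge system
#'
#' Solves \eqn{A x = b} for the scaled surface charge density
#' \eqn{\rho^* = \rho/\epsilon_0} with unrestarted GMRES from a zero initial
#' guess. The second-kind system is well conditioned and typically converges
#' in a few tens of iterations.
#'
#' @param op a `system_operator`.
#' @param b right-hand side from [assemble_rhs()].
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual history.
#' @return a `charge_solution`: `rho` (V/m per facet), `residual`,
#'   `iterations`, `solver_tag = "iterative"`.
#' @export
solve_iterative <- function(op, b, tol = 1e-6, max_iter = 200L) {
  res <- gmres(function(x) apply_operator(op, x), as.numeric(b),
               tol = tol, max_iter = max_iter)
  if (!res$converged) {
    e <- simpleError(sprintf(
      "GMRES did not reach tol %g in %d iterations (residual %g)",
      tol, res$iterations, res$residual))
    e$best <- res$x
    e$history <- res$history
    stop(e)
  }
  charge_solution(res$x, residual = res$residual, tag = "iterative",
                  iterations = res$iterations, coil_tag = attr(b, "coil_tag"),
                  fingerprint = op$fingerprint)
}

charge_solution <- function(rho, residual, tag, iterations = NA_integer_,
                            coil_tag = NULL, fingerprint = NULL) {
  structure(list(rho = as.numeric(rho), residual = residual,
                 solver_tag = tag, iterations = iterations,
                 coil_tag = coil_tag, fingerprint = fingerprint),
            class = "charge_solution")
}

#' @export
print.charge_solution <- function(x, ...) {
  cat("charge_solution:", length(x$rho), "facets, solver =", x$solver_tag)
  if (!is.na(x$iterations)) cat(",", x$iterations, "iterations")
  cat(", residual", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Dense LU factorization of the system operator
#'
#' Builds one reusable pivoted LU decomposition (LAPACK, via
#' \pkg{Matrix}) per head model, bound to the model by its geometry
#' fingerprint. Every later right-hand side then costs only triangular
#' solves ([solve_direct()]).
#'
#' @param op a dense-mode `system_operator`.
#' @return a `bem_factorization`.
#' @export
factorize <- function(op) {
  if (!inherits(op, "system_operator") || op$mode != "dense")
    stop("factorize requires a dense-mode system_operator")
  lu <- Matrix::lu(op$dense)
  .tmsbem_state$factorization_builds <-
    .tmsbem_state$factorization_builds + 1L
  structure(list(lu = lu, n = op$n, fingerprint = op$fingerprint,
                 near_threshold = op$near_threshold,
                 built = format(Sys.time(), tz = "UTC")),
            class = "bem_factorization")
}

#' @export
print.bem_factorization <- function(x, ...) {
  cat("bem_factorization: N =", x$n, ", model fingerprint", x$fingerprint,
      "\n")
  invisible(x)
}

#' Direct solves against a stored factorization
#'
#' Solves one or many right-hand sides by forward/back substitution; the
#' factorization is never rebuilt. When `op` is supplied its fingerprint is
#' checked against the one the factorization was built from.
#'
#' @param fact a `bem_factorization`.
#' @param bs one right-hand side vector or a list of them.
#' @param op optional `system_operator` for fingerprint verification.
#' @return one `charge_solution` or a list of them (matching `bs`).
#' @export
solve_direct <- function(fact, bs, op = NULL) {
  if (!inherits(fact, "bem_factorization")) stop("not a bem_factorization")
  if (!is.null(op) && !identical(op$fingerprint, fact$fingerprint))
    stop("factorization fingerprint mismatch: it was built from a ",
         "different model/conductivities")
  single <- !is.list(bs)
  if (single) bs <- list(bs)
  if (any(vapply(bs, length, 1L) != fact$n))
    stop("right-hand side length must equal ", fact$n)
  B <- do.call(cbind, lapply(bs, as.numeric))
  X <- as.matrix(Matrix::solve(fact$lu, B))
  out <- lapply(seq_along(bs), function(i)
    charge_solution(X[, i], residual = NA_real_, tag = "direct",
                    coil_tag = attr(bs[[i]], "coil_tag"),
                    fingerprint = fact$fingerprint))
  if (single) out[[1]] else out
}

#' Save / load a factorization
#'
#' Serializes the factors, pivots and model fingerprint to a single file
#' (R's native binary serialization). A reloaded factorization produces
#' bitwise-identical solves.
#'
#' @param fact a `bem_factorization`.
#' @param path file path.
#' @return `save_factorization`: invisibly `path`; `load_factorization`:
#'   the `bem_factorization`.
#' @export
save_factorization <- function(fact, path) {
  if (!inherits(fact, "bem_factorization")) stop("not a bem_factorization")
  saveRDS(fact, path)
  invisible(path)
}

#' @rdname save_factorization
#' @export
load_factorization <- function(path) {
  fact <- readRDS(path)
  if (!inherits(fact, "bem_factorization"))
    stop("file does not contain a factorization: ", path)
  fact
}
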