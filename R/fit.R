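#' Fit the surface-charge model of a TMS session
#'
#' The central entry point: given a nested-compartment head model and a coil,
#' solves the second-kind Fredholm equation for the scaled surface charge
#' density \eqn{\rho^* = \rho/\epsilon_0} on every conductivity interface,
#' either iteratively (GMRES) or through a dense LU factorization that can
#' be reused across coil placements. The fitted object supports
#' `coef()` (the charges), `predict()` (total fields at new points),
#' `residuals()` (the normal-current continuity violation), `summary()` and
#' `plot()`.
#'
#' @param model a `head_model`.
#' @param coil a `coil` or [uniform_field_source()].
#' @param method `"gmres"` or `"lu"`.
#' @param tol GMRES relative residual tolerance.
#' @param max_iter GMRES iteration cap.
#' @param near_threshold analytic near-field radius in local facet sizes.
#' @param mode operator storage; default dense up to `dense_limit` facets,
#'   matrix-free beyond (LU requires dense).
#' @param dense_limit automatic mode switch point.
#' @param operator optionally, a prebuilt `system_operator` for this model.
#' @param factorization optionally, a prebuilt `bem_factorization`
#'   (fingerprint-checked); implies `method = "lu"`.
#' @return an object of class `tms_fit`.
#' @examples
#' sm <- make_sphere_model(0.09, 0.33, subdivisions = 2)
#' fit <- tms_fit(sm$model, make_figure8(didt = 9.4e7, height = 0.095))
#' fit
#' head(coef(fit))
#' @export
tms_fit <- function(model, coil, method = c("gmres", "lu"), tol = 1e-6,
                    max_iter = 200L, near_threshold = 5, mode = NULL,
                    dense_limit = 6000L, operator = NULL,
                    factorization = NULL) {
  method <- match.arg(method)
  if (!is.null(factorization)) method <- "lu"
  if (is.null(operator)) {
    if (is.null(mode))
      mode <- if (method == "lu" || model$total_facets <= dense_limit)
        "dense" else "matrix-free"
    operator <- assemble_operator(model, near_threshold = near_threshold,
                                  mode = mode)
  }
  if (method == "lu" && operator$mode != "dense")
    stop("the LU path requires a dense-mode operator")
  b <- assemble_rhs(operator, coil)
  if (method == "gmres") {
    sol <- solve_iterative(operator, b, tol = tol, max_iter = max_iter)
  } else {
    if (is.null(factorization)) factorization <- factorize(operator)
    sol <- solve_direct(factorization, b, op = operator)
  }
  structure(list(model = model, coil = coil, solution = sol,
                 operator_mode = operator$mode,
                 near_threshold = near_threshold,
                 method = method, tol = if (method == "gmres") tol else NA,
                 factorization = factorization,
                 fingerprint = operator$fingerprint),
            class = "tms_fit")
}

#' @export
print.tms_fit <- function(x, ...) {
  cat("TMS surface-charge fit (", x$method, ")\n", sep = "")
  print(x$model)
  s <- x$solution
  if (!is.na(s$iterations))
    cat("  GMRES:", s$iterations, "iterations, residual",
        format(s$residual, digits = 3), "\n")
  cat("  rho* range [", format(min(s$rho), digits = 4), ",",
      format(max(s$rho), digits = 4), "] V/m\n")
  invisible(x)
}

#' @export
coef.tms_fit <- function(object, ...) object$solution$rho

#' Predict total E-fields from a fit
#'
#' @param object a `tms_fit`.
#' @param points off-surface observation points (n x 3); ignored when
#'   `side` is given.
#' @param side `"in"` or `"out"` for one-sided on-surface evaluation at
#'   facet centroids.
#' @param facets facet subset for one-sided evaluation.
#' @param ... unused.
#' @return a `field_result`.
#' @export
predict.tms_fit <- function(object, points = NULL, side = NULL,
                            facets = NULL, ...) {
  if (!is.null(side))
    return(field_one_sided(object$model, object$solution, object$coil,
                           facets = facets, side = side,
                           near_threshold = object$near_threshold))
  if (is.null(points)) stop("supply points or side")
  field_off_surface(object$model, object$solution, object$coil, points,
                    near_threshold = object$near_threshold)
}

#' @export
residuals.tms_fit <- function(object, ...) {
  bc_residual(object$model, object$solution, object$coil,
              near_threshold = object$near_threshold)
}

#' @export
summary.tms_fit <- function(object, ...) {
  r <- residuals(object)
  g <- model_geometry(object$model)
  per_if <- vapply(seq_along(object$model$interfaces), function(i) {
    loc <- facet_location(object$model, seq_len(object$model$total_facets))
    idx <- loc$interface == i
    sum(object$solution$rho[idx] * g$areas[idx])
  }, 1)
  out <- list(fit = object,
              bc_residual_mean = attr(r, "area_weighted_mean"),
              net_charge_per_interface = per_if)
  class(out) <- "summary.tms_fit"
  out
}

#' @export
print.summary.tms_fit <- function(x, ...) {
  print(x$fit)
  cat("  area-weighted mean boundary-condition residual:",
      format(x$bc_residual_mean, digits = 3), "\n")
  cat("  net scaled charge per interface (~0 for inductive drive):",
      paste(format(x$net_charge_per_interface, digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' Plot the field magnitude on a plane through the model
#'
#' @param x a `tms_fit`.
#' @param center,u,v,extent,n plane specification, see [plane_grid()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the evaluated grid field.
#' @export
plot.tms_fit <- function(x, center = c(0, 0, 0), u = c(1, 0, 0),
                         v = c(0, 0, 1), extent = 0.05, n = 41L, ...) {
  pts <- plane_grid(center, u, v, extent = extent, n = n)
  f <- tryCatch(predict(x, points = pts),
                error = function(e) stop("plane intersects the surface ",
                                         "guard region: ", conditionMessage(e)))
  mag <- matrix(sqrt(rowSums(f$e_total^2)), n, n)
  s <- seq(-extent, extent, length.out = n)
  graphics::image(s, s, mag, xlab = "u (m)", ylab = "v (m)",
                  main = "|E| (V/m)", useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(f)
}
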