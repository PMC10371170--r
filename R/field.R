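#' Total E-field at off-surface points
#'
#' \eqn{E(r) = E^p(r) + \sum_n \rho^*_n F_n(r)}: primary coil field plus the
#' Coulomb field of the solved facet charges. Facets whose centroid lies
#' within `near_threshold` facet sizes of a point contribute their analytic
#' integral, the rest their centroid monopole. Points closer to a facet
#' centroid than `guard` times the local facet size are rejected: so close
#' to the surface the one-sided evaluation must be used.
#'
#' @param model a `head_model`.
#' @param solution a `charge_solution`.
#' @param coil the `coil` the solution was driven by (or NULL for the
#'   secondary field only).
#' @param points observation points (n x 3, meters).
#' @param near_threshold analytic near-field radius in facet sizes.
#' @param guard minimum allowed distance in facet sizes (0 disables).
#' @return a `field_result`: data.frame-like list with `points`, `e_total`,
#'   `e_primary`, `provenance`.
#' @export
field_off_surface <- function(model, solution, coil, points,
                              near_threshold = 5, guard = 0.1) {
  g <- model_geometry(model)
  points <- rbind3(points)
  if (guard > 0) {
    # nearest facet-centroid distance in units of that facet's size
    for (i in seq_len(nrow(points))) {
      d2 <- (g$centroids[, 1] - points[i, 1])^2 +
        (g$centroids[, 2] - points[i, 2])^2 +
        (g$centroids[, 3] - points[i, 3])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) < guard * sqrt(g$areas[j]))
        stop("point ", i, " lies within the surface guard distance; ",
             "use field_one_sided for on-surface evaluation")
    }
  }
  es <- .field_secondary_cpp(points, integer(nrow(points)), g$vertices,
                             g$triangles - 1L, g$centroids, g$normals,
                             g$areas, solution$rho, near_threshold)
  ep <- if (is.null(coil)) matrix(0, nrow(points), 3)
        else primary_field(coil, points)
  field_result(points, ep + es, ep, solution, coil)
}

#' One-sided total E-field at facet centroids
#'
#' The limiting field just inside (`side = "in"`, against the normal) or
#' just outside (`side = "out"`) the surface at facet centroids:
#' \deqn{E_{in/out}(c_m) = E^p(c_m) + \mathrm{PV}\sum_n \rho^*_n F_n(c_m)
#'   \mp n_m \rho^*_m / 2.}
#' The self facet enters the principal-value sum only through its (finite)
#' in-plane tangential field; its normal effect is entirely the planar-sheet
#' jump, so `E_out - E_in = n \rho^*` exactly, and off-surface evaluation at
#' points approaching the centroid converges to the one-sided values.
#'
#' @param model a `head_model`.
#' @param solution a `charge_solution`.
#' @param coil the driving `coil` (or NULL).
#' @param facets global facet indices (default all).
#' @param side `"in"` or `"out"`.
#' @param near_threshold analytic near-field radius in facet sizes.
#' @return a `field_result` at the facet centroids.
#' @export
field_one_sided <- function(model, solution, coil, facets = NULL,
                            side = c("in", "out"), near_threshold = 5) {
  side <- match.arg(side)
  g <- model_geometry(model)
  if (is.null(facets)) facets <- seq_len(nrow(g$centroids))
  facets <- as.integer(facets)
  if (any(facets < 1L | facets > nrow(g$centroids)))
    stop("facet index out of range")
  pts <- g$centroids[facets, , drop = FALSE]
  # exclude = 0: the self facet's analytic in-plane PV term is kept (the
  # solid-angle part vanishes exactly in the facet's own plane)
  es <- .field_secondary_cpp(pts, integer(length(facets)), g$vertices,
                             g$triangles - 1L, g$centroids, g$normals,
                             g$areas, solution$rho, near_threshold)
  jump <- (if (side == "in") -0.5 else 0.5) *
    g$normals[facets, , drop = FALSE] * solution$rho[facets]
  ep <- if (is.null(coil)) matrix(0, length(facets), 3)
        else primary_field(coil, pts)
  res <- field_result(pts, ep + es + jump, ep, solution, coil)
  res$facets <- facets
  res$side <- side
  res
}

field_result <- function(points, e_total, e_primary, solution, coil) {
  structure(list(points = points, e_total = e_total, e_primary = e_primary,
                 provenance = list(
                   solver = solution$solver_tag,
                   residual = solution$residual,
                   coil = if (is.null(coil)) "none" else coil_tag(coil),
                   fingerprint = solution$fingerprint)),
            class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  mag <- sqrt(rowSums(x$e_total^2))
  cat("field_result:", nrow(x$points), "points; |E| range [",
      format(min(mag), digits = 4), ",", format(max(mag), digits = 4),
      "] V/m\n")
  invisible(x)
}

#' @export
as.data.frame.field_result <- function(x, ...) {
  data.frame(x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
             Ex = x$e_total[, 1], Ey = x$e_total[, 2], Ez = x$e_total[, 3],
             mag = sqrt(rowSums(x$e_total^2)))
}

#' Boundary-condition residual of a solution
#'
#' The solved equation enforces continuity of the normal current,
#' \eqn{\sigma_{in} n \cdot E_{in} = \sigma_{out} n \cdot E_{out}}. This
#' diagnostic returns the per-facet violation
#' \eqn{|\sigma_{in} n \cdot E_{in} - \sigma_{out} n \cdot E_{out}|}
#' normalized by the local current-density scale
#' \eqn{\max(\sigma_{in}, \sigma_{out})\,(|E_{in}| + |E_{out}|)/2}
#' (with a small additive floor, so an interface to air — where one side
#' carries no current at all — is still judged against the field magnitude,
#' not against the vanishing normal current itself). The attribute
#' `area_weighted_mean` carries the area-weighted mean; it shrinks under
#' mesh refinement.
#'
#' @param model a `head_model`.
#' @param solution a `charge_solution`.
#' @param coil the driving excitation.
#' @param near_threshold analytic near-field radius in facet sizes.
#' @param floor additive denominator floor, as a fraction of the maximum
#'   current-density scale over the model.
#' @return numeric vector of per-facet residuals.
#' @export
bc_residual <- function(model, solution, coil, near_threshold = 5,
                        floor = 1e-9) {
  g <- model_geometry(model)
  ein <- field_one_sided(model, solution, coil, side = "in",
                         near_threshold = near_threshold)
  eout <- field_one_sided(model, solution, coil, side = "out",
                          near_threshold = near_threshold)
  sig <- do.call(rbind, lapply(model$interfaces, function(f)
    c(f$sigma_in, f$sigma_out)))
  nf <- vapply(model$interfaces, function(f) nrow(f$surface$triangles), 1L)
  s_in <- rep(sig[, 1], nf)
  s_out <- rep(sig[, 2], nf)
  jin <- s_in * rowSums(g$normals * ein$e_total)
  jout <- s_out * rowSums(g$normals * eout$e_total)
  scale <- pmax(s_in, s_out) *
    (sqrt(rowSums(ein$e_total^2)) + sqrt(rowSums(eout$e_total^2))) / 2
  r <- abs(jin - jout) / (scale + floor * max(scale, 1e-300))
  attr(r, "area_weighted_mean") <- sum(r * g$areas) / sum(g$areas)
  r
}

#' Deterministic quasi-uniform points on a sphere
#'
#' Fibonacci lattice; used for interior probe shells.
#'
#' @param n number of points.
#' @param radius sphere radius (m).
#' @param center 3-vector center.
#' @return n x 3 matrix.
#' @export
fibonacci_sphere <- function(n, radius = 1, center = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * i
  out <- sweep(radius * cbind(r * cos(th), r * sin(th), z), 2, center, "+")
  dimnames(out) <- NULL
  out
}

#' Regular grid of points on a plane
#'
#' @param center plane center (3-vector, m).
#' @param u,v in-plane spanning directions (normalized internally).
#' @param extent half-width along u and v (m).
#' @param n points per side.
#' @return `n^2` x 3 matrix.
#' @export
plane_grid <- function(center, u = c(1, 0, 0), v = c(0, 1, 0),
                       extent = 0.05, n = 21L) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  s <- seq(-extent, extent, length.out = n)
  gg <- expand.grid(a = s, b = s)
  out <- sweep(outer(gg$a, u) + outer(gg$b, v), 2, center, "+")
  dimnames(out) <- NULL
  out
}

#' Read / write observation points and field tables
#'
#' Points: whitespace-delimited `x y z` per line. Fields: TSV with header
#' `x y z Ex Ey Ez mag`.
#'
#' @param path file path.
#' @return `read_points`: n x 3 matrix.
#' @export
read_points <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 3L) stop("observation point file must have 3 columns")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' @rdname read_points
#' @param points n x 3 matrix.
#' @export
write_points <- function(points, path) {
  utils::write.table(format(rbind3(points), digits = 17), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_points
#' @param field a `field_result`.
#' @export
write_field_tsv <- function(field, path) {
  df <- as.data.frame(field)
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_points
#' @export
read_field_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  list(points = unname(as.matrix(df[, c("x", "y", "z")])),
       e = unname(as.matrix(df[, c("Ex", "Ey", "Ez")])))
}
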