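#' Concentric multilayer-sphere head model
#'
#' Synthetic stand-in for MRI-derived head models: nested icosphere
#' interfaces with per-shell conductivities (outside of the outermost is
#' air, sigma = 0) and an interior probe shell for field evaluation.
#'
#' @param radii strictly decreasing interface radii (m), outermost first.
#' @param conductivities per-shell conductivities (S/m), one per interface;
#'   element i is the conductivity just inside interface i.
#' @param subdivisions icosphere subdivision count per interface (facets =
#'   `20 * 4^subdivisions`).
#' @param center common center (m).
#' @param probe_n number of interior probe points.
#' @param probe_frac probe shell radius as a fraction of the innermost
#'   interface radius.
#' @return list with `model` (a `head_model`, sphere-tagged for projected
#'   refinement) and `probes` (probe_n x 3 matrix).
#' @examples
#' sm <- make_sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.01, 0.33), 1)
#' sm$model
#' @export
make_sphere_model <- function(radii, conductivities, subdivisions = 3L,
                              center = c(0, 0, 0), probe_n = 1000L,
                              probe_frac = 0.8) {
  if (any(diff(radii) >= 0))
    stop("radii must be strictly decreasing (outermost first)")
  if (length(conductivities) != length(radii))
    stop("one conductivity per interface required")
  if (any(conductivities < 0)) stop("conductivities must be >= 0")
  n <- length(radii)
  sigma_out <- c(0, conductivities[-n])
  ifs <- lapply(seq_len(n), function(i)
    interface(make_icosphere(radii[i], subdivisions, center),
              sigma_in = conductivities[i], sigma_out = sigma_out[i],
              name = sprintf("sphere_r%.4g", radii[i]),
              sphere = list(center = center, radius = radii[i])))
  list(model = head_model(ifs),
       probes = fibonacci_sphere(probe_n, probe_frac * radii[n], center))
}

#' Analytic oracle: sphere in a uniform applied field
#'
#' A homogeneous conducting sphere in an insulating exterior under a uniform
#' conservative applied field \eqn{E_0 \hat z} carries the surface charge
#' \eqn{\rho^*(\theta) = 3 E_0 \cos\theta} and has exactly zero total field
#' inside (the separation-of-variables Laplace solution). Returns the
#' closed-form reference evaluated at the facet centroids of a mesh.
#'
#' @param surface a `triangle_surface` discretizing the sphere.
#' @param E0 applied field magnitude (V/m), along +z.
#' @param center sphere center.
#' @return list `rho` (closed-form centroid values), `interior_field`
#'   (zero vector).
#' @export
analytic_uniform_field_case <- function(surface, E0, center = c(0, 0, 0)) {
  d <- sweep(surface$centroids, 2, center)
  costh <- d[, 3] / sqrt(rowSums(d^2))
  list(rho = 3 * E0 * costh, interior_field = c(0, 0, 0))
}

#' Conductivity-profile independence check
#'
#' In a spherically symmetric conductor the total interior E-field induced
#' by a coil (inductive excitation) is independent of the radial
#' conductivity profile. Solves two sphere models of equal outer radius and
#' different profiles and reports the field discrepancy at shared interior
#' probe points - a ground-truth-free correctness check.
#'
#' @param spec_single,spec_multi lists of arguments to
#'   [make_sphere_model()] with the same outer radius.
#' @param coil a closed-loop `coil`.
#' @param tol GMRES tolerance for both solves.
#' @return an error report (see [error_report()]) plus fields
#'   `radial_fraction_single`, `radial_fraction_multi`: RMS radial
#'   component over RMS magnitude at the probes (near 0 for symmetric
#'   conductors under induction).
#' @export
profile_independence_check <- function(spec_single, spec_multi, coil,
                                       tol = 1e-8) {
  s1 <- do.call(make_sphere_model, spec_single)
  s2 <- do.call(make_sphere_model, spec_multi)
  r1 <- spec_single$radii[1]
  if (abs(r1 - spec_multi$radii[1]) > 1e-12)
    stop("outer radii must match")
  probes <- s1$probes
  f1 <- solve_and_eval(s1$model, coil, probes, tol = tol)
  f2 <- solve_and_eval(s2$model, coil, probes, tol = tol)
  rep_ <- error_report(f2, f1, roi_tag = "interior probe shell")
  rad <- function(f) {
    u <- probes / sqrt(rowSums(probes^2))
    sqrt(sum(rowSums(f$e_total * u)^2) / sum(f$e_total^2))
  }
  rep_$radial_fraction_single <- rad(f1)
  rep_$radial_fraction_multi <- rad(f2)
  rep_
}

# assemble, solve (auto dense/matrix-free), evaluate at points
solve_and_eval <- function(model, coil, points, tol = 1e-8,
                           near_threshold = 5, dense_limit = 6000L,
                           max_iter = 200L) {
  mode <- if (model$total_facets <= dense_limit) "dense" else "matrix-free"
  op <- assemble_operator(model, near_threshold = near_threshold,
                          mode = mode)
  b <- assemble_rhs(op, coil)
  sol <- solve_iterative(op, b, tol = tol, max_iter = max_iter)
  field_off_surface(model, sol, coil, points,
                    near_threshold = near_threshold)
}

#' Refined-mesh ground truth
#'
#' Applies `levels` uniform 1:4 subdivisions to every interface (projected
#' back onto the sphere for sphere-tagged interfaces), solves at a tight
#' tolerance, and evaluates the total field at the caller's observation
#' points. Serves as the reference solution for convergence studies.
#'
#' @param model a `head_model`.
#' @param coil the driving excitation.
#' @param points observation points.
#' @param levels number of 1:4 refinements (1 or 2; 2 gives 1:16).
#' @param tol GMRES tolerance for the refined solve.
#' @param near_threshold analytic near-field radius in facet sizes.
#' @param max_iter GMRES iteration cap.
#' @return a `field_result` with `provenance$ground_truth = TRUE`.
#' @export
refined_ground_truth <- function(model, coil, points, levels = 2L,
                                 tol = 1e-8, near_threshold = 5,
                                 max_iter = 200L) {
  if (!levels %in% c(1L, 2L)) stop("levels must be 1 or 2")
  refined <- refine_model(model, levels)
  res <- solve_and_eval(refined, coil, points, tol = tol,
                        near_threshold = near_threshold,
                        max_iter = max_iter)
  res$provenance$ground_truth <- TRUE
  res$provenance$levels <- levels
  res$provenance$facets <- refined$total_facets
  res
}

#' Uniformly refine every interface of a model
#'
#' @param model a `head_model`.
#' @param levels number of 1:4 subdivisions.
#' @return the refined `head_model`.
#' @export
refine_model <- function(model, levels = 1L) {
  ifs <- lapply(model$interfaces, function(f) {
    s <- f$surface
    for (i in seq_len(levels))
      s <- subdivide_1to4(s, project = f$sphere)
    interface(s, f$sigma_in, f$sigma_out, name = f$name, sphere = f$sphere)
  })
  head_model(ifs)
}
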