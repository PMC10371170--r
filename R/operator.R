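#' Field of a uniformly charged triangle
#'
#' Closed-form E-field of a flat triangle carrying unit scaled charge
#' density \eqn{\rho^* = \rho/\epsilon_0 = 1}:
#' \deqn{F(r) = \frac{1}{4\pi} \int_t \frac{r - r'}{|r - r'|^3}\,dA'.}
#' The normal part is the signed solid angle (van Oosterom-Strackee), the
#' in-plane part a sum of edge integrals of \eqn{1/R}. For a point in the
#' triangle's plane the result is the principal value, whose normal
#' component vanishes. Far from the triangle it approaches the centroid
#' monopole \eqn{A (r - c) / (4\pi |r - c|^3)}.
#'
#' @param triangle 3x3 matrix, one vertex per row; winding defines the
#'   normal.
#' @param points observation points (n x 3 or a 3-vector); must not be a
#'   vertex of the triangle.
#' @return n x 3 matrix of field vectors (V/m per unit rho*).
#' @export
triangle_field_integral <- function(triangle, points) {
  triangle <- as.matrix(triangle)
  if (!all(dim(triangle) == c(3, 3))) stop("triangle must be 3x3")
  points <- rbind3(points)
  e1 <- triangle[2, ] - triangle[1, ]
  e2 <- triangle[3, ] - triangle[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  nrm2 <- sqrt(sum(cr^2))
  if (nrm2 <= 0) stop("degenerate triangle")
  for (i in seq_len(nrow(points)))
    for (j in 1:3)
      if (sqrt(sum((points[i, ] - triangle[j, ])^2)) < 1e-14)
        stop("observation point coincides with a triangle vertex")
  .tri_field_cpp(triangle, cr / nrm2, points)
}

#' Assemble the system operator of the surface-charge equation
#'
#' Discretizes the second-kind surface-charge equation with piecewise
#' constant charge per facet:
#' \deqn{A_{mn} = \tfrac12 \delta_{mn} -
#'   K_m\, n_m \cdot \langle F_n \rangle_m,}
#' where \eqn{F_n} is the unit-density field of facet `n` and
#' \eqn{\langle\cdot\rangle_m} averages over the collocation facet `t_m`.
#' The self term is exactly \eqn{1/2}: the principal-value field of a flat
#' facet is purely tangential everywhere in its own plane. Facet pairs with
#' centroid distance at most `near_threshold * sqrt(max(A_m, A_n))` use the
#' analytic triangle integral averaged over `t_m` with an `outer_rule`-point
#' symmetric quadrature; farther pairs use the centroid monopole (for which
#' averaging is immaterial at this order). `near_threshold = Inf` makes
#' every entry analytic; `outer_rule = 1` degrades the average to plain
#' centroid collocation.
#'
#' @param model a `head_model`.
#' @param near_threshold near-field radius in local facet sizes (default 5).
#' @param mode `"dense"` (store the N x N matrix) or `"matrix-free"` (store
#'   only the sparse near-field correction; the far field is summed on the
#'   fly at each application).
#' @param outer_rule quadrature points on the collocation facet for near
#'   pairs: 1 (centroid), 3 (degree 2) or 7 (degree 5, default).
#' @param dense_cap refuse dense assembly above this N.
#' @return a `system_operator`.
#' @export
assemble_operator <- function(model, near_threshold = 5,
                              mode = c("dense", "matrix-free"),
                              outer_rule = 7L, dense_cap = 60000L) {
  mode <- match.arg(mode)
  if (!outer_rule %in% c(1L, 3L, 7L)) stop("outer_rule must be 1, 3 or 7")
  g <- model_geometry(model)
  N <- nrow(g$centroids)
  tri0 <- g$triangles - 1L
  cor <- .near_corrections_cpp(g$vertices, tri0, g$centroids, g$normals,
                               g$areas, near_threshold,
                               as.integer(outer_rule))
  if (mode == "dense") {
    if (N > dense_cap)
      stop("N = ", N, " exceeds the dense capacity cap (", dense_cap,
           "); use mode = \"matrix-free\"")
    G <- .dense_monopole_cpp(g$centroids, g$normals, g$areas)
    if (length(cor$i))
      G[cbind(cor$i, cor$j)] <- G[cbind(cor$i, cor$j)] + cor$x
    A <- -g$contrast * G       # row scaling: column-major recycling
    diag(A) <- diag(A) + 0.5
    dense <- A
    near <- NULL
  } else {
    near <- Matrix::sparseMatrix(i = cor$i, j = cor$j, x = cor$x,
                                 dims = c(N, N))
    dense <- NULL
  }
  structure(list(model = model, geometry = g, n = N, mode = mode,
                 near_threshold = near_threshold, outer_rule = outer_rule,
                 dense = dense, near = near,
                 fingerprint = model_fingerprint(model)),
            class = "system_operator")
}

#' @export
print.system_operator <- function(x, ...) {
  cat("system_operator: N =", x$n, "facets, mode =", x$mode,
      ", near_threshold =", x$near_threshold, "\n")
  invisible(x)
}

#' Apply the system operator to a vector
#'
#' Dense mode multiplies the stored matrix; matrix-free mode sums centroid
#' monopoles pairwise on the fly and adds the stored sparse analytic
#' near-field correction. Both modes agree to 1e-10 relative.
#'
#' @param op a `system_operator`.
#' @param x numeric vector of length N.
#' @return numeric vector `A x`.
#' @export
apply_operator <- function(op, x) {
  if (length(x) != op$n) stop("length(x) must equal ", op$n)
  if (op$mode == "dense") return(drop(op$dense %*% x))
  g <- op$geometry
  gx <- .matvec_monopole_cpp(g$centroids, g$normals, g$areas, x) +
    as.numeric(op$near %*% x)
  as.numeric(0.5 * x - g$contrast * gx)
}

#' Assemble the right-hand side for a coil
#'
#' \eqn{b_m = K_m\, n_m \cdot \langle E^p \rangle_m}: the normal component
#' of the primary field averaged over each facet (same symmetric quadrature
#' rule as the operator's near field; `outer_rule = 1` evaluates at the
#' centroid only). Linear in the coil's dI/dt.
#'
#' @param model a `head_model` (or a `system_operator`, reusing its cached
#'   geometry and quadrature rule).
#' @param coil a `coil` or [uniform_field_source()].
#' @param outer_rule facet-averaging rule (1, 3 or 7 points); defaults to
#'   the operator's when `model` is a `system_operator`, else 7.
#' @return numeric vector of length N with attribute `coil_tag`.
#' @export
assemble_rhs <- function(model, coil, outer_rule = NULL) {
  if (inherits(model, "system_operator")) {
    g <- model$geometry
    if (is.null(outer_rule)) outer_rule <- model$outer_rule
  } else {
    g <- model_geometry(model)
    if (is.null(outer_rule)) outer_rule <- 7L
  }
  rule <- quad_points(outer_rule)
  nep <- 0
  for (q in seq_len(nrow(rule))) {
    pts <- rule[q, 1] * g$vertices[g$triangles[, 1], , drop = FALSE] +
      rule[q, 2] * g$vertices[g$triangles[, 2], , drop = FALSE] +
      rule[q, 3] * g$vertices[g$triangles[, 3], , drop = FALSE]
    nep <- nep + rule[q, 4] * rowSums(g$normals * primary_field(coil, pts))
  }
  b <- g$contrast * nep
  attr(b, "coil_tag") <- coil_tag(coil)
  b
}

# barycentric quadrature rules (columns: l1, l2, l3, weight)
quad_points <- function(nq) {
  if (nq == 1L) return(matrix(c(1 / 3, 1 / 3, 1 / 3, 1), 1))
  if (nq == 3L)
    return(cbind(rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5)),
                 rep(1 / 3, 3)))
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  w1 <- 0.132394152788506; w2 <- 0.125939180544827
  cbind(rbind(c(1, 1, 1) / 3,
              c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
              c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2)),
        c(0.225, w1, w1, w1, w2, w2, w2))
}

coil_tag <- function(coil) {
  if (inherits(coil, "uniform_source"))
    return(sprintf("uniform E0=(%g,%g,%g)", coil$E0[1], coil$E0[2],
                   coil$E0[3]))
  sprintf("coil n=%d didt=%g hash=%s", nrow(coil$positions), coil$didt,
          .fnv1a_cpp(c(as.numeric(coil$positions),
                       as.numeric(coil$moments), coil$didt)))
}
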