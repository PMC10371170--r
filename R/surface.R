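#' Triangulated surface with derived facet geometry
#'
#' Constructs a `triangle_surface` from a vertex matrix and a triangle index
#' matrix, deriving per-facet areas, outward unit normals (right-hand rule on
#' the stored winding) and centroids. Degenerate facets are rejected.
#'
#' @param vertices numeric matrix, one 3-D vertex per row (meters).
#' @param triangles integer matrix, one row of three 1-based vertex indices
#'   per facet; winding defines the normal direction.
#' @param validate logical; check for degenerate facets and index validity.
#' @return An object of class `triangle_surface` with components `vertices`,
#'   `triangles`, `areas` (m^2), `normals` (unit), `centroids` (m).
#' @examples
#' s <- make_icosphere(1, 0)
#' sum(s$areas)
#' @export
triangle_surface <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (nrow(triangles) < 1L) stop("surface has zero facets")
  nv <- nrow(vertices)
  if (validate) {
    if (any(triangles < 1L) || any(triangles > nv))
      stop("triangle indices out of range")
    same <- triangles[, 1] == triangles[, 2] |
      triangles[, 1] == triangles[, 3] | triangles[, 2] == triangles[, 3]
    if (any(same))
      stop("triangles with repeated vertex indices: ",
           paste(which(same), collapse = ", "))
  }
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  twoA <- sqrt(rowSums(cr^2))
  areas <- twoA / 2
  if (validate) {
    edge2 <- pmax(rowSums(e1^2), rowSums(e2^2), rowSums((v3 - v2)^2))
    bad <- areas < 1e-16 | (areas > 0 & edge2 / (2 * pmax(areas, 1e-300)) > 1e6)
    if (any(bad))
      stop("degenerate facets (zero area or extreme aspect ratio): ",
           paste(which(bad), collapse = ", "))
  }
  normals <- cr / twoA
  centroids <- (v1 + v2 + v3) / 3
  structure(list(vertices = vertices, triangles = triangles, areas = areas,
                 normals = normals, centroids = centroids),
            class = "triangle_surface")
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat("triangle_surface:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "facets, total area",
      format(sum(x$areas), digits = 6), "m^2\n")
  defect <- closure_defect(x)
  cat("  closure defect |sum(A n)| / sum(A):", format(defect, digits = 3),
      "\n")
  invisible(x)
}

#' Divergence-theorem closure defect of a surface
#'
#' For a closed oriented surface the facet area-weighted normals sum to the
#' zero vector; the defect is reported relative to the total area.
#'
#' @param surface a `triangle_surface`.
#' @return scalar `||sum_m A_m n_m|| / sum_m A_m`.
#' @export
closure_defect <- function(surface) {
  s <- colSums(surface$areas * surface$normals)
  sqrt(sum(s^2)) / sum(surface$areas)
}

#' Signed volume enclosed by a closed oriented surface
#'
#' Positive for outward-oriented normals (divergence theorem applied to
#' \eqn{x/3}).
#' @param surface a `triangle_surface`.
#' @return scalar volume in m^3.
#' @export
signed_volume <- function(surface) {
  sum(surface$areas * rowSums(surface$centroids * surface$normals)) / 3
}

#' Icosphere mesh
#'
#' Builds a geodesic sphere by recursive 1:4 subdivision of an icosahedron,
#' projecting every vertex onto the sphere. Facet count is
#' `20 * 4^subdivisions`; normals point outward.
#'
#' @param radius sphere radius in meters (> 0).
#' @param subdivisions non-negative integer subdivision count.
#' @param center 3-vector sphere center (meters).
#' @return a `triangle_surface`.
#' @examples
#' nrow(make_icosphere(0.09, 2)$triangles)  # 320
#' @export
make_icosphere <- function(radius, subdivisions = 0L, center = c(0, 0, 0)) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  s <- triangle_surface(v, f)
  if (subdivisions > 0L) {
    for (i in seq_len(subdivisions))
      s <- subdivide_1to4(s, project = list(center = c(0, 0, 0), radius = 1))
  }
  vv <- s$vertices * radius
  vv <- sweep(vv, 2, center, "+")
  triangle_surface(vv, s$triangles)
}

#' Uniform 1:4 surface refinement
#'
#' Splits every triangle at its edge midpoints into four. Shared edges are
#' split consistently so watertightness is preserved; without projection the
#' total area of a flat-facet mesh is unchanged. With `project` the new and
#' old vertices are pushed onto a sphere (used for refining sphere models).
#'
#' @param surface a `triangle_surface` describing a closed surface.
#' @param project optional `list(center =, radius =)`; project all vertices
#'   onto this sphere after splitting.
#' @return the refined `triangle_surface` (4x the facet count).
#' @export
subdivide_1to4 <- function(surface, project = NULL) {
  v <- surface$vertices
  f <- surface$triangles
  nf <- nrow(f)
  # consistent midpoint identification through ordered edge keys
  ea <- pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
  eb <- pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
  key <- paste(ea, eb)
  tab <- table(key)
  if (any(tab != 2L))
    stop("non-manifold or boundary edges found (each edge must be shared ",
         "by exactly 2 facets on a closed surface)")
  ukey <- unique(key)
  mid_id <- match(key, ukey)          # per (facet, edge-slot) midpoint index
  dim(mid_id) <- dim(ea)
  first <- match(ukey, key)
  mids <- (v[ea[first], , drop = FALSE] + v[eb[first], , drop = FALSE]) / 2
  nv <- nrow(v)
  vv <- rbind(v, mids)
  m12 <- nv + mid_id[, 1]
  m23 <- nv + mid_id[, 2]
  m31 <- nv + mid_id[, 3]
  ff <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  # interleave so children of facet i are contiguous
  ord <- as.vector(t(matrix(seq_len(4L * nf), nrow = nf)))
  ff <- ff[ord, , drop = FALSE]
  if (!is.null(project)) {
    ctr <- project$center
    r <- project$radius
    d <- sweep(vv, 2, ctr)
    vv <- sweep(d * (r / sqrt(rowSums(d^2))), 2, ctr, "+")
  }
  triangle_surface(vv, ff)
}

#' Weld duplicate vertices
#'
#' Merges vertices whose coordinates agree within `tol` (lexicographic
#' rounding), reindexing the triangles. Used by the STL reader, where each
#' facet carries its own vertex copies.
#'
#' @param vertices numeric matrix of vertex rows.
#' @param triangles integer triangle index matrix.
#' @param tol welding tolerance in meters.
#' @return list with welded `vertices` and reindexed `triangles`.
#' @keywords internal
weld_vertices <- function(vertices, triangles, tol = 1e-9) {
  keyv <- round(vertices / tol)
  key <- paste(keyv[, 1], keyv[, 2], keyv[, 3])
  ukey <- unique(key)
  idx <- match(key, ukey)
  keep <- match(ukey, key)
  tri <- matrix(idx[triangles], ncol = 3)
  list(vertices = vertices[keep, , drop = FALSE], triangles = tri)
}
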