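#' TMS coil as elementary current elements
#'
#' A coil is a set of straight elementary current elements: positions
#' \eqn{r_j} and moments \eqn{m_j} (direction times segment length times
#' winding weight), driven at a rate \eqn{dI/dt}. The primary (free-space)
#' field is \eqn{E^p(r) = -(\mu_0/4\pi)\, dI/dt \sum_j m_j / |r - r_j|},
#' the time derivative of the magnetostatic vector potential of the current
#' path.
#'
#' @param positions numeric matrix of element positions (m), one per row.
#' @param moments numeric matrix of element moment vectors (m), same shape.
#' @param didt drive rate dI/dt in A/s.
#' @return a `coil` object.
#' @export
coil <- function(positions, moments, didt = 1) {
  positions <- as.matrix(positions)
  moments <- as.matrix(moments)
  if (ncol(positions) != 3L || ncol(moments) != 3L ||
      nrow(positions) != nrow(moments))
    stop("positions and moments must be n x 3 matrices of equal size")
  if (!all(is.finite(positions)) || !all(is.finite(moments)) ||
      !is.finite(didt))
    stop("coil coordinates, moments and didt must be finite")
  if (any(rowSums(moments^2) == 0))
    stop("zero-moment coil elements are not allowed")
  dimnames(positions) <- NULL
  dimnames(moments) <- NULL
  structure(list(positions = positions, moments = moments,
                 didt = as.numeric(didt)),
            class = "coil")
}

#' @export
print.coil <- function(x, ...) {
  cat("coil:", nrow(x$positions), "current elements, dI/dt =",
      format(x$didt, digits = 6), "A/s\n")
  s <- colSums(x$moments)
  cat("  |sum of moments| =", format(sqrt(sum(s^2)), digits = 3),
      "m (0 for closed loops)\n")
  invisible(x)
}

#' Primary coil field at points
#'
#' Evaluates \eqn{E^p(r) = -(\mu_0/4\pi)\, dI/dt \sum_j m_j/|r - r_j|}
#' (V/m) by direct summation over elements.
#'
#' @param coil a `coil` (or any object with a `primary_field` method).
#' @param points numeric matrix of observation points (m), one per row.
#' @return numeric matrix of field vectors, one per row.
#' @export
primary_field <- function(coil, points) UseMethod("primary_field")

#' @export
primary_field.coil <- function(coil, points) {
  points <- rbind3(points)
  .primary_field_cpp(points, coil$positions, coil$moments, coil$didt)
}

#' Synthetic uniform applied field
#'
#' A test excitation whose "primary field" is a constant vector `E0`
#' everywhere. Nonphysical as a coil (it is conservative, not inductive) but
#' exact for the analytic sphere oracle where the surface-charge response to
#' a uniform applied field is known in closed form.
#'
#' @param E0 3-vector, the applied field (V/m).
#' @return an object with a `primary_field` method.
#' @export
uniform_field_source <- function(E0) {
  stopifnot(length(E0) == 3, all(is.finite(E0)))
  structure(list(E0 = as.numeric(E0), didt = 1), class = "uniform_source")
}

#' @export
primary_field.uniform_source <- function(coil, points) {
  points <- rbind3(points)
  matrix(coil$E0, nrow = nrow(points), ncol = 3, byrow = TRUE)
}

#' Figure-8 coil generator
#'
#' Two coplanar circular loops of opposite winding sense in the plane
#' `z = height` (canonical frame), centers at `x = ±separation/2`, each
#' discretized into straight current elements. Element moments sum to zero
#' (closed loops).
#'
#' @param radius loop radius (m).
#' @param turns number of turns per loop (moment weight).
#' @param segments_per_turn polygon segments per loop, >= 8.
#' @param separation distance between loop centers (m).
#' @param didt drive rate (A/s).
#' @param height z-coordinate of the coil plane (m).
#' @return a `coil` with `2 * segments_per_turn` elements.
#' @export
make_figure8 <- function(radius = 0.035, turns = 1L, segments_per_turn = 64L,
                         separation = 0.07, didt = 1, height = 0) {
  if (radius <= 0) stop("radius must be > 0")
  if (segments_per_turn < 8L) stop("segments_per_turn must be >= 8")
  loop <- function(cx, sense) {
    th <- 2 * pi * (seq_len(segments_per_turn) - 1L) / segments_per_turn
    a <- cbind(cx + radius * cos(th), radius * sin(th), height)
    b <- a[c(2:segments_per_turn, 1L), , drop = FALSE]
    list(pos = (a + b) / 2, mom = sense * turns * (b - a))
  }
  l1 <- loop(-separation / 2, +1)
  l2 <- loop(+separation / 2, -1)
  coil(rbind(l1$pos, l2$pos), rbind(l1$mom, l2$mom), didt = didt)
}

#' Rigid transform of a coil
#'
#' Rotates element positions and moments and translates positions. The field
#' of the transformed coil at transformed points equals the rotated field at
#' the original points.
#'
#' @param coil a `coil`.
#' @param rotation 3x3 orthonormal matrix.
#' @param translation 3-vector (m).
#' @return the transformed `coil`.
#' @export
transform_coil <- function(coil, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-12)) ||
      det(rotation) <= 0)
    stop("rotation must be a proper orthonormal 3x3 matrix")
  pos <- coil$positions %*% t(rotation)
  pos <- sweep(pos, 2, translation, "+")
  coil(pos, coil$moments %*% t(rotation), didt = coil$didt)
}

#' Write a coil to a plain-text file
#'
#' Whitespace-delimited, one element per line: `x y z mx my mz` (meters),
#' after a header line `tmscoil units=m didt=<A/s> n=<elements>`.
#'
#' @param coil a `coil`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_coil_file <- function(coil, path) {
  n <- nrow(coil$positions)
  hdr <- sprintf("tmscoil units=m didt=%.17g n=%d", coil$didt, n)
  m <- cbind(coil$positions, coil$moments)
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a coil from a plain-text file
#'
#' @param path coil file written by [write_coil_file()].
#' @return a `coil`.
#' @export
read_coil_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty coil file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (hdr[1] != "tmscoil")
    stop("not a tmscoil file (bad header): ", path)
  kv <- strsplit(hdr[-1], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  didt <- as.numeric(vals[["didt"]])
  n <- as.integer(vals[["n"]])
  body <- lines[-1]
  if (length(body) != n)
    stop("coil file declares ", n, " elements but has ", length(body))
  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(rows, length, 1L) != 6L)
  if (length(bad))
    stop("malformed coil element line ", bad[1] + 1L,
         " (expected 6 columns)")
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 6,
              byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value in coil file: ", path)
  coil(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], didt = didt)
}

# coerce a point, vector or matrix to an n x 3 double matrix
rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns")
  storage.mode(points) <- "double"
  points
}
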