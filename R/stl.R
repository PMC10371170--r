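#' Read a triangulated surface from an STL file
#'
#' Reads binary or ASCII STL (auto-detected), welds duplicate vertices within
#' `weld_tol`, preserves facet winding from the file, and derives areas,
#' normals and centroids. Coordinates are interpreted in `units`.
#'
#' @param path STL file path.
#' @param units `"m"` or `"mm"`; `"mm"` coordinates are converted to meters.
#' @param weld_tol vertex welding tolerance in meters.
#' @return a `triangle_surface`.
#' @export
read_stl <- function(path, units = c("m", "mm"), weld_tol = 1e-9) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("cannot read STL file: ", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  ascii <- grepl("^\\s*solid", txt)
  if (ascii) {
    # an ASCII file must actually contain facet records; some binary files
    # begin with the word "solid" in the header
    lines <- readLines(path, warn = FALSE)
    ascii <- any(grepl("facet\\s+normal", lines))
  }
  if (ascii) {
    tri <- parse_stl_ascii(lines)
  } else {
    tri <- parse_stl_binary(path)
  }
  if (nrow(tri) == 0L) stop("STL file contains zero facets: ", path)
  if (units == "mm") tri <- tri / 1000
  nf <- nrow(tri) / 3L
  triangles <- matrix(seq_len(3L * nf), ncol = 3, byrow = TRUE)
  w <- weld_vertices(tri, triangles, tol = weld_tol)
  triangle_surface(w$vertices, w$triangles)
}

parse_stl_ascii <- function(lines) {
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) return(matrix(numeric(0), ncol = 3))
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    x <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(x)) stop("malformed vertex line in ASCII STL")
    x
  })
  m <- do.call(rbind, nums)
  if (nrow(m) %% 3L != 0L) stop("ASCII STL vertex count not a multiple of 3")
  m
}

parse_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L) stop("malformed binary STL header: ", path)
  if (nf == 0L) return(matrix(numeric(0), ncol = 3))
  rec <- readBin(con, "raw", nf * 50L)
  if (length(rec) < nf * 50L) stop("truncated binary STL: ", path)
  dim(rec) <- c(50L, nf)
  fl <- readBin(as.vector(rec[1:48, ]), "numeric", nf * 12L, size = 4L,
                endian = "little")
  dim(fl) <- c(12L, nf)
  # rows 4..12 are the three vertices; 1..3 the stored normal (recomputed).
  # column-major order of fl[4:12, ] is v1,v2,v3 within each facet record
  matrix(fl[4:12, ], ncol = 3L, byrow = TRUE)
}

#' Write a surface to an STL file
#'
#' @param surface a `triangle_surface`.
#' @param path output file path.
#' @param binary write binary STL (default) or ASCII.
#' @param units `"m"` (native) or `"mm"` (coordinates multiplied by 1000).
#' @return invisibly, `path`.
#' @export
write_stl <- function(surface, path, binary = TRUE, units = c("m", "mm")) {
  units <- match.arg(units)
  if (!inherits(surface, "triangle_surface")) stop("not a triangle_surface")
  scale <- if (units == "mm") 1000 else 1
  v <- surface$vertices * scale
  f <- surface$triangles
  nf <- nrow(f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("tmsbem binary STL, %d facets", nf))
    writeBin(c(hdr, raw(80L - length(hdr))), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    rec <- matrix(0, nrow = 12L, ncol = nf)
    rec[1:3, ] <- t(surface$normals)
    rec[4:6, ] <- t(v[f[, 1], , drop = FALSE])
    rec[7:9, ] <- t(v[f[, 2], , drop = FALSE])
    rec[10:12, ] <- t(v[f[, 3], , drop = FALSE])
    body <- writeBin(as.vector(rec), raw(), size = 4L, endian = "little")
    dim(body) <- c(48L, nf)
    pad <- matrix(as.raw(0), nrow = 2L, ncol = nf)
    writeBin(as.vector(rbind(body, pad)), con)
  } else {
    fmt <- function(x) sprintf("%.9e", x)
    out <- character(7L * nf + 2L)
    out[1] <- "solid tmsbem"
    k <- 2L
    for (i in seq_len(nf)) {
      n <- surface$normals[i, ]
      out[k] <- paste(" facet normal", fmt(n[1]), fmt(n[2]), fmt(n[3]))
      out[k + 1L] <- "  outer loop"
      for (j in 1:3) {
        p <- v[f[i, j], ]
        out[k + 1L + j] <- paste("   vertex", fmt(p[1]), fmt(p[2]), fmt(p[3]))
      }
      out[k + 5L] <- "  endloop"
      out[k + 6L] <- " endfacet"
      k <- k + 7L
    }
    out[k] <- "endsolid tmsbem"
    writeLines(out, path)
  }
  invisible(path)
}
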