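#' Conductivity contrast at an interface
#'
#' \eqn{K = (\sigma_{in} - \sigma_{out}) / (\sigma_{in} + \sigma_{out})},
#' the factor controlling the induced surface charge. `sigma_in` is the
#' conductivity on the side the facet normals point away from (the enclosed
#' tissue, for outward-oriented closed surfaces).
#'
#' @param sigma_in,sigma_out conductivities in S/m, non-negative, not both 0.
#' @return contrast in \eqn{[-1, 1]}.
#' @examples
#' conductivity_contrast(0.33, 0)     # scalp-air: 1
#' conductivity_contrast(1, 3)        # -0.5
#' @export
conductivity_contrast <- function(sigma_in, sigma_out) {
  if (any(sigma_in < 0) || any(sigma_out < 0))
    stop("conductivities must be non-negative")
  if (any(sigma_in + sigma_out <= 0))
    stop("sigma_in and sigma_out must not both be zero")
  (sigma_in - sigma_out) / (sigma_in + sigma_out)
}

#' Conductivity interface
#'
#' Pairs a closed oriented surface with the conductivities on its two sides.
#' Normals point from the `sigma_in` side to the `sigma_out` side (outward
#' for nested head compartments).
#'
#' @param surface a `triangle_surface`.
#' @param sigma_in,sigma_out conductivities (S/m).
#' @param name optional label.
#' @param sphere optional `list(center =, radius =)` marking an analytic
#'   sphere this mesh discretizes (enables projected refinement).
#' @return an `interface` object carrying the derived contrast `K`.
#' @export
interface <- function(surface, sigma_in, sigma_out, name = NULL,
                      sphere = NULL) {
  if (!inherits(surface, "triangle_surface")) stop("not a triangle_surface")
  structure(list(surface = surface, sigma_in = sigma_in,
                 sigma_out = sigma_out,
                 contrast = conductivity_contrast(sigma_in, sigma_out),
                 name = name, sphere = sphere),
            class = "interface")
}

#' Nested-compartment head model
#'
#' Stacks conductivity interfaces (outermost first) into one model with a
#' global facet indexing. Nesting is declared by the ordering, not inferred
#' geometrically.
#'
#' @param interfaces list of `interface` objects, outermost first.
#' @return a `head_model` with `facet_offsets` and `total_facets`.
#' @export
head_model <- function(interfaces) {
  if (inherits(interfaces, "interface")) interfaces <- list(interfaces)
  if (!length(interfaces) || !all(vapply(interfaces, inherits, TRUE,
                                         "interface")))
    stop("interfaces must be a non-empty list of interface objects")
  counts <- vapply(interfaces, function(i) nrow(i$surface$triangles), 1L)
  structure(list(interfaces = interfaces,
                 facet_offsets = c(0L, cumsum(counts))[seq_along(counts)],
                 total_facets = sum(counts)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("head_model:", length(x$interfaces), "interfaces,",
      x$total_facets, "facets\n")
  for (i in seq_along(x$interfaces)) {
    f <- x$interfaces[[i]]
    cat(sprintf("  [%d] %s: %d facets, sigma_in=%g sigma_out=%g K=%.4g\n",
                i, if (is.null(f$name)) "interface" else f$name,
                nrow(f$surface$triangles), f$sigma_in, f$sigma_out,
                f$contrast))
  }
  invisible(x)
}

# stacked per-facet geometry across all interfaces
model_geometry <- function(model) {
  surfs <- lapply(model$interfaces, `[[`, "surface")
  nvert <- vapply(surfs, function(s) nrow(s$vertices), 1L)
  voff <- c(0L, cumsum(nvert))[seq_along(surfs)]
  tris <- do.call(rbind, Map(function(s, o) s$triangles + o, surfs, voff))
  list(vertices = do.call(rbind, lapply(surfs, `[[`, "vertices")),
       triangles = tris,
       centroids = do.call(rbind, lapply(surfs, `[[`, "centroids")),
       normals = do.call(rbind, lapply(surfs, `[[`, "normals")),
       areas = unlist(lapply(surfs, `[[`, "areas"), use.names = FALSE),
       contrast = rep(vapply(model$interfaces, `[[`, 1, "contrast"),
                      vapply(surfs, function(s) nrow(s$triangles), 1L)))
}

#' Map global facet indices to (interface, local facet)
#'
#' @param model a `head_model`.
#' @param idx global facet indices (1-based).
#' @return data.frame with columns `interface`, `facet`.
#' @export
facet_location <- function(model, idx) {
  off <- model$facet_offsets
  if (any(idx < 1L | idx > model$total_facets))
    stop("global facet index out of range")
  iface <- findInterval(idx - 1L, off)
  data.frame(interface = iface, facet = as.integer(idx - off[iface]))
}

#' Validate a head model
#'
#' Reports per-interface closure defect, orientation (sign of the enclosed
#' volume), and conductivity consistency along the declared nesting (the
#' outside conductivity of an inner interface must equal the inside
#' conductivity of its enclosing one).
#'
#' @param model a `head_model`.
#' @param fatal raise an error on orientation or conductivity defects.
#' @return data.frame report, one row per interface, invisibly when `fatal`.
#' @export
validate_model <- function(model, fatal = TRUE) {
  n <- length(model$interfaces)
  rep_ <- data.frame(interface = seq_len(n),
                     name = vapply(model$interfaces, function(i)
                       if (is.null(i$name)) "" else i$name, ""),
                     facets = vapply(model$interfaces, function(i)
                       nrow(i$surface$triangles), 1L),
                     closure = NA_real_, volume = NA_real_,
                     outward = NA, sigma_ok = NA)
  for (i in seq_len(n)) {
    f <- model$interfaces[[i]]
    rep_$closure[i] <- closure_defect(f$surface)
    rep_$volume[i] <- signed_volume(f$surface)
    rep_$outward[i] <- rep_$volume[i] > 0
    rep_$sigma_ok[i] <- if (i == 1L) TRUE else
      isTRUE(all.equal(f$sigma_out, model$interfaces[[i - 1L]]$sigma_in))
  }
  problems <- character(0)
  if (any(!rep_$outward))
    problems <- c(problems, paste("inward-oriented interface(s):",
                                  paste(which(!rep_$outward), collapse = ", ")))
  if (any(!rep_$sigma_ok))
    problems <- c(problems,
                  paste("conductivity mismatch along nesting at interface(s):",
                        paste(which(!rep_$sigma_ok), collapse = ", ")))
  big <- rep_$closure > 1e-10
  if (any(big))
    problems <- c(problems, paste("closure defect above 1e-10 at:",
                                  paste(which(big), collapse = ", ")))
  attr(rep_, "problems") <- problems
  if (fatal && length(problems)) stop(paste(problems, collapse = "; "))
  if (fatal) invisible(rep_) else rep_
}

#' Model fingerprint
#'
#' Deterministic 64-bit hash over all vertex coordinates, triangle indices
#' and conductivities; binds a factorization to the model it was built from.
#'
#' @param model a `head_model`.
#' @return hex string.
#' @export
model_fingerprint <- function(model) {
  g <- model_geometry(model)
  sig <- unlist(lapply(model$interfaces,
                       function(i) c(i$sigma_in, i$sigma_out)))
  .fnv1a_cpp(c(as.numeric(g$vertices), as.numeric(g$triangles), sig))
}

#' Read a model description file
#'
#' JSON with fields `units` ("m" or "mm") and `interfaces`: an ordered array
#' (outermost first) of `{stl_path, sigma_in, sigma_out, name}`. Relative STL
#' paths are resolved against the JSON file's directory.
#'
#' @param path JSON model file.
#' @return a `head_model`.
#' @export
read_model <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("units", "interfaces")
  if (length(setdiff(names(spec), known)))
    stop("unknown model file keys: ",
         paste(setdiff(names(spec), known), collapse = ", "))
  units <- if (is.null(spec$units)) "m" else spec$units
  dir <- dirname(path)
  ifs <- lapply(spec$interfaces, function(e) {
    p <- e$stl_path
    if (!file.exists(p)) p <- file.path(dir, e$stl_path)
    interface(read_stl(p, units = units), e$sigma_in, e$sigma_out,
              name = e$name)
  })
  head_model(ifs)
}

#' Write a model (STL files plus JSON description)
#'
#' @param model a `head_model`.
#' @param dir output directory (created if absent).
#' @param stem file-name stem for the STL files.
#' @return path of the JSON description file.
#' @export
write_model <- function(model, dir, stem = "interface") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(model$interfaces), function(i) {
    f <- model$interfaces[[i]]
    fn <- sprintf("%s_%02d.stl", stem, i)
    write_stl(f$surface, file.path(dir, fn))
    list(stl_path = fn, sigma_in = f$sigma_in, sigma_out = f$sigma_out,
         name = if (is.null(f$name)) sprintf("interface_%02d", i) else f$name)
  })
  out <- file.path(dir, paste0(stem, "_model.json"))
  jsonlite::write_json(list(units = "m", interfaces = entries), out,
                       auto_unbox = TRUE, digits = NA)
  out
}
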