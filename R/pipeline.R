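#' Run the full field-mapping pipeline from a config
#'
#' Three stages per coil pose: (I) primary coil field and right-hand side
#' assembly, (II) solve for the surface charges - iteratively, or via one
#' shared LU factorization across all poses - and (III) total-field
#' evaluation at the observation points. Writes one field TSV per pose, an
#' optional error report against a reference field file, and a provenance
#' JSON from which every output is reconstructible.
#'
#' Config (JSON file or an equivalent named list): `model` (model JSON
#' path), `coil` (coil file path), `poses` (optional array of
#' `{rotation: 9 numbers row-major, translation: 3}`; default identity),
#' `didt` (optional drive-rate override, A/s), `solver` ("iterative" |
#' "direct" | "auto": direct when poses > 3), `tol`, `near_threshold`,
#' `observation_points` (x y z text file; default the outermost-interface
#' centroids is not assumed - the key is required), `roi` (optional
#' `{center, diameter}`), `reference` (optional field TSV), `output_dir`,
#' `seed` (recorded; the solve path is deterministic). Unknown keys are
#' rejected.
#'
#' @param config path to a JSON config or a named list.
#' @return invisibly, list with per-pose field file paths, error reports,
#'   and the provenance path.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config))
    jsonlite::fromJSON(config, simplifyVector = FALSE) else config
  known <- c("model", "coil", "poses", "didt", "solver", "tol",
             "near_threshold", "observation_points", "roi", "reference",
             "output_dir", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  need <- c("model", "coil", "observation_points", "output_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing config keys: ", paste(miss, collapse = ", "))

  stage <- "config"
  out <- tryCatch({
    stage <- "model input"
    model <- read_model(cfg$model)
    validate_model(model)
    base_coil <- read_coil_file(cfg$coil)
    if (!is.null(cfg$didt))
      base_coil <- coil(base_coil$positions, base_coil$moments,
                        didt = cfg$didt)
    points <- read_points(cfg$observation_points)
    poses <- cfg$poses
    if (is.null(poses))
      poses <- list(list(rotation = as.numeric(diag(3)),
                         translation = c(0, 0, 0)))
    coils <- lapply(poses, function(p) {
      R <- matrix(unlist(p$rotation), 3, 3, byrow = TRUE)
      transform_coil(base_coil, R, unlist(p$translation))
    })
    solver <- if (is.null(cfg$solver)) "auto" else cfg$solver
    if (solver == "auto")
      solver <- if (length(coils) > 3L) "direct" else "iterative"
    tol <- if (is.null(cfg$tol)) 1e-6 else cfg$tol
    nthr <- if (is.null(cfg$near_threshold)) 5 else cfg$near_threshold
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "I: primary field / RHS assembly"
    op <- assemble_operator(model, near_threshold = nthr,
                            mode = if (solver == "direct") "dense"
                                   else if (model$total_facets <= 6000L)
                                     "dense" else "matrix-free")
    bs <- lapply(coils, function(cl) assemble_rhs(op, cl))

    stage <- "II: solve"
    sols <- if (solver == "direct") {
      fact <- factorize(op)
      solve_direct(fact, bs, op = op)
    } else {
      lapply(bs, function(b) solve_iterative(op, b, tol = tol))
    }

    stage <- "III: field evaluation"
    files <- character(length(sols))
    reports <- vector("list", length(sols))
    for (i in seq_along(sols)) {
      f <- field_off_surface(model, sols[[i]], coils[[i]], points,
                             near_threshold = nthr)
      files[i] <- file.path(cfg$output_dir, sprintf("field_pose%02d.tsv", i))
      write_field_tsv(f, files[i])
      if (!is.null(cfg$reference)) {
        ref <- read_field_tsv(cfg$reference)
        roi <- if (!is.null(cfg$roi))
          roi_select(points, unlist(cfg$roi$center), cfg$roi$diameter)
        reports[[i]] <- error_report(f$e_total, ref$e, roi = roi,
                                     roi_tag = if (is.null(cfg$roi))
                                       "all points" else "roi")
      }
    }

    prov <- list(
      config = cfg,
      model_fingerprint = model_fingerprint(model),
      solver = solver,
      solver_report = lapply(sols, function(s)
        list(tag = s$solver_tag, iterations = s$iterations,
             residual = s$residual)),
      factorization_builds_session = factorization_builds(),
      field_files = basename(files),
      field_md5 = unname(tools::md5sum(files)))
    provpath <- file.path(cfg$output_dir, "provenance.json")
    jsonlite::write_json(prov, provpath, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    if (!is.null(cfg$reference)) {
      jsonlite::write_json(reports,
                           file.path(cfg$output_dir, "error_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(field_files = files, reports = reports, provenance = provpath)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out)
}

#' Command-line interface
#'
#' Subcommand dispatcher used by the `inst/cli/tmsbem.R` Rscript wrapper:
#' `make-sphere`, `make-coil`, `factorize`, `solve`, `evaluate`, `compare`,
#' `run`. Call with a character vector of arguments, e.g.
#' `tmsbem_cli(c("make-sphere", "--radii", "0.09,0.085,0.08", ...))`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
tmsbem_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tmsbem <command> [options]",
    "commands:",
    "  make-sphere --radii r1,r2,.. --sigma s1,s2,.. --subdiv k --out DIR",
    "  make-coil   --radius r --separation d --segments n --didt x",
    "              --height z --out FILE",
    "  factorize   --model model.json [--near-threshold t] --out FILE",
    "  solve       --model model.json --coil coil.txt",
    "              [--factorization F] [--tol t] --points P.txt --out DIR",
    "  evaluate    --model model.json --coil coil.txt --rho rho.txt",
    "              --points P.txt --out FILE",
    "  compare     A.tsv B.tsv [--roi-center x,y,z --roi-diameter d]",
    "  run         --config config.json",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  getd <- function(name, default = NULL) {
    if (!is.null(opts$named[[name]])) opts$named[[name]] else default
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ",")[[1]])
  switch(cmd,
    "make-sphere" = {
      radii <- num(getd("radii", "0.09,0.085,0.08"))
      sigma <- num(getd("sigma", "0.33,0.01,0.33"))
      layers <- getd("layers")
      if (!is.null(layers)) {
        k <- as.integer(layers)
        radii <- radii[seq_len(k)]
        sigma <- sigma[seq_len(k)]
      }
      sm <- make_sphere_model(radii, sigma,
                              subdivisions = as.integer(getd("subdiv", "3")))
      out <- getd("out", "sphere_model")
      p <- write_model(sm$model, out, stem = "sphere")
      write_points(sm$probes, file.path(out, "probes.txt"))
      message("wrote ", p)
    },
    "make-coil" = {
      cl <- make_figure8(radius = as.numeric(getd("radius", "0.035")),
                         separation = as.numeric(getd("separation", "0.07")),
                         segments_per_turn = as.integer(getd("segments", "64")),
                         didt = as.numeric(getd("didt", "1")),
                         height = as.numeric(getd("height", "0")))
      write_coil_file(cl, getd("out", "coil.txt"))
      message("wrote ", getd("out", "coil.txt"))
    },
    "factorize" = {
      model <- read_model(getd("model"))
      op <- assemble_operator(model,
        near_threshold = as.numeric(getd("near-threshold", "5")))
      save_factorization(factorize(op), getd("out", "factorization.rds"))
      message("wrote ", getd("out", "factorization.rds"))
    },
    "solve" = {
      model <- read_model(getd("model"))
      cl <- read_coil_file(getd("coil"))
      factf <- getd("factorization")
      fit <- if (!is.null(factf)) {
        tms_fit(model, cl, factorization = load_factorization(factf))
      } else {
        tms_fit(model, cl, tol = as.numeric(getd("tol", "1e-6")))
      }
      dir.create(getd("out", "."), showWarnings = FALSE, recursive = TRUE)
      pts <- read_points(getd("points"))
      f <- predict(fit, points = pts)
      write_field_tsv(f, file.path(getd("out", "."), "field.tsv"))
      utils::write.table(format(coef(fit), digits = 17),
                         file.path(getd("out", "."), "rho.txt"),
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      message("wrote ", file.path(getd("out", "."), "field.tsv"))
    },
    "evaluate" = {
      model <- read_model(getd("model"))
      cl <- read_coil_file(getd("coil"))
      rho <- as.numeric(readLines(getd("rho")))
      sol <- charge_solution(rho, residual = NA_real_, tag = "loaded")
      f <- field_off_surface(model, sol, cl, read_points(getd("points")))
      write_field_tsv(f, getd("out", "field.tsv"))
      message("wrote ", getd("out", "field.tsv"))
    },
    "compare" = {
      if (length(opts$positional) < 2L) stop("compare needs two field files")
      a <- read_field_tsv(opts$positional[1])
      b <- read_field_tsv(opts$positional[2])
      roi <- NULL
      if (!is.null(opts$named[["roi-center"]]))
        roi <- roi_select(a$points, num(opts$named[["roi-center"]]),
                          as.numeric(getd("roi-diameter", "0.04")))
      rep_ <- error_report(a$e, b$e, roi = roi,
                           roi_tag = if (is.null(roi)) "all points" else "roi")
      cat(jsonlite::toJSON(rep_, auto_unbox = TRUE, digits = NA), "\n")
    },
    "run" = {
      run_pipeline(getd("config"))
      message("pipeline complete")
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}

parse_cli_opts <- function(args) {
  named <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        named[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        named[[key]] <- "TRUE"
        i <- i + 1L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(named = named, positional = positional)
}
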