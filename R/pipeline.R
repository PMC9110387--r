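# Pipeline driver and the `combscan` command-line entry point.
#
# The pipeline runs the analysis stages in dependency order on a single
# input volume (or a generated phantom) and records a manifest of every
# artifact with its content hash, so identical configurations always
# reproduce identical outputs.

pipeline_stages <- c("convert", "sdf", "mesh", "curvature", "geodesics",
                     "segment", "skeleton", "cells", "materials",
                     "buildorder")

stage_deps <- list(
  convert = character(0), sdf = "convert", mesh = "sdf",
  curvature = "mesh", geodesics = "sdf", segment = "mesh",
  skeleton = "mesh", cells = "sdf", materials = "convert",
  buildorder = c("skeleton", "geodesics", "cells"))

#' Run the comb analysis pipeline
#'
#' Executes the requested stages in dependency order on an input volume
#' (NRRD path or [density_volume]), or on a freshly generated default
#' phantom when no input is given. Stage parameters mirror the defaults
#' of the underlying functions.
#'
#' @param config a list: `input` (path or density_volume; NULL for the
#'   default phantom), `stages` (subset of
#'   convert/sdf/mesh/curvature/geodesics/segment/skeleton/cells/
#'   materials/buildorder), `out_dir`, `iso_threshold`,
#'   `curvature_radius_mm`, `n_segments`, `n_contours`,
#'   `closure_radius_mm`, `downsample_factor`, `seed`.
#' @return A list: `manifest` (data frame of stage, path, md5) and
#'   `results` (the in-memory stage outputs).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    input = NULL, stages = pipeline_stages, out_dir = tempfile("combscan_"),
    iso_threshold = 0.2, curvature_radius_mm = 6, n_segments = 2,
    n_contours = 15, closure_radius_mm = 10, downsample_factor = 1,
    seed = 1), config)
  stages <- cfg$stages
  for (s in stages) {
    missing <- setdiff(stage_deps[[s]], stages)
    if (length(missing))
      stopf("stage '%s' requires missing stage(s): %s", s,
            paste(missing, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- data.frame(stage = character(0), path = character(0),
                         md5 = character(0))
  emit <- function(stage, name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, path = path,
                                  md5 = unname(tools::md5sum(path))))
  }

  for (stage in intersect(pipeline_stages, stages)) {
    if (stage == "convert") {
      vol <- if (is.null(cfg$input)) {
        generate_phantom(comb_phantom_spec(rng_seed = cfg$seed))$volume
      } else if (is_density_volume(cfg$input)) cfg$input
      else load_volume(cfg$input, format = "nrrd")
      if (cfg$downsample_factor > 1)
        vol <- downsample(vol, cfg$downsample_factor)
      res$volume <- vol
      emit("convert", "volume.nrrd", function(p) write_nrrd(vol, p))
    } else if (stage == "sdf") {
      res$sdf <- to_sdf(res$volume, cfg$iso_threshold)
      emit("sdf", "sdf.nrrd", function(p) write_nrrd(res$sdf, p))
    } else if (stage == "mesh") {
      res$mesh <- extract_mesh(res$sdf)
      emit("mesh", "comb.ply", function(p) write_ply(res$mesh, p))
    } else if (stage == "curvature") {
      res$curvature <- compute_curvature_field(res$mesh,
                                               cfg$curvature_radius_mm)
      emit("curvature", "curvature_hist.csv", function(p)
        utils::write.csv(curvature_histogram(res$curvature, "kappa1"),
                         p, row.names = FALSE))
      emit("curvature", "comb_curv.ply", function(p)
        write_ply(res$curvature$mesh, p))
    } else if (stage == "geodesics") {
      src <- res$volume$values >= 0.55  # substrate band of the phantom
      if (!any(src)) {
        # fall back to the topmost grid slab that holds solid material
        solid <- res$sdf$distances < 0
        ktop <- max(which(apply(solid, 3, any)))
        src <- solid & slice_mask(res$sdf$dims, 3, ktop)
      }
      res$geodesic <- solve_eikonal(res$sdf, src, metric = 1)
      emit("geodesics", "u.nrrd", function(p)
        write_nrrd(res$geodesic$u, p, spacing_mm = res$sdf$spacing_mm,
                   origin_mm = res$sdf$origin_mm))
    } else if (stage == "segment") {
      # clustered meshes are generally non-manifold: use the graph kind
      res$basis <- eigenbasis(
        build_laplacian(decimate_for_spectral(res$mesh), "graph"),
        k = max(6, cfg$n_segments + 1))
      res$segments <- fiedler_segment(res$basis, cfg$n_segments)
      emit("segment", "labels.csv", function(p)
        utils::write.csv(data.frame(vertex_id = seq_along(res$segments$labels),
                                    label = res$segments$labels),
                         p, row.names = FALSE))
    } else if (stage == "skeleton") {
      if (is.null(res$basis))
        res$basis <- eigenbasis(
          build_laplacian(decimate_for_spectral(res$mesh), "graph"), k = 6)
      res$skeleton <- suppressWarnings(curve_skeleton(res$basis,
                                                      cfg$n_contours))
      emit("skeleton", "skeleton.json", function(p)
        writeLines(jsonlite::toJSON(list(nodes = res$skeleton$nodes,
                                         edges = res$skeleton$edges,
                                         tangents = res$skeleton$tangents),
                                    digits = NA), p))
    } else if (stage == "cells") {
      res$cells <- cell_frames(extract_cells(res$sdf,
                                             cfg$closure_radius_mm))
      res$plane <- median_plane(res$cells)
      res$cells <- cell_frames(res$cells, res$plane)
      emit("cells", "cells.csv", function(p)
        utils::write.csv(cell_metrics(res$cells, res$plane), p,
                         row.names = FALSE))
      tg <- try(tilt_and_gravity(res$cells, res$plane), silent = TRUE)
      if (!inherits(tg, "try-error"))
        emit("cells", "gravity.json", function(p)
          writeLines(jsonlite::toJSON(list(gravity = tg$gravity,
                                           mean_tilt_deg = tg$mean_tilt_deg),
                                      digits = NA), p))
    } else if (stage == "materials") {
      cal <- calibrate(data.frame(value = c(0.465, 0.7),
                                  density = c(0.93, 1.4),
                                  label = c("wax", "honey")))
      bands <- list(material_band("wax", 0.85, 1.0),
                    material_band("substrate", 1.1, 1.3),
                    material_band("honey", 1.3, 1.5))
      sb <- segment_bands(res$volume, cal, bands)
      res$materials <- sb
      emit("materials", "volumes.csv", function(p)
        utils::write.csv(sb$table, p, row.names = FALSE))
    } else if (stage == "buildorder") {
      res$timeline <- reconstruct_build_order(res$skeleton, res$geodesic,
                                              res$cells)
      emit("buildorder", "timeline.json", function(p)
        writeLines(timeline_report(res$timeline)$json, p))
    }
  }
  list(manifest = manifest, results = res)
}

slice_mask <- function(dims, axis, index) {
  m <- array(FALSE, dim = dims)
  idx <- lapply(dims, seq_len)
  idx[[axis]] <- index
  do.call(`[<-`, c(list(m), idx, list(TRUE)))
}

# spectral analysis is dense; cap the mesh size by voxel-grid vertex
# clustering (collapse vertices sharing a coarse grid cell)
decimate_for_spectral <- function(mesh, target_vertices = 1200) {
  nv <- nrow(mesh$vertices)
  if (nv <= target_vertices) return(mesh)
  bb <- apply(mesh$vertices, 2, range)
  vol <- prod(pmax(bb[2, ] - bb[1, ], 1e-6))
  cell <- (vol / target_vertices)^(1 / 3)
  repeat {
    key <- floor(sweep(mesh$vertices, 2, bb[1, ]) / cell)
    id <- paste(key[, 1], key[, 2], key[, 3])
    fid <- match(id, unique(id))
    if (max(fid) <= target_vertices * 1.5 || cell > max(bb[2, ] - bb[1, ]))
      break
    cell <- cell * 1.3
  }
  nvx <- max(fid)
  V <- matrix(0, nvx, 3)
  for (c in 1:3) V[, c] <- as.vector(tapply(mesh$vertices[, c], fid, mean))
  T <- matrix(fid[mesh$triangles], ncol = 3)
  keep <- T[, 1] != T[, 2] & T[, 2] != T[, 3] & T[, 1] != T[, 3]
  T <- T[keep, , drop = FALSE]
  # drop duplicate faces
  fk <- apply(T, 1, function(r) paste(sort(r), collapse = "-"))
  T <- T[!duplicated(fk), , drop = FALSE]
  # connectivity comes from the full edge set (collapsed triangles must
  # not disconnect the cluster graph), restricted to the largest
  # component
  E <- matrix(fid[mesh$edges], ncol = 2)
  E <- E[E[, 1] != E[, 2], , drop = FALSE]
  E <- unique(cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2])))
  dm <- surface_mesh(V, T, edges = E)
  comp <- mesh_components(dm)
  main <- which.max(tabulate(comp))
  if (any(comp != main)) {
    keepv <- which(comp == main)
    remap <- integer(nvx)
    remap[keepv] <- seq_along(keepv)
    T <- T[comp[T[, 1]] == main, , drop = FALSE]
    E <- E[comp[E[, 1]] == main & comp[E[, 2]] == main, , drop = FALSE]
    dm <- surface_mesh(V[keepv, , drop = FALSE],
                       matrix(remap[T], ncol = 3),
                       edges = matrix(remap[E], ncol = 2))
  }
  dm
}

#' Command-line entry point
#'
#' Implements the `combscan` subcommands (`synth`, `convert`, `mesh`,
#' `morph`, `curvature`, `geodesic`, `segment`, `skeleton`, `cells`,
#' `materials`, `buildorder`, `run`) as a thin wrapper over the package
#' functions. Invoked by the `inst/cli/combscan` script.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return Exit status, invisibly.
#' @export
combscan_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: combscan <synth|convert|mesh|morph|curvature|geodesic|",
        "segment|skeleton|cells|materials|buildorder|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  get_opt <- function(name, default = NULL, numeric = FALSE) {
    v <- opts[[name]] %||% default
    if (numeric && !is.null(v)) as.numeric(v) else v
  }
  load_in <- function() load_volume(get_opt("in"), format = "nrrd")
  switch(cmd,
    synth = {
      spec_args <- if (!is.null(get_opt("spec")))
        jsonlite::fromJSON(get_opt("spec")) else list()
      spec_args$rng_seed <- as.integer(get_opt("seed", 1))
      ph <- generate_phantom(do.call(comb_phantom_spec, spec_args))
      write_nrrd(ph$volume, get_opt("out", "phantom.nrrd"))
      if (!is.null(get_opt("truth")))
        writeLines(jsonlite::toJSON(ph$truth[c("n_cells", "tilt_deg",
                                               "honey_mm3",
                                               "material_voxels")],
                                    digits = NA, auto_unbox = TRUE),
                   get_opt("truth"))
    },
    convert = {
      vol <- load_volume(get_opt("in"), format = get_opt("format",
                                                         "tiff_stack"),
                         normalize = TRUE,
                         spacing_mm = get_opt("spacing-mm", 0.1,
                                              numeric = TRUE))
      write_nrrd(vol, get_opt("out", "vol.nrrd"))
    },
    mesh = {
      sdf <- to_sdf(load_in(), get_opt("iso", 0.5, numeric = TRUE))
      write_ply(extract_mesh(sdf), get_opt("out", "comb.ply"))
    },
    morph = {
      sdf <- to_sdf_passthrough(get_opt("in"))
      r <- structuring_ball(get_opt("radius-mm", 1, numeric = TRUE))
      out <- switch(get_opt("op", "close"),
                    dilate = sdf_dilate(sdf, r), erode = sdf_erode(sdf, r),
                    close = sdf_close(sdf, r), open = sdf_open(sdf, r))
      write_nrrd(out, get_opt("out", "morph.nrrd"))
    },
    curvature = {
      vol <- load_in()
      mesh <- extract_mesh(to_sdf(vol, get_opt("iso", 0.5,
                                               numeric = TRUE)))
      cf <- compute_curvature_field(mesh, get_opt("radius-mm", 15,
                                                  numeric = TRUE))
      write_ply(cf$mesh, get_opt("out", "comb_curv.ply"))
      if (!is.null(get_opt("hist")))
        utils::write.csv(curvature_histogram(cf, "kappa1"),
                         get_opt("hist"), row.names = FALSE)
    },
    geodesic = {
      vol <- load_in()
      srcvol <- read_nrrd_raw(get_opt("source"))
      field <- solve_eikonal(vol, srcvol$values > 0,
                             metric = get_opt("metric", "density"))
      write_nrrd(field$u, get_opt("out", "u.nrrd"),
                 spacing_mm = vol$spacing_mm, origin_mm = vol$origin_mm)
    },
    segment = {
      mesh <- extract_mesh(to_sdf(load_in(), get_opt("iso", 0.5,
                                                     numeric = TRUE)))
      basis <- eigenbasis(build_laplacian(decimate_for_spectral(mesh)),
                          k = 6)
      seg <- fiedler_segment(basis, as.integer(get_opt("segments", 4)))
      utils::write.csv(data.frame(vertex_id = seq_along(seg$labels),
                                  label = seg$labels),
                       get_opt("out", "labels.csv"), row.names = FALSE)
    },
    skeleton = {
      mesh <- extract_mesh(to_sdf(load_in(), get_opt("iso", 0.5,
                                                     numeric = TRUE)))
      basis <- eigenbasis(build_laplacian(decimate_for_spectral(mesh)),
                          k = 6)
      sk <- suppressWarnings(
        curve_skeleton(basis, as.integer(get_opt("contours", 25))))
      writeLines(jsonlite::toJSON(list(nodes = sk$nodes, edges = sk$edges,
                                       tangents = sk$tangents),
                                  digits = NA),
                 get_opt("out", "skeleton.json"))
    },
    cells = {
      sdf <- to_sdf_passthrough(get_opt("in"))
      cs <- cell_frames(extract_cells(sdf, get_opt("closure-mm", 10,
                                                   numeric = TRUE)))
      plane <- median_plane(cs)
      cs <- cell_frames(cs, plane)
      if (!is.null(get_opt("out")))
        write_nrrd(cs$labels, get_opt("out"), type = "uint16",
                   spacing_mm = cs$spacing_mm, origin_mm = cs$origin_mm)
      if (!is.null(get_opt("metrics")))
        utils::write.csv(cell_metrics(cs, plane), get_opt("metrics"),
                         row.names = FALSE)
      if (!is.null(get_opt("gravity"))) {
        tg <- tilt_and_gravity(cs, plane)
        writeLines(jsonlite::toJSON(list(gravity = tg$gravity,
                                         mean_tilt_deg = tg$mean_tilt_deg),
                                    digits = NA), get_opt("gravity"))
      }
    },
    materials = {
      vol <- load_in()
      cal_df <- jsonlite::fromJSON(get_opt("calib"))
      bands_df <- jsonlite::fromJSON(get_opt("bands"))
      cal <- calibrate(cal_df)
      bands <- lapply(seq_len(nrow(bands_df)), function(i)
        material_band(bands_df$label[i], bands_df$lo[i], bands_df$hi[i]))
      sb <- segment_bands(vol, cal, bands)
      if (!is.null(get_opt("out")))
        write_nrrd(sb$labels, get_opt("out"), type = "uint16",
                   spacing_mm = vol$spacing_mm, origin_mm = vol$origin_mm)
      utils::write.csv(sb$table, get_opt("report", "volumes.csv"),
                       row.names = FALSE)
    },
    run = {
      cfg <- if (!is.null(get_opt("config")))
        jsonlite::fromJSON(get_opt("config")) else list()
      if (!is.null(get_opt("in"))) cfg$input <- get_opt("in")
      if (!is.null(get_opt("out"))) cfg$out_dir <- get_opt("out")
      pr <- run_pipeline(cfg)
      utils::write.csv(pr$manifest,
                       file.path(dirname(pr$manifest$path[1]),
                                 "manifest.csv"),
                       row.names = FALSE)
      print(pr$manifest)
    },
    stopf("unknown subcommand '%s'", cmd))
  invisible(0L)
}

# treat an NRRD file on disk as an SDF
to_sdf_passthrough <- function(path) {
  raw <- read_nrrd_raw(path)
  signed_distance_volume(raw$values, raw$spacing, raw$origin)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        opts[[key]] <- TRUE
        i <- i + 1
      }
    } else i <- i + 1
  }
  opts
}
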