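# End-to-end orchestration: phantom -> segment -> design -> slice -> place ->
# gauge -> conform, with a validated config, per-stage artifacts, checksums
# and stage-level resume.

pipeline_schema <- list(
  output_dir = "character", seed = "numeric",
  phantom = list(crater_shape = "character", crater_depth = "numeric",
                 crater_extent = "numeric", limb_radius = "numeric",
                 limb_length = "numeric", spacing = "numeric",
                 noise_sd = "numeric", tissue_value = "numeric",
                 air_value = "numeric"),
  design = list(thickness = "numeric", smooth_window = "numeric",
                margin = "numeric", threshold_mode = "character",
                threshold_value = "numeric"),
  slice = list(layer_height = "numeric", speed = "numeric",
               perimeters = "numeric", top_bottom_layers = "numeric",
               infill_density = "numeric", infill_angle = "numeric",
               extrusion_width = "numeric", flow = "numeric",
               infill_overlap = "numeric", connect_infill = "logical"),
  gauge = list(samples = "numeric", bin_width = "numeric",
               perturb_angle_deg = "numeric", perturb_mm = "numeric"),
  conform = list(min_void = "numeric", air_threshold = "numeric",
                 crop_margin = "numeric"))

validate_config <- function(config) {
  bad <- character(0)
  for (k in names(config)) {
    if (!k %in% names(pipeline_schema)) { bad <- c(bad, k); next }
    if (is.list(pipeline_schema[[k]]) && is.list(config[[k]])) {
      for (k2 in names(config[[k]]))
        if (!k2 %in% names(pipeline_schema[[k]]))
          bad <- c(bad, paste(k, k2, sep = "."))
    }
  }
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Default demo configuration for [run_pipeline()]
#'
#' A desk-scale hemisphere wound phantom (0.7 mm voxels) with the study's
#' print settings; see the methods vignette for the choice of sizes.
#' @export
default_config <- function() {
  list(seed = 1,
       phantom = list(crater_shape = "hemisphere", crater_depth = 15,
                      limb_radius = 25, limb_length = 60, spacing = 0.7,
                      noise_sd = 0),
       design = list(thickness = 4, smooth_window = 3, margin = 0),
       slice = list(layer_height = 0.16, speed = 20, perimeters = 2,
                    top_bottom_layers = 2, infill_density = 0.4,
                    extrusion_width = 0.4, flow = 1, infill_overlap = 0.5,
                    connect_infill = TRUE),
       gauge = list(samples = 20000, bin_width = 0.1),
       conform = list(min_void = 0.001, air_threshold = -500,
                      crop_margin = NULL))
}

stage_log <- function(stage, t0, msg = "done") {
  message(sprintf("[%s] %s (%.1f s)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full wound-patch pipeline
#'
#' Generates (or loads) the wound volume, segments it, designs the patch,
#' slices it to G-code, voxelizes the patch back in place (the in-silico
#' "implanted print"), gauges the placed patch against the design, and runs
#' the conformality/void analysis. Every artifact lands in \code{output_dir};
#' \code{manifest.json} records parameters, seeds and per-file MD5 checksums.
#' Stages whose outputs already exist are skipped (delete a file to recompute
#' that stage).
#'
#' @param config a config list (see [default_config()]), or the path of a
#'   YAML file with the same structure. Unknown keys raise a config error.
#' @param output_dir destination directory (overrides the config entry).
#' @param force rerun all stages even if outputs exist.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  config <- modifyList(default_config(), config)
  if (is.null(output_dir)) output_dir <- config$output_dir
  if (is.null(output_dir)) stop("no output_dir given")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(output_dir, f)
  seed <- as.integer(config$seed)

  # --- stage: phantom -------------------------------------------------------
  if (force || !file.exists(pth("wound.nrrd"))) {
    t0 <- as.numeric(Sys.time())
    ph <- config$phantom
    spec <- wound_phantom_spec(
      limb_radius = ph$limb_radius %||% 25,
      limb_length = ph$limb_length %||% 60,
      crater_shape = ph$crater_shape %||% "hemisphere",
      crater_depth = ph$crater_depth %||% 15,
      crater_extent = ph$crater_extent %||% c(30, 30),
      tissue_value = ph$tissue_value %||% 40,
      air_value = ph$air_value %||% -1000,
      noise_sd = ph$noise_sd %||% 0,
      spacing = ph$spacing %||% 0.7,
      seed = seed)
    phantom <- make_limb_wound_phantom(spec)
    write_volume(phantom$volume, pth("wound.nrrd"))
    write_stl(phantom$surface, pth("wound_surface_truth.stl"))
    saveRDS(phantom[c("geometry", "spec")], pth("phantom_meta.rds"))
    stage_log("phantom", t0)
  }
  phantom_meta <- readRDS(pth("phantom_meta.rds"))
  roi <- crater_roi(phantom_meta)

  # --- stage: design --------------------------------------------------------
  if (force || !file.exists(pth("patch.stl"))) {
    t0 <- as.numeric(Sys.time())
    vol <- read_volume(pth("wound.nrrd"))
    de <- config$design
    params <- shell_params(thickness = de$thickness %||% 4,
                           smooth_window = de$smooth_window %||% 3,
                           margin = de$margin %||% 0)
    design <- design_patch(vol, roi, params,
                           mode = de$threshold_mode %||% "otsu",
                           value = de$threshold_value)
    write_stl(design$mesh, pth("patch.stl"))
    write_volume(design$shell, pth("shell_mask.nrrd"))
    write_volume(design$segmentation$tissue, pth("tissue_mask.nrrd"))
    stage_log("design", t0)
  }

  # --- stage: slice ---------------------------------------------------------
  if (force || !file.exists(pth("patch.gcode"))) {
    t0 <- as.numeric(Sys.time())
    sl <- config$slice
    settings <- print_settings(
      layer_height = sl$layer_height %||% 0.16,
      speed = sl$speed %||% 20,
      perimeters = sl$perimeters %||% 2,
      top_bottom_layers = sl$top_bottom_layers %||% 2,
      infill_density = sl$infill_density %||% 0.4,
      infill_angle = sl$infill_angle,
      extrusion_width = sl$extrusion_width %||% 0.4,
      flow = sl$flow %||% 1,
      infill_overlap = sl$infill_overlap %||% 0.5,
      connect_infill = sl$connect_infill %||% TRUE)
    mesh <- read_stl(pth("patch.stl"))
    tp <- make_toolpath(mesh, settings)
    plan <- plan_gcode(tp)
    write_gcode(plan$program, pth("patch.gcode"))
    jsonlite::write_json(plan$estimate, pth("print_estimate.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("slice", t0)
  }

  # --- stage: place + gauge -------------------------------------------------
  if (force || !file.exists(pth("gauge.json"))) {
    t0 <- as.numeric(Sys.time())
    ga <- config$gauge
    vol <- read_volume(pth("wound.nrrd"))
    mesh <- read_stl(pth("patch.stl"))
    offset <- NULL
    if (!is.null(ga$perturb_angle_deg) || !is.null(ga$perturb_mm)) {
      ctr <- mesh_centroid(mesh)
      offset <- rigid_rotation(ga$perturb_angle_deg %||% 0,
                               axis = c(0, 0, 1), center = ctr,
                               translation = c(ga$perturb_mm %||% 0, 0, 0))
    }
    placed <- make_placed_patch_phantom(
      vol, mesh, placed_patch_spec(placement_offset = offset),
      air_threshold = config$conform$air_threshold %||% -500)
    write_volume(placed$volume, pth("implanted.nrrd"))
    write_volume(placed$patch_mask, pth("patch_mask.nrrd"))
    printed_mesh <- mask_to_mesh(placed$patch_mask)
    rep <- gauge_meshes(printed_mesh, mesh,
                        samples = as.integer(ga$samples %||% 20000),
                        seed = seed, bin_width = ga$bin_width %||% 0.1)
    out <- list(mean_abs_mm = rep$mean_abs, max_mm = rep$max, n = rep$n,
                seed = seed, converged = rep$transform$converged)
    jsonlite::write_json(out, pth("gauge.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(rep$histogram, pth("gauge_histogram.csv"),
                     row.names = FALSE)
    stage_log("gauge", t0)
  }

  # --- stage: conform -------------------------------------------------------
  if (force || !file.exists(pth("conform.json"))) {
    t0 <- as.numeric(Sys.time())
    co <- config$conform
    placed_vol <- read_volume(pth("implanted.nrrd"))
    patch_mask_v <- read_volume(pth("patch_mask.nrrd"))
    tissue_v <- read_volume(pth("tissue_mask.nrrd"))
    patch_mask <- mask_like(patch_mask_v, patch_mask_v$data > 0.5, "patch")
    tissue <- mask_like(tissue_v, tissue_v$data > 0.5, "tissue")
    voids <- detect_voids(placed_vol, tissue, patch_mask,
                          min_void = co$min_void %||% 0.001,
                          air_threshold = co$air_threshold %||% -500)
    patch_mesh <- mask_to_mesh(patch_mask)
    wound_mesh <- mask_to_mesh(tissue)
    cm <- co$crop_margin %||% (2 * placed_vol$spacing[1])
    rep <- contact_percentage(patch_mesh, wound_mesh, footprint = patch_mask,
                              crop_margin = cm, void_set = voids)
    out <- list(contact_percent = rep$contact_percent,
                sa_bottom_mm2 = rep$sa_bottom, sa_top_mm2 = rep$sa_top,
                void_count = voids$count,
                void_total_mm3 = voids$total_volume)
    jsonlite::write_json(out, pth("conform.json"), auto_unbox = TRUE,
                         digits = NA)
    stage_log("conform", t0)
  }

  # --- manifest -------------------------------------------------------------
  files <- list.files(output_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("woundpatch")),
    seed = seed,
    config = config,
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
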