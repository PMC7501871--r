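# End-to-end orchestration: simulate -> bin -> embed -> propagate /
# homogenize -> landscapes -> transition map -> functional path -> frames
# -> optional toy reconstruction, with provenance and fixed seeds.

#' Default pipeline configuration
#'
#' All tunables in one place, echoed into every output's metadata. Seeds
#' are mandatory for stochastic stages (no silent entropy).
#'
#' @param ... Overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preset = "shifted_double_well",
    n_per_condition = 2500,
    n_directions = 50,
    phantom_size = 32,
    image_size = 32,
    noise_sigma = 0,
    jitter = 0,
    seed = 1,
    aperture = NULL,        # default: matched to n_directions
    resolution = NULL,      # with `diameter`: aperture from the
    diameter = NULL,        #   Shannon angle instead
    aperture_multiplier = 2,
    min_bin_members = 20,
    k_eigenpairs = 10,
    plateau_tau = 0.5,
    grid_dims = c(24, 24),
    kT = 1,
    path_mode = "integral",
    n_frames = 50,
    frame_half_width = 1,
    hotspot_rel_threshold = 0.5,
    reconstruct = FALSE,
    reconstruct_frames = integer(0))
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config fields: ",
                            paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Aperture whose tessellation has a given number of centers
#'
#' Inverse of [aperture_bin_count()]: useful to match the binning
#' tessellation to a known number of simulated directions.
#'
#' @param n_centers Desired center count.
#' @return Aperture in radians.
#' @export
aperture_for_bins <- function(n_centers) {
  0.5 * acos(1 - 2 / n_centers)
}

#' Run the full analysis pipeline on a synthetic ensemble
#'
#' Executes simulate -> bin -> embed -> propagate/homogenize ->
#' per-condition landscapes -> transition map -> functional path ->
#' frames (-> optional reconstruction) and returns every stage's output
#' plus a compact report. Re-running with the same config is
#' bit-reproducible.
#'
#' @param config A [pipeline_config()].
#' @param stack Optional pre-built [snapshot_stack()] (skips the simulate
#'   stage; the config's generator fields are then ignored).
#' @param out_dir Optional directory; when given, landscapes, the
#'   transition map, the path and the report are written there (CSV/JSON)
#'   together with the config.
#' @return List with `stack`, `bins`, `embeddings`, `selection`, `cmap`,
#'   `coords`, `occ` (minus/plus), `landscapes` (minus/plus), `tmap`,
#'   `path`, `frames`, `volumes` (optional), `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), stack = NULL,
                         out_dir = NULL) {
  stage <- "simulate"
  res <- tryCatch({
    pair <- define_dual_landscape(config$preset)
    if (is.null(stack)) {
      stack <- simulate_ensemble(
        pair, n_per_condition = config$n_per_condition,
        n_directions = config$n_directions,
        phantom = phantom_default(config$phantom_size),
        noise_sigma = config$noise_sigma, jitter = config$jitter,
        seed = config$seed, image_size = config$image_size)
    }
    stage <- "bin"
    aperture <- if (!is.null(config$aperture)) config$aperture
    else if (!is.null(config$resolution) && !is.null(config$diameter))
      shannon_aperture(config$resolution, config$diameter,
                       config$aperture_multiplier)
    else aperture_for_bins(config$n_directions)
    bins <- bin_orientations(stack, aperture,
                             min_members = config$min_bin_members)
    stage <- "embed"
    embeddings <- embed_bins(stack, bins, k = config$k_eigenpairs)
    spectra <- lapply(embeddings[!vapply(embeddings, is.null,
                                         logical(1))],
                      `[[`, "eigenvalues")
    selection <- coordinates_above_noise(spectra, tau = config$plateau_tau)
    stage <- "propagate"
    cmap <- propagate_coordinates(embeddings, bins, stack)
    coords <- homogenize_and_pool(embeddings, cmap, length(stack))
    stage <- "landscape"
    cc <- coords$coords
    occ_m <- occupancy_grid(cc[stack$condition == "minus", ],
                            dims = config$grid_dims, condition = "minus")
    occ_p <- occupancy_grid(cc[stack$condition == "plus", ],
                            dims = config$grid_dims, condition = "plus")
    E_m <- energy_from_occupancy(occ_m, kT = config$kT)
    E_p <- energy_from_occupancy(occ_p, kT = config$kT)
    stage <- "transitions"
    tmap <- transition_map(occ_m, occ_p)
    stage <- "path"
    path <- dual_landscape_path(E_m, E_p, tmap, occ_minus = occ_m,
                                mode = config$path_mode)
    stage <- "frames"
    cond_idx <- stack$condition
    frames <- suppressWarnings(
      path_frames(path, coords, cond_idx, config$grid_dims,
                  n_frames = config$n_frames,
                  half_width = config$frame_half_width))
    volumes <- NULL
    if (isTRUE(config$reconstruct)) {
      stage <- "reconstruct"
      sel_frames <- if (length(config$reconstruct_frames) > 0)
        config$reconstruct_frames else c(1, config$n_frames)
      volumes <- lapply(sel_frames, function(f) {
        mem <- frames$members[[f]]
        if (length(mem) == 0) return(NULL)
        backproject_frame(stack$images[, , mem, drop = FALSE],
                          stack$orientations[mem, ],
                          config$phantom_size)
      })
      names(volumes) <- paste0("frame", sel_frames)
    }
    report <- list(
      n_snapshots = length(stack),
      n_bins = length(bins$bins),
      n_bins_used = coords$n_bins_used,
      retained_coordinates = selection$retained,
      fraction_bins_retaining_2 = mean(selection$per_bin == 2),
      delta_g_max_minus = E_m$delta_g_max,
      delta_g_max_plus = E_p$delta_g_max,
      hotspot = path$hotspot,
      hotspot_transition_prob = path$summaries$hotspot_transition_prob,
      hotspot_window_fraction_minus =
        path$summaries$hotspot_window_fraction_minus,
      path_length = nrow(path$cells),
      path_action = path$action,
      config = unclass(config))
    list(stack = stack, bins = bins, embeddings = embeddings,
         selection = selection, cmap = cmap, coords = coords,
         occ = list(minus = occ_m, plus = occ_p),
         landscapes = list(minus = E_m, plus = E_p), tmap = tmap,
         path = path, frames = frames, volumes = volumes,
         report = report)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    landscape_to_df(res$landscapes$minus,
                    file.path(out_dir, "landscape_minus.csv"))
    landscape_to_df(res$landscapes$plus,
                    file.path(out_dir, "landscape_plus.csv"))
    tm <- res$tmap
    utils::write.csv(data.frame(
      i1 = rep(seq_len(tm$dims[1]), tm$dims[2]),
      i2 = rep(seq_len(tm$dims[2]), each = tm$dims[1]),
      T = as.vector(tm$T)),
      file.path(out_dir, "transition_map.csv"), row.names = FALSE)
    utils::write.csv(data.frame(res$path$cells, side = res$path$side,
                                energy = res$path$energy),
                     file.path(out_dir, "functional_path.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fr <- res$frames
    jsonlite::write_json(
      list(centers = fr$centers, cells = fr$cells, side = fr$side,
           half_width = fr$half_width, members = fr$members),
      file.path(out_dir, "frames.json"), digits = NA)
    if (!is.null(res$volumes)) {
      for (nm in names(res$volumes)) {
        if (!is.null(res$volumes[[nm]]))
          write_mrc(res$volumes[[nm]],
                    file.path(out_dir, paste0(nm, ".mrc")))
      }
    }
  }
  res
}
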