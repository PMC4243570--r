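#' Default pipeline configuration
#'
#' Every numeric constant of the pipeline in one flat key/value list, all
#' overridable from a YAML config file or per call. The stock values are the
#' pipeline's operating point: 60% brightness threshold, 62 inflation rounds,
#' post-processing constants 0.7/0.5, 0.5 um depth bins, On/Off surfaces at
#' 0/12 um, 6 um second-peak exclusion, -6 um profile truncation for the
#' threshold path.
#'
#' @return A named list of parameters.
#' @export
default_config <- function() {
  list(
    pitch = c(0.4, 0.4, 0.5),
    threshold_frac = 0.6,
    rounds = 62L,
    stale_copy = FALSE,
    dilation_radius = 2L,
    size_threshold = 500L,
    search_radius = 8L,
    post_threshold = 0.7,
    post_conservative = 0.5,
    kernel_shape = "ball",
    smooth_sigma = 1,
    bin = 0.5,
    support = c(-20, 25),
    kb_width = 3,
    kb_beta = 6,
    on_depth = 0,
    off_depth = 12,
    second_peak_exclusion = 6,
    truncate_below = -6,
    flatness_window = 32,
    fit_radius = 25,
    seed = 0L
  )
}

#' Read a pipeline configuration file
#'
#' A flat YAML key/value file; keys absent from [default_config()] are
#' rejected before any stage runs.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides named list applied after the file.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, user)
  cfg$rounds <- as.integer(cfg$rounds)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Automated depth profile of one two-channel stack
#'
#' The full automated path on in-memory stacks: enhancement (threshold
#' baseline, or a network forward pass when `spec`/`weights` are given),
#' post-processing, starburst surface detection, quasi-conformal flattening,
#' in-plane registration, volumetric warp, Kaiser-Bessel gridding, and peak
#' detection (profile truncated below `truncate_below` for the threshold
#' path).
#'
#' @param neuron neuron-channel [image_stack()].
#' @param chat fiducial-channel [image_stack()].
#' @param config configuration list, see [default_config()].
#' @param bistratified report a second stratification peak?
#' @param spec,weights optional [network_spec()] and parameter set; when
#'   given, enhancement uses [forward()] (thresholded at 0.5 probability)
#'   instead of [threshold_binarize()], and no profile truncation is applied.
#' @return A list: `volume` (cleaned [binary_volume()]), `warp`, `points`
#'   (warped voxel table), `profile` (unit-normalized [depth_profile()]),
#'   `peaks`.
#' @export
arbor_depth_profile <- function(neuron, chat, config = default_config(),
                                bistratified = FALSE, spec = NULL,
                                weights = NULL) {
  if (is.null(spec)) {
    binv <- threshold_binarize(neuron, config$threshold_frac)
    truncate_at <- config$truncate_below
  } else {
    mx <- max(neuron$values)
    norm <- image_stack(neuron$values / mx, neuron$grid, neuron$role)
    prob <- forward(spec, weights, norm)
    binv <- binary_volume(prob$values > 0.5, neuron$grid)
    truncate_at <- NULL
  }
  params <- postprocess_params(config$dilation_radius, config$size_threshold,
                               config$search_radius, config$post_threshold,
                               config$post_conservative, config$kernel_shape)
  clean <- postprocess(as_image_stack(binv), params)
  surf <- detect_surfaces(chat, smooth_sigma = config$smooth_sigma)
  on_map <- flatten_lscm(surf$on)
  off_map <- flatten_lscm(surf$off)
  reg <- register_inplane(on_map, off_map, surf$on, surf$off,
                          config$flatness_window)
  off_map <- apply_offset(off_map, reg$offset)
  wf <- build_warp(on_map, off_map, surf$on, surf$off, neuron$grid,
                   fit_radius_um = config$fit_radius,
                   off_depth_um = config$off_depth)
  pts <- warp_volume_points(wf, clean)
  prof <- depth_profile(pts$depth_um, pts$weight, bin = config$bin,
                        support = config$support, kb_width = config$kb_width,
                        kb_beta = config$kb_beta)
  peak_prof <- if (!is.null(truncate_at))
    truncate_profile(prof, truncate_at) else prof
  peaks <- find_peaks(peak_prof, bistratified = bistratified,
                      exclusion = config$second_peak_exclusion)
  list(volume = clean, warp = wf, points = pts,
       profile = normalize_profile(prof), peaks = peaks)
}

#' Run the full pipeline on files, writing all intermediate artifacts
#'
#' Stages: simulate (when no input stacks are given), enhance, postprocess,
#' flatten, profile, stats. Intermediates (TIFF/CSV) are always written so
#' any stage can be rerun in isolation, together with a run manifest (config
#' echo, package version, seed).
#'
#' @param config configuration list (see [default_config()]); additionally
#'   uses `out_dir` passed here.
#' @param out_dir output directory, created if needed.
#' @param neuron_path,chat_path input TIFFs; when `NULL`, a phantom of
#'   `sim_type` is simulated with `config$seed`.
#' @param sim_type phantom cell type for simulation.
#' @return Invisibly, the [arbor_depth_profile()] result.
#' @export
run_pipeline <- function(config = default_config(), out_dir = ".",
                         neuron_path = NULL, chat_path = NULL,
                         sim_type = "W3") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    message(sprintf("[arbordepth %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  t0 <- proc.time()[3]
  if (is.null(neuron_path)) {
    log_stage("simulate: %s phantom, seed %d", sim_type, config$seed)
    ph <- make_phantom(phantom_spec(sim_type, pitch = config$pitch,
                                    seed = config$seed))
    neuron <- ph$neuron; chat <- ph$chat
    write_stack(neuron, file.path(out_dir, "neuron.tif"))
    write_stack(chat, file.path(out_dir, "chat.tif"))
    write_swc(ph$truth$skeleton, file.path(out_dir, "truth.swc"))
    write.csv(ph$truth$depths, file.path(out_dir, "truth_depths.csv"),
              row.names = FALSE)
  } else {
    neuron <- read_stack(neuron_path, config$pitch, "neuron")
    chat <- read_stack(chat_path, config$pitch, "fiducial")
  }
  bis <- sim_type == "BDa"
  log_stage("enhance + postprocess + flatten + profile")
  res <- arbor_depth_profile(neuron, chat, config, bistratified = bis)
  write_stack(res$volume, file.path(out_dir, "clean.tif"))
  write.csv(res$points, file.path(out_dir, "warped_points.csv"),
            row.names = FALSE)
  write_profile_csv(res$profile, file.path(out_dir, "profile.csv"))
  summary <- data.frame(type = sim_type, n = 1L,
                        peak1 = res$peaks$peak1, peak2 = res$peaks$peak2,
                        crest = crest_factor(res$profile))
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  manifest <- c(list(package = "arbordepth",
                     version = as.character(packageVersion("arbordepth")),
                     r_version = R.version.string),
                config)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_stage("done in %.1f s; peak at %.2f um", proc.time()[3] - t0,
            res$peaks$peak1)
  invisible(res)
}
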