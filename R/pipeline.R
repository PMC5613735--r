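# End-to-end pipeline: read -> auto-contrast -> mark/grayscale ->
# smooth/down-sample -> align -> classify -> repair damaged ->
# region-grow -> XY down-sample -> write VTK + run report.

.config_defaults <- function() {
  list(
    manifest = NULL,
    landmarks_dir = NULL,
    output_vtk = NULL,
    output_report = NULL,
    reference_index = "middle",
    registration_mode = "chain",
    preprocess = list(
      autocontrast_saturation = 0,
      red_threshold = 25,
      red_threshold_overrides = list(),
      mark_boost = 100,
      gaussian_sigma = "auto",   # factor / 2 when factor > 1, else 0
      downsample_factor = 1
    ),
    thresholds = list(positive_above = 80, background_below = 3),
    connectivity = 6,
    region_seed = "auto",
    xy_downsample_factor = 2,
    value_map = list(background = 0, negative = 100, positive = 200),
    spacing = c(5.8, 8.9, 2.5),
    origin = c(0, 0, 0),
    unit_label = "as published (mm)"
  )
}

.merge_checked <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("config: unknown key%s %s%s",
                 if (length(unknown) > 1) "s" else "",
                 paste(sQuote(unknown), collapse = ", "),
                 if (nzchar(where)) paste0(" in '", where, "'") else ""),
         call. = FALSE)
  }
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list),
#' applies documented defaults, rejects unknown keys (typo protection)
#' and out-of-bound values, and resolves input paths relative to the
#' configuration file's directory. Defaulted fields are reported via
#' `message()`.
#'
#' @param config path to a YAML file, or a named list.
#' @param quiet suppress the defaulted-field messages.
#' @return A fully-defaulted object of class `pipeline_config`.
#' @export
validate_config <- function(config, quiet = FALSE) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: '%s'", config), call. = FALSE)
    }
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a YAML file path or a named list",
                             call. = FALSE)
  defaults <- .config_defaults()
  user_keys <- names(config)
  cfg <- .merge_checked(defaults, config, "")
  for (sub in c("preprocess", "thresholds", "value_map")) {
    if (sub %in% user_keys) {
      cfg[[sub]] <- .merge_checked(defaults[[sub]], config[[sub]], sub)
    }
  }
  if (is.null(cfg$manifest)) stop("config: 'manifest' is required", call. = FALSE)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|~)", p)) p else file.path(base, p)
  }
  cfg$manifest <- resolve(cfg$manifest)
  cfg$landmarks_dir <- resolve(cfg$landmarks_dir)
  cfg$output_vtk <- resolve(cfg$output_vtk)
  cfg$output_report <- resolve(cfg$output_report)
  if (!file.exists(cfg$manifest)) {
    stop(sprintf("config: manifest '%s' does not exist", cfg$manifest),
         call. = FALSE)
  }
  if (!is.null(cfg$landmarks_dir) && !dir.exists(cfg$landmarks_dir)) {
    stop(sprintf("config: landmarks_dir '%s' does not exist", cfg$landmarks_dir),
         call. = FALSE)
  }
  if (is.null(cfg$output_vtk)) stop("config: 'output_vtk' is required",
                                    call. = FALSE)
  if (is.null(cfg$output_report)) {
    cfg$output_report <- sub("\\.vtk$", "", cfg$output_vtk)
    cfg$output_report <- paste0(cfg$output_report, "_report.yaml")
  }
  pp <- cfg$preprocess
  check_range <- function(value, field, lo, hi) {
    if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
        value < lo || value > hi) {
      stop(sprintf("config: '%s' must be in [%s, %s]", field, lo, hi),
           call. = FALSE)
    }
  }
  check_range(pp$red_threshold, "preprocess.red_threshold", 0, 255)
  check_range(pp$mark_boost, "preprocess.mark_boost", 0, 255)
  if (pp$autocontrast_saturation < 0 || pp$autocontrast_saturation >= 0.5) {
    stop("config: 'preprocess.autocontrast_saturation' must be in [0, 0.5)",
         call. = FALSE)
  }
  if (pp$downsample_factor < 1) {
    stop("config: 'preprocess.downsample_factor' must be >= 1", call. = FALSE)
  }
  if (identical(pp$gaussian_sigma, "auto")) {
    cfg$preprocess$gaussian_sigma <-
      if (pp$downsample_factor > 1) pp$downsample_factor / 2 else 0
  } else if (!is.numeric(pp$gaussian_sigma) || pp$gaussian_sigma < 0) {
    stop("config: 'preprocess.gaussian_sigma' must be \"auto\" or >= 0",
         call. = FALSE)
  }
  th <- cfg$thresholds
  check_range(th$positive_above, "thresholds.positive_above", 0, 255)
  check_range(th$background_below, "thresholds.background_below", 0,
              th$positive_above)
  if (!cfg$connectivity %in% c(6, 26)) {
    stop("config: 'connectivity' must be 6 or 26", call. = FALSE)
  }
  if (!identical(cfg$region_seed, "auto")) {
    if (length(cfg$region_seed) != 3 || !is.numeric(cfg$region_seed)) {
      stop("config: 'region_seed' must be \"auto\" or a (x, y, z) triple",
           call. = FALSE)
    }
  }
  if (cfg$xy_downsample_factor < 1) {
    stop("config: 'xy_downsample_factor' must be >= 1", call. = FALSE)
  }
  for (nm in c("background", "negative", "positive")) {
    check_range(cfg$value_map[[nm]], paste0("value_map.", nm), 0, 255)
  }
  if (length(cfg$spacing) != 3 || any(cfg$spacing <= 0)) {
    stop("config: 'spacing' must be three positive numbers", call. = FALSE)
  }
  if (!quiet) {
    defaulted <- setdiff(names(defaults), user_keys)
    if (length(defaulted) > 0) {
      message("config: using defaults for ", paste(defaulted, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

.stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full reconstruction pipeline
#'
#' Executes the staged reconstruction on an on-disk stack: read the
#' manifest-ordered sections, per-image auto-contrast, red-channel
#' marking with grayscale conversion, Gaussian smoothing and
#' down-sampling, landmark-based rigid alignment to the reference slice,
#' three-class intensity segmentation, nearest-neighbour repair of
#' damaged slices, seeded region growing to remove extra-organ noise,
#' majority-label XY down-sampling, and legacy-VTK output. The run is
#' deterministic for fixed inputs and configuration.
#'
#' When `preprocess.downsample_factor > 1`, landmark coordinates are
#' divided by the factor so they stay consistent with the decimated
#' grid (decimation keeps every factor-th pixel starting at index 0).
#'
#' @param config a `pipeline_config` from [validate_config()], or a path
#'   / list accepted by it.
#' @param quiet suppress per-stage log messages.
#' @return A `run_report` list: per-slice registration table, class
#'   counts before and after region growing, removed-voxel count,
#'   positive fraction of tissue, per-slice tissue counts (full
#'   resolution, after cleanup), final dims and spacing, parameter echo,
#'   and output paths. Also written to `config$output_report` as YAML
#'   (registration table additionally as TSV).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_config(config, quiet = quiet)
  }
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    .stage_log(quiet, "[%s] done in %.2fs", name,
               as.numeric(difftime(Sys.time(), ts, units = "secs")))
    out
  }

  sections <- stage("read_stack", read_stack(config$manifest))
  n <- length(sections)
  damaged_idx <- which(vapply(sections, function(s) s$damaged, logical(1))) - 1L
  .stage_log(quiet, "[read_stack] %d slices, %d flagged damaged", n,
             length(damaged_idx))

  pp <- config$preprocess
  sections <- stage("auto_contrast", lapply(sections, auto_contrast,
                                            saturation = pp$autocontrast_saturation))
  slices <- stage("mark_and_grayscale", lapply(sections, function(s) {
    thr <- pp$red_threshold
    ov <- pp$red_threshold_overrides[[as.character(s$slice_index)]]
    if (!is.null(ov)) thr <- ov
    mark_and_grayscale(s, red_threshold = thr, mark_boost = pp$mark_boost)
  }))
  if (!quiet) {
    for (s in slices) {
      .stage_log(quiet, "  slice %d: intensity range [%d, %d]", s$slice_index,
                 min(s$pixels), max(s$pixels))
    }
  }
  slices <- stage("gaussian_downsample", lapply(slices, gaussian_downsample,
                                                sigma = pp$gaussian_sigma,
                                                factor = pp$downsample_factor))

  landmark_sets <- vector("list", n)
  if (!is.null(config$landmarks_dir)) {
    for (i in seq_len(n)) {
      idx <- sections[[i]]$slice_index
      p <- file.path(config$landmarks_dir, sprintf("landmarks_%03d.txt", idx))
      if (file.exists(p)) {
        lm <- read_landmarks(p)
        landmark_sets[[i]] <- lm / pp$downsample_factor
      }
    }
  }
  aligned <- if (all(vapply(landmark_sets, is.null, logical(1)))) {
    .stage_log(quiet, "[align_stack] no landmarks: stack passed through unaligned")
    list(slices = slices, transforms = replicate(n, transform_identity(),
                                                 simplify = FALSE),
         report = data.frame(slice = vapply(slices, function(s) s$slice_index,
                                            integer(1)),
                             theta_deg = 0, tx = 0, ty = 0, rms = 0))
  } else {
    stage("align_stack", align_stack(slices, landmark_sets,
                                     reference_index = config$reference_index,
                                     mode = config$registration_mode))
  }

  d <- dim(aligned$slices[[1]]$pixels)
  meta <- volume_meta(c(d[2], d[1], n), spacing = config$spacing,
                      origin = config$origin, unit_label = config$unit_label)
  volume <- stage("classify_volume",
                  classify_volume(aligned$slices,
                                  positive_above = config$thresholds$positive_above,
                                  background_below = config$thresholds$background_below,
                                  meta = meta))
  counts_before <- label_counts(volume)
  volume <- stage("interpolate_damaged",
                  interpolate_damaged_slices(volume, damaged_idx))
  grown <- stage("region_grow", region_grow_cleanup(volume,
                                                    connectivity = config$connectivity,
                                                    seed = config$region_seed))
  volume <- grown$volume
  counts_after <- label_counts(volume)
  .stage_log(quiet, "[region_grow] removed %d extra-organ voxels", grown$removed)
  per_slice_tissue <- vapply(seq_len(dim(volume$labels)[3]), function(z) {
    sum(volume$labels[, , z] != LABEL_BACKGROUND)
  }, numeric(1))
  tissue_total <- counts_after[["negative"]] + counts_after[["positive"]]
  positive_fraction <- if (tissue_total > 0) {
    counts_after[["positive"]] / tissue_total
  } else 0

  final <- stage("volume_downsample",
                 volume_downsample(volume, config$xy_downsample_factor))
  vm <- config$value_map
  stage("write_vtk", write_vtk_structured_points(
    final, value_map = c(background = vm$background, negative = vm$negative,
                         positive = vm$positive),
    path = config$output_vtk))

  report <- structure(list(
    registration = aligned$report,
    counts_before_grow = as.list(counts_before),
    counts_after_grow = as.list(counts_after),
    removed_voxels = grown$removed,
    positive_fraction = positive_fraction,
    per_slice_tissue_counts = as.integer(per_slice_tissue),
    damaged_slices = as.integer(damaged_idx),
    final_dims = final$meta$dims,
    final_spacing = final$meta$spacing,
    unit_label = final$meta$unit_label,
    parameters = unclass(config),
    tool_version = as.character(utils::packageVersion("histovol")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    output_vtk = config$output_vtk,
    output_report = config$output_report
  ), class = "run_report")

  rep_out <- report
  rep_out$registration <- NULL
  yaml::write_yaml(rapply(unclass(rep_out), f = function(x) x, how = "replace"),
                   config$output_report)
  utils::write.table(aligned$report,
                     sub("\\.ya?ml$", "_registration.tsv", config$output_report),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .stage_log(quiet, "pipeline finished in %.1fs; volume %s -> %s",
             report$elapsed_sec,
             paste(final$meta$dims, collapse = "x"), config$output_vtk)
  invisible(report)
}
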