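#' Configuration of a full simulation experiment
#'
#' Defaults reproduce the study design: the 17-canopy suite photographed at
#' nine exposure manipulations (-3..+5 stop) and analysed at thresholding
#' manipulations over the same stop range.
#'
#' @param suite List of [canopy_spec()] (default [generate_canopy_suite()]).
#' @param exposure_stops Exposure manipulations in stops (default -3..+5).
#' @param threshold_stops Thresholding manipulations in stops (default
#'   -3..+5, so ETM extents from -8 to +8 occur, with the matched diagonal
#'   M = 0 always present).
#' @param camera A [camera_config()].
#' @param pixel_scale Rendering resolution, mm per pixel (default 0.047,
#'   close to the source images' scale and fine enough that the blurred
#'   mixed-pixel zone stays narrow against the thinnest canopy bars).
#' @param extent_mm Target extent of the rendered analysis region (default
#'   60 mm; the region is trimmed to whole pattern periods).
#' @param supersample Rendering supersampling factor (default 8).
#' @param seed Optional seed, used only when the camera adds noise;
#'   recorded in outputs.
#' @param out_dir Optional output directory for CSV/PNG/JSON artefacts.
#' @param write_photos Write each photograph as PNG + JSON sidecar (slow;
#'   default FALSE).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(suite = generate_canopy_suite(),
                              exposure_stops = -3:5,
                              threshold_stops = -3:5,
                              camera = camera_config(),
                              pixel_scale = 0.047,
                              extent_mm = 60,
                              supersample = 8,
                              seed = NULL,
                              out_dir = NULL,
                              write_photos = FALSE) {
  stopifnot(length(exposure_stops) >= 1, length(threshold_stops) >= 1,
            inherits(camera, "camera_config"))
  structure(
    list(suite = suite, exposure_stops = exposure_stops,
         threshold_stops = threshold_stops, camera = camera,
         pixel_scale = pixel_scale, extent_mm = extent_mm,
         supersample = supersample, seed = seed, out_dir = out_dir,
         write_photos = write_photos),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields of the YAML file override the [experiment_config()]
#' defaults; `camera:` may hold [camera_config()] arguments.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cam <- do.call(camera_config, y$camera %||% list())
  y$camera <- NULL
  suite_args <- y$suite %||% list()
  y$suite <- NULL
  do.call(experiment_config,
          c(list(suite = do.call(generate_canopy_suite, suite_args),
                 camera = cam), y))
}

#' Run the full simulation experiment
#'
#' For every canopy in the suite: render the scene once, photograph it at
#' each exposure manipulation, compute the greyness histogram, grey-pixel
#' bounds and fraction, the matched threshold, the Sobel mixed-pixel-zone
#' fraction of the matched binary map, and one analysis record per
#' thresholding manipulation.  With a noise-free camera the run is fully
#' deterministic: the same configuration always yields byte-identical CSV
#' outputs.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per canopy (default FALSE).
#' @return A list with `suite` (canopy table), `records` (one row per
#'   photograph x thresholding manipulation) and `photos_n` (number of
#'   photographs simulated).  When `config$out_dir` is set,
#'   `canopy_suite.csv`, `records.csv` and `run.json` (provenance: seed,
#'   stops, camera settings) are written there, plus photographs if
#'   requested.
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  records <- vector("list", length(config$suite))
  photos_n <- 0L
  for (ci in seq_along(config$suite)) {
    spec <- config$suite[[ci]]
    scene <- render_canopy(spec, pixel_scale = config$pixel_scale,
                           supersample = config$supersample,
                           extent_mm = config$extent_mm)
    per_photo <- vector("list", length(config$exposure_stops))
    for (xi in seq_along(config$exposure_stops)) {
      X <- config$exposure_stops[xi]
      photo <- simulate_photograph(scene, X, config$camera)
      photos_n <- photos_n + 1L
      hist <- greyness_histogram(photo)
      grey <- grey_pixel_bounds(hist)
      thr0 <- matched_threshold(photo, hist)
      mpz <- mpz_sobel(binarize(photo, thr0))
      rows <- lapply(config$threshold_stops, function(S_t) {
        analyze_with_etm(photo, S_t, hist = hist, grey = grey,
                         mpz_fraction = mpz$mpz_fraction)
      })
      rows <- do.call(rbind, rows)
      rows$matched_threshold_dn <- thr0
      per_photo[[xi]] <- rows
      if (!is.null(out_dir) && isTRUE(config$write_photos)) {
        write_photograph(photo, file.path(out_dir, sprintf(
          "photo_%s_X%+d.png", spec$id, as.integer(X)
        )))
      }
    }
    records[[ci]] <- do.call(rbind, per_photo)
    if (progress) {
      message(sprintf("canopy %s done (%d/%d)", spec$id, ci,
                      length(config$suite)))
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  suite_tab <- canopy_suite_table(config$suite)

  if (!is.null(out_dir)) {
    utils::write.csv(suite_tab, file.path(out_dir, "canopy_suite.csv"),
                     row.names = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(
        seed = config$seed,
        exposure_stops = config$exposure_stops,
        threshold_stops = config$threshold_stops,
        pixel_scale = config$pixel_scale,
        extent_mm = config$extent_mm,
        supersample = config$supersample,
        camera = unclass(config$camera),
        photographs = photos_n
      ),
      file.path(out_dir, "run.json"),
      auto_unbox = TRUE, null = "null", digits = NA
    )
  }
  list(suite = suite_tab, records = records, photos_n = photos_n)
}

#' Write a photograph as 8-bit greyscale PNG with a JSON sidecar
#'
#' @param photo A `photograph`.
#' @param path PNG output path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_photograph <- function(photo, path) {
  stopifnot(inherits(photo, "photograph"))
  png::writePNG(photo$dn / 255, path)
  jsonlite::write_json(
    list(
      exposure = photo$exposure,
      blur_sigma = photo$blur_sigma,
      canopy_id = photo$canopy_id,
      pixel_scale = photo$pixel_scale,
      gap_fraction_true = photo$gap_fraction_true,
      scb_per_area = photo$scb_per_area,
      camera = unclass(photo$cfg)
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' Read an 8-bit greyscale PNG as a bare photograph
#'
#' Metadata is restored from the JSON sidecar when present; ground-truth
#' fields are left `NULL` otherwise.
#'
#' @param path PNG path.
#' @return A `photograph` (without ground-truth labels).
#' @export
read_photograph <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  dn <- round(img * 255)
  storage.mode(dn) <- "integer"
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::fromJSON(sidecar)
  cfg <- if (!is.null(meta$camera)) {
    do.call(camera_config, meta$camera[names(meta$camera) != "mask_diameter"])
  } else {
    camera_config()
  }
  diameter <- meta$camera$mask_diameter
  mask <- if (is.null(diameter)) {
    matrix(TRUE, nrow(dn), ncol(dn))
  } else {
    circular_mask(dim(dn), diameter)
  }
  structure(
    list(
      dn = dn,
      mask = mask,
      exposure = meta$exposure %||% NA_real_,
      blur_sigma = meta$blur_sigma %||% NA_real_,
      cfg = cfg,
      labels = NULL,
      occupancy = NULL,
      gap_fraction_true = meta$gap_fraction_true %||% NULL,
      scb_per_area = meta$scb_per_area %||% NULL,
      gf_designed = NULL,
      pixel_scale = meta$pixel_scale %||% NA_real_,
      canopy_id = meta$canopy_id %||% NA_character_
    ),
    class = "photograph"
  )
}
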