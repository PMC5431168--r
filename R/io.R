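#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pixel counts are clipped to [0, 65535], rounded and written as 16-bit
#' TIFF pages; the sidecar \code{<base>.json} round-trips the scan metadata
#' (angle_deg, step_um, pixel_um, origin_um, seed, noise).
#'
#' @param stack an \linkS4class{ImageStack}
#' @param path output TIFF path; the sidecar replaces the extension by .json
#' @return invisibly, the sidecar path
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  n <- dim(stack@frames)
  pages <- lapply(seq_len(n[3]), function(i)
    pmin(pmax(round(stack@frames[, , i]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- list(angle_deg = stack@scan@angleDeg, step_um = stack@scan@step,
               pixel_um = stack@pixel, n_frames = stack@scan@nFrames,
               origin_um = stack@meta$origin, seed = stack@meta$seed,
               noise = stack@meta$noise)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an image stack written by \code{\link{writeStack}}
#'
#' Also accepts any multi-page TIFF accompanied by a compliant JSON sidecar
#' (required fields: angle_deg, step_um, pixel_um).
#'
#' @param path TIFF path
#' @return an \linkS4class{ImageStack}
#' @export
readStack <- function(path) {
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf(paste0("missing JSON sidecar '%s'; expected fields: ",
                        "angle_deg, step_um, pixel_um"), sidecar))
  meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                   error = function(e)
                     stop(sprintf("corrupt sidecar '%s': %s", sidecar,
                                  conditionMessage(e))))
  need <- c("angle_deg", "step_um", "pixel_um")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("sidecar '%s' is missing required fields: %s", sidecar,
                 paste(miss, collapse = ", ")))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- round(pages[[i]] * 65535)
  scan <- scanGeometry(meta$angle_deg, meta$step_um, length(pages))
  new("ImageStack", frames = frames, scan = scan, pixel = meta$pixel_um,
      meta = list(origin = if (!is.null(meta$origin_um))
                    as.numeric(meta$origin_um) else c(0, 0),
                  seed = meta$seed, noise = meta$noise))
}

#' Write a sheet field as 32-bit float TIFF with a JSON sidecar
#'
#' @param sheet a \linkS4class{SheetField}
#' @param path output TIFF path
#' @return invisibly, the sidecar path
#' @export
writeSheetField <- function(sheet, path) {
  stopifnot(is(sheet, "SheetField"))
  tiff::writeTIFF(sheet@values, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- list(x_um = sheet@grid@x, z_um = sheet@grid@z, meta = sheet@meta)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read and validate a run configuration file
#'
#' YAML with blocks illumination, mask, pulse, detection, scan, noise,
#' analysis plus scalar keys seed and output. Unknown top-level or
#' block-level keys are rejected. Physical quantities carry units in their
#' key names (_nm, _um, _fs, _mm, _deg).
#'
#' @param path YAML file path
#' @return named list with constructed S4 configuration objects
#'   (illumination, mask or NULL, pulse, detection, scan) plus the raw
#'   noise/analysis lists, seed and output
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  knownTop <- c("illumination", "mask", "pulse", "detection", "scan",
                "noise", "analysis", "seed", "output")
  unknown <- setdiff(names(cfg), knownTop)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  checkKeys <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop(sprintf("unknown keys in '%s' block: %s", name,
                   paste(bad, collapse = ", ")))
  }
  ill <- cfg$illumination
  checkKeys(ill, c("na", "fill_factor", "immersion", "objective_focal_mm",
                   "relay_magnification", "n_pupil"), "illumination")
  illumination <- illuminationConfig(
    naExcitation = ill$na %||% 0.3,
    fillFactor = ill$fill_factor %||% 1.0,
    immersion = dispersionModel(ill$immersion %||% "water"),
    objectiveFocal = ill$objective_focal_mm %||% 18,
    relayMagnification = ill$relay_magnification %||% 2,
    nPupil = ill$n_pupil %||% 1025L)
  maskObj <- NULL
  if (!is.null(cfg$mask)) {
    checkKeys(cfg$mask, c("alpha", "reference_wavelength_nm",
                          "aperture_radius_mm", "substrate"), "mask")
    maskObj <- cubicMask(cfg$mask$alpha,
      referenceWavelength = cfg$mask$reference_wavelength_nm %||% 532,
      apertureRadius = cfg$mask$aperture_radius_mm %||% 3.5,
      substrate = dispersionModel(cfg$mask$substrate %||% "fused_silica"))
  }
  pl <- cfg$pulse
  checkKeys(pl, c("center_wavelength_nm", "duration_fwhm_fs", "n_samples"),
            "pulse")
  pulse <- pulseSpec(pl$center_wavelength_nm %||% 780,
                     pl$duration_fwhm_fs %||% 20,
                     pl$n_samples %||% 33L)
  dt <- cfg$detection
  checkKeys(dt, c("na", "magnification", "camera_pixel_um",
                  "emission_wavelength_nm", "immersion_index"), "detection")
  detection <- detectionConfig(
    naDetection = dt$na %||% 0.5,
    magnification = dt$magnification %||% 20,
    cameraPixel = dt$camera_pixel_um %||% 6.5,
    emissionWavelength = dt$emission_wavelength_nm %||% 520,
    immersionIndex = dt$immersion_index %||% 1.333)
  sc <- cfg$scan
  checkKeys(sc, c("angle_deg", "step_um", "n_frames"), "scan")
  scan <- if (is.null(sc)) NULL else
    scanGeometry(sc$angle_deg %||% 45, sc$step_um %||% 0.092, sc$n_frames)
  if (!is.null(cfg$noise))
    checkKeys(cfg$noise, c("photon_scale", "read_sigma", "background",
                           "poisson"), "noise")
  list(illumination = illumination, mask = maskObj, pulse = pulse,
       detection = detection, scan = scan, noise = cfg$noise,
       analysis = cfg$analysis, seed = cfg$seed %||% 1L,
       output = cfg$output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
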