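# Image I/O (32-bit float TIFF with JSON sidecars) and unit-checked run
# configuration.

#' Read a grayscale TIFF image or stack
#'
#' Reads single- or multi-page grayscale TIFFs (8/16-bit integer or
#' 32-bit float) into float-valued matrices with the stored dynamic
#' range preserved (integer samples keep their integer values).
#'
#' @param path Path to a TIFF file.
#' @return List of numeric matrices, one per page, in storage order.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # as.is=TRUE keeps integer sample values; it is rejected for float
  # samples, which are already read natively without it
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      if (grepl("floating point", conditionMessage(e)))
                        tiff::readTIFF(path, all = TRUE)
                      else stop(e)
                    })
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L)
      stop("multi-channel (RGB) TIFF input is not supported; ",
           "grayscale images only")
    storage.mode(p) <- "double"
    p
  })
}

#' Write a 32-bit float grayscale TIFF with a JSON sidecar
#'
#' Writes a single-page, uncompressed, little-endian TIFF with IEEE
#' 32-bit float samples (values of any range are preserved to float32
#' precision), plus a `<path>.json` sidecar recording the geometry and
#' any provenance metadata.
#'
#' @param path Output path.
#' @param image Numeric matrix of finite values (unless `allow_nan`).
#' @param geometry Optional [imaging_geometry] recorded in the sidecar.
#' @param meta Optional named list of extra sidecar fields (e.g. the
#'   kernel choice or command line).
#' @param allow_nan If `TRUE`, non-finite values are written as-is.
#' @param sidecar If `FALSE`, skip the JSON sidecar.
#' @return Invisibly, `path`.
#' @export
write_image <- function(path, image, geometry = NULL, meta = list(),
                        allow_nan = FALSE, sidecar = TRUE) {
  image <- .as_matrix_image(image)
  if (!allow_nan && any(!is.finite(image)))
    stop("non-finite values in `image`; set allow_nan = TRUE to keep them")
  .write_float_tiff(path, image)
  if (sidecar) {
    side <- list(shape = dim(image), format = "float32 tiff")
    if (!is.null(geometry)) {
      stopifnot(inherits(geometry, "imaging_geometry"))
      side$geometry <- list(pixel_size_m = geometry$pixel_size,
                            distance_m = geometry$distance,
                            psf_fwhm_px = geometry$psf_fwhm)
    }
    if (length(meta)) side <- c(side, meta)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

# Minimal single-strip uncompressed little-endian TIFF writer for IEEE
# 32-bit float samples.  Needed because installed TIFF writers clamp or
# wrap float samples outside [0, 1].
.write_float_tiff <- function(path, image) {
  con <- file(path, "wb")
  on.exit(close(con))
  nr <- nrow(image)
  nc <- ncol(image)
  nbytes <- 4L * nr * nc
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  wb4 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  entry <- function(tag, type, count, value) {
    wb2(tag); wb2(type); wb4(count)
    if (type == 3L) { wb2(value); wb2(0L) } else wb4(value)
  }
  writeBin(charToRaw("II"), con)
  wb2(42L)
  wb4(8L + nbytes)                     # IFD follows the pixel data
  writeBin(as.vector(t(image)), con, size = 4, endian = "little")
  wb2(10L)                             # entry count
  entry(256L, 4L, 1L, nc)              # ImageWidth
  entry(257L, 4L, 1L, nr)              # ImageLength
  entry(258L, 3L, 1L, 32L)             # BitsPerSample
  entry(259L, 3L, 1L, 1L)              # Compression: none
  entry(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
  entry(273L, 4L, 1L, 8L)              # StripOffsets
  entry(277L, 3L, 1L, 1L)              # SamplesPerPixel
  entry(278L, 4L, 1L, nr)              # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)          # StripByteCounts
  entry(339L, 3L, 1L, 3L)              # SampleFormat: IEEE float
  wb4(0L)                              # no next IFD
}

# ---------------------------------------------------------------------
# Run configuration with mandatory unit suffixes.

.unit_table <- list(
  length = c(m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6, nm = 1e-9),
  inv_length = c("1/m" = 1, "/m" = 1, "1/cm" = 100, "/cm" = 100,
                 "1/mm" = 1000, "/mm" = 1000),
  energy = c(keV = 1, eV = 1e-3),
  pixels = c(px = 1),
  angle = c(deg = 1)
)

.parse_quantity <- function(x, kind, key) {
  if (kind == "none") {
    if (!is.numeric(x))
      stop(sprintf("config key '%s' must be a plain number", key))
    return(x)
  }
  units <- .unit_table[[kind]]
  parse_one <- function(s) {
    if (is.numeric(s))
      stop(sprintf("config key '%s' must carry a unit (one of: %s)",
                   key, paste(names(units), collapse = ", ")))
    parts <- strsplit(trimws(s), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[1]))))
      stop(sprintf("config key '%s': cannot parse quantity '%s'", key, s))
    u <- units[parts[2]]
    if (is.na(u))
      stop(sprintf("config key '%s': unknown unit '%s' (one of: %s)",
                   key, parts[2], paste(names(units), collapse = ", ")))
    as.numeric(parts[1]) * unname(u)
  }
  vapply(as.list(x), parse_one, 0)
}

.config_schema <- list(
  geometry = list(pixel_size = "length", distance = "length",
                  psf_fwhm = "pixels", shape = "none"),
  materials = NULL,  # named sub-lists, validated separately
  kernel = "enum",
  simulation = list(radius = "pixels", thickness = "length",
                    upsample = "none", pre_blur = "pixels"),
  metrology = list(centre = "none", r_min = "pixels", r_max = "pixels",
                   arc = "angle", bin_width = "pixels"),
  spectral = list(energy_a = "energy", energy_b = "energy"),
  seed = "none"
)

.material_schema <- list(delta = "none", beta = "none",
                         mu = "inv_length", energy = "energy")

.check_known <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop(sprintf("unknown config key%s under '%s': %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")))
}

#' Read a unit-checked run configuration
#'
#' Parses a YAML configuration in which every physical quantity carries
#' an explicit unit suffix (e.g. `pixel_size: 25 um`, `mu: 57.2 1/m`,
#' `energy: 24 keV`), converting lengths to metres and energies to keV.
#' Unknown keys are rejected.
#'
#' @param path Path to a YAML file with (all optional) sections
#'   `geometry`, `materials`, `kernel`, `simulation`, `metrology`,
#'   `spectral`, and `seed`.
#' @return A list of class `run_config` with numeric SI values;
#'   `materials` entries are [material_optics] objects and `geometry`
#'   (when complete) an [imaging_geometry].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  .check_known(raw, names(.config_schema), "(top level)")
  out <- list()
  for (section in intersect(names(raw), names(.config_schema))) {
    spec <- .config_schema[[section]]
    x <- raw[[section]]
    if (section == "kernel") {
      out$kernel <- .kernel_choice(x)
    } else if (section == "seed") {
      out$seed <- .parse_quantity(x, "none", "seed")
    } else if (section == "materials") {
      if (!is.list(x) || is.null(names(x)))
        stop("config 'materials' must be a named mapping")
      out$materials <- lapply(names(x), function(nm) {
        m <- x[[nm]]
        .check_known(m, names(.material_schema), paste0("materials/", nm))
        args <- lapply(names(m), function(k)
          .parse_quantity(m[[k]], .material_schema[[k]],
                          paste0("materials/", nm, "/", k)))
        names(args) <- names(m)
        do.call(material_optics, c(args, list(name = nm)))
      })
      names(out$materials) <- names(x)
    } else {
      .check_known(x, names(spec), section)
      vals <- lapply(names(x), function(k)
        .parse_quantity(x[[k]], spec[[k]], paste0(section, "/", k)))
      names(vals) <- names(x)
      out[[section]] <- vals
    }
  }
  if (!is.null(out$geometry) &&
      all(c("pixel_size", "distance") %in% names(out$geometry))) {
    g <- out$geometry
    out$geometry <- imaging_geometry(
      g$pixel_size, g$distance,
      psf_fwhm = if (is.null(g$psf_fwhm)) 0 else g$psf_fwhm,
      shape = g$shape)
  }
  class(out) <- "run_config"
  out
}
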