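# File formats and configuration: transmission matrices (RDS containers with
# schema versioning), kymographs and image stacks (TIFF/CSV with YAML
# sidecars), traces and spectra (CSV), run configuration (YAML).

TM_FORMAT_VERSION <- 1L

#' Hash an R object
#'
#' Dependency-free provenance hash: MD5 of the object's serialisation.
#'
#' @param x Any R object.
#' @return Character MD5 digest.
#' @export
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Save / load a transmission matrix
#'
#' The on-disk container is an RDS file carrying the matrix and all metadata
#' (grid, basis, calibration plane, wavelength, medium index) plus a content
#' hash and a format version; the round trip is bit-exact and the hash is
#' re-verified at load.
#'
#' @param tm A [transmission_matrix()].
#' @param path Destination file.
#' @return `save_tm` returns `path` invisibly; `load_tm` returns the
#'   `transmission_matrix`.
#' @export
save_tm <- function(tm, path) {
  stopifnot(inherits(tm, "transmission_matrix"))
  payload <- list(format_version = TM_FORMAT_VERSION, tm = tm,
                  hash = object_hash(tm))
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname save_tm
#' @export
load_tm <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$format_version))
    stop_fibrescope("not a transmission-matrix container (missing field: format_version)",
                    "schema_error")
  if (payload$format_version != TM_FORMAT_VERSION)
    stop_fibrescope(sprintf("unsupported container version %s (expected %d)",
                            payload$format_version, TM_FORMAT_VERSION),
                    "schema_error")
  for (field in c("matrix", "output_grid", "calibration_plane_z",
                  "wavelength", "medium_index"))
    if (is.null(payload$tm[[field]]))
      stop_fibrescope(sprintf("container missing field: %s", field),
                      "schema_error")
  if (!identical(payload$hash, object_hash(payload$tm)))
    stop_fibrescope("content hash mismatch: file corrupted", "schema_error")
  payload$tm
}

# TIFF stores values in [0, 1]; real-valued data are scaled and the factor
# recorded in the YAML sidecar.
#' @noRd
write_scaled_tiff <- function(pages, path) {
  if (!is.list(pages)) pages <- list(pages)
  scale <- max(1e-300, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L)
  scale
}

#' @noRd
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yml")

#' Write / read a kymograph
#'
#' Single-page 32-bit TIFF (`.tif`) or CSV (`.csv`) with a YAML sidecar
#' carrying `line_rate`, `pixel_pitch` and the intensity scale.
#'
#' @param k A [kymograph()].
#' @param path Destination (`.tif` or `.csv`).
#' @return `write_kymograph` returns `path` invisibly; `read_kymograph`
#'   returns the `kymograph`.
#' @export
write_kymograph <- function(k, path) {
  stopifnot(inherits(k, "kymograph"))
  ext <- tolower(tools::file_ext(path))
  meta <- list(type = "kymograph", line_rate = k$line_rate,
               pixel_pitch = k$pixel_pitch, scale = 1)
  if (ext == "csv") {
    utils::write.table(k$data, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    meta$scale <- write_scaled_tiff(k$data, path)
  }
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  ext <- tolower(tools::file_ext(path))
  data <- if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else {
    tiff::readTIFF(path) * meta$scale
  }
  dimnames(data) <- NULL
  kymograph(data, meta$line_rate, meta$pixel_pitch)
}

#' Write / read a z-stack record as multi-page TIFF with a YAML manifest
#'
#' Pages are ordered stack-major (all planes of stack 1, then stack 2, ...);
#' the manifest records the stack count, plane count, frame rate and
#' intensity scale.
#'
#' @param record A [scan_record()].
#' @param path Destination `.tif`.
#' @return `write_record` returns `path` invisibly; `read_record` the
#'   `scan_record`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "scan_record"))
  pages <- unlist(lapply(record$stacks, function(st)
    lapply(st, as.matrix)), recursive = FALSE)
  scale <- write_scaled_tiff(pages, path)
  yaml::write_yaml(list(type = "scan_record",
                        n_stacks = length(record$stacks),
                        n_planes = length(record$stacks[[1]]),
                        frame_rate = record$frame_rate,
                        insertion_speed = record$insertion_speed,
                        probe_geometry = record$probe_geometry,
                        scale = scale),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  stacks <- lapply(seq_len(meta$n_stacks), function(k) {
    lapply(seq_len(meta$n_planes), function(p)
      pages[[(k - 1) * meta$n_planes + p]] * meta$scale)
  })
  scan_record(stacks, meta$frame_rate,
              insertion_speed = meta$insertion_speed %||% NA_real_,
              probe_geometry = meta$probe_geometry %||% "side")
}

#' Write a stitched volume as multi-page TIFF plus sidecar
#'
#' One page per axial plane; the sidecar records voxel size, speed, scale
#' and the per-voxel sample-count summary. The full count map is stored next
#' to the volume as `<path>_count.tif`.
#'
#' @param vol A [stitch()] result.
#' @param path Destination `.tif`.
#' @return `path`, invisibly.
#' @export
write_stitched <- function(vol, path) {
  stopifnot(inherits(vol, "stitched_volume"))
  n_planes <- dim(vol$volume)[1]
  pages <- lapply(seq_len(n_planes), function(p) vol$volume[p, , ])
  scale <- write_scaled_tiff(pages, path)
  count_path <- paste0(tools::file_path_sans_ext(path), "_count.tif")
  cmax <- max(vol$count)
  tiff::writeTIFF(lapply(seq_len(n_planes), function(p)
    vol$count[p, , ] / cmax), count_path, bits.per.sample = 32L)
  yaml::write_yaml(list(type = "stitched_volume",
                        voxel_size = as.numeric(vol$voxel_size),
                        speed = as.numeric(vol$speed), scale = scale,
                        count_scale = cmax, n_planes = n_planes),
                   sidecar_path(path))
  invisible(path)
}

#' Write / read a velocity trace or spectrum as CSV
#'
#' @param x Data frame (e.g. a [velocity_trace()] or [power_spectrum()]).
#' @param path Destination `.csv`.
#' @return `write_trace` returns `path` invisibly; `read_trace` a data
#'   frame.
#' @export
write_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(type = "trace")
  for (a in c("units", "line_rate", "pixel_pitch"))
    if (!is.null(attr(x, a))) meta[[a]] <- attr(x, a)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- utils::read.csv(path)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    for (a in c("units", "line_rate", "pixel_pitch"))
      if (!is.null(meta[[a]])) attr(out, a) <- meta[[a]]
  }
  out
}

#' Read / write a run configuration
#'
#' YAML mapping holding the fibre spec, grid, basis size, refocus ladder,
#' scan plan, estimator settings, seeds and output paths; the round trip
#' through the file format is lossless for scalars, vectors and nested
#' mappings.
#'
#' @param cfg Named list.
#' @param path `.yml` file.
#' @return `read_run_config` returns the named list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_fibrescope(sprintf("config file not found: %s", path), "io_error")
  yaml::read_yaml(path)
}
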