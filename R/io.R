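#' Run configuration
#'
#' Structured configuration for reproducible runs. Units are embedded in
#' the key names (`_ms`, `_mm`, `_S_per_m`, ...) to prevent unit bugs.
#' [load_config()] validates against the default schema: unknown keys are
#' rejected by name, missing keys are filled with defaults. Configurations
#' round-trip losslessly through YAML.
#'
#' @return the default configuration (a named list of class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    geometry = list(kind = "sheet", nx = 81, ny = 81, h_mm = 0.5,
                    sigma_S_per_m = 0.15, regions = "none",
                    segments_k = 2),
    fibrosis = list(preset = "none", nonconductive_fraction = 0.5,
                    seed = 1),
    membrane = list(model = "fast_test", preset = "control"),
    solver = list(dt_ms = 0.02, dt_out_ms = 1, beta_per_mm = 140,
                  cm_uF_per_cm2 = 1),
    pacing = list(d_mm = 10, margin_mm = 5, amplitude = 30,
                  duration_ms = 2, edge_mm = 2),
    protocol = list(name = "peerp", max_beats = 4, erp_resolution_ms = 1,
                    s_ms = 300, l_ms = 200, step_ms = 10, N = 1,
                    check = "B", psd_cl_ms = 315,
                    psd_speed_m_per_s = 0.7),
    analysis = list(tau_ms = 10, window_ms = 1500),
    output = list(dir = "atriavuln-out")
  ), class = "run_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  def <- unclass(default_config())
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    .stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(def[[sec]]))
    if (length(bad))
      .stopf("unknown key(s) in section '%s': %s", sec,
             paste(bad, collapse = ", "))
    def[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  structure(def, class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; embedded in result artifacts
#' so outputs are traceable to their configuration.
#'
#' @param config a `run_config` (or any list).
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Build geometry and membrane model from a configuration
#'
#' @param config a `run_config`.
#' @return list with `geom` and `model`.
#' @export
build_from_config <- function(config) {
  g <- config$geometry
  geom <- if (g$kind == "strand") make_strand(g$nx, g$h_mm, g$sigma_S_per_m)
          else make_sheet(g$nx, g$ny, g$h_mm, g$sigma_S_per_m,
                          regions = g$regions)
  geom <- partition_segments(geom, g$segments_k)
  f <- config$fibrosis
  if (!identical(f$preset, "none")) {
    fp <- fibrosis_preset(f$preset,
                          fractions = if (!is.null(f$fractions))
                            unlist(f$fractions) else NULL,
                          nonconductive_fraction = f$nonconductive_fraction,
                          seed = f$seed)
    geom <- apply_fibrosis(geom, fp)
  }
  m <- config$membrane
  model <- membrane_model(m$model)
  if (!identical(m$preset, "control"))
    model <- apply_remodeling(model, remodeling_preset(m$preset))
  list(geom = geom, model = model)
}

# ---- voltage-movie container -----------------------------------------------

.MOVIE_MAGIC <- "AVMOVIE1"

#' Read and write voltage movies
#'
#' A self-described binary container for voltage movies: an ASCII magic
#' line, a JSON metadata line (grid dimensions, spacing, frame interval,
#' format version), then the frame data as little-endian doubles. The
#' round trip is lossless; truncated files and version mismatches are
#' reported as errors.
#'
#' @param movie a `vm_movie`.
#' @param path file path.
#' @return `read_movie` returns a `vm_movie`; `write_movie` the path,
#'   invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "vm_movie"))
  con <- file(path, "wb")
  on.exit(close(con))
  meta <- list(version = 1L, nframes = nrow(movie$vm), nx = movie$nx,
               ny = movie$ny, h_mm = movie$h, dt_out_ms = movie$dt_out,
               t0_ms = movie$times[1])
  writeLines(c(.MOVIE_MAGIC,
               as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA))), con)
  writeBin(as.vector(t(movie$vm)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) .stopf("movie file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, .MOVIE_MAGIC))
    .stopf("not a voltage-movie file (bad magic): %s", path)
  meta <- jsonlite::fromJSON(readLines(con, n = 1))
  if (!identical(as.integer(meta$version), 1L))
    .stopf("unsupported movie container version %s", meta$version)
  nn <- meta$nx * meta$ny
  expected <- meta$nframes * nn
  dat <- readBin(con, "double", n = expected, size = 8, endian = "little")
  if (length(dat) != expected)
    .stopf("truncated movie file: expected %d values, found %d",
           expected, length(dat))
  vm <- matrix(dat, nrow = meta$nframes, ncol = nn, byrow = TRUE)
  structure(list(vm = vm,
                 times = meta$t0_ms + (seq_len(meta$nframes) - 1) *
                   meta$dt_out_ms,
                 nx = meta$nx, ny = meta$ny, h = meta$h_mm,
                 dt_out = meta$dt_out_ms),
            class = "vm_movie")
}

# ---- legacy VTK writers ----------------------------------------------------

#' Write geometry or voltage fields as legacy VTK
#'
#' `write_vtk_geometry` writes the element labels and conductivities as
#' cell data of a structured-points dataset (plus a JSON sidecar with the
#' named regions and segments); `write_vtk_frame` writes one movie frame
#' as point data.
#'
#' @param geom a `tissue_geometry`.
#' @param path output `.vtk` path.
#' @param sidecar write the JSON sidecar next to `path`? (default TRUE)
#' @return the path, invisibly.
#' @export
write_vtk_geometry <- function(geom, path, sidecar = TRUE) {
  stopifnot(inherits(geom, "tissue_geometry"))
  enx <- nrow(geom$label)
  eny <- ncol(geom$label)
  ncell <- enx * eny
  lines <- c(
    "# vtk DataFile Version 3.0",
    "atriavuln tissue geometry", "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", geom$nx, geom$ny),
    sprintf("ORIGIN 0 0 0"),
    sprintf("SPACING %g %g 1", geom$h, geom$h),
    sprintf("CELL_DATA %d", ncell),
    "SCALARS label int 1", "LOOKUP_TABLE default",
    paste(as.vector(geom$label), collapse = " "),
    "SCALARS sigma double 1", "LOOKUP_TABLE default",
    paste(format(as.vector(geom$sigma), digits = 10), collapse = " "),
    "SCALARS segment int 1", "LOOKUP_TABLE default",
    paste(as.vector(geom$segments), collapse = " "))
  writeLines(lines, path)
  if (sidecar) {
    meta <- list(kind = geom$kind, h_mm = geom$h,
                 regions = geom$regions,
                 label_names = .label_names)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_vtk_geometry
#' @param movie a `vm_movie`.
#' @param frame frame index.
#' @export
write_vtk_frame <- function(movie, frame, path) {
  stopifnot(inherits(movie, "vm_movie"))
  v <- movie$vm[frame, ]
  lines <- c(
    "# vtk DataFile Version 3.0",
    sprintf("atriavuln Vm at t = %g ms", movie$times[frame]), "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", movie$nx, movie$ny),
    "ORIGIN 0 0 0",
    sprintf("SPACING %g %g 1", movie$h, movie$h),
    sprintf("POINT_DATA %d", length(v)),
    "SCALARS Vm double 1", "LOOKUP_TABLE default",
    paste(format(v, digits = 8), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a vulnerability report as JSON
#'
#' The JSON embeds the configuration hash and seeds so published artifacts
#' are traceable.
#'
#' @param report a `vulnerability_report`.
#' @param path output `.json` path.
#' @param config optional `run_config` used for the run (hashed into the
#'   artifact).
#' @param seeds named list of seeds used.
#' @return the path, invisibly.
#' @export
write_vulnerability_report <- function(report, path, config = NULL,
                                       seeds = list()) {
  stopifnot(inherits(report, "vulnerability_report"))
  payload <- list(
    protocol = report$protocol,
    analysis_window_ms = report$analysis_window,
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    seeds = seeds,
    sites = report$sites)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
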