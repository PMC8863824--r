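FORMAT_VERSION <- "1.0"

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write per-frame angle series
#'
#' CSV with columns `cell_id`, `frame`, `increment_deg` (signed degrees per
#' frame).
#'
#' @param angles A data frame of angle increments.
#' @param path File path.
#' @return `read_angle_csv()` returns a tibble; `write_angle_csv()` returns
#'   the path invisibly.
#' @export
write_angle_csv <- function(angles, path) {
  readr::write_csv(angles[c("cell_id", "frame", "increment_deg")], path)
  invisible(path)
}

#' @rdname write_angle_csv
#' @export
read_angle_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_character(),
    frame = readr::col_integer(),
    increment_deg = readr::col_double()))
}

#' Read and write CW-bias traces
#'
#' CSV with columns `t_start`, `cw_bias` (empty cell = missing bin), plus a
#' JSON sidecar (same basename, `.json`) holding `bin_width`,
#' `stimulus_time`, `n_cells` and the format version.
#'
#' @param trace A [cw_trace()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_trace_csv()` returns a [cw_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cw_trace"))
  readr::write_csv(tibble::as_tibble(trace), path, na = "")
  meta <- list(format_version = FORMAT_VERSION,
               bin_width = attr(trace, "bin_width"),
               stimulus_time = attr(trace, "stimulus_time"),
               n_cells = attr(trace, "n_cells"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort(sprintf("sidecar not found: %s", sc))
  tbl <- readr::read_csv(path, na = "", col_types = readr::cols(
    t_start = readr::col_double(), cw_bias = readr::col_double()))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  cw_trace(tbl$t_start, tbl$cw_bias, bin_width = meta$bin_width,
           stimulus_time = meta$stimulus_time,
           n_cells = if (is.null(meta$n_cells)) NA_integer_ else meta$n_cells)
}

#' Read and write characteristic-vector tables
#'
#' CSV with columns `vector_id` (optional), `y1`..`y15`, `label`
#' (`"UNKNOWN"` for blind samples) and `concentration_mM` (empty when
#' unknown).
#'
#' @param vectors A data frame of characteristic vectors.
#' @param path File path.
#' @return `read_vectors_csv()` returns a tibble.
#' @export
write_vectors_csv <- function(vectors, path) {
  validate_vectors(vectors)
  cols <- intersect(c("vector_id", paste0("y", 1:15), "label", "concentration_mM"),
                    names(vectors))
  readr::write_csv(vectors[cols], path, na = "")
  invisible(path)
}

#' @rdname write_vectors_csv
#' @export
read_vectors_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols()))
  spec <- readr::cols(.default = readr::col_double(),
                      label = readr::col_character())
  if ("vector_id" %in% header) {
    spec$cols$vector_id <- readr::col_character()
  }
  tbl <- readr::read_csv(path, na = "", col_types = spec)
  validate_vectors(tbl)
  tbl
}

#' Serialise and restore a model set
#'
#' Single JSON document holding the chemical order, the basis family, the
#' per-(chemical, index) coefficients, sigma and concentration range, the
#' training vectors, and a format-version field.
#'
#' @param models A `model_set`.
#' @param path File path.
#' @return `read_model_set()` returns a `model_set`.
#' @export
write_model_set <- function(models, path) {
  stopifnot(inherits(models, "model_set"))
  doc <- list(format_version = FORMAT_VERSION,
              chemicals = models$chemicals,
              basis = models$basis,
              sigma_floor_frac = models$sigma_floor_frac,
              functions = models$functions,
              training = models$training)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("chemicals", "basis", "functions")) {
    if (is.null(doc[[f]])) abort(sprintf("model-set JSON lacks field `%s` in %s", f, path))
  }
  fns <- tibble::as_tibble(doc$functions)
  if (!"c2" %in% names(fns)) fns$c2 <- NA_real_
  fns$c2 <- as.numeric(fns$c2)
  structure(list(chemicals = doc$chemicals, basis = doc$basis,
                 sigma_floor_frac = doc$sigma_floor_frac,
                 functions = fns,
                 training = tibble::as_tibble(doc$training)),
            class = "model_set")
}

#' Serialise and restore chemical profiles
#'
#' @param profiles A named list of [chemical_profile()]s.
#' @param path File path.
#' @return `read_profiles_json()` returns a named list of profiles.
#' @export
write_profiles_json <- function(profiles, path) {
  doc <- list(format_version = FORMAT_VERSION,
              profiles = purrr::map(profiles, unclass))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  prs <- purrr::map(doc$profiles, function(p) {
    do.call(chemical_profile, p[c("name", "tau0", "beta", "recovery_total",
                                  "recovery_fracs", "recovery_shape",
                                  "overshoot", "conc_range", "cell_cv",
                                  "baseline_mean", "baseline_kappa")])
  })
  names(prs) <- purrr::map_chr(prs, "name")
  prs
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report` from [loo_accuracy()].
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  doc <- c(list(format_version = FORMAT_VERSION), unclass(report))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
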