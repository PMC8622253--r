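# Image and tabular I/O, run configuration, and the batch quantification
# driver behind the command-line interface.

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return Integer `H x W x 3` array with values in 0-255. An alpha channel,
#'   if present, is dropped.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) != 3 || dim(raw)[3] < 3) {
    stop("expected an RGB image: ", path, call. = FALSE)
  }
  raw <- raw[, , 1:3, drop = FALSE]
  array(as.integer(floor(raw * 255 + 0.5)), dim(raw))
}

#' Write an 8-bit RGB array as PNG
#'
#' @param image Integer `H x W x 3` array, values 0-255.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3,
            min(image) >= 0, max(image) <= 255)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet maps image files to tissue cores and patients. Required
#' columns: `patient_id`, `core_id`, `image_path`; optional `include`
#' (logical or 0/1, default `TRUE`). Relative image paths are resolved
#' against the sheet's directory.
#'
#' @param path CSV file path.
#' @param check_files Verify that every included image file exists.
#' @return `data.frame` with the validated rows and resolved `image_path`.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "core_id", "image_path")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(sheet) == 0) stop("sample sheet is empty", call. = FALSE)
  if (is.null(sheet$include)) {
    sheet$include <- TRUE
  } else {
    sheet$include <- as.logical(sheet$include)
    sheet$include[is.na(sheet$include)] <- TRUE
  }
  key <- paste(sheet$patient_id, sheet$core_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rows <- which(key == dup)
    stop("duplicate (patient_id, core_id) in sample sheet rows ",
         paste(rows, collapse = " and "), call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$image_path)
  sheet$image_path[rel] <- file.path(dirname(path), sheet$image_path[rel])
  if (check_files) {
    missing_files <- sheet$image_path[sheet$include & !file.exists(sheet$image_path)]
    if (length(missing_files)) {
      stop("image file(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
  }
  sheet
}

#' Read a follow-up table
#'
#' @param path CSV with columns `patient_id`, `time_months`, `event` (0/1);
#'   missing `time_months` marks patients without a documented recurrence
#'   timepoint (excluded from survival analyses).
#' @return Validated `data.frame`.
#' @export
read_followup <- function(path) {
  if (!file.exists(path)) stop("follow-up table not found: ", path, call. = FALSE)
  fup <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "time_months", "event")
  missing_cols <- setdiff(required, names(fup))
  if (length(missing_cols)) {
    stop("follow-up table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(fup$time_months < 0, na.rm = TRUE)) {
    stop("negative follow-up time", call. = FALSE)
  }
  if (!all(fup$event %in% c(0, 1))) {
    stop("event must be 0 or 1", call. = FALSE)
  }
  fup
}

config_defaults <- function() {
  list(stains = list(hematoxylin = c(0.650, 0.704, 0.286),
                     dab = c(0.269, 0.568, 0.778),
                     background_intensity = 255),
       masking = list(median_radius = 2,
                      border_fraction = 0.05,
                      min_tumor_fraction = 0.01,
                      overlap_mode = "pixel"),
       cutoff = list(value = 1, statistic = "max"))
}

#' Assemble and validate a run configuration
#'
#' Merges user settings over the defaults; unknown sections or keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param config Nested list with any of the sections `stains`
#'   (`hematoxylin`, `dab`, `background_intensity`), `masking`
#'   (`median_radius`, `border_fraction`, `min_tumor_fraction`,
#'   `overlap_mode`) and `cutoff` (`value`, `statistic`).
#' @return List of class `run_config` with `stains` (3x3 matrix),
#'   `background_intensity`, `params` ([masking_params()]) and `cutoff`.
#' @export
run_config <- function(config = list()) {
  defaults <- config_defaults()
  bad_sections <- setdiff(names(config), names(defaults))
  if (length(bad_sections)) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  }
  merged <- defaults
  for (sec in names(config)) {
    bad_keys <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad_keys)) {
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad_keys, collapse = ", "), call. = FALSE)
    }
    merged[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  stopifnot(merged$cutoff$value > 0)
  structure(list(
    stains = build_stain_matrix(unlist(merged$stains$hematoxylin),
                                unlist(merged$stains$dab)),
    background_intensity = merged$stains$background_intensity,
    params = masking_params(merged$masking$median_radius,
                            merged$masking$border_fraction,
                            merged$masking$min_tumor_fraction,
                            merged$masking$overlap_mode),
    cutoff = list(value = merged$cutoff$value,
                  statistic = match.arg(merged$cutoff$statistic,
                                        c("max", "min", "mean", "median")))),
    class = "run_config")
}

#' Read a YAML run configuration file
#'
#' @param path YAML file using the sections documented in [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  run_config(yaml::read_yaml(path))
}

#' Quantify every core of a sample sheet and aggregate per patient
#'
#' Processes each included sample-sheet row through [quantify_core()].
#' Unreadable images do not abort the run: the core appears in the output
#' with `status = "failed"` and is counted in the summary. Writes
#' `cores.csv` (per-core results, TSR rounded to 4 decimals),
#' `patients.csv` (per-patient aggregation and category) and `summary.json`
#' (core/patient counts and exclusions per reason).
#'
#' @param sheet Sample sheet path or `data.frame` from [read_sample_sheet()].
#' @param out_dir Output directory (created if missing).
#' @param config A `run_config` (default: all defaults).
#' @return Invisibly, a list with `cores`, `patients` and `summary`.
#' @export
run_quantify <- function(sheet, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet, check_files = FALSE)
  included <- sheet[sheet$include, , drop = FALSE]
  if (nrow(included) == 0) stop("no included rows in sample sheet", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- lapply(seq_len(nrow(included)), function(i) {
    r <- included[i, ]
    res <- tryCatch({
      img <- read_image(r$image_path)
      cbind(quantify_core(img, config$params, config$stains,
                          config$background_intensity,
                          core_id = as.character(r$core_id),
                          patient_id = as.character(r$patient_id)),
            status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      message("core ", r$core_id, " failed: ", conditionMessage(e))
      data.frame(core_id = as.character(r$core_id),
                 patient_id = as.character(r$patient_id),
                 tumor_area_px = NA_integer_, stroma_area_px = NA_integer_,
                 tsr = NA_real_, four_sides_pass = NA, epcam_negative = NA,
                 empty_stroma = NA, informative = FALSE, status = "failed",
                 stringsAsFactors = FALSE)
    })
    res
  })
  cores <- do.call(rbind, rows)

  patients <- tryCatch(
    aggregate_patients(cores[cores$status == "ok", , drop = FALSE],
                       cutoff = config$cutoff$value,
                       statistic = config$cutoff$statistic),
    error = function(e) NULL)

  ok <- cores$status == "ok"
  summary <- list(
    n_cores_total = nrow(sheet),
    n_cores_included = nrow(included),
    n_cores_failed = sum(!ok),
    n_cores_informative = sum(cores$informative, na.rm = TRUE),
    excluded_by_reason = list(
      technical_failure = sum(!ok),
      four_sides = sum(ok & !cores$four_sides_pass, na.rm = TRUE),
      epcam_negative = sum(ok & cores$epcam_negative, na.rm = TRUE),
      empty_stroma = sum(ok & cores$empty_stroma, na.rm = TRUE)),
    n_patients = length(unique(cores$patient_id)),
    n_patients_informative = if (is.null(patients)) 0L else nrow(patients),
    patients_excluded = if (is.null(patients)) {
      unique(cores$patient_id)
    } else as.list(attr(patients, "excluded_patients")),
    cutoff = config$cutoff)

  cores_out <- cores
  cores_out$tsr <- round(cores_out$tsr, 4)
  utils::write.csv(cores_out, file.path(out_dir, "cores.csv"),
                   row.names = FALSE)
  if (!is.null(patients)) {
    patients_out <- patients
    num <- vapply(patients_out, is.numeric, TRUE)
    patients_out[num] <- lapply(patients_out[num], round, 4)
    utils::write.csv(patients_out, file.path(out_dir, "patients.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cores = cores, patients = patients, summary = summary))
}
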