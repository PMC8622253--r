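# Per-core TSR computation, patient-level aggregation and dichotomization.

#' Tumor-to-stroma ratio of two binary masks
#'
#' @param tumor,stroma Disjoint logical masks of identical shape.
#' @return `tumor area / stroma area`, or `NA` when the stroma mask is empty
#'   (undefined TSR; the core is marked non-informative downstream).
#' @export
compute_tsr <- function(tumor, stroma) {
  stopifnot(is.logical(tumor), is.logical(stroma))
  if (!identical(dim(tumor), dim(stroma))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  if (any(tumor & stroma)) {
    stop("tumor and stroma masks overlap; apply exclude_overlap() first",
         call. = FALSE)
  }
  sa <- sum(stroma)
  if (sa == 0) return(NA_real_)
  sum(tumor) / sa
}

#' Quantify the TSR of a single tissue-core image
#'
#' Runs the full per-core pipeline: color deconvolution of the RGB image into
#' hematoxylin and DAB channels, median filtering of each 8-bit channel,
#' Tsai moment-preserving thresholding of the DAB channel (tumor mask),
#' Otsu thresholding of the hematoxylin channel (stroma mask), removal of
#' stroma overlapping tumor, QC flags, and the tumor/stroma area ratio.
#' A channel with no gray-level variation (e.g. a render without any DAB) is
#' treated as unstained and yields an empty mask, since a histogram threshold
#' cannot separate a single level.
#'
#' @param image `H x W x 3` 8-bit RGB array (see [read_image()]).
#' @param params [masking_params()].
#' @param stains 3x3 stain matrix, default [hdab_stain_matrix()].
#' @param background_intensity Incident intensity `I0` for the
#'   optical-density conversion.
#' @param core_id,patient_id Optional identifiers carried into the result.
#' @return A one-row `data.frame` with columns `core_id`, `patient_id`,
#'   `tumor_area_px`, `stroma_area_px`, `tsr`, `four_sides_pass`,
#'   `epcam_negative`, `empty_stroma`, `informative`. `tsr` is `NA` for
#'   non-informative cores.
#' @export
quantify_core <- function(image,
                          params = masking_params(),
                          stains = hdab_stain_matrix(),
                          background_intensity = 255,
                          core_id = NA_character_,
                          patient_id = NA_character_) {
  stopifnot(inherits(params, "masking_params"))
  od <- rgb_to_od(image, background_intensity)
  conc <- deconvolve(od, stains)

  stain_mask <- function(concentration, threshold_fun) {
    ch <- to_channel_image(concentration)
    ch <- median_filter(ch, params$median_radius)
    if (diff(range(ch)) == 0L) {
      return(matrix(FALSE, nrow(ch), ncol(ch)))  # unstained channel
    }
    t <- threshold_fun(channel_histogram(ch))
    apply_threshold(ch, t)
  }

  tumor <- stain_mask(conc$dab, moments_threshold)
  stroma_raw <- stain_mask(conc$hematoxylin, otsu_threshold)
  stroma <- exclude_overlap(stroma_raw, tumor, params$overlap_mode)

  four_sides <- four_sides_qc(tumor, params$border_fraction)
  epcam_neg <- epcam_negativity_flag(tumor, params$min_tumor_fraction)
  empty_stroma <- sum(stroma) == 0
  informative <- four_sides && !epcam_neg && !empty_stroma

  data.frame(core_id = core_id,
             patient_id = patient_id,
             tumor_area_px = sum(tumor),
             stroma_area_px = sum(stroma),
             tsr = if (informative) compute_tsr(tumor, stroma) else NA_real_,
             four_sides_pass = four_sides,
             epcam_negative = epcam_neg,
             empty_stroma = empty_stroma,
             informative = informative,
             stringsAsFactors = FALSE)
}

#' Dichotomize TSR values at a cut-off
#'
#' @param tsr Numeric vector of TSR values.
#' @param cutoff Cut-off value; scores strictly below it are `"low"`, scores
#'   at or above it (boundary included) are `"high"`.
#' @return Factor with levels `low`, `high`.
#' @export
categorize_tsr <- function(tsr, cutoff = 1) {
  stopifnot(is.numeric(tsr), cutoff > 0)
  factor(ifelse(tsr < cutoff, "low", "high"), levels = c("low", "high"))
}

#' Aggregate per-core TSR values to patient level
#'
#' Only informative cores contribute. Minimal and maximal (plus mean and
#' median) TSR are recorded per patient; a patient with a single informative
#' core gets that core's value for all statistics. The chosen statistic
#' (default: the maximum) is dichotomized at `cutoff` into a low/high
#' category. Patients with no informative core are excluded from the result
#' and reported in the `excluded_patients` attribute.
#'
#' @param cores `data.frame` of per-core results as returned by
#'   [quantify_core()] (rows may come from several patients).
#' @param cutoff Dichotomization cut-off (default 1).
#' @param statistic Which per-patient statistic is categorized: `"max"`
#'   (default), `"min"`, `"mean"` or `"median"`.
#' @return `data.frame` with columns `patient_id`, `n_informative_cores`,
#'   `tsr_min`, `tsr_max`, `tsr_mean`, `tsr_median`, `category`; attribute
#'   `excluded_patients` lists patient ids with zero informative cores.
#' @export
aggregate_patients <- function(cores, cutoff = 1,
                               statistic = c("max", "min", "mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(cores),
            all(c("patient_id", "tsr", "informative") %in% names(cores)))
  ok <- cores[cores$informative & !is.na(cores$tsr), , drop = FALSE]
  excluded <- setdiff(unique(cores$patient_id), unique(ok$patient_id))
  if (length(excluded)) {
    message(length(excluded), " patient(s) without informative cores excluded: ",
            paste(excluded, collapse = ", "))
  }
  if (nrow(ok) == 0) {
    stop("no informative cores: nothing to aggregate", call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(ok, ok$patient_id), function(g) {
    data.frame(patient_id = g$patient_id[1],
               n_informative_cores = nrow(g),
               tsr_min = min(g$tsr),
               tsr_max = max(g$tsr),
               tsr_mean = mean(g$tsr),
               tsr_median = stats::median(g$tsr),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  stat_col <- paste0("tsr_", statistic)
  agg$category <- categorize_tsr(agg[[stat_col]], cutoff)
  attr(agg, "excluded_patients") <- excluded
  agg
}
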