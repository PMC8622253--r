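# Synthetic H-DAB histology rendering with known tumor/stroma/lumen ground
# truth, and cohort simulation with TSR-dependent hazards. Together these
# provide an end-to-end validation path for the pipeline in the absence of
# clinical slide scans.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

LABEL_TUMOR <- 1L
LABEL_STROMA <- 2L
LABEL_LUMEN <- 3L

# Paint elliptical glands (tumor ring around a central lumen) over a stroma
# background at a given global size scale.
paint_glands <- function(h, w, centers, axes, angles, lumen_fraction, scale) {
  labels <- matrix(LABEL_STROMA, h, w)
  row_g <- matrix(seq_len(h), h, w)
  col_g <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    a <- axes[i, 1] * scale
    b <- axes[i, 2] * scale
    th <- angles[i]
    dy <- row_g - centers[i, 1]
    dx <- col_g - centers[i, 2]
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    q <- u^2 + v^2
    labels[q <= 1] <- LABEL_TUMOR
    labels[q <= lumen_fraction] <- LABEL_LUMEN
  }
  labels
}

#' Generate a synthetic tissue layout with a known tumor/stroma ratio
#'
#' Places elliptical "glands" (tumor rings with central lumina, mimicking
#' prostatic gland architecture) on a stroma background. Four glands are
#' anchored at the edge midpoints so informative layouts satisfy the
#' four-sides criterion; the rest are placed at seeded random positions.
#' Gland size is adjusted by bisection until the realized tumor/stroma area
#' ratio is within 5% of `target_ratio`.
#'
#' @param height,width Canvas size in pixels (>= 64).
#' @param target_ratio Intended tumor-area / stroma-area ratio, in
#'   [0.02, 50].
#' @param gland_count Number of glands (>= 4).
#' @param lumen_fraction Fraction of each gland's area occupied by the
#'   central lumen.
#' @param seed Integer seed; layouts are reproducible per seed.
#' @return List of class `tissue_layout` with `labels` (integer matrix,
#'   1 = tumor, 2 = stroma, 3 = lumen), `target_ratio`, `realized_ratio`,
#'   and `seed`.
#' @export
make_layout <- function(height = 256, width = 256, target_ratio = 1,
                        gland_count = 12, lumen_fraction = 0.15, seed = 1) {
  stopifnot(height >= 64, width >= 64, gland_count >= 4,
            lumen_fraction >= 0, lumen_fraction < 1)
  if (target_ratio > 50 || target_ratio < 0.02) {
    stop("target_ratio outside the renderable range [0.02, 50]", call. = FALSE)
  }
  with_seed(seed, {
    # initial gland area from the disjoint-gland approximation:
    # tumor = (1 - lumen) * G, stroma = canvas - G
    canvas <- height * width
    g_total <- target_ratio * canvas / (1 - lumen_fraction + target_ratio)
    g_each <- g_total / gland_count
    base_r <- sqrt(g_each / pi)

    centers <- rbind(
      c(1, width / 2), c(height, width / 2),      # north, south
      c(height / 2, 1), c(height / 2, width),     # west, east
      cbind(stats::runif(gland_count - 4, 1, height),
            stats::runif(gland_count - 4, 1, width)))
    aspect <- stats::runif(gland_count, 0.6, 1)
    size <- stats::runif(gland_count, 0.8, 1.2)
    axes <- cbind(base_r * size / sqrt(aspect), base_r * size * sqrt(aspect))
    angles <- stats::runif(gland_count, 0, pi)

    ratio_at <- function(s) {
      lab <- paint_glands(height, width, centers, axes, angles,
                          lumen_fraction, s)
      sum(lab == LABEL_TUMOR) / max(sum(lab == LABEL_STROMA), 1)
    }
    lo <- 0.2; hi <- 1.0
    while (ratio_at(hi) < target_ratio && hi < 64) hi <- hi * 1.5
    if (ratio_at(hi) < target_ratio || ratio_at(lo) > target_ratio) {
      stop("target_ratio infeasible for this canvas", call. = FALSE)
    }
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      r <- ratio_at(mid)
      if (abs(r / target_ratio - 1) <= 0.02) { lo <- hi <- mid; break }
      if (r < target_ratio) lo <- mid else hi <- mid
    }
    s <- (lo + hi) / 2
    labels <- paint_glands(height, width, centers, axes, angles,
                           lumen_fraction, s)
    realized <- sum(labels == LABEL_TUMOR) / sum(labels == LABEL_STROMA)
    if (abs(realized / target_ratio - 1) > 0.05) {
      stop("could not realize target_ratio within 5%", call. = FALSE)
    }
    structure(list(labels = labels, target_ratio = target_ratio,
                   realized_ratio = realized, seed = seed),
              class = "tissue_layout")
  })
}

#' Rendering parameters for synthetic H-DAB images
#'
#' @param dab_od_amplitude DAB optical density in tumor pixels.
#' @param hema_od_amplitude Hematoxylin optical density in stroma pixels.
#' @param hema_background_in_tumor Hematoxylin counterstain OD in tumor.
#' @param noise_sd Standard deviation of additive Gaussian noise in OD space
#'   (multiplicative in intensity).
#' @param seed Integer seed for the noise stream, or `NULL`.
#' @return List of class `render_params`.
#' @export
render_params <- function(dab_od_amplitude = 1.0,
                          hema_od_amplitude = 0.7,
                          hema_background_in_tumor = 0.2,
                          noise_sd = 0.05,
                          seed = NULL) {
  stopifnot(dab_od_amplitude >= 0, hema_od_amplitude >= 0,
            hema_background_in_tumor >= 0, noise_sd >= 0)
  structure(list(dab_od_amplitude = dab_od_amplitude,
                 hema_od_amplitude = hema_od_amplitude,
                 hema_background_in_tumor = hema_background_in_tumor,
                 noise_sd = noise_sd, seed = seed),
            class = "render_params")
}

#' Render a tissue layout as an 8-bit RGB brightfield image
#'
#' Forward Beer-Lambert model, the inverse of the deconvolution path:
#' per pixel `OD = c_h * hema_row + c_d * dab_row` with class-dependent
#' concentrations (tumor: DAB plus a light hematoxylin counterstain; stroma:
#' hematoxylin only; lumen: unstained, near-white), plus optional Gaussian
#' OD noise, then `RGB = round(255 * 10^-OD)` clamped to 0-255.
#'
#' @param layout A `tissue_layout` from [make_layout()].
#' @param params [render_params()].
#' @param stains 3x3 stain matrix, default [hdab_stain_matrix()].
#' @return Integer `H x W x 3` RGB array.
#' @export
render_ihc <- function(layout, params = render_params(),
                       stains = hdab_stain_matrix()) {
  stopifnot(inherits(layout, "tissue_layout"), inherits(params, "render_params"))
  lab <- layout$labels
  c_h <- matrix(0, nrow(lab), ncol(lab))
  c_d <- matrix(0, nrow(lab), ncol(lab))
  c_h[lab == LABEL_STROMA] <- params$hema_od_amplitude
  c_h[lab == LABEL_TUMOR] <- params$hema_background_in_tumor
  c_d[lab == LABEL_TUMOR] <- params$dab_od_amplitude
  od <- array(0, c(nrow(lab), ncol(lab), 3))
  for (k in 1:3) {
    od[, , k] <- c_h * stains["hematoxylin", k] + c_d * stains["dab", k]
  }
  if (params$noise_sd > 0) {
    od <- od + with_seed(params$seed,
                         array(stats::rnorm(length(od), 0, params$noise_sd),
                               dim(od)))
  }
  img <- floor(255 * 10^(-od) + 0.5)
  img[img < 0] <- 0
  img[img > 255] <- 255
  array(as.integer(img), dim(od))
}

#' Ground-truth masks of a tissue layout
#'
#' @param layout A `tissue_layout`.
#' @return List with logical matrices `tumor`, `stroma`, `lumen`.
#' @export
layout_masks <- function(layout) {
  stopifnot(inherits(layout, "tissue_layout"))
  list(tumor = layout$labels == LABEL_TUMOR,
       stroma = layout$labels == LABEL_STROMA,
       lumen = layout$labels == LABEL_LUMEN)
}

#' Simulate a patient cohort with TSR-dependent recurrence hazards
#'
#' Draws a log-normal latent TSR per patient and jittered per-core values
#' around it, dichotomizes the per-patient maximum at `cutoff`, then draws
#' exponential times to biochemical recurrence with the high-TSR hazard
#' `hazard_ratio` times the low-TSR hazard. The baseline hazard is calibrated
#' so the expected overall event fraction before the administrative censoring
#' horizon equals `event_rate`.
#'
#' Defaults mirror a validation-scale prostatectomy cohort: per-core TSR
#' median about 2.14 with roughly 23% of patients below a cut-off of 1,
#' about 20.6% biochemical recurrences, and up to 17 years of follow-up.
#'
#' @param n_patients Number of patients (>= 2).
#' @param cores_per_patient Tissue cores per patient.
#' @param tsr_meanlog,tsr_sdlog Log-normal parameters of the latent
#'   per-patient TSR.
#' @param core_sdlog Log-scale SD of the per-core jitter around the latent
#'   value (within-patient variability).
#' @param cutoff Dichotomization cut-off.
#' @param hazard_ratio Recurrence hazard ratio, high vs low TSR (> 0).
#' @param event_rate Target overall event fraction by the horizon.
#' @param followup_horizon Administrative censoring time (months).
#' @param seed Integer seed; cohorts are reproducible per seed.
#' @return List of class `simulated_cohort` with `patients` (patient_id,
#'   tsr_max, category), `cores` (patient_id, core_id, true_tsr) and
#'   `survival` (patient_id, time_months, event).
#' @export
simulate_cohort <- function(n_patients = 209,
                            cores_per_patient = 2,
                            tsr_meanlog = log(2.14),
                            tsr_sdlog = 1.03,
                            core_sdlog = 0.2,
                            cutoff = 1,
                            hazard_ratio = 2.75,
                            event_rate = 0.206,
                            followup_horizon = 204,
                            seed = 1) {
  stopifnot(n_patients >= 2, cores_per_patient >= 1, hazard_ratio > 0,
            event_rate > 0, event_rate < 1, followup_horizon > 0)
  with_seed(seed, {
    pid <- sprintf("P%04d", seq_len(n_patients))
    latent <- stats::rlnorm(n_patients, tsr_meanlog, tsr_sdlog)
    cores <- data.frame(
      patient_id = rep(pid, each = cores_per_patient),
      core_id = paste0(rep(pid, each = cores_per_patient), "_c",
                       rep(seq_len(cores_per_patient), n_patients)),
      true_tsr = rep(latent, each = cores_per_patient) *
        stats::rlnorm(n_patients * cores_per_patient, 0, core_sdlog),
      stringsAsFactors = FALSE)
    tsr_max <- vapply(split(cores$true_tsr, cores$patient_id), max, 0)[pid]
    category <- categorize_tsr(tsr_max, cutoff)

    # calibrate the low-TSR hazard so the expected event fraction by the
    # horizon matches event_rate for this cohort's category mix
    high <- category == "high"
    pfun <- function(lam) {
      mean(1 - exp(-ifelse(high, lam * hazard_ratio, lam) * followup_horizon)) -
        event_rate
    }
    lam_low <- stats::uniroot(pfun, c(1e-9, 1), tol = 1e-12)$root
    rate <- ifelse(high, lam_low * hazard_ratio, lam_low)
    t_event <- stats::rexp(n_patients, rate)
    survival <- data.frame(patient_id = pid,
                           time_months = pmin(t_event, followup_horizon),
                           event = as.integer(t_event <= followup_horizon),
                           stringsAsFactors = FALSE)
    structure(list(patients = data.frame(patient_id = pid,
                                         tsr_max = unname(tsr_max),
                                         category = category,
                                         stringsAsFactors = FALSE),
                   cores = cores,
                   survival = survival,
                   hazard_ratio_high_vs_low = hazard_ratio,
                   seed = seed),
              class = "simulated_cohort")
  })
}

#' Write a complete synthetic image dataset to disk
#'
#' Renders one image per core of a small simulated cohort (core ratios are
#' clamped to the renderable range), writing PNG images, ground-truth label
#' masks, a sample sheet, a truth table and a follow-up table — everything
#' [run_quantify()] and [survival_report()] need for an end-to-end run.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_patients,cores_per_patient Cohort size.
#' @param size Image side length in pixels.
#' @param noise_sd Render noise (OD units).
#' @param hazard_ratio,event_rate,followup_horizon See [simulate_cohort()].
#' @param seed Integer seed.
#' @return Invisibly, a list with the written file paths and the cohort.
#' @export
simulate_dataset <- function(out_dir, n_patients = 5, cores_per_patient = 2,
                             size = 192, noise_sd = 0.05,
                             hazard_ratio = 2.75, event_rate = 0.206,
                             followup_horizon = 204, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n_patients = n_patients,
                            cores_per_patient = cores_per_patient,
                            hazard_ratio = hazard_ratio,
                            event_rate = event_rate,
                            followup_horizon = followup_horizon,
                            seed = seed)
  cores <- cohort$cores
  cores$render_ratio <- pmin(pmax(cores$true_tsr, 0.05), 20)
  sheet <- data.frame(patient_id = cores$patient_id,
                      core_id = cores$core_id,
                      image_path = paste0(cores$core_id, ".png"),
                      include = TRUE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cores))) {
    lay <- make_layout(size, size, cores$render_ratio[i],
                       seed = seed * 10000L + i)
    img <- render_ihc(lay, render_params(noise_sd = noise_sd,
                                         seed = seed * 10000L + i))
    write_image(img, file.path(out_dir, sheet$image_path[i]))
    png::writePNG((lay$labels - 1) / 2,
                  file.path(out_dir, paste0(cores$core_id[i], "_labels.png")))
  }
  sheet_path <- file.path(out_dir, "cores.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  fup_path <- file.path(out_dir, "followup.csv")
  utils::write.csv(sheet, sheet_path, row.names = FALSE)
  utils::write.csv(cores[, c("core_id", "patient_id", "true_tsr",
                             "render_ratio")],
                   truth_path, row.names = FALSE)
  utils::write.csv(cohort$survival, fup_path, row.names = FALSE)
  invisible(list(sheet = sheet_path, truth = truth_path, followup = fup_path,
                 dir = out_dir, cohort = cohort))
}
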