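# Binary tumor/stroma mask construction: median filtering, automatic
# histogram thresholding (Otsu, Tsai moments), overlap exclusion and the
# per-core informativeness (QC) flags.

#' Masking parameters
#'
#' Bundles the tunable parameters of the masking stage.
#'
#' @param median_radius Radius (pixels) of the disc-shaped median filter
#'   applied to each stain channel before thresholding; 0 disables filtering.
#' @param border_fraction Fraction of each image dimension defining the four
#'   edge bands of the four-sides informativeness criterion.
#' @param min_tumor_fraction Minimal tumor-mask area fraction below which a
#'   core is flagged EpCAM-negative and routed to manual scoring.
#' @param overlap_mode How stroma pixels overlapping the tumor mask are
#'   removed: `"pixel"` subtracts overlapping pixels; `"component"` removes
#'   every 8-connected stroma component that touches the tumor mask.
#' @return A list of class `masking_params`.
#' @export
masking_params <- function(median_radius = 2,
                           border_fraction = 0.05,
                           min_tumor_fraction = 0.01,
                           overlap_mode = c("pixel", "component")) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(median_radius >= 0,
            border_fraction > 0, border_fraction <= 0.5,
            min_tumor_fraction >= 0, min_tumor_fraction < 1)
  structure(list(median_radius = median_radius,
                 border_fraction = border_fraction,
                 min_tumor_fraction = min_tumor_fraction,
                 overlap_mode = overlap_mode),
            class = "masking_params")
}

# Reflect-pad a matrix by `r` pixels on each side (edge row/column included).
pad_reflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(r < h, r < w)
  ri <- c(r:1, seq_len(h), h:(h - r + 1))
  ci <- c(r:1, seq_len(w), w:(w - r + 1))
  if (r == 0) return(m)
  m[ri, ci]
}

#' Median filter with a disc-shaped neighborhood
#'
#' Replaces each pixel by the median of its disc neighborhood of the given
#' radius (offsets with `dx^2 + dy^2 <= radius^2`); image borders are handled
#' by reflection. Radius 0 returns the input unchanged.
#'
#' @param channel Integer `H x W` matrix (8-bit channel).
#' @param radius Neighborhood radius in pixels.
#' @return Filtered integer matrix of the same shape.
#' @export
median_filter <- function(channel, radius = 2) {
  stopifnot(is.matrix(channel), is.numeric(channel), radius >= 0)
  r <- as.integer(floor(radius))
  if (r == 0L) return(channel)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, , drop = FALSE]
  h <- nrow(channel); w <- ncol(channel)
  p <- pad_reflect(channel, r)
  k <- nrow(offs)
  stack <- matrix(0, h * w, k)
  for (i in seq_len(k)) {
    stack[, i] <- p[(r + 1 + offs$dy[i]):(r + h + offs$dy[i]),
                    (r + 1 + offs$dx[i]):(r + w + offs$dx[i])]
  }
  # disc neighborhoods are symmetric around the center pixel, so k is odd
  # and the median of integers is an integer
  med <- apply(stack, 1, stats::median.default)
  matrix(as.integer(med), h, w)
}

#' 256-bin histogram of an 8-bit channel
#'
#' @param channel Integer matrix with values in 0-255.
#' @return Integer vector of 256 counts for gray levels 0..255.
#' @export
channel_histogram <- function(channel) {
  stopifnot(is.numeric(channel), all(channel >= 0), all(channel <= 255))
  tabulate(as.integer(channel) + 1L, nbins = 256L)
}

check_histogram <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) == 256,
            all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) <= 0) stop("empty histogram", call. = FALSE)
  invisible(counts)
}

#' Otsu's automatic threshold
#'
#' Returns the gray level `t` maximizing the between-class variance of the
#' split into classes `<= t` and `> t`. Ties are broken towards the smallest
#' `t` (objectives within a relative 1e-10 of the maximum count as tied, so
#' floating-point noise cannot break mathematically flat regions); a
#' histogram with all mass in one bin returns that bin's gray level.
#'
#' @param counts 256-bin histogram (see [channel_histogram()]).
#' @return Integer threshold in 0-255.
#' @references Otsu, N. (1979) A threshold selection method from gray-level
#'   histograms. IEEE Trans. Syst. Man Cybern. 9(1), 62-66.
#' @export
otsu_threshold <- function(counts) {
  check_histogram(counts)
  nz <- which(counts > 0)
  if (length(nz) == 1L) return(nz - 1L)
  z <- 0:255
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * z)
  mu_t <- mu_cum[256]
  sb <- (mu_t * w0 - mu_cum)^2 / (w0 * (1 - w0))
  sb[w0 <= 0 | w0 >= 1] <- -Inf
  mx <- max(sb)
  as.integer(which(sb >= mx - abs(mx) * 1e-10)[1] - 1L)
}

#' Tsai's moment-preserving automatic threshold
#'
#' Computes the first three gray-level moments of the histogram, solves for
#' the two-level distribution preserving them, and returns the gray level at
#' which the cumulative histogram fraction first reaches the darker class
#' fraction `p0`.
#'
#' @param counts 256-bin histogram (see [channel_histogram()]).
#' @return Integer threshold in 0-255.
#' @references Tsai, W.-H. (1985) Moment-preserving thresholding: a new
#'   approach. Computer Vision, Graphics, and Image Processing 29, 377-393.
#' @export
moments_threshold <- function(counts) {
  check_histogram(counts)
  nz <- which(counts > 0)
  if (length(nz) == 1L) return(nz - 1L)
  z <- 0:255
  p <- counts / sum(counts)
  m1 <- sum(p * z)
  m2 <- sum(p * z^2)
  m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  if (cd <= .Machine$double.eps * m2) return(nz[1] - 1L)
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0  # numerically degenerate near-single-level case
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)  # fraction of the darker class
  cum <- cumsum(p)
  as.integer(min(which(cum >= p0 - 1e-12)) - 1L)
}

#' Binarize a channel at a threshold
#'
#' Stain-positive pixels are dark in the pseudo-transmittance channels, so
#' the mask is true where `value <= t`.
#'
#' @param channel Integer `H x W` matrix with values in 0-255.
#' @param t Threshold in 0-255.
#' @return Logical `H x W` mask.
#' @export
apply_threshold <- function(channel, t) {
  stopifnot(is.numeric(channel), length(t) == 1, t >= 0, t <= 255)
  channel <= t
}

# 8-connected component labels of a logical mask by iterated minimum-label
# propagation; 0 marks background. Convergence takes at most the longest
# geodesic path within a component.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- which(mask)
  if (!any(mask)) return(lab)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  big <- .Machine$integer.max
  repeat {
    cur <- lab
    m <- matrix(big, h + 2, w + 2)
    tmp <- lab
    tmp[!mask] <- big
    m[2:(h + 1), 2:(w + 1)] <- tmp
    best <- tmp
    for (i in seq_len(nrow(shifts))) {
      nb <- m[(2 + shifts$dy[i]):(h + 1 + shifts$dy[i]),
              (2 + shifts$dx[i]):(w + 1 + shifts$dx[i])]
      best <- pmin(best, nb)
    }
    lab[mask] <- best[mask]
    if (identical(lab, cur)) break
  }
  lab
}

#' Remove stroma pixels or regions overlapping the tumor mask
#'
#' Only stroma not overlapping tumor is considered valid. In `"pixel"` mode
#' overlapping pixels are subtracted (`stroma & !tumor`); in `"component"`
#' mode every 8-connected stroma component sharing at least one pixel with
#' the tumor mask is removed entirely. Both modes return a mask disjoint
#' from the tumor mask.
#'
#' @param stroma,tumor Logical masks of identical shape.
#' @param mode `"pixel"` (default) or `"component"`.
#' @return Logical mask of valid stroma.
#' @export
exclude_overlap <- function(stroma, tumor, mode = c("pixel", "component")) {
  mode <- match.arg(mode)
  stopifnot(is.logical(stroma), is.logical(tumor))
  if (!identical(dim(stroma), dim(tumor))) {
    stop("stroma and tumor masks must have the same shape", call. = FALSE)
  }
  if (mode == "pixel") return(stroma & !tumor)
  lab <- label_components(stroma)
  bad <- unique(lab[stroma & tumor])
  out <- stroma
  if (length(bad)) out[lab %in% bad] <- FALSE
  out & !tumor
}

#' Four-sides informativeness criterion
#'
#' A core is informative only if tumor is present at all four sides of the
#' field of view. Operationalized as: the tumor mask has at least one true
#' pixel in each of the four edge bands of width
#' `ceiling(border_fraction * dimension)`.
#'
#' @param tumor Logical tumor mask.
#' @param border_fraction Relative width of the edge bands, in (0, 0.5].
#' @return `TRUE` if all four bands contain tumor.
#' @export
four_sides_qc <- function(tumor, border_fraction = 0.05) {
  stopifnot(is.logical(tumor), is.matrix(tumor),
            border_fraction > 0, border_fraction <= 0.5)
  h <- nrow(tumor); w <- ncol(tumor)
  bh <- ceiling(border_fraction * h)
  bw <- ceiling(border_fraction * w)
  any(tumor[seq_len(bh), ]) &&                 # north
    any(tumor[(h - bh + 1):h, ]) &&            # south
    any(tumor[, seq_len(bw)]) &&               # west
    any(tumor[, (w - bw + 1):w])               # east
}

#' EpCAM-negativity flag
#'
#' Tumors with (nearly) no DAB signal cannot be auto-scored; they are
#' flagged when the tumor-mask area fraction falls strictly below
#' `min_tumor_fraction` and routed to manual TSR entry.
#'
#' @param tumor Logical tumor mask.
#' @param min_tumor_fraction Area-fraction cutoff in [0, 1).
#' @return `TRUE` if the core is flagged EpCAM-negative.
#' @export
epcam_negativity_flag <- function(tumor, min_tumor_fraction = 0.01) {
  stopifnot(is.logical(tumor), min_tumor_fraction >= 0, min_tumor_fraction < 1)
  mean(tumor) < min_tumor_fraction
}
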