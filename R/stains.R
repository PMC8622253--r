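# Stain separation: Beer-Lambert conversion to optical density and
# Ruifrok-Johnston color deconvolution into per-stain concentration maps.

#' Build a 3x3 stain matrix from two stain vectors
#'
#' Assembles the optical-density basis used for color deconvolution. Rows 1
#' and 2 are the unit-normalized hematoxylin and DAB absorption vectors; row
#' 3 (the residual channel) is their unit-normalized cross product, so the
#' basis is always invertible for non-collinear inputs.
#'
#' @param hema_vector Numeric length-3 absorption vector (R, G, B optical
#'   densities) for hematoxylin.
#' @param dab_vector Numeric length-3 absorption vector for DAB.
#' @return A 3x3 numeric matrix with rows `hematoxylin`, `dab`, `residual`,
#'   each of unit Euclidean norm.
#' @seealso [hdab_stain_matrix()] for the default H-DAB basis.
#' @examples
#' build_stain_matrix(c(1, 0, 0), c(0, 1, 0))
#' @export
build_stain_matrix <- function(hema_vector, dab_vector) {
  stopifnot(is.numeric(hema_vector), length(hema_vector) == 3,
            is.numeric(dab_vector), length(dab_vector) == 3,
            all(is.finite(hema_vector)), all(is.finite(dab_vector)))
  nh <- sqrt(sum(hema_vector^2))
  nd <- sqrt(sum(dab_vector^2))
  if (nh == 0 || nd == 0) {
    stop("stain vectors must be non-zero", call. = FALSE)
  }
  h <- hema_vector / nh
  d <- dab_vector / nd
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) {
    stop("singular stain basis: hematoxylin and DAB vectors are collinear",
         call. = FALSE)
  }
  m <- rbind(hematoxylin = h, dab = d, residual = r / nr)
  colnames(m) <- c("red", "green", "blue")
  m
}

#' Default H-DAB stain matrix
#'
#' The hematoxylin and DAB absorption vectors of the standard H-DAB preset
#' used by common color-deconvolution implementations: hematoxylin
#' (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778), completed with their
#' cross product as the residual channel.
#'
#' @param hema,dab Optional replacement absorption vectors.
#' @return A 3x3 stain matrix; see [build_stain_matrix()].
#' @export
hdab_stain_matrix <- function(hema = c(0.650, 0.704, 0.286),
                              dab = c(0.269, 0.568, 0.778)) {
  build_stain_matrix(hema, dab)
}

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert relation `OD = -log10(I / I0)` channel-wise.
#' Intensities are floored at 1 before taking the logarithm so fully black
#' pixels map to a finite maximal density rather than infinity.
#'
#' @param image Integer-valued `H x W x 3` array with values in 0-255.
#' @param background_intensity The incident (white) intensity `I0`,
#'   in (0, 255]; default 255.
#' @return An `H x W x 3` numeric array of optical densities (all >= 0),
#'   with the `background_intensity` used stored as an attribute.
#' @examples
#' img <- array(255L, c(2, 2, 3))
#' rgb_to_od(img)  # zero absorption everywhere
#' @export
rgb_to_od <- function(image, background_intensity = 255) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (!is.numeric(image) || anyNA(image) ||
      min(image) < 0 || max(image) > 255 || any(image != round(image))) {
    stop("expected 8-bit intensities: integers in [0, 255]", call. = FALSE)
  }
  stopifnot(is.numeric(background_intensity), length(background_intensity) == 1,
            background_intensity > 0, background_intensity <= 255)
  od <- -log10(pmax(image, 1) / background_intensity)
  od[od < 0] <- 0  # guards I > I0 when a darker background is configured
  attr(od, "background_intensity") <- background_intensity
  od
}

#' Unmix an optical-density image into stain concentration maps
#'
#' Solves the per-pixel linear system `OD = c %*% stains` exactly, yielding
#' the contribution of each stain to the observed optical density. Small
#' negative concentrations can occur in noisy pixels and are preserved.
#'
#' @param od `H x W x 3` optical-density array, e.g. from [rgb_to_od()].
#' @param stains 3x3 stain matrix from [build_stain_matrix()].
#' @return A list with `H x W` numeric matrices `hematoxylin`, `dab`,
#'   `residual`.
#' @export
deconvolve <- function(od, stains) {
  if (!is.array(od) || length(dim(od)) != 3 || dim(od)[3] != 3) {
    stop("expected an H x W x 3 optical-density array", call. = FALSE)
  }
  stopifnot(is.matrix(stains), all(dim(stains) == c(3, 3)))
  if (!all(is.finite(od))) stop("optical densities must be finite", call. = FALSE)
  inv <- tryCatch(solve(stains),
                  error = function(e) stop("singular stain matrix", call. = FALSE))
  d <- dim(od)
  conc <- matrix(od, ncol = 3) %*% inv
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       dab         = matrix(conc[, 2], d[1], d[2]),
       residual    = matrix(conc[, 3], d[1], d[2]))
}

#' Render a concentration map as an 8-bit pseudo-transmittance channel
#'
#' Converts stain amounts back to displayable intensities by
#' `round(255 * 10^(-c))`, clamped to 0-255: zero concentration maps to 255
#' (white, no stain), heavy stain maps towards 0 (dark). Automatic
#' thresholding operates on these 8-bit channels.
#'
#' @param concentration `H x W` numeric matrix of stain amounts.
#' @return Integer matrix with values in 0-255.
#' @export
to_channel_image <- function(concentration) {
  stopifnot(is.numeric(concentration))
  if (!all(is.finite(concentration))) {
    stop("concentration field must be finite", call. = FALSE)
  }
  v <- floor(255 * 10^(-concentration) + 0.5)
  v <- pmin(pmax(v, 0), 255)
  out <- matrix(as.integer(v), nrow(concentration), ncol(concentration))
  out
}
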