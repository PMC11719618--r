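#' Specification of a synthetic whole-colony image
#'
#' Describes a colony as a filled disc (the central colony mass) plus
#' straight radial filaments rendered as rectangles anchored on the disc
#' boundary, on a darker agar background. With `noise_sd = 0` the
#' rendered image is a deterministic function of the spec, and the
#' inner/outer areas of the rendered mask are known exactly by pixel
#' counting, which makes the spec usable as segmentation ground truth.
#'
#' @param image_width,image_height image dimensions in pixels.
#' @param center numeric length-2, colony center `(x, y)` in 0-based pixel
#'   coordinates. Defaults to the image center.
#' @param inner_radius disc radius in pixels (> 0).
#' @param filaments a data frame (or 3-column matrix) with columns
#'   `angle` (radians), `length` (pixels, extent beyond the disc
#'   boundary, >= 0) and `width` (pixels, >= 1 and < `inner_radius`).
#'   `NULL` means a bare disc.
#' @param foreground_level,background_level colony and agar intensities on
#'   the 0--255 scale; the colony must be brighter than the agar
#'   (use `invert = TRUE` in [render_colony()] for dark-colony rendering).
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units; 0 disables noise).
#' @param seed integer seed controlling the noise draw, or `NULL`.
#' @return an object of class `colony_spec`.
#' @seealso [render_colony()], [radial_filaments()], [spec_for_f()]
#' @export
colony_spec <- function(image_width, image_height,
                        center = c((image_width - 1) / 2, (image_height - 1) / 2),
                        inner_radius,
                        filaments = NULL,
                        foreground_level = 200,
                        background_level = 60,
                        noise_sd = 0,
                        seed = NULL) {
  if (image_width < 1 || image_height < 1)
    stop("image dimensions must be positive")
  if (!is.numeric(center) || length(center) != 2)
    stop("center must be a numeric (x, y) pair")
  if (!is.numeric(inner_radius) || inner_radius <= 0)
    stop("inner_radius must be > 0")
  filaments <- normalize_filaments(filaments)
  if (nrow(filaments)) {
    if (any(filaments$width < 1) || any(filaments$width >= inner_radius))
      stop("every filament width must be >= 1 px and < inner_radius")
    if (any(filaments$length < 0))
      stop("filament length must be >= 0")
  }
  if (foreground_level <= background_level)
    stop("foreground_level must exceed background_level")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 center = as.numeric(center),
                 inner_radius = as.numeric(inner_radius),
                 filaments = filaments,
                 foreground_level = as.numeric(foreground_level),
                 background_level = as.numeric(background_level),
                 noise_sd = as.numeric(noise_sd),
                 seed = seed),
            class = "colony_spec")
}

normalize_filaments <- function(filaments) {
  if (is.null(filaments))
    return(data.frame(angle = numeric(), length = numeric(), width = numeric()))
  if (is.matrix(filaments)) {
    filaments <- as.data.frame(filaments)
    names(filaments) <- c("angle", "length", "width")
  }
  stopifnot(all(c("angle", "length", "width") %in% names(filaments)))
  filaments[c("angle", "length", "width")]
}

#' Evenly spaced radial filaments
#'
#' Convenience constructor for the `filaments` field of [colony_spec()]:
#' `n` spokes at equal angular spacing, optionally jittered.
#'
#' @param n number of filaments.
#' @param length,width spoke dimensions in pixels (recycled).
#' @param jitter half-width of uniform angular jitter in radians.
#' @param seed integer seed for the jitter draw, or `NULL`.
#' @return a data frame suitable for `colony_spec(filaments = )`.
#' @export
radial_filaments <- function(n, length, width, jitter = 0, seed = NULL) {
  angles <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  if (jitter > 0)
    angles <- angles + with_seed(seed, runif(n, -jitter, jitter))
  data.frame(angle = angles,
             length = rep_len(length, n),
             width = rep_len(width, n))
}

# Noiseless foreground masks for a colony spec, on the pixel-center grid.
# Returns list(disc, union) of W x H logical matrices. Each filament is the
# set of pixels whose projection along the spoke direction lies in
# [inner_radius - overlap, inner_radius + length] with perpendicular offset
# <= width/2; the overlap guarantees attachment to the disc.
colony_masks <- function(spec) {
  W <- spec$image_width; H <- spec$image_height
  cx <- spec$center[1]; cy <- spec$center[2]
  dx <- (seq_len(W) - 1) - cx         # x offsets, length W
  dy <- (seq_len(H) - 1) - cy         # y offsets, length H
  dx2 <- matrix(dx^2, W, H)
  dy2 <- matrix(dy^2, W, H, byrow = TRUE)
  disc <- dx2 + dy2 <= spec$inner_radius^2
  union <- disc
  fil <- spec$filaments
  for (i in seq_len(nrow(fil))) {
    if (fil$length[i] <= 0) next      # zero-length spoke adds no area
    a <- fil$angle[i]; w <- fil$width[i]
    overlap <- max(2, w / 2)
    t0 <- spec$inner_radius - overlap
    t1 <- spec$inner_radius + fil$length[i]
    u <- c(cos(a), sin(a))
    tmat <- outer(dx * u[1], dy * u[2], `+`)        # along-spoke coordinate
    smat <- outer(dx * -u[2], dy * u[1], `+`)       # perpendicular offset
    rect <- tmat >= t0 & tmat <= t1 & abs(smat) <= w / 2
    if (!any(rect & disc))
      stop("filament ", i, " is detached from the colony disc")
    union <- union | rect
  }
  list(disc = disc, union = union)
}

#' Render a synthetic colony image with exact ground truth
#'
#' Rasterizes a [colony_spec()] into a 3-channel image (bright colony on
#' darker agar, plus optional additive Gaussian noise) and computes exact
#' segmentation ground truth by pixel counting on the noiseless mask:
#' `a_inner_true` is the disc pixel count, `a_outer_true` the pixel count
#' of the filled external boundary of disc-plus-filaments (enclosed
#' pockets between filaments count only when fully surrounded by
#' foreground, matching the pipeline's void-filling step), and
#' `f_true = (a_outer_true - a_inner_true) / a_inner_true`.
#'
#' @param spec a [colony_spec()].
#' @param invert render a dark colony on bright agar instead (the ground
#'   truth is unaffected).
#' @return a list with elements `image` (a [raster_image()], RGB, 0--255)
#'   and `truth` (list `a_inner_true`, `a_outer_true`, `f_true`).
#' @export
render_colony <- function(spec, invert = FALSE) {
  stopifnot(inherits(spec, "colony_spec"))
  masks <- colony_masks(spec)
  a_inner <- sum(masks$disc)
  filled <- fill_mask_holes(masks$union)
  a_outer <- sum(filled)
  fg <- spec$foreground_level; bg <- spec$background_level
  if (invert) { tmp <- fg; fg <- bg; bg <- tmp }
  g <- ifelse(masks$union, fg, bg)
  if (spec$noise_sd > 0) {
    g <- g + with_seed(spec$seed,
                       matrix(rnorm(length(g), 0, spec$noise_sd), nrow(g)))
    g <- pmin(pmax(g, 0), 255)
  }
  img <- raster_image(array(rep(g, 3), dim = c(dim(g), 3)),
                      channel_order = "RGB")
  truth <- list(a_inner_true = a_inner,
                a_outer_true = a_outer,
                f_true = (a_outer - a_inner) / a_inner)
  list(image = img, truth = truth)
}

# Fill enclosed background holes of a logical W x H mask (background
# components with no path to the image border; 4-connectivity).
fill_mask_holes <- function(mask) {
  img <- EBImage::fillHull(EBImage::Image(mask * 1))
  EBImage::imageData(img) > 0.5
}

#' Build a colony spec targeting a given filamentation index
#'
#' Chooses spoke lengths so that the total protrusion area of `n_filaments`
#' equally spaced spokes is approximately `f_target` times the disc area.
#' The realized `f_true` (from [render_colony()]) differs slightly from the
#' target because of rasterization and the spoke/disc overlap; use the
#' returned ground truth, not the target, as the reference value.
#'
#' @param f_target desired filamentation index (>= 0).
#' @param image_width,image_height image dimensions in pixels.
#' @param inner_radius disc radius in pixels.
#' @param n_filaments number of spokes.
#' @param filament_width spoke width in pixels.
#' @param jitter angular jitter passed to [radial_filaments()].
#' @param seed seed for jitter and rendering noise.
#' @param noise_sd rendering noise passed to [colony_spec()].
#' @return a [colony_spec()].
#' @export
spec_for_f <- function(f_target, image_width = 640, image_height = 480,
                       inner_radius = 60, n_filaments = 16,
                       filament_width = 9, jitter = 0.05, seed = NULL,
                       noise_sd = 0) {
  stopifnot(f_target >= 0)
  len <- f_target * pi * inner_radius^2 / (n_filaments * filament_width)
  max_len <- min(image_width, image_height) / 2 - inner_radius - 2
  if (len > max_len)
    stop("f_target too large for this geometry: required spoke length ",
         round(len, 1), " px exceeds the available ", round(max_len, 1), " px")
  fil <- if (f_target == 0) NULL else
    radial_filaments(n_filaments, len, filament_width, jitter = jitter,
                     seed = seed)
  colony_spec(image_width, image_height, inner_radius = inner_radius,
              filaments = fil, noise_sd = noise_sd, seed = seed)
}
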