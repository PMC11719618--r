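# Shoelace area of an n x 2 vertex matrix (absolute value).
shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# External boundary of the largest foreground component as a 0-based
# (x, y) vertex matrix.
outer_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(matrix(numeric(0), 0, 2))
  oc[[which.max(vapply(oc, nrow, integer(1)))]]
}

largest_component <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  list(mask = lab == which.max(sizes), sizes = sort(sizes, decreasing = TRUE))
}

#' Extract inner and outer colony contours and their areas
#'
#' Identifies the two most prominent boundaries in a segmented colony
#' mask. The outer boundary encloses the whole colony including every
#' filamentous protrusion: the largest foreground component with its
#' enclosed voids filled; `a_outer` is its filled pixel area. The inner
#' boundary delimits the central colony mass, derived by morphological
#' opening with a disc structuring element of radius `opening_radius`,
#' which deterministically removes protrusions thinner than roughly twice
#' that radius; `a_inner` is the filled area of the largest component
#' that survives the opening.
#'
#' When a second foreground component of comparable size is present (a
#' neighboring colony in frame), the largest is measured and the result
#' is flagged for manual review.
#'
#' @param mask a `binary_mask`.
#' @param opening_radius disc radius in pixels for the opening (default
#'   8 at the standardized 2560 x 1920 scale). Radius 0 skips the
#'   opening, so the inner boundary equals the outer one and f = 0.
#' @param pixel_pitch_um optional physical pixel pitch (micrometers per
#'   pixel, e.g. 2.2); when given, areas are also reported in um^2.
#' @return object of class `contour_measurement`: list with
#'   `outer_polygon`, `inner_polygon` (0-based (x, y) vertices),
#'   `a_outer`, `a_inner` (pixel counts), optional `a_outer_um2`,
#'   `a_inner_um2`, and `review_flag`.
#' @export
extract_contours <- function(mask, opening_radius = 8, pixel_pitch_um = NULL) {
  m <- unclass(mask) > 0
  if (!any(m)) stop("mask has no foreground component")
  comp <- largest_component(m)
  review <- FALSE
  if (length(comp$sizes) > 1 && comp$sizes[2] >= 0.5 * comp$sizes[1]) {
    warning("multiple comparable-size components; measuring the largest ",
            "and flagging for manual review")
    review <- TRUE
  }
  colony <- fill_mask_holes(comp$mask)
  a_outer <- sum(colony)
  outer_poly <- outer_contour(colony)

  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * round(opening_radius) + 1, shape = "disc")
    opened <- EBImage::imageData(
      EBImage::opening(EBImage::Image(colony * 1), brush)) > 0.5
    if (!any(opened))
      stop("opening radius ", opening_radius,
           " erased the colony entirely; choose a radius smaller than the ",
           "central mass radius")
    inner <- fill_mask_holes(largest_component(opened)$mask)
  } else {
    inner <- colony
  }
  a_inner <- sum(inner)
  inner_poly <- outer_contour(inner)

  out <- list(outer_polygon = outer_poly, inner_polygon = inner_poly,
              a_outer = a_outer, a_inner = a_inner,
              opening_radius = opening_radius, review_flag = review)
  if (!is.null(pixel_pitch_um)) {
    out$a_outer_um2 <- a_outer * pixel_pitch_um^2
    out$a_inner_um2 <- a_inner * pixel_pitch_um^2
  }
  structure(out, class = "contour_measurement")
}

#' Filamentation index from a contour measurement
#'
#' `f = (a_outer - a_inner) / a_inner`: the relative excess of the area
#' enclosed by the protrusion-spanning outer boundary over the central
#' colony mass area. Reported as a dimensionless fraction (0.5 means the
#' outer boundary encloses 50% more area than the central mass);
#' multiply by 100 for a percent reading.
#'
#' @param measurement a [extract_contours()] result, or any list with
#'   numeric `a_outer` and `a_inner`.
#' @return the f-measure, a nonnegative scalar.
#' @export
f_measure <- function(measurement) {
  a_i <- measurement$a_inner; a_o <- measurement$a_outer
  if (is.null(a_i) || is.na(a_i) || a_i <= 0)
    stop("a_inner must be > 0: no central colony mass was measured")
  (a_o - a_i) / a_i
}

#' Pipeline configuration
#'
#' Collects every tunable of the measurement chain with its default.
#'
#' @param resolution target standardized resolution `c(width, height)`.
#' @param gaussian_kernel odd Gaussian kernel side length.
#' @param gaussian_sigma Gaussian standard deviation in pixels.
#' @param threshold `"auto"` (Otsu) or a manual intensity in 0--255.
#' @param polarity `"foreground-bright"` or `"foreground-dark"`.
#' @param max_void_px void-filling size cap in pixels (`Inf` = fill all).
#' @param opening_radius_px disc radius for the inner-mass opening.
#' @param pixel_pitch_um physical pixel pitch in micrometers, or `NULL`.
#' @param keep_intermediates retain intermediate images on the record
#'   (as an attribute) for QC.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(resolution = c(2560, 1920),
                            gaussian_kernel = 5,
                            gaussian_sigma = 1.1,
                            threshold = "auto",
                            polarity = "foreground-bright",
                            max_void_px = Inf,
                            opening_radius_px = 8,
                            pixel_pitch_um = NULL,
                            keep_intermediates = FALSE) {
  structure(list(resolution = resolution, gaussian_kernel = gaussian_kernel,
                 gaussian_sigma = gaussian_sigma, threshold = threshold,
                 polarity = polarity, max_void_px = max_void_px,
                 opening_radius_px = opening_radius_px,
                 pixel_pitch_um = pixel_pitch_um,
                 keep_intermediates = keep_intermediates),
            class = "pipeline_config")
}

#' Measure the filamentation index of one colony image
#'
#' Runs the full chain standardize -> grayscale -> Gaussian blur ->
#' binarize -> fill voids -> contour extraction -> f-measure. Any stage
#' failure is re-raised with the stage name and colony id attached.
#' Deterministic for a fixed configuration.
#'
#' @param image a file path (PNG/JPEG) or a [raster_image()].
#' @param config a [pipeline_config()].
#' @param metadata named list or one-row data frame carrying `colony_id`,
#'   `strain`, `compound`, `concentration_uM` (missing entries become NA).
#' @return one-row data frame: `colony_id`, `strain`, `compound`,
#'   `concentration_uM`, `threshold_used`, `a_inner_px2`, `a_outer_px2`,
#'   `a_inner_um2`, `a_outer_um2`, `f`, `review_flag`. With
#'   `keep_intermediates`, the stages are attached as attribute
#'   `"intermediates"`.
#' @export
process_image <- function(image, config = pipeline_config(),
                          metadata = list()) {
  id <- metadata$colony_id %||% if (is.character(image)) basename(image) else "colony"
  run <- function(stage, expr)
    tryCatch(expr, error = function(e) stop_stage(stage, id, conditionMessage(e)))
  img <- if (is.character(image)) run("read", read_colony_image(image)) else image
  stopifnot(inherits(img, "raster_image"))

  std <- run("standardize",
             standardize(img, config$resolution[1], config$resolution[2]))
  gray <- run("to_gray", to_gray(std))
  blurred <- run("blur",
                 gaussian_blur(gray, config$gaussian_kernel, config$gaussian_sigma))
  mask <- run("binarize", binarize(blurred, config$threshold, config$polarity))
  filled <- run("fill_voids", fill_voids(mask, config$max_void_px))
  meas <- run("contours",
              extract_contours(filled, config$opening_radius_px,
                               config$pixel_pitch_um))
  f <- run("f_measure", f_measure(meas))

  rec <- data.frame(
    colony_id = id,
    strain = metadata$strain %||% NA_character_,
    compound = metadata$compound %||% NA_character_,
    concentration_uM = as.numeric(metadata$concentration_uM %||% NA_real_),
    threshold_used = attr(mask, "threshold_used"),
    a_inner_px2 = meas$a_inner,
    a_outer_px2 = meas$a_outer,
    a_inner_um2 = meas$a_inner_um2 %||% NA_real_,
    a_outer_um2 = meas$a_outer_um2 %||% NA_real_,
    f = f,
    review_flag = meas$review_flag,
    stringsAsFactors = FALSE)
  if (isTRUE(config$keep_intermediates))
    attr(rec, "intermediates") <- list(standardized = std, gray = gray,
                                       blurred = blurred, mask = mask,
                                       filled = filled, measurement = meas)
  rec
}

#' Measure a batch of colony images listed in a manifest
#'
#' @param manifest data frame (or CSV path) with columns `file`,
#'   `colony_id`, `strain`, `compound`, `concentration_uM`.
#' @param image_dir directory against which relative `file` entries are
#'   resolved.
#' @param config a [pipeline_config()].
#' @param on_error `"skip"` logs per-image failures and continues
#'   (mirroring manual rejection of unusable photographs); `"stop"`
#'   aborts on the first failure.
#' @return data frame of per-colony records (see [process_image()]);
#'   failures, if any, are attached as attribute `"failures"`
#'   (data frame `colony_id`, `error`).
#' @export
process_batch <- function(manifest, image_dir = ".",
                          config = pipeline_config(),
                          on_error = c("skip", "stop")) {
  on_error <- match.arg(on_error)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  records <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- row$file
    if (!file.exists(path)) path <- file.path(image_dir, row$file)
    res <- tryCatch(process_image(path, config, as.list(row)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") stop(res)
      failures[[length(failures) + 1]] <-
        data.frame(colony_id = row$colony_id, error = conditionMessage(res))
    } else {
      records[[length(records) + 1]] <- res
    }
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(colony_id = character(0))
  if (length(failures)) attr(out, "failures") <- do.call(rbind, failures)
  out
}

#' Draw the measured contours onto an image for quality control
#'
#' Writes a PNG of the standardized image with the outer boundary in red
#' and the inner (central-mass) boundary in blue.
#'
#' @param img the standardized [raster_image()] the measurement was made on.
#' @param measurement a [extract_contours()] result.
#' @param path output PNG path.
#' @export
write_qc_overlay <- function(img, measurement, path) {
  a <- unclass(img)
  if (attr(img, "channel_order") == "BGR") a <- a[, , 3:1, drop = FALSE]
  paint <- function(a, poly, rgb) {
    if (!nrow(poly)) return(a)
    x <- poly[, 1] + 1; y <- poly[, 2] + 1
    for (ch in 1:3) a[cbind(x, y, ch)] <- rgb[ch]
    a
  }
  a <- paint(a, measurement$outer_polygon, c(255, 0, 0))
  a <- paint(a, measurement$inner_polygon, c(0, 0, 255))
  png::writePNG(aperm(a, c(2, 1, 3)) / 255, path)
  invisible(path)
}
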