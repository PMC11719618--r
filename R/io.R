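#' Read and validate an image manifest
#'
#' A manifest maps image files to experimental metadata, one colony per
#' row, with columns `file`, `colony_id`, `strain`, `compound`,
#' `concentration_uM`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "colony_id", "strain", "compound", "concentration_uM")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  m$concentration_uM <- as.numeric(m$concentration_uM)
  m
}

#' Read a dose design from a plain config file
#'
#' The file is a CSV with columns `concentration_uM`, `n`, `mean_f`,
#' `sd_f`; leading comment lines of the form `# key = value` set design
#' options (`family`, `outlier_rate`, `outlier_scale`, `strain`,
#' `compound`, `seed`).
#'
#' @param path file path.
#' @return a [dose_design()].
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  opts <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", h))[[1]]
    if (length(kv) == 3) opts[[kv[2]]] <- kv[3]
  }
  groups <- read.csv(textConnection(lines[!grepl("^\\s*#", lines)]),
                     stringsAsFactors = FALSE)
  dose_design(groups,
              family = opts$family %||% "lognormal",
              outlier_rate = as.numeric(opts$outlier_rate %||% 0),
              outlier_scale = as.numeric(opts$outlier_scale %||% 1),
              strain = opts$strain %||% "synthetic",
              compound = opts$compound %||% "synthetic",
              seed = if (is.null(opts$seed)) NULL else as.integer(opts$seed))
}

#' Generate a set of synthetic colony images with ground truth
#'
#' For each group of a dose design, draws target f-measures from the
#' design's distribution, renders one disc-plus-spokes colony per draw
#' (spoke length set so the rendered `f_true` approximates the draw; see
#' [spec_for_f()]), and writes PNG images, a manifest CSV (`file`,
#' `colony_id`, `strain`, `compound`, `concentration_uM`) and a
#' ground-truth CSV (`colony_id`, `a_inner_true`, `a_outer_true`,
#' `f_true`). Deterministic for a fixed seed.
#'
#' @param design a [dose_design()].
#' @param dir output directory (created if needed); images go to
#'   `dir/images/`.
#' @param n_per_group overrides the design group sizes (recycled), e.g.
#'   to render a small pilot set.
#' @param seed integer seed.
#' @param image_width,image_height,inner_radius,n_filaments,filament_width
#'   rendering geometry in pixels (see [spec_for_f()]).
#' @param noise_sd additive Gaussian pixel noise (intensity units).
#' @return invisibly, list with `manifest` and `truth` data frames (also
#'   written to `dir/manifest.csv` and `dir/ground_truth.csv`).
#' @export
generate_colony_set <- function(design, dir, n_per_group = NULL, seed = 1,
                                image_width = 640, image_height = 480,
                                inner_radius = 60, n_filaments = 16,
                                filament_width = 9, noise_sd = 6) {
  stopifnot(inherits(design, "dose_design"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  # largest f renderable in this geometry (spoke length limited by frame)
  max_len <- min(image_width, image_height) / 2 - inner_radius - 2
  f_max <- n_filaments * filament_width * max_len / (pi * inner_radius^2)
  sim_design <- design
  if (!is.null(n_per_group))
    sim_design$groups$n <- rep_len(n_per_group, nrow(design$groups))
  tab <- simulate_fmeasures(sim_design, seed = seed)
  manifest <- NULL; truth <- NULL
  for (i in seq_len(nrow(tab))) {
    f_target <- min(tab$f[i], 0.98 * f_max)
    spec <- spec_for_f(f_target, image_width, image_height, inner_radius,
                       n_filaments, filament_width,
                       seed = seed + i, noise_sd = noise_sd)
    rc <- render_colony(spec)
    file <- file.path("images", sprintf("colony_%04d.png", i))
    write_colony_image(rc$image, file.path(dir, file))
    manifest <- rbind(manifest, data.frame(
      file = file, colony_id = tab$colony_id[i], strain = tab$strain[i],
      compound = tab$compound[i], concentration_uM = tab$concentration_uM[i]))
    truth <- rbind(truth, data.frame(
      colony_id = tab$colony_id[i],
      a_inner_true = rc$truth$a_inner_true,
      a_outer_true = rc$truth$a_outer_true,
      f_true = rc$truth$f_true))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  writeLines(c(sprintf("seed: %d", seed),
               sprintf("family: %s", design$family),
               sprintf("noise_sd: %g", noise_sd)),
             file.path(dir, "generation_meta.txt"))
  invisible(list(manifest = manifest, truth = truth))
}
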