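#' Specify one synthetic sample (one set of two-channel fields)
#'
#' A sample is a collection of microscope fields imaged in two channels:
#' green (target protein, FITC) and red (housekeeping protein, Texas Red).
#' The forward model assumes the housekeeping signal is approximately
#' constant across cells (level `red_mean_level`, coefficient of variation
#' `red_cell_cv`) while each cell's green level equals its true
#' expression ratio times its red level. Per-cell true ratios are drawn
#' from a normal distribution with mean `true_mean_ratio` and standard
#' deviation `between_cell_sd`, truncated at zero.
#'
#' @param sample_id unique sample identifier (used in filenames and seeds)
#' @param group_label study group the sample belongs to
#' @param true_mean_ratio mean of the per-cell green/red expression ratio;
#'   the quantity the measurement pipeline is meant to recover
#' @param seed integer seed; all randomness for this sample derives from
#'   `(seed, sample_id, image index)` so samples are independent and
#'   order-insensitive
#' @param n_images number of fields imaged for the sample (study design:
#'   20-30 per sample)
#' @param cells_per_image number of cells placed in each field
#' @param between_cell_sd SD of the per-cell true ratio within the sample
#' @param red_mean_level mean housekeeping intensity (detector counts)
#' @param red_cell_cv coefficient of variation of per-cell red level
#' @param background_level constant background added to both channels
#' @param pixel_noise_sd SD of additive per-pixel Gaussian noise (counts);
#'   ignored when `noise_model = "poisson"`
#' @param image_shape `(height, width)` of each field in pixels
#' @param cell_radius_range `(min, max)` ellipse semi-axis length in pixels
#' @param bit_depth 8 or 16; rendered images are clipped to this range
#' @param noise_model `"gaussian"` (default) or `"poisson"`
#' @return an object of class `sample_spec`
#' @export
sample_spec <- function(sample_id, group_label, true_mean_ratio, seed,
                        n_images = 20L, cells_per_image = 15L,
                        between_cell_sd = 0.05,
                        red_mean_level = 20000, red_cell_cv = 0.10,
                        background_level = 0, pixel_noise_sd = 300,
                        image_shape = c(128L, 128L),
                        cell_radius_range = c(4, 7),
                        bit_depth = 16L,
                        noise_model = c("gaussian", "poisson")) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id),
            is.character(group_label), length(group_label) == 1L)
  assert_scalar_num(true_mean_ratio, "true_mean_ratio", 0, strict_min = TRUE)
  assert_scalar_num(between_cell_sd, "between_cell_sd", 0)
  assert_scalar_num(red_mean_level, "red_mean_level", 0, strict_min = TRUE)
  assert_scalar_num(red_cell_cv, "red_cell_cv", 0)
  assert_scalar_num(background_level, "background_level", 0)
  assert_scalar_num(pixel_noise_sd, "pixel_noise_sd", 0)
  assert_scalar_num(seed, "seed")
  stopifnot(length(n_images) == 1L, n_images >= 1L,
            length(cells_per_image) == 1L, cells_per_image >= 0L,
            length(image_shape) == 2L, all(image_shape >= 1L),
            length(cell_radius_range) == 2L,
            cell_radius_range[1] > 0,
            cell_radius_range[1] <= cell_radius_range[2],
            bit_depth %in% c(8L, 16L))
  if (between_cell_sd >= true_mean_ratio) {
    stop("between_cell_sd must be < true_mean_ratio so truncation at 0 stays negligible")
  }
  if (2 * cell_radius_range[2] + 2 >= min(image_shape)) {
    stop("cell_radius_range does not fit inside image_shape")
  }
  spec <- list(
    sample_id = sample_id, group_label = group_label,
    n_images = as.integer(n_images), cells_per_image = as.integer(cells_per_image),
    true_mean_ratio = true_mean_ratio, between_cell_sd = between_cell_sd,
    red_mean_level = red_mean_level, red_cell_cv = red_cell_cv,
    background_level = background_level, pixel_noise_sd = pixel_noise_sd,
    image_shape = as.integer(image_shape),
    cell_radius_range = as.numeric(cell_radius_range),
    bit_depth = as.integer(bit_depth),
    noise_model = match.arg(noise_model),
    seed = as.integer(seed))
  class(spec) <- "sample_spec"
  spec
}

#' Draw ground-truth cells for one field
#'
#' Places `cells_per_image` non-overlapping ellipses fully inside the image
#' by rejection sampling, and draws each cell's true expression ratio and
#' housekeeping level. Fully reproducible from
#' `(spec$seed, spec$sample_id, image_index)`.
#'
#' @param spec a [sample_spec()]
#' @param image_index 0-based field index, `< spec$n_images`
#' @return data.frame with columns `cell_id`, `center_row`, `center_col`,
#'   `r_row`, `r_col`, `true_ratio`, `true_red_level` (one row per cell).
#'   Coordinates are 0-based `(row, col)`.
#' @export
draw_cell_truths <- function(spec, image_index) {
  stopifnot(inherits(spec, "sample_spec"),
            image_index >= 0L, image_index < spec$n_images)
  n <- spec$cells_per_image
  empty <- data.frame(cell_id = integer(0), center_row = numeric(0),
                      center_col = numeric(0), r_row = numeric(0),
                      r_col = numeric(0), true_ratio = numeric(0),
                      true_red_level = numeric(0))
  if (n == 0L) return(empty)
  withr::with_seed(derive_seed(spec$seed, spec$sample_id, image_index, "truths"), {
    h <- spec$image_shape[1]; w <- spec$image_shape[2]
    rmin <- spec$cell_radius_range[1]; rmax <- spec$cell_radius_range[2]
    centers <- matrix(NA_real_, n, 2)
    radii <- matrix(NA_real_, n, 2)
    reach <- numeric(n)  # conservative circular footprint per cell
    max_attempts <- 500L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        rr <- stats::runif(1, rmin, rmax)
        rc <- stats::runif(1, rmin, rmax)
        rmx <- max(rr, rc)
        # keep the ellipse (and a 1-px guard) strictly inside the image
        cr <- stats::runif(1, rmx + 1, h - rmx - 2)
        cc <- stats::runif(1, rmx + 1, w - rmx - 2)
        ok <- TRUE
        if (i > 1L) {
          d <- sqrt((centers[seq_len(i - 1L), 1] - cr)^2 +
                    (centers[seq_len(i - 1L), 2] - cc)^2)
          ok <- all(d > reach[seq_len(i - 1L)] + rmx + 1)
        }
        if (ok) {
          centers[i, ] <- c(cr, cc); radii[i, ] <- c(rr, rc); reach[i] <- rmx
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n, " non-overlapping cells in a ",
             h, "x", w, " field for sample '", spec$sample_id,
             "' (image ", image_index, "); reduce cells_per_image or ",
             "cell_radius_range, or enlarge image_shape")
      }
    }
    data.frame(
      cell_id = seq_len(n),
      center_row = centers[, 1], center_col = centers[, 2],
      r_row = radii[, 1], r_col = radii[, 2],
      true_ratio = rnorm_trunc0(n, spec$true_mean_ratio, spec$between_cell_sd),
      true_red_level = rnorm_trunc0(n, spec$red_mean_level,
                                    spec$red_mean_level * spec$red_cell_cv))
  })
}

#' Render one two-channel field plus its label mask
#'
#' Forward model: inside cell i the red channel is
#' `true_red_level_i + background_level` and the green channel is
#' `true_ratio_i * true_red_level_i + background_level`; outside all cells
#' both channels sit at `background_level`. Per-pixel noise is added
#' (Gaussian with SD `pixel_noise_sd`, or Poisson when
#' `noise_model = "poisson"`), then values are rounded to integer detector
#' counts and clipped to the bit-depth range. Clipping emits a warning with
#' the clipped-pixel fraction.
#'
#' @param truths data.frame from [draw_cell_truths()]
#' @param spec the [sample_spec()] the truths were drawn from
#' @param image_index field index, used for the noise stream and field id
#' @return list with elements `green`, `red` (both [channel_image()]) and
#'   `mask` (integer matrix, 0 = background, `cell_id` inside each cell)
#' @export
render_field <- function(truths, spec, image_index = 0L) {
  stopifnot(inherits(spec, "sample_spec"), is.data.frame(truths))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  green <- matrix(spec$background_level, h, w)
  red <- matrix(spec$background_level, h, w)
  mask <- matrix(0L, h, w)
  cr_v <- truths$center_row; cc_v <- truths$center_col
  rr_v <- truths$r_row; rc_v <- truths$r_col
  ratio_v <- truths$true_ratio; level_v <- truths$true_red_level
  id_v <- truths$cell_id
  for (i in seq_len(nrow(truths))) {
    rows <- max(1, floor(cr_v[i] - rr_v[i] + 1)):min(h, ceiling(cr_v[i] + rr_v[i] + 1))
    cols <- max(1, floor(cc_v[i] - rc_v[i] + 1)):min(w, ceiling(cc_v[i] + rc_v[i] + 1))
    # 0-based pixel coordinates of the bounding box
    dr <- (rows - 1 - cr_v[i]) / rr_v[i]
    dc <- (cols - 1 - cc_v[i]) / rc_v[i]
    inside <- outer(dr^2, dc^2, `+`) <= 1
    if (!any(inside)) next
    lin <- rep(rows, times = length(cols)) + h * rep(cols - 1L, each = length(rows))
    lin <- lin[inside]
    mask[lin] <- id_v[i]
    green[lin] <- ratio_v[i] * level_v[i] + spec$background_level
    red[lin] <- level_v[i] + spec$background_level
  }
  withr::with_seed(derive_seed(spec$seed, spec$sample_id, image_index, "render"), {
    if (spec$noise_model == "poisson") {
      green <- stats::rpois(h * w, lambda = pmax(green, 0))
      red <- stats::rpois(h * w, lambda = pmax(red, 0))
      dim(green) <- c(h, w); dim(red) <- c(h, w)
    } else if (spec$pixel_noise_sd > 0) {
      green <- green + rnorm(h * w, 0, spec$pixel_noise_sd)
      red <- red + rnorm(h * w, 0, spec$pixel_noise_sd)
    }
  })
  top <- 2^spec$bit_depth - 1
  quantize <- function(x, chan) {
    x <- round(x)
    n_over <- sum(x > top)
    if (n_over > 0) {
      warning(sprintf("%s channel: %.4f%% of pixels overflow the %d-bit range (clipped)",
                      chan, 100 * n_over / length(x), spec$bit_depth))
    }
    # negative counts (noise below a zero/low background) clamp silently:
    # a photon-counting detector cannot report them
    x <- pmin(pmax(x, 0), top)
    storage.mode(x) <- "integer"
    x
  }
  field_id <- sprintf("%s_%03d", spec$sample_id, image_index)
  list(
    green = channel_image(quantize(green, "green"), "green", spec$bit_depth,
                          field_id = field_id, sample_id = spec$sample_id,
                          validate = FALSE),
    red = channel_image(quantize(red, "red"), "red", spec$bit_depth,
                        field_id = field_id, sample_id = spec$sample_id,
                        validate = FALSE),
    mask = mask)
}

#' Build per-sample specs for one study group
#'
#' Adds the hierarchical layer above [sample_spec()]: each sample's true
#' mean ratio is drawn from Normal(`mean_ratio`, `between_sample_sd`),
#' truncated at zero, so the spread of sample-level mean ratios within a
#' group matches the between-sample SDs reported for grouped
#' immunofluorescence studies (order 0.01-0.05).
#'
#' @param group_label group name; also the sample-id prefix
#' @param n_samples number of samples in the group
#' @param mean_ratio group-level mean of the per-sample true mean ratios
#' @param between_sample_sd SD of per-sample true mean ratios
#' @param seed master seed; sample means and per-sample streams derive from it
#' @param ... further arguments passed to [sample_spec()] (noise, geometry...)
#' @return list of [sample_spec()] objects
#' @export
group_sample_specs <- function(group_label, n_samples, mean_ratio,
                               between_sample_sd, seed, ...) {
  stopifnot(n_samples >= 1L)
  assert_scalar_num(between_sample_sd, "between_sample_sd", 0)
  means <- withr::with_seed(
    derive_seed(seed, group_label, "sample_means"),
    rnorm_trunc0(n_samples, mean_ratio, between_sample_sd))
  lapply(seq_len(n_samples), function(i) {
    sid <- sprintf("%s_%02d", group_label, i)
    sample_spec(sample_id = sid, group_label = group_label,
                true_mean_ratio = means[i],
                seed = derive_seed(seed, sid), ...)
  })
}

#' Generate a full synthetic study on disk
#'
#' Writes, for every sample and field, a green TIFF, a red TIFF and a
#' 16-bit label-mask TIFF (`<sample>_<image#>_{green|red|mask}.tif`),
#' plus `manifest.csv`, the per-cell ground truth (`truths.csv`) and a
#' JSON study config sufficient for exact regeneration.
#'
#' @param specs list of [sample_spec()] (e.g. from [group_sample_specs()])
#' @param output_dir directory to write into (created if needed)
#' @return the manifest data.frame, invisibly; paths are relative to
#'   `output_dir`
#' @export
generate_study <- function(specs, output_dir) {
  if (inherits(specs, "sample_spec")) specs <- list(specs)
  stopifnot(length(specs) > 0, all(vapply(specs, inherits, logical(1), "sample_spec")))
  ids <- vapply(specs, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in study config: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", sum(vapply(specs, `[[`, integer(1), "n_images")))
  truth_rows <- list()
  k <- 0L
  for (spec in specs) {
    for (img in seq_len(spec$n_images) - 1L) {
      truths <- draw_cell_truths(spec, img)
      field <- render_field(truths, spec, img)
      stem <- sprintf("%s_%03d", spec$sample_id, img)
      gp <- paste0(stem, "_green.tif"); rp <- paste0(stem, "_red.tif")
      mp <- paste0(stem, "_mask.tif")
      write_channel_image(field$green, file.path(output_dir, gp))
      write_channel_image(field$red, file.path(output_dir, rp))
      write_label_mask(field$mask, file.path(output_dir, mp))
      k <- k + 1L
      rows[[k]] <- data.frame(sample_id = spec$sample_id,
                              group = spec$group_label,
                              image_index = img,
                              green_path = gp, red_path = rp, mask_path = mp)
      if (nrow(truths) > 0) {
        truth_rows[[length(truth_rows) + 1L]] <-
          cbind(sample_id = spec$sample_id, image_index = img, truths)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(output_dir, "manifest.csv"))
  truths_all <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  if (!is.null(truths_all)) {
    write.csv(truths_all, file.path(output_dir, "truths.csv"), row.names = FALSE)
  }
  jsonlite::write_json(lapply(specs, unclass),
                       file.path(output_dir, "study_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
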