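#' Measure every cell in one field
#'
#' For each labelled cell the green and red means are arithmetic means of
#' pixel intensity over exactly the pixels carrying that label, and the
#' expression ratio is `green_mean / red_mean`. No background subtraction
#' is applied by default. Cells are excluded (with a warning) when the red
#' (housekeeping) mean is zero, when the cell is smaller than
#' `min_cell_area` pixels, or — because truncation biases their means —
#' when they touch the image border.
#'
#' @param green,red [channel_image()]s of the same field
#' @param mask integer label matrix of the same shape
#' @param min_cell_area minimum pixel count for a usable cell
#' @param exclude_border drop cells touching the image border (default TRUE)
#' @param background_subtract if TRUE, subtract the per-field median
#'   background intensity (pixels with label 0) from each channel before
#'   averaging, clamping at zero
#' @return data.frame with columns `sample_id, field_id, cell_id,
#'   green_mean, red_mean, ratio, n_pixels`
#' @export
measure_field <- function(green, red, mask, min_cell_area = 1L,
                          exclude_border = TRUE, background_subtract = FALSE) {
  stopifnot(inherits(green, "channel_image"), inherits(red, "channel_image"),
            is.matrix(mask))
  if (!all(dim(green$pixels) == dim(mask)) || !all(dim(red$pixels) == dim(mask))) {
    stop("green, red and mask must share the same shape")
  }
  if (green$channel != "green" || red$channel != "red") {
    stop("channel tags are swapped: pass the green plane first")
  }
  gpx <- as.numeric(green$pixels)
  rpx <- as.numeric(red$pixels)
  if (background_subtract) {
    bg <- mask == 0L
    if (any(bg)) {
      gpx <- pmax(gpx - stats::median(gpx[bg]), 0)
      rpx <- pmax(rpx - stats::median(rpx[bg]), 0)
    }
  }
  inside <- mask > 0L
  ids <- sort(unique(mask[inside]))
  empty <- data.frame(sample_id = character(0), field_id = character(0),
                      cell_id = integer(0), green_mean = numeric(0),
                      red_mean = numeric(0), ratio = numeric(0),
                      n_pixels = integer(0))
  if (length(ids) == 0L) return(empty)
  lab <- mask[inside]
  np <- as.integer(rowsum(rep(1L, length(lab)), lab)[, 1])
  gm <- rowsum(gpx[inside], lab)[, 1] / np
  rm_ <- rowsum(rpx[inside], lab)[, 1] / np
  border <- unique(c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)]))
  border <- border[border > 0L]
  keep <- rep(TRUE, length(ids))
  if (exclude_border && length(border)) {
    drop_b <- ids %in% border
    if (any(drop_b)) {
      warning(sum(drop_b), " cell(s) touching the border excluded in field '",
              green$field_id, "'")
      keep <- keep & !drop_b
    }
  }
  small <- np < min_cell_area
  if (any(small & keep)) {
    warning(sum(small & keep), " cell(s) below min_cell_area (", min_cell_area,
            " px) excluded in field '", green$field_id, "'")
    keep <- keep & !small
  }
  nored <- rm_ == 0
  if (any(nored & keep)) {
    warning(sum(nored & keep), " cell(s) with zero housekeeping signal ",
            "excluded in field '", green$field_id, "'")
    keep <- keep & !nored
  }
  if (!any(keep)) return(empty)
  data.frame(sample_id = green$sample_id, field_id = green$field_id,
             cell_id = ids[keep],
             green_mean = as.numeric(gm[keep]),
             red_mean = as.numeric(rm_[keep]),
             ratio = as.numeric(gm[keep]) / as.numeric(rm_[keep]),
             n_pixels = np[keep], row.names = NULL)
}

#' Measure a single labelled cell
#'
#' @inheritParams measure_field
#' @param cell_id label of the cell to measure (must be present in `mask`)
#' @return one-row data.frame as in [measure_field()]
#' @export
measure_cell <- function(green, red, mask, cell_id, min_cell_area = 1L) {
  if (!any(mask == cell_id)) stop("mask contains no cell with label ", cell_id)
  m <- measure_field(green, red, mask * (mask == cell_id),
                     min_cell_area = min_cell_area, exclude_border = FALSE)
  if (nrow(m) == 0L) {
    stop("cell ", cell_id, " was excluded (zero housekeeping signal or below min area)")
  }
  m
}

#' Segment cells from the housekeeping (red) channel
#'
#' Automated stand-in for manual boundary selection: the red channel marks
#' all cells because the housekeeping protein is expressed everywhere.
#' Otsu's histogram threshold is applied globally, connected components are
#' labelled, components below `min_cell_area` are removed, and surviving
#' labels are renumbered 1..k in raster (row-major, 0-based) order of each
#' component's first pixel.
#'
#' @param red a [channel_image()] (red channel)
#' @param min_cell_area minimum component size in pixels
#' @return integer label matrix (0 = background); a blank image yields an
#'   all-zero mask
#' @export
segment_cells <- function(red, min_cell_area = 20L) {
  stopifnot(inherits(red, "channel_image"))
  top <- 2^red$bit_depth - 1
  x <- red$pixels / top
  if (max(x) == min(x)) return(matrix(0L, nrow(x), ncol(x)))
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1),
                       levels = if (red$bit_depth == 8L) 256L else 65536L)
  lab <- EBImage::bwlabel(x > thr)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(x), ncol(x))
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab)
  drop <- which(sizes < min_cell_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # renumber by raster (row-major) order of each component's first pixel
  first_lin <- vapply(setdiff(sort(unique(as.integer(lab))), 0L), function(id) {
    hits <- which(lab == id)
    rr <- (hits - 1L) %% nrow(lab); cc <- (hits - 1L) %/% nrow(lab)
    min(rr * ncol(lab) + cc)
  }, numeric(1))
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  remap <- integer(max(ids)); remap[ids[order(first_lin)]] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Select a fixed-size random cell collection for one sample
#'
#' Draws a uniform random subset of `k` cells without replacement across
#' all of the sample's fields (the digitized analogue of picking a 30-cell
#' collection from the sample's images). If fewer than `k` cells are
#' available, all are returned with a warning.
#'
#' @param measurements data.frame of cell measurements for one sample
#' @param k collection size (default 30)
#' @param seed integer seed making the draw reproducible
#' @param include optional logical vector (or vector of row indices) marking
#'   cells eligible for selection
#' @return data.frame subset of `measurements`
#' @export
select_cell_collection <- function(measurements, k = 30L, seed = 1L,
                                   include = NULL) {
  stopifnot(is.data.frame(measurements), k > 0)
  if (!is.null(include)) measurements <- measurements[include, , drop = FALSE]
  n <- nrow(measurements)
  if (n == 0L) stop("no measured cells: sample unanalyzable")
  if (n < k) {
    warning("only ", n, " cells available for a ", k,
            "-cell collection; returning all")
    return(measurements)
  }
  idx <- withr::with_seed(as.integer(seed %% 2147483647),
                          sample.int(n, size = k, replace = FALSE))
  measurements[sort(idx), , drop = FALSE]
}

#' Summarize one sample's cell collection
#'
#' The sample's mean ratio (M.R) is the arithmetic mean of the collection's
#' per-cell ratios; the SD uses the n-1 denominator. A single-cell
#' collection gets SD 0 by convention, with a warning.
#'
#' @param collection data.frame of cell measurements from ONE sample
#' @param group_label group to record in the summary
#' @return one-row data.frame `sample_id, group_label, n_cells, mean_ratio,
#'   sd_ratio`
#' @export
summarize_sample <- function(collection, group_label) {
  stopifnot(is.data.frame(collection), nrow(collection) > 0)
  sid <- unique(collection$sample_id)
  if (length(sid) != 1L) {
    stop("collection mixes cells from multiple samples: ",
         paste(sid, collapse = ", "))
  }
  n <- nrow(collection)
  s <- if (n == 1L) {
    warning("single-cell collection for sample '", sid, "': SD set to 0")
    0
  } else {
    sd(collection$ratio)
  }
  data.frame(sample_id = sid, group_label = group_label, n_cells = n,
             mean_ratio = mean(collection$ratio), sd_ratio = s)
}

#' Quantify a whole study from its manifest
#'
#' Reads every field triple, measures all cells, draws one seeded
#' fixed-size collection per sample, and summarizes each sample.
#'
#' @param manifest data.frame from [read_manifest()] (or [generate_study()]
#'   output with `base_dir` supplied)
#' @param base_dir directory image paths are relative to (defaults to the
#'   manifest's `base_dir` attribute)
#' @param k_cells collection size per sample
#' @param seed master seed; each sample's collection draw derives from
#'   `(seed, sample_id)`
#' @param min_cell_area,background_subtract passed to [measure_field()]
#' @param auto_segment if TRUE, ignore the supplied masks and segment from
#'   the red channel via [segment_cells()]
#' @return list with data.frames `cells` (all measurements), `collections`
#'   (the selected subsets) and `samples` (one summary row per sample)
#' @export
quantify_study <- function(manifest, base_dir = attr(manifest, "base_dir"),
                           k_cells = 30L, seed = 1L, min_cell_area = 5L,
                           background_subtract = FALSE, auto_segment = FALSE) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  resolve <- function(p) {
    if (is.null(base_dir) || file.exists(p[1])) p else file.path(base_dir, p)
  }
  cells <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    fid <- sprintf("%s_%03d", row$sample_id, row$image_index)
    g <- read_channel_image(resolve(row$green_path), "green",
                            field_id = fid, sample_id = row$sample_id)
    r <- read_channel_image(resolve(row$red_path), "red",
                            field_id = fid, sample_id = row$sample_id)
    msk <- if (auto_segment) {
      segment_cells(r, min_cell_area = min_cell_area)
    } else {
      read_label_mask(resolve(row$mask_path), expected_shape = dim(g$pixels))
    }
    cells[[i]] <- measure_field(g, r, msk, min_cell_area = min_cell_area,
                                background_subtract = background_subtract)
  }
  cells <- do.call(rbind, cells)
  groups <- manifest$group[!duplicated(manifest$sample_id)]
  names(groups) <- manifest$sample_id[!duplicated(manifest$sample_id)]
  coll_list <- list(); summ_list <- list()
  for (sid in names(groups)) {
    sample_cells <- cells[cells$sample_id == sid, , drop = FALSE]
    coll <- select_cell_collection(sample_cells, k = k_cells,
                                   seed = derive_seed(seed, sid, "collection"))
    coll_list[[sid]] <- coll
    summ_list[[sid]] <- summarize_sample(coll, group_label = groups[[sid]])
  }
  list(cells = cells,
       collections = do.call(rbind, c(coll_list, list(make.row.names = FALSE))),
       samples = do.call(rbind, c(summ_list, list(make.row.names = FALSE))))
}

#' Simulate one sample end to end in memory
#'
#' Runs the full generator -> render -> measure -> collect -> summarize
#' path for one sample without touching disk. Used by the power and
#' recovery simulations.
#'
#' @param spec a [sample_spec()]
#' @param k_cells collection size
#' @param min_cell_area passed to [measure_field()]
#' @return one-row summary data.frame (as [summarize_sample()]), with the
#'   mean of all drawn true ratios in attribute `"truth_mean"`
#' @export
simulate_sample_summary <- function(spec, k_cells = 30L, min_cell_area = 5L) {
  cells <- vector("list", spec$n_images)
  truth_means <- numeric(spec$n_images)
  for (img in seq_len(spec$n_images) - 1L) {
    truths <- draw_cell_truths(spec, img)
    field <- render_field(truths, spec, img)
    cells[[img + 1L]] <- measure_field(field$green, field$red, field$mask,
                                       min_cell_area = min_cell_area)
    truth_means[img + 1L] <- mean(truths$true_ratio)
  }
  cells <- do.call(rbind, cells)
  coll <- select_cell_collection(cells, k = k_cells,
                                 seed = derive_seed(spec$seed, spec$sample_id,
                                                    "collection"))
  out <- summarize_sample(coll, group_label = spec$group_label)
  attr(out, "truth_mean") <- mean(truth_means)
  out
}
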