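#' Construct a single-channel image
#'
#' @param pixels integer matrix of detector counts (rows x cols)
#' @param channel `"green"` (target protein) or `"red"` (housekeeping)
#' @param bit_depth 8 or 16
#' @param field_id,sample_id identifiers carried through to measurements
#' @param validate check range/type invariants (internal callers that
#'   construct provably valid grids may skip this)
#' @return object of class `channel_image`
#' @export
channel_image <- function(pixels, channel = c("green", "red"),
                          bit_depth = 16L, field_id = "", sample_id = "",
                          validate = TRUE) {
  channel <- match.arg(channel)
  if (!validate) {
    return(structure(list(pixels = pixels, channel = channel,
                          bit_depth = as.integer(bit_depth),
                          field_id = field_id, sample_id = sample_id),
                     class = "channel_image"))
  }
  stopifnot(is.matrix(pixels), length(pixels) > 0, bit_depth %in% c(8L, 16L))
  if (is.double(pixels)) {
    if (any(pixels != round(pixels))) stop("pixel values must be integers")
    pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  }
  if (any(pixels < 0L)) stop("pixel values must be nonnegative")
  if (any(pixels > 2^bit_depth - 1)) {
    stop("pixel values exceed the ", bit_depth, "-bit range")
  }
  structure(list(pixels = pixels, channel = channel,
                 bit_depth = as.integer(bit_depth),
                 field_id = field_id, sample_id = sample_id),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %s, %dx%d, %d-bit, field '%s', sample '%s'>\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$field_id, x$sample_id))
  invisible(x)
}

#' Read a grayscale TIFF as a channel image
#'
#' Pixel values are loaded as stored, with no rescaling; bit depth is
#' taken from the file header. Multi-sample (RGB/RGBA) files are rejected.
#'
#' @param path TIFF file path
#' @param expected_channel channel tag to attach (`"green"` or `"red"`)
#' @param field_id,sample_id identifiers to attach
#' @return a [channel_image()]
#' @export
read_channel_image <- function(path, expected_channel,
                               field_id = "", sample_id = "") {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  info <- tiff::readTIFF(path, payload = FALSE)
  if (is.list(info) && !is.data.frame(info)) info <- as.data.frame(info)
  spp <- info$samples.per.pixel[1]
  if (!is.null(spp) && spp != 1L) {
    stop("expected single-plane grayscale TIFF, got ", spp,
         " samples per pixel: ", path)
  }
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) != 2L) {
    stop("expected single-plane grayscale TIFF, got array of dim ",
         paste(dim(px), collapse = "x"), ": ", path)
  }
  bits <- as.integer(info$bits.per.sample[1])
  channel_image(px, expected_channel, bit_depth = bits,
                field_id = field_id, sample_id = sample_id)
}

#' Write a channel image as a grayscale TIFF
#'
#' @param img a [channel_image()]
#' @param path output path
#' @export
write_channel_image <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  tiff::writeTIFF(img$pixels / (2^img$bit_depth - 1), path,
                  bits.per.sample = img$bit_depth, compression = "LZW")
  invisible(path)
}

#' Read a 16-bit label mask (0 = background, k > 0 = cell k)
#'
#' @param path mask TIFF path
#' @param expected_shape optional `(height, width)`; mismatch is an error
#' @return integer matrix of labels
#' @export
read_label_mask <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) != 2L) {
    stop("label mask must be a single-plane TIFF: ", path)
  }
  if (any(px != round(px)) || any(px < 0)) {
    stop("label mask must contain nonnegative integer labels: ", path)
  }
  if (!is.null(expected_shape) && !all(dim(px) == expected_shape)) {
    stop("mask shape ", paste(dim(px), collapse = "x"),
         " does not match expected ", paste(expected_shape, collapse = "x"),
         ": ", path)
  }
  matrix(as.integer(px), nrow(px), ncol(px))
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask integer matrix, labels in `[0, 65535]`
#' @param path output path
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask <= 65535))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "LZW")
  invisible(path)
}

manifest_cols <- c("sample_id", "group", "image_index",
                   "green_path", "red_path", "mask_path")

#' Write a study manifest CSV
#' @param manifest data.frame with columns
#'   `sample_id, group, image_index, green_path, red_path, mask_path`
#' @param path output CSV path
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest), all(manifest_cols %in% names(manifest)))
  write.csv(manifest[, manifest_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a study manifest
#'
#' Image paths are interpreted relative to the manifest's directory; every
#' referenced file must exist and each `(sample_id, image_index)` pair must
#' be unique.
#'
#' @param path manifest CSV path
#' @return data.frame with absolute paths and a `base_dir` attribute
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_cols, names(m))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(m$sample_id, m$image_index)
  if (anyDuplicated(key)) {
    stop("manifest has duplicate (sample_id, image_index) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  base <- dirname(normalizePath(path))
  for (col in c("green_path", "red_path", "mask_path")) {
    m[[col]] <- file.path(base, m[[col]])
    gone <- !file.exists(m[[col]])
    if (any(gone)) {
      stop("manifest references missing files: ",
           paste(utils::head(m[[col]][gone], 3), collapse = ", "),
           if (sum(gone) > 3) sprintf(" (and %d more)", sum(gone) - 3) else "")
    }
  }
  attr(m, "base_dir") <- base
  m
}

#' Write per-cell measurements or sample summaries to CSV
#'
#' Floating-point columns are written with 15 significant digits so that
#' ratios survive a save/load cycle bit-for-bit at the documented
#' precision.
#'
#' @param rows data.frame of cell measurements (or sample summaries)
#' @param path output CSV path
#' @export
write_measurements <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  is_cell <- all(c("ratio", "green_mean") %in% names(rows)) || nrow(rows) == 0
  is_summary <- all(c("mean_ratio", "sd_ratio") %in% names(rows))
  if (!is_cell && !is_summary) {
    stop("rows must be homogeneous cell measurements or sample summaries")
  }
  out <- rows
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurements CSV written by [write_measurements()]
#' @param path CSV path
#' @return data.frame
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a contingency table from a CSV grid
#'
#' First column holds row labels; header holds column labels; cells hold
#' nonnegative integer counts.
#'
#' @param path CSV path
#' @return integer matrix with dimnames
#' @export
read_contingency_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  if (any(is.na(m)) || any(m < 0)) stop("contingency counts must be nonnegative integers")
  m
}
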