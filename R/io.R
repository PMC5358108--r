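#' Multichannel image stacks
#'
#' An image stack is a named list of co-registered 2D nonnegative
#' intensity matrices (channels), typically `CFP`, `GFP`, `RFP`, `DAPI`
#' and optionally `BF` (bright-field). All channels must share dimensions.
#'
#' @param ... named channel matrices (or a single spliced list via
#'   `!!!`).
#' @param pixel_size optional physical pixel size (microns per pixel);
#'   metadata only, never used in computation.
#' @return a `lam_stack` object.
#' @examples
#' s <- image_stack(DAPI = matrix(1, 8, 8), CFP = matrix(0, 8, 8))
#' channel_names(s)
#' @export
image_stack <- function(..., pixel_size = NULL) {
  chans <- rlang::list2(...)
  if (length(chans) == 1 && is.list(chans[[1]]) && !is.matrix(chans[[1]]))
    chans <- chans[[1]]
  if (is.null(names(chans)) || any(names(chans) == ""))
    stop("all channels must be named")
  dims <- unique(lapply(chans, dim))
  if (length(dims) != 1)
    stop("all channels must share dimensions")
  if (any(vapply(chans, function(m) any(!is.finite(m)) || any(m < 0), logical(1))))
    stop("channel intensities must be finite and nonnegative")
  structure(chans, class = "lam_stack", pixel_size = pixel_size)
}

#' @rdname image_stack
#' @export
channel_names <- function(stack) names(stack)

#' @export
print.lam_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<image stack> %d x %d px, channels: %s\n",
              d[1], d[2], paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Read a multichannel TIFF (or directory of single-channel images)
#'
#' Pages are mapped to channel names through `channel_map`, a named
#' integer vector (`c(CFP = 1, GFP = 2, ...)`) for multipage TIFFs or a
#' named character vector of file names for directories. If
#' [write_stack()] left a JSON sidecar next to the file, channel names and
#' any intensity scale are recovered from it automatically. Intensities
#' are taken as stored: 8/16-bit integer data are read unscaled, float
#' data as-is; no normalisation is applied (downstream profiles are
#' normalised, so intensity units cancel).
#'
#' @param path a TIFF file or a directory of single-channel PNG/TIFF
#'   images.
#' @param channel_map named vector mapping channel name to page index or
#'   file name; default maps pages 1-4 to CFP, GFP, RFP, DAPI.
#' @param require channels that must be present (default `CFP`, `GFP`,
#'   `DAPI`, the channels needed for scoring).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL,
                       require = c("CFP", "GFP", "DAPI")) {
  if (dir.exists(path)) {
    if (is.null(channel_map)) {
      files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
      channel_map <- stats::setNames(files, toupper(tools::file_path_sans_ext(files)))
    }
    chans <- lapply(channel_map, function(f) read_gray(file.path(path, f)))
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    # undo the reader's [0,1] scaling for integer pages; float pages
    # (32 bits per sample) are stored as-is
    pages <- lapply(pages, function(p) {
      bits <- attr(p, "bits.per.sample") %||% 32
      collapse_gray(p) * if (bits < 32) 2^bits - 1 else 1
    })
    scale <- 1
    sidecar <- paste0(path, ".json")
    if (is.null(channel_map) && file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      channel_map <- stats::setNames(seq_along(meta$channels), meta$channels)
      scale <- meta$scale %||% 1
    }
    if (is.null(channel_map))
      channel_map <- stats::setNames(seq_len(min(4, length(pages))),
                                     c("CFP", "GFP", "RFP", "DAPI")[seq_len(min(4, length(pages)))])
    bad <- channel_map[channel_map > length(pages)]
    if (length(bad) > 0)
      stop("missing channel(s): ", paste(names(bad), collapse = ", "),
           " (file has ", length(pages), " page(s))")
    chans <- lapply(channel_map, function(i) pages[[i]] * scale)
  }
  missing <- setdiff(require, names(chans))
  if (length(missing) > 0)
    stop("missing required channel(s): ", paste(missing, collapse = ", "))
  dims <- unique(lapply(chans, dim))
  if (length(dims) != 1) stop("channel pages have mismatched dimensions")
  image_stack(!!!chans)
}

# read a single-channel png/tiff as a numeric matrix
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path, as.is = TRUE),
                stop("unsupported image format: ", ext))
  collapse_gray(img)
}

collapse_gray <- function(img) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.numeric(img), nrow(img), ncol(img))  # drop reader attributes
}

#' Write an image stack as a multichannel float TIFF
#'
#' One 32-bit float page per channel. Because the TIFF writer stores
#' values in `[0, 1]`, intensities are divided by a single power-of-two
#' scale covering the stack's maximum; the scale and the channel order are
#' recorded in a JSON sidecar (`<path>.json`) that [read_stack()] uses to
#' restore original values (exactly, up to float32 quantisation).
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  mx <- max(vapply(stack, max, numeric(1)), 0)
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  pages <- lapply(stack, function(m) m / scale)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32)
  jsonlite::write_json(list(channels = names(stack), scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a cell table to CSV
#'
#' @param cells cell table from [place_cells()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
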