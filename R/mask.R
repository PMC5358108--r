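#' Aggregate masks
#'
#' A mask is a binary matrix (0 = background, 1 = aggregate) with a
#' `provenance` attribute recording how it was obtained: `"auto"`
#' (Chan-Vese segmentation), `"manual"` (user-drawn, loaded from file) or
#' `"truth"` (synthetic ground truth). A valid mask has exactly one
#' connected foreground component and no interior holes.
#'
#' @param x binary (0/1 or logical) matrix.
#' @param provenance one of `"auto"`, `"manual"`, `"truth"`.
#' @return `as_mask()` returns a `lam_mask` object (a 0/1 numeric matrix).
#' @examples
#' m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
#' mask <- as_mask(m, "manual")
#' mask_area(mask)
#' @export
as_mask <- function(x, provenance = c("auto", "manual", "truth")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(x)) stop("mask must be a matrix")
  x <- (x != 0) * 1
  structure(x, class = c("lam_mask", class(matrix())), provenance = provenance)
}

#' @rdname as_mask
#' @export
is_mask <- function(x) inherits(x, "lam_mask")

#' @rdname as_mask
#' @export
mask_area <- function(x) sum(x != 0)

#' @rdname as_mask
#' @export
mask_provenance <- function(x) attr(x, "provenance") %||% "manual"

#' @export
print.lam_mask <- function(x, ...) {
  cat(sprintf("<aggregate mask> %d x %d px, area %d px, provenance: %s\n",
              nrow(x), ncol(x), mask_area(x), mask_provenance(x)))
  invisible(x)
}

# coerce anything mask-like (logical/numeric matrix) for internal use
coerce_mask <- function(mask) {
  if (is_mask(mask)) return(mask)
  as_mask(mask, "manual")
}

# centroid of the foreground, c(row, col)
mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  colMeans(idx)
}

# largest connected component -> fill holes; returns plain 0/1 matrix
keep_largest_filled <- function(m) {
  lab <- EBImage::bwlabel(m)
  lab <- EBImage::imageData(lab)
  if (max(lab) < 1) return(m * 0)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  m2 <- (lab == keep) * 1
  EBImage::imageData(EBImage::fillHull(m2))
}

n_components <- function(m) {
  max(EBImage::imageData(EBImage::bwlabel((m != 0) * 1)))
}

has_holes <- function(m) {
  filled <- EBImage::imageData(EBImage::fillHull((m != 0) * 1))
  any(filled != (m != 0) * 1)
}

#' Write a mask to an 8-bit PNG or TIFF file
#'
#' Foreground is stored as 255, background as 0.
#'
#' @param mask a `lam_mask` or binary matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- (coerce_mask(mask) != 0) * 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8)
  } else {
    stop("unsupported mask format: ", ext, " (use png or tiff)")
  }
  invisible(path)
}
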