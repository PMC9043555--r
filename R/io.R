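#' Load a grayscale image or volume
#'
#' Reads PNG, TIFF (including multi-page), or NIfTI (`.nii`/`.nii.gz`)
#' files into a [gray_image] with intensities on the unit scale. RGB
#' inputs are converted to grayscale by averaging the colour channels.
#' 2D images gain a depth axis of size 1; spatial shape is otherwise
#' never changed by loading.
#'
#' @param path file path.
#' @param declared_range scale of the stored intensities: `"8bit"`
#'   (values on \[0,255\], divided by 255 on load) or `"unit"` (already
#'   \[0,1\]). PNG and TIFF readers return unit-scale values for integer
#'   data, so this matters mainly for NIfTI and float TIFF.
#' @return a [gray_image].
#' @export
load_image <- function(path, declared_range = c("8bit", "unit")) {
  declared_range <- match.arg(declared_range)
  if (!file.exists(path)) stop_arg("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  raw_scale <- FALSE  # TRUE when the reader returns values on the declared scale
  arr <- switch(
    ext,
    png = {
      x <- tryCatch(png::readPNG(path),
                    error = function(e) stop_arg("unreadable PNG ", path, ": ",
                                                 conditionMessage(e)))
      collapse_rgb(x)
    },
    tif = ,
    tiff = {
      pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                        error = function(e) stop_arg("unreadable TIFF ", path,
                                                     ": ", conditionMessage(e)))
      if (!is.list(pages)) pages <- list(pages)
      pages <- lapply(pages, collapse_rgb)
      arr <- array(0, c(dim(pages[[1]]), length(pages)))
      for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
      arr
    },
    nii = {
      raw_scale <- TRUE
      x <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop_arg("unreadable NIfTI ", path,
                                                 ": ", conditionMessage(e)))
      a <- as.array(x)
      if (length(dim(a)) > 3) dim(a) <- dim(a)[1:3]
      a
    },
    stop_arg("unsupported image format: .", ext, " (", path, ")")
  )
  if (raw_scale && declared_range == "8bit") arr <- arr / 255
  if (!all(is.finite(arr)))
    stop_arg("format error: non-finite values in ", path)
  if (min(arr) < -1e-9 || max(arr) > 1 + 1e-9)
    stop_arg("format error: intensities outside the declared range in ", path)
  gray_image(clip01(arr), source_range = declared_range)
}

collapse_rgb <- function(x) {
  if (length(dim(x)) == 3) {
    nc <- dim(x)[3]
    if (nc >= 3) x <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3 else x <- x[, , 1]
  }
  x
}

#' Save a grayscale image or volume
#'
#' Writes a [gray_image] to PNG (single slice only), TIFF (multi-page for
#' volumes), or NIfTI. The round trip through [load_image] reproduces the
#' data within one quantization step of the output bit depth.
#'
#' @param img a [gray_image].
#' @param path output file path; the parent directory must exist.
#' @param out_range `"8bit"` quantizes to 8-bit; `"unit"` writes 32-bit
#'   float (TIFF/NIfTI only).
#' @return `invisible(path)`.
#' @export
save_image <- function(img, path, out_range = c("8bit", "unit")) {
  out_range <- match.arg(out_range)
  data <- as_gray_data(img)
  if (!dir.exists(dirname(path)))
    stop_arg("parent directory does not exist: ", dirname(path))
  if (min(data) < 0 || max(data) > 1) {
    warning("clipping out-of-range intensities before saving ", path)
    data <- clip01(data)
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  d <- dim(data)
  switch(
    ext,
    png = {
      if (d[3] != 1) stop_arg("PNG cannot store volumes; use TIFF or NIfTI")
      png::writePNG(data[, , 1], target = path)
    },
    tif = ,
    tiff = {
      pages <- lapply(seq_len(d[3]), function(z) data[, , z])
      bits <- if (out_range == "8bit") 8L else 32L
      tiff::writeTIFF(pages, where = path, bits.per.sample = bits)
    },
    nii = {
      if (out_range == "8bit") {
        RNifti::writeNifti(RNifti::asNifti(round(data * 255)), file = path,
                           datatype = "uint8")
      } else {
        RNifti::writeNifti(RNifti::asNifti(data), file = path,
                           datatype = "float")
      }
    },
    stop_arg("unsupported image format: .", ext, " (", path, ")")
  )
  invisible(path)
}
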