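#' Grayscale image/volume container
#'
#' The universal payload of every pipeline stage: a height x width x depth
#' array of intensities on the unit scale. 2D images are promoted to
#' depth-1 volumes so every downstream operation is dimension-agnostic.
#' Axis order is (y, x, z) with z the slice axis.
#'
#' @param data numeric matrix (2D) or 3D array with finite values in
#'   \[0, 1\].
#' @param source_range descriptor of the original intensity scale, either
#'   `"unit"` (stored in \[0,1\]) or `"8bit"` (stored as \[0,255\]).
#' @param spacing optional numeric length-3 per-axis physical spacing;
#'   recorded but unused by the method.
#' @return an object of class `gray_image`: a list with elements `data`
#'   (3D array), `source_range` and `spacing`.
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8))
#' dim(img$data)  # 8 8 1
#' @export
gray_image <- function(data, source_range = "unit", spacing = NULL) {
  if (is.null(dim(data))) stop_arg("data must be a matrix or 3D array")
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) stop_arg("data must be 2D or 3D")
  if (length(data) == 0) stop_arg("empty image")
  if (!all(is.finite(data))) stop_arg("image contains non-finite values")
  if (min(data) < 0 || max(data) > 1)
    stop_arg("image values must lie in [0, 1]; got range [",
             signif(min(data), 4), ", ", signif(max(data), 4), "]")
  if (!source_range %in% c("unit", "8bit"))
    stop_arg("source_range must be \"unit\" or \"8bit\"")
  if (!is.null(spacing)) stopifnot(is.numeric(spacing), length(spacing) == 3)
  structure(list(data = unname(data), source_range = source_range,
                 spacing = spacing), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gray_image %d x %d x %d, range [%.3f, %.3f], source %s>\n",
              d[1], d[2], d[3], min(x$data), max(x$data), x$source_range))
  invisible(x)
}

as_gray_data <- function(img) {
  if (inherits(img, "gray_image")) img$data
  else if (is.array(img) || is.matrix(img)) gray_image(img)$data
  else stop_arg("expected a gray_image or numeric array")
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_arg(what, " must have the same shape: ",
             paste(dim(a), collapse = "x"), " vs ",
             paste(dim(b), collapse = "x"))
}
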