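# Image preprocessing for the classifier: log-normalization to [0, 1] and
# bilinear resizing to the square network input.

#' Logarithmic normalization of a detector image
#'
#' Applies `x <- log(x + 1) / MaxLog` per pixel, where `MaxLog` is the
#' maximum of the image after the logarithmic transform. The +1 offset keeps
#' the logarithm non-negative for count data; the normalization makes the
#' image independent of counting statistics. The output is in [0, 1] with
#' maximum exactly 1 for any image with a positive pixel. The logarithm base
#' cancels in the ratio.
#'
#' @param image Matrix of non-negative counts.
#' @return The normalized matrix, with the normalizing constant retained as
#'   attribute `"MaxLog"` (natural-log scale).
#' @examples
#' log_normalize(matrix(c(0, 3, 9), 1))  # 0, 0.602, 1 (log 4 / log 10)
#' @export
log_normalize <- function(image) {
  x <- unclass(image)
  if (any(x < 0)) stop("negative pixel values in input image")
  l <- log1p(x)
  maxlog <- max(l)
  if (maxlog == 0)
    stop("all-zero image cannot be normalized (MaxLog = 0); ",
         "clean the dataset first")
  out <- l / maxlog
  attr(out, "MaxLog") <- maxlog
  out
}

#' Bilinear resize
#'
#' Resizes a numeric matrix with half-pixel-centred bilinear interpolation.
#' Output values are convex combinations of input values, so the output
#' range is contained in the input range; an explicit clamp to [0, 1] guards
#' against floating-point spill for normalized inputs.
#'
#' @param image Numeric matrix.
#' @param rows,cols Output dimensions (default the 180 x 180 network input).
#' @param clamp01 Clamp the output to [0, 1].
#' @return The resized matrix.
#' @export
resize_image <- function(image, rows = 180, cols = 180, clamp01 = TRUE) {
  out <- .resize_bilinear_cpp(unclass(image), as.integer(rows),
                              as.integer(cols))
  if (clamp01) out <- pmin(pmax(out, 0), 1)
  out
}

#' Full preprocessing of one detector image
#'
#' Log-normalization followed by the 180 x 180 bilinear resize: the
#' transformation between raw detector counts and classifier input.
#' Interpolation averages neighbouring pixels and so can pull the maximum
#' slightly below 1; a final rescale restores max = 1 so the network input
#' contract (values in [0, 1], maximum exactly 1) holds for any image with a
#' positive pixel. Applied on the fly; stored partitions keep raw counts.
#'
#' @param image 144 x 256 matrix of non-negative counts.
#' @return 180 x 180 matrix in [0, 1] with maximum 1, and attribute
#'   `"MaxLog"`.
#' @export
preprocess_image <- function(image) {
  ln <- log_normalize(image)
  out <- resize_image(ln, 180, 180)
  m <- max(out)
  if (m > 0) out <- out / m
  attr(out, "MaxLog") <- attr(ln, "MaxLog")
  out
}

#' Preprocess a partition into a classifier design matrix
#'
#' @param partition A `sans_partition` (or `sans_dataset`).
#' @return List with `X` (n x 32400 matrix, one flattened 180 x 180 image
#'   per row, column-major) and `y` (integer labels).
#' @export
preprocess_partition <- function(partition) {
  n <- length(partition$target)
  X <- matrix(0, n, 180 * 180)
  for (i in seq_len(n)) {
    img <- partition$data[i, , ]
    X[i, ] <- as.numeric(preprocess_image(img))
  }
  list(X = X, y = as.integer(partition$target))
}
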