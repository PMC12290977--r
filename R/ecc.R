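#' Grayscale image with foreground mask
#'
#' Light container for an 8-bit intensity field on a pixel grid together
#' with a logical foreground mask of the same shape. All topological
#' operations in the package act on this class.
#'
#' @param pixels integer matrix of gray levels in [0, 255].
#' @param mask logical matrix, same shape, with at least one TRUE pixel;
#'   defaults to all-foreground.
#' @return An object of class \code{"gray_image"}.
#' @examples
#' img <- gray_image(matrix(128L, 8, 8))
#' @export
gray_image <- function(pixels, mask = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 255L)) {
    stop("'pixels' must be gray levels in [0, 255]")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(pixels))) {
    stop("'mask' and 'pixels' must have the same shape")
  }
  if (!any(mask)) stop("'mask' must contain at least one foreground pixel")
  structure(list(pixels = pixels, mask = mask), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image %d x %d, %d foreground pixels, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              min(x$pixels[x$mask]), max(x$pixels[x$mask])))
  invisible(x)
}

#' Convert an RGB image to grayscale
#'
#' Standard luminance conversion with weights 0.299 (R), 0.587 (G),
#' 0.114 (B), rounded to the nearest integer gray level. The mask of the
#' result is all-foreground; use [segment_sample()] to restrict it.
#'
#' @param rgb_image numeric array \code{h x w x 3} with channels in
#'   [0, 255].
#' @return A [gray_image()].
#' @examples
#' px <- array(0, c(2, 2, 3)); px[, , 1] <- 255
#' to_grayscale(px)$pixels[1, 1]  # 76
#' @export
to_grayscale <- function(rgb_image) {
  if (length(dim(rgb_image)) != 3L || dim(rgb_image)[3] != 3L) {
    stop("'rgb_image' must be an h x w x 3 array")
  }
  if (any(rgb_image < 0) || any(rgb_image > 255)) {
    stop("channel values must lie in [0, 255]")
  }
  g <- 0.299 * rgb_image[, , 1] + 0.587 * rgb_image[, , 2] +
    0.114 * rgb_image[, , 3]
  gray_image(round(g))
}

#' Segment a sample photographed against a blue background
#'
#' Classifies as background every pixel whose blue channel exceeds the
#' larger of red and green by at least \code{blue_margin} gray levels,
#' keeps the largest 4-connected foreground component, and fills any holes
#' inside it (interior specks of backdrop color are part of the sample).
#'
#' @param rgb_image numeric array \code{h x w x 3}, channels in [0, 255].
#' @param blue_margin gray-level margin of the blue-dominance rule
#'   (default 20).
#' @return A logical foreground mask.
#' @examples
#' px <- array(0, c(10, 10, 3)); px[, , 3] <- 255   # all blue backdrop
#' px[3:7, 3:7, ] <- 120                            # gray sample
#' mask <- segment_sample(px)
#' sum(mask)  # 25
#' @export
segment_sample <- function(rgb_image, blue_margin = 20) {
  if (length(dim(rgb_image)) != 3L || dim(rgb_image)[3] != 3L) {
    stop("'rgb_image' must be an h x w x 3 array")
  }
  bg <- rgb_image[, , 3] >
    pmax(rgb_image[, , 1], rgb_image[, , 2]) + blue_margin
  fg <- !bg
  if (!any(fg)) stop("segmentation failure: no foreground pixels found")
  lab <- EBImage::bwlabel(fg * 1)            # 4-connected labeling
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  filled <- EBImage::fillHull(keep * 1) > 0
  matrix(as.logical(filled), nrow(fg), ncol(fg))
}

#' Euler characteristic of a binary image
#'
#' Computes \eqn{\chi = V - E + F} of the closed cubical complex whose
#' 2-cells are the TRUE pixels (shared edges and vertices identified).
#' Under this closed-square model the value equals the number of
#' 8-connected foreground components minus the number of 4-connected
#' background components that do not touch the image border (the holes).
#'
#' @param binary_image logical matrix (coerced from numeric if needed).
#' @return Integer Euler characteristic.
#' @examples
#' ring <- matrix(TRUE, 5, 5); ring[2:4, 2:4] <- FALSE; ring[3, 3] <- FALSE
#' euler_characteristic(matrix(TRUE, 5, 5))  # 1
#' @export
euler_characteristic <- function(binary_image) {
  B <- as.matrix(binary_image)
  storage.mode(B) <- "logical"
  n <- nrow(B); m <- ncol(B)
  if (!any(B)) return(0L)
  P <- matrix(FALSE, n + 2L, m + 2L)
  P[2:(n + 1L), 2:(m + 1L)] <- B
  faces <- sum(B)
  # horizontal pixel edges: between vertically adjacent cells (incl. border)
  e_h <- sum(P[1:(n + 1L), 2:(m + 1L)] | P[2:(n + 2L), 2:(m + 1L)])
  # vertical pixel edges: between horizontally adjacent cells
  e_v <- sum(P[2:(n + 1L), 1:(m + 1L)] | P[2:(n + 1L), 2:(m + 2L)])
  verts <- sum(P[1:(n + 1L), 1:(m + 1L)] | P[2:(n + 2L), 1:(m + 1L)] |
                 P[1:(n + 1L), 2:(m + 2L)] | P[2:(n + 2L), 2:(m + 2L)])
  as.integer(verts - (e_h + e_v) + faces)
}

#' Euler characteristic curve of a grayscale image
#'
#' Thresholds the masked image at each level of an intensity filtration
#' and records the Euler characteristic of the resulting binary set.
#' In the default superlevel direction, level \eqn{\ell} keeps foreground
#' pixels with intensity \eqn{\ge \ell}: sweeping \eqn{\ell} downward
#' first reveals the bright (lightly stained) domains as components and
#' then the dark (heavily stained) domains as holes. \code{chi_norm} is
#' \eqn{\chi} divided by the foreground pixel count, so curves from images
#' of different sizes are comparable.
#'
#' @param image a [gray_image()].
#' @param levels ordered intensity thresholds in [0, 255]
#'   (default \code{0:255}).
#' @param direction \code{"superlevel"} (keep intensity >= level, the
#'   default) or \code{"sublevel"} (keep intensity <= level).
#' @return An object of class \code{"euler_curve"} with fields
#'   \code{levels}, \code{chi}, \code{chi_norm} and \code{n_pixels} (the
#'   foreground count used for normalization).
#' @examples
#' img <- gray_image(matrix(100L, 6, 6))
#' ec <- euler_curve(img)
#' ec$chi[c(1, 101, 102)]  # 1 1 0
#' @export
euler_curve <- function(image, levels = 0:255,
                        direction = c("superlevel", "sublevel")) {
  stopifnot(inherits(image, "gray_image"))
  direction <- match.arg(direction)
  levels <- as.numeric(levels)
  if (length(levels) == 0L) stop("'levels' must be nonempty")
  if (any(levels < 0) || any(levels > 255) || any(diff(levels) <= 0)) {
    stop("'levels' must be strictly increasing within [0, 255]")
  }
  n_fg <- sum(image$mask)
  chi <- integer(length(levels))
  for (k in seq_along(levels)) {
    B <- if (direction == "superlevel") {
      image$mask & (image$pixels >= levels[k])
    } else {
      image$mask & (image$pixels <= levels[k])
    }
    chi[k] <- euler_characteristic(B)
  }
  structure(list(levels = levels, chi = chi, chi_norm = chi / n_fg,
                 n_pixels = n_fg, direction = direction),
            class = "euler_curve")
}

#' @export
print.euler_curve <- function(x, ...) {
  cat(sprintf(
    "euler_curve: %d levels (%s), chi in [%d, %d], max-min %.4g\n",
    length(x$levels), x$direction, min(x$chi), max(x$chi),
    max_min_difference(x)))
  invisible(x)
}

#' Max-Min uniformity metric of an Euler characteristic curve
#'
#' The difference between the maximum and minimum of the normalized ECC.
#' Sharp, tall peaks (many small domains over a narrow intensity band)
#' give a large value; a uniformly impregnated sample gives a small one.
#' Always nonnegative, and invariant to reversing the level order.
#'
#' @param curve an [euler_curve()].
#' @return Nonnegative dimensionless metric.
#' @examples
#' max_min_difference(euler_curve(gray_image(matrix(50L, 4, 4))))  # 1/16
#' @export
max_min_difference <- function(curve) {
  stopifnot(inherits(curve, "euler_curve"))
  max(curve$chi_norm) - min(curve$chi_norm)
}

#' Detect the double-peak structure of an ECC
#'
#' Images arising from a Gaussian-field-like staining pattern (the
#' signature of a diffusive process) produce an ECC with one positive peak
#' (bright domains appearing as components) and one negative trough (dark
#' domains appearing as holes). This test smooths the normalized curve
#' with a centered moving average, then counts the interior runs exceeding
#' \code{+tol} and falling below \code{-tol}: the flag is TRUE when there
#' is exactly one of each.
#'
#' @param curve an [euler_curve()].
#' @param window moving-average window in levels (odd; default 5).
#' @param tol peak threshold; defaults to \code{1/n_pixels}, i.e. one
#'   normalized unit of a single component, which suppresses the trivial
#'   step curve of a constant image.
#' @return A list with \code{double_peak} (flag), \code{max_level} and
#'   \code{min_level} (filtration levels of the extrema, NA when absent).
#' @examples
#' detect_double_peak(euler_curve(gray_image(matrix(77L, 9, 9))))$double_peak
#' @export
detect_double_peak <- function(curve, window = 5L, tol = NULL) {
  stopifnot(inherits(curve, "euler_curve"))
  if (is.null(tol)) tol <- 1 / curve$n_pixels
  window <- max(1L, as.integer(window))
  s <- as.numeric(stats::filter(curve$chi_norm, rep(1 / window, window),
                                sides = 2))
  s[is.na(s)] <- 0  # window-truncated ends treated as flat
  n <- length(s)
  interior <- seq_len(n) > 1L & seq_len(n) < n

  runs_of <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  pos <- runs_of(s > tol & interior)
  neg <- runs_of(s < -tol & interior)
  max_level <- NA_real_
  min_level <- NA_real_
  if (nrow(pos) >= 1L) {
    i <- pos[1, 1]:pos[1, 2]
    max_level <- curve$levels[i[which.max(s[i])]]
  }
  if (nrow(neg) >= 1L) {
    i <- neg[1, 1]:neg[1, 2]
    min_level <- curve$levels[i[which.min(s[i])]]
  }
  list(double_peak = nrow(pos) == 1L && nrow(neg) == 1L,
       max_level = max_level, min_level = min_level)
}
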