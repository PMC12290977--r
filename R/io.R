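#' Write a grayscale image as an 8-bit PNG
#'
#' @param image a [gray_image()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Read an image file as a grayscale image
#'
#' Reads an 8-bit PNG (or TIFF when the \pkg{tiff} package is available);
#' RGB content is converted with [to_grayscale()], an alpha channel is
#' ignored. The mask is initialized all-foreground.
#'
#' @param path image file path (.png, .tif/.tiff).
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) {
    to_grayscale(a[, , 1:3] * 255)
  } else {
    if (length(dim(a)) == 3L) a <- a[, , 1]
    gray_image(round(a * 255))
  }
}

#' Read a kinetic series from CSV
#'
#' Expects a header \code{time_s,value} (or \code{time_min,value}, in
#' which case times are converted to seconds on read).
#'
#' @param path CSV file path.
#' @param substance label to attach.
#' @return A [kinetic_series()].
#' @export
read_kinetics_csv <- function(path, substance = "") {
  d <- read.csv(path)
  if ("time_s" %in% names(d)) {
    t <- d$time_s
  } else if ("time_min" %in% names(d)) {
    t <- d$time_min * 60
  } else {
    stop("expected a 'time_s' or 'time_min' column")
  }
  if (!"value" %in% names(d)) stop("expected a 'value' column")
  kinetic_series(substance, t, d$value)
}

#' Write a kinetic series to CSV (header \code{time_s,value})
#'
#' @param series a [kinetic_series()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_kinetics_csv <- function(series, path) {
  stopifnot(inherits(series, "kinetic_series"))
  write.csv(data.frame(time_s = series$times, value = series$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a shrinkage series from CSV
#'
#' Expects a header \code{time_s,value} (dimensionless V/V0), as written
#' by [write_shrinkage_csv()].
#'
#' @param path CSV file path.
#' @return A [shrinkage_series()].
#' @export
read_shrinkage_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(d))) {
    stop("expected columns 'time_s' and 'value'")
  }
  shrinkage_series(d$time_s, d$value)
}

#' Write a shrinkage series to CSV (header \code{time_s,value})
#'
#' @param series a [shrinkage_series()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_shrinkage_csv <- function(series, path) {
  stopifnot(inherits(series, "shrinkage_series"))
  write.csv(data.frame(time_s = series$times, value = series$v_ratio),
            path, row.names = FALSE)
  invisible(path)
}

#' Write an Euler characteristic curve to CSV
#'
#' Columns \code{level,chi,chi_norm}.
#'
#' @param curve an [euler_curve()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_euler_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "euler_curve"))
  write.csv(data.frame(level = curve$levels, chi = curve$chi,
                       chi_norm = curve$chi_norm),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds the [simulation_config()] field names; unknown fields
#' are rejected by the constructor's validation.
#'
#' @param path .yaml/.yml (requires the \pkg{yaml} package) or .json file.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(simulation_config, lst)
}
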