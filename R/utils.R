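# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# MD5 of a serialized configuration list; used to stamp run artifacts.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

as_pixel_matrix <- function(x, what = "image") {
  if (inherits(x, "noisy_stimulus")) x <- x$pixels
  if (inherits(x, "ground_truth_axis")) x <- x$pixels
  if (inherits(x, "classification_image")) x <- x$pixel_ci
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  x
}

#' Write a grayscale image as an 8-bit PNG
#'
#' Values are clipped to \code{[0, 1]} and quantized to 8 bits. Reading the
#' file back with [read_png_gray()] reproduces the quantized pixels exactly.
#'
#' @param image Numeric matrix with values in \code{[0, 1]}.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png_gray <- function(image, path) {
  image <- as_pixel_matrix(image)
  png::writePNG(clip01(image), target = path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG as a numeric matrix
#'
#' @param path PNG file path.
#' @return Numeric matrix with values in \code{[0, 1]}; color images are
#'   reduced to their first channel.
#' @export
read_png_gray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
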