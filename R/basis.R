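#' Construct a sinusoid patch noise basis
#'
#' Builds the fixed dictionary of localized sinusoid components used to
#' generate noise images. The image is tiled, at each spatial scale, into a
#' regular grid of square patches; every patch holds one sinusoid per
#' combination of orientation and phase, spanning `cycles_per_patch` cycles
#' across the patch and zero outside it. A noise image is a weighted sum of
#' all components, with weights given by a parameter vector (see
#' [synthesize_noise()]).
#'
#' With the defaults (five scales at 2, 4, 8, 16, 32 cycles/image realised by
#' grids of 1, 2, 4, 8, 16 patches per side, six orientations and two phases)
#' the basis has \eqn{K = 4092} parameters, split (12, 48, 192, 768, 3072)
#' across scales.
#'
#' Orientation is measured in degrees from the horizontal image axis, with
#' the row index increasing downwards; phase is in radians. Each component
#' has unit sinusoid amplitude before weighting, so parameter magnitudes are
#' comparable across scales.
#'
#' @param image_size Pixels per side of the (square) noise image. Must be
#'   divisible by every grid dimension.
#' @param scales Nominal spatial frequencies, in cycles/image, one per scale
#'   layer. Labels only; the realised frequency is
#'   `cycles_per_patch * grid_dims`.
#' @param grid_dims Patches per side at each scale; same length as `scales`.
#' @param orientations Sinusoid orientations in degrees.
#' @param phases Sinusoid phases in radians.
#' @param cycles_per_patch Sinusoid cycles spanning one patch.
#' @return An object of class `noise_basis`: a list with the configuration,
#'   the total parameter count `K`, and a `components` data frame mapping
#'   each parameter index to its (scale, patch_row, patch_col, orientation,
#'   phase) coordinates.
#' @examples
#' b <- noise_basis(image_size = 64)
#' b$K                      # 4092
#' table(b$components$scale)
#' @export
noise_basis <- function(image_size = 512,
                        scales = c(2, 4, 8, 16, 32),
                        grid_dims = c(1, 2, 4, 8, 16),
                        orientations = c(0, 30, 60, 90, 120, 150),
                        phases = c(0, pi / 2),
                        cycles_per_patch = 2) {
  stopifnot(length(image_size) == 1L, image_size >= 1,
            image_size == round(image_size),
            length(scales) >= 1L, length(grid_dims) == length(scales),
            length(orientations) >= 1L, length(phases) >= 1L,
            cycles_per_patch > 0)
  if (anyDuplicated(scales))
    stop("scales must be distinct", call. = FALSE)
  bad <- which(image_size %% grid_dims != 0)
  if (length(bad))
    stop("image_size ", image_size, " is not divisible by grid_dim ",
         grid_dims[bad[1L]], " (scale ", scales[bad[1L]], " cycles/image)",
         call. = FALSE)

  n_op <- length(orientations) * length(phases)
  comp <- do.call(rbind, lapply(seq_along(scales), function(s) {
    g <- grid_dims[s]
    d <- expand.grid(phase = phases, orientation = orientations,
                     patch_col = seq_len(g), patch_row = seq_len(g),
                     KEEP.OUT.ATTRS = FALSE)
    data.frame(scale = scales[s], grid_dim = g,
               patch_row = d$patch_row, patch_col = d$patch_col,
               orientation = d$orientation, phase = d$phase)
  }))
  comp <- cbind(index = seq_len(nrow(comp)), comp)
  rownames(comp) <- NULL

  basis <- structure(list(
    image_size = as.integer(image_size),
    scales = scales, grid_dims = as.integer(grid_dims),
    orientations = orientations, phases = phases,
    cycles_per_patch = cycles_per_patch,
    n_op = n_op,
    K = nrow(comp),
    components = comp,
    scale_index = lapply(seq_along(scales),
                         function(s) which(comp$scale == scales[s])),
    patterns = NULL, pixel_order = NULL, amp_bound = NULL
  ), class = "noise_basis")

  # Per-scale machinery: the patch-local sinusoid stack (identical for every
  # patch at a scale) and the pixel permutation that lays patch blocks out
  # into the full image.
  basis$patterns <- lapply(seq_along(scales), function(s)
    patch_patterns(basis, s))
  basis$pixel_order <- lapply(seq_along(scales), function(s)
    patch_pixel_order(image_size, grid_dims[s]))
  basis$amp_bound <- sum(vapply(basis$patterns, function(S)
    max(rowSums(abs(S))), numeric(1)))
  basis
}

# p^2 x (n_orient * n_phase) matrix: one column per (orientation, phase),
# phase varying fastest, rows in column-major patch order (row index = y).
patch_patterns <- function(basis, s) {
  p <- basis$image_size / basis$grid_dims[s]
  x <- matrix(rep(0:(p - 1), each = p), nrow = p * p, ncol = 1)  # column
  y <- matrix(rep(0:(p - 1), times = p), nrow = p * p, ncol = 1) # row
  cols <- expand.grid(phase = basis$phases, orientation = basis$orientations,
                      KEEP.OUT.ATTRS = FALSE)
  S <- matrix(0, nrow = p * p, ncol = nrow(cols))
  for (j in seq_len(nrow(cols))) {
    th <- cols$orientation[j] * pi / 180
    S[, j] <- sin(2 * pi * basis$cycles_per_patch *
                    (x * cos(th) + y * sin(th)) / p + cols$phase[j])
  }
  S
}

# Index vector ord such that image_vector[ord] <- stacked patch blocks
# (patches ordered patch_col fastest, matching the component table).
patch_pixel_order <- function(image_size, g) {
  p <- image_size / g
  ord <- integer(image_size * image_size)
  pos <- 1L
  for (i in seq_len(g)) {       # patch_row
    for (j in seq_len(g)) {     # patch_col
      for (x in seq_len(p)) {   # patch column -> image column
        col0 <- (j - 1L) * p + x - 1L
        ord[pos:(pos + p - 1L)] <- col0 * image_size + (i - 1L) * p +
          seq_len(p)
        pos <- pos + p
      }
    }
  }
  ord
}

#' @export
print.noise_basis <- function(x, ...) {
  cat("Sinusoid noise basis\n")
  cat("  image size :", x$image_size, "x", x$image_size, "px\n")
  cat("  parameters :", x$K, "\n")
  counts <- vapply(x$scale_index, length, integer(1))
  cat("  scales     :", paste0(x$scales, " c/img (", counts, ")",
                               collapse = ", "), "\n")
  cat("  orientations:", paste(x$orientations, collapse = ", "),
      "deg; phases:", paste(signif(x$phases, 3), collapse = ", "), "rad\n")
  invisible(x)
}

basis_config <- function(basis) {
  basis[c("image_size", "scales", "grid_dims", "orientations", "phases",
          "cycles_per_patch")]
}

same_basis <- function(a, b) isTRUE(all.equal(basis_config(a), basis_config(b)))

#' Sample uniform amplitude parameter vectors
#'
#' Draws `n` parameter vectors with i.i.d. Uniform(-1, 1) entries, one
#' amplitude per basis component.
#'
#' @param basis A [noise_basis()].
#' @param n Number of vectors.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return An `n` by `K` numeric matrix, one parameter vector per row.
#' @export
sample_parameters <- function(basis, n, seed = NULL) {
  stopifnot(inherits(basis, "noise_basis"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed,
    matrix(stats::runif(n * basis$K, -1, 1), nrow = n, ncol = basis$K))
}

# Core synthesis kernel: P is n x K (rows = parameter vectors); returns a
# (image_size^2) x n matrix, one image per column. `scales` restricts to a
# subset of scale layers.
synthesize_batch <- function(basis, P, scales = seq_along(basis$scales)) {
  n <- nrow(P)
  npix <- basis$image_size^2
  out <- matrix(0, nrow = npix, ncol = n)
  for (s in scales) {
    g <- basis$grid_dims[s]
    A <- t(P[, basis$scale_index[[s]], drop = FALSE])     # K_s x n
    dim(A) <- c(basis$n_op, g * g * n)
    M <- basis$patterns[[s]] %*% A                        # p^2 x (g^2 n)
    dim(M) <- c(npix, n)
    ord <- basis$pixel_order[[s]]
    out[ord, ] <- out[ord, ] + M
  }
  out
}

#' Synthesize a noise image from a parameter vector
#'
#' The noise image is the exactly linear combination
#' \eqn{\sum_k a_k \, C_k} of the basis components \eqn{C_k} weighted by the
#' amplitudes \eqn{a_k}. No clipping or quantization is applied.
#'
#' @param basis A [noise_basis()].
#' @param params Numeric vector of length `basis$K`.
#' @return An `image_size` by `image_size` numeric matrix with attribute
#'   `amp_bound`, the basis-wide bound on \eqn{\max_j \sum_k |C_k(j)|} used
#'   by [superimpose()] to map noise into display range.
#' @export
synthesize_noise <- function(basis, params) {
  stopifnot(inherits(basis, "noise_basis"))
  params <- check_params(basis, params)
  img <- synthesize_batch(basis, matrix(params, nrow = 1))
  dim(img) <- c(basis$image_size, basis$image_size)
  attr(img, "amp_bound") <- basis$amp_bound
  img
}

check_params <- function(basis, params) {
  if (!is.numeric(params) || length(params) != basis$K)
    stop("parameter vector has length ", length(params),
         "; basis expects ", basis$K, call. = FALSE)
  if (!all(is.finite(params)))
    stop("parameter vector contains non-finite values", call. = FALSE)
  as.numeric(params)
}

#' Synthesize the noise carried by a single spatial scale
#'
#' Restricts synthesis to the components of one scale layer. The projections
#' over all scales sum exactly to the full [synthesize_noise()] image.
#'
#' @inheritParams synthesize_noise
#' @param scale One of `basis$scales` (cycles/image).
#' @return Numeric pixel matrix.
#' @export
project_to_scale <- function(basis, params, scale) {
  stopifnot(inherits(basis, "noise_basis"))
  params <- check_params(basis, params)
  s <- match_scale(basis, scale)
  img <- synthesize_batch(basis, matrix(params, nrow = 1), scales = s)
  dim(img) <- c(basis$image_size, basis$image_size)
  img
}

match_scale <- function(basis, scale) {
  s <- match(scale, basis$scales)
  if (is.na(s))
    stop("unknown scale ", scale, "; basis scales are ",
         paste(basis$scales, collapse = ", "), call. = FALSE)
  s
}
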