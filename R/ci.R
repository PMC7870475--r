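#' Estimate a classification image from trial records
#'
#' The classification image (CI) is the reverse-correlation estimate of the
#' observer's internal template: in parameter space it is the difference of
#' class-conditional mean noise amplitudes,
#' \deqn{\hat{c}_k = \overline{a_k \mid \mathrm{female}} -
#'       \overline{a_k \mid \mathrm{male}},}
#' and in pixel space it is the synthesis of \eqn{\hat{c}} through the noise
#' basis. For a linear template observer the pixel CI converges (up to
#' scale) on the observer's true axis as the number of trials grows.
#'
#' @param trials Data frame of trial records with columns `label`
#'   (`"female"`/`"male"`) and `pv_id` (row index into `params`; `NA` falls
#'   back to the trial's own row position).
#' @param params Matrix of parameter vectors (trials in rows), as produced
#'   by [sample_parameters()].
#' @param basis The [noise_basis()] the parameters refer to.
#' @return An object of class `classification_image` with components
#'   `param_ci` (length-`K` vector), `pixel_ci` (pixel matrix), `n_female`,
#'   `n_male`, and `basis`. Supports `print()`, `summary()`, `coef()`
#'   (the parameter-space CI), `plot()`, and `predict()` (CI activations of
#'   new images, see [ci_activation()]).
#' @examples
#' b <- noise_basis(image_size = 32, scales = c(2, 4), grid_dims = c(1, 2))
#' P <- sample_parameters(b, 200, seed = 1)
#' lab <- ifelse(P[, 1] > 0, "female", "male")
#' ci <- compute_ci(data.frame(label = lab), P, b)
#' which.max(abs(coef(ci)))  # parameter 1 drives the labels
#' @export
compute_ci <- function(trials, params, basis) {
  stopifnot(is.data.frame(trials), is.matrix(params),
            inherits(basis, "noise_basis"))
  if (ncol(params) != basis$K)
    stop("params has ", ncol(params), " columns; basis expects ", basis$K,
         call. = FALSE)
  idx <- trial_param_rows(trials, params)
  lab <- as.character(trials$label)
  bad <- setdiff(unique(lab), c("female", "male"))
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  f <- idx[lab == "female"]
  m <- idx[lab == "male"]
  if (length(f) == 0L) stop("no trials labelled 'female'", call. = FALSE)
  if (length(m) == 0L) stop("no trials labelled 'male'", call. = FALSE)
  param_ci <- colMeans(params[f, , drop = FALSE]) -
    colMeans(params[m, , drop = FALSE])
  pixel_ci <- synthesize_noise(basis, param_ci)
  attr(pixel_ci, "amp_bound") <- NULL
  structure(list(param_ci = unname(param_ci), pixel_ci = pixel_ci,
                 n_female = length(f), n_male = length(m), basis = basis),
            class = "classification_image")
}

trial_param_rows <- function(trials, params) {
  idx <- if ("pv_id" %in% names(trials)) as.integer(trials$pv_id)
         else rep(NA_integer_, nrow(trials))
  idx[is.na(idx)] <- seq_len(nrow(trials))[is.na(idx)]
  if (any(idx < 1L | idx > nrow(params)))
    stop("pv_id out of range of the parameter store", call. = FALSE)
  idx
}

#' @export
print.classification_image <- function(x, ...) {
  cat("Classification image (female - male)\n")
  cat("  trials     :", x$n_female, "female /", x$n_male, "male\n")
  cat("  parameters :", length(x$param_ci), "| image",
      nrow(x$pixel_ci), "x", ncol(x$pixel_ci), "px\n")
  invisible(x)
}

#' @export
summary.classification_image <- function(object, ...) {
  b <- object$basis
  energy <- vapply(seq_along(b$scales), function(s) {
    img <- synthesize_batch(b, matrix(object$param_ci, nrow = 1), scales = s)
    sum(img^2)
  }, numeric(1))
  out <- list(
    n_female = object$n_female, n_male = object$n_male,
    scale_energy = data.frame(scale = b$scales, energy = energy,
                              share = energy / sum(energy)),
    pixel_range = range(object$pixel_ci))
  class(out) <- "summary.classification_image"
  out
}

#' @export
print.summary.classification_image <- function(x, ...) {
  cat("Classification image summary\n")
  cat("  trials:", x$n_female, "female /", x$n_male, "male\n")
  cat("  pixel range: [", signif(x$pixel_range[1], 4), ",",
      signif(x$pixel_range[2], 4), "]\n")
  cat("  pixel energy by scale (cycles/image):\n")
  se <- x$scale_energy
  for (i in seq_len(nrow(se)))
    cat(sprintf("    %4g : %5.1f%%\n", se$scale[i], 100 * se$share[i]))
  invisible(x)
}

#' @export
coef.classification_image <- function(object, ...) object$param_ci

#' @export
plot.classification_image <- function(x, scale = NULL, ...) {
  img <- if (is.null(scale)) x$pixel_ci else ci_by_scale(x, scale)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = 1,
                  main = if (is.null(scale)) "Classification image"
                         else paste0("CI at ", scale, " cycles/image"), ...)
  invisible(x)
}

#' @param object A `classification_image`.
#' @param newdata A pixel matrix, a list of pixel matrices, or a 3-D array
#'   of images.
#' @param center Mean-center each image before the inner product (default).
#' @param ... Unused.
#' @return Numeric vector of CI activations, one per image.
#' @rdname compute_ci
#' @export
predict.classification_image <- function(object, newdata, center = TRUE,
                                         ...) {
  imgs <- as_image_list(newdata)
  vapply(imgs, function(im) ci_activation(object, im, center = center),
         numeric(1))
}

#' Synthesize the part of a CI carried by one spatial scale
#'
#' @param ci A `classification_image`.
#' @param scale One of the basis scales (cycles/image).
#' @return Pixel matrix; the per-scale images over all scales sum exactly to
#'   `ci$pixel_ci`.
#' @export
ci_by_scale <- function(ci, scale) {
  stopifnot(inherits(ci, "classification_image"))
  b <- ci$basis
  s <- match_scale(b, scale)
  img <- synthesize_batch(b, matrix(ci$param_ci, nrow = 1), scales = s)
  dim(img) <- c(b$image_size, b$image_size)
  img
}

#' Correlate two classification images
#'
#' Pearson correlation between two CIs, by default over flattened pixel
#' images, optionally over parameter vectors (basis-exact), and optionally
#' one correlation per spatial scale. Pearson r is invariant to affine
#' display normalization, so raw and normalized CIs give identical values.
#'
#' @param ci_a,ci_b `classification_image` objects on the same basis.
#' @param space `"pixel"` or `"parameter"`.
#' @param per_scale Also report one correlation per scale.
#' @return An object of class `ci_similarity`: list with `r` (overall),
#'   `space`, and `per_scale` (named vector or `NULL`). A zero-variance CI
#'   yields `NA` with a warning rather than a fabricated 0.
#' @export
ci_similarity <- function(ci_a, ci_b, space = c("pixel", "parameter"),
                          per_scale = FALSE) {
  stopifnot(inherits(ci_a, "classification_image"),
            inherits(ci_b, "classification_image"))
  if (!same_basis(ci_a$basis, ci_b$basis))
    stop("classification images use different bases", call. = FALSE)
  space <- match.arg(space)
  r <- if (space == "pixel")
    safe_cor(as.numeric(ci_a$pixel_ci), as.numeric(ci_b$pixel_ci))
  else safe_cor(ci_a$param_ci, ci_b$param_ci)
  ps <- NULL
  if (per_scale) {
    b <- ci_a$basis
    ps <- vapply(b$scales, function(sc) {
      if (space == "pixel")
        safe_cor(as.numeric(ci_by_scale(ci_a, sc)),
                 as.numeric(ci_by_scale(ci_b, sc)))
      else {
        k <- b$scale_index[[match_scale(b, sc)]]
        safe_cor(ci_a$param_ci[k], ci_b$param_ci[k])
      }
    }, numeric(1))
    names(ps) <- b$scales
  }
  structure(list(r = r, space = space, per_scale = ps),
            class = "ci_similarity")
}

safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: zero-variance input", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' @export
print.ci_similarity <- function(x, ...) {
  cat("CI similarity (", x$space, " space): r = ", signif(x$r, 3), "\n",
      sep = "")
  if (!is.null(x$per_scale)) {
    cat("  per scale (cycles/image):\n")
    for (s in names(x$per_scale))
      cat(sprintf("    %4s : r = %s\n", s, signif(x$per_scale[[s]], 3)))
  }
  invisible(x)
}

#' Normalize a CI to 8-bit for display
#'
#' Affine map of the pixel CI to \code{[0, 1]} followed by 8-bit
#' quantization. Display-only: analysis always uses the raw CI.
#'
#' @param ci A `classification_image` or pixel matrix.
#' @return Integer matrix with values in 0..255 and attribute `mapping`
#'   (the affine offset/scale used).
#' @export
normalize_ci_for_display <- function(ci) {
  px <- as_pixel_matrix(ci, "ci")
  rng <- range(px)
  if (rng[1] == rng[2])
    stop("constant classification image cannot be normalized", call. = FALSE)
  u <- (px - rng[1]) / (rng[2] - rng[1])
  out <- matrix(as.integer(round(u * 255)), nrow = nrow(px))
  attr(out, "mapping") <- c(offset = rng[1], scale = rng[2] - rng[1])
  out
}
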