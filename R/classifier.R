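# CI-weighted one-layer classifier: the CI as the connected weights of a
# single output unit, applied to aligned face images.

as_image_list <- function(x) {
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  if (is.list(x)) return(lapply(x, as_pixel_matrix, what = "image"))
  stop("images must be a matrix, a 3-D array, or a list of matrices",
       call. = FALSE)
}

#' Activation of an image under a CI weight map
#'
#' The inner product of an image with the CI, using the whole image as the
#' input layer and the CI as the weights of a one-layer network with one
#' output unit. By default each image is mean-centered first, so the
#' activation is invariant to adding a constant brightness.
#'
#' @param ci A `classification_image` or a pixel matrix of weights.
#' @param image Pixel matrix, same size as the CI.
#' @param center Subtract the image mean before the inner product.
#' @return A single activation value.
#' @export
ci_activation <- function(ci, image, center = TRUE) {
  w <- as_pixel_matrix(ci, "ci")
  image <- as_pixel_matrix(image, "image")
  if (!identical(dim(w), dim(image)))
    stop("image is ", paste(dim(image), collapse = "x"),
         " but CI is ", paste(dim(w), collapse = "x"), call. = FALSE)
  if (center) image <- image - mean(image)
  sum(image * w)
}

# Vectorized activations for a stack of images (npix x n).
activation_stack <- function(w, mat, center = TRUE) {
  if (center) mat <- sweep(mat, 2, colMeans(mat))
  as.numeric(crossprod(mat, as.numeric(w)))
}

#' Class separation of CI activations
#'
#' Computes the activation of every image in two class-labelled sets and
#' summarizes their separation as Cohen's d with the pooled SD, signed as
#' female mean minus male mean. A well-estimated CI of a gender-diagnostic
#' template separates the two classes; a scrambled CI does not (see
#' [randomized_ci_baseline()]).
#'
#' @param ci A `classification_image` or weight matrix.
#' @param female_images,male_images Image sets: list of matrices, 3-D array,
#'   or a single matrix; at least 2 images per class.
#' @param center Mean-center images before the inner product.
#' @return Object of class `activation_distribution`: activations per
#'   class, class means, pooled SD, and `d`.
#' @export
separation <- function(ci, female_images, male_images, center = TRUE) {
  w <- as_pixel_matrix(ci, "ci")
  fi <- as_image_list(female_images)
  mi <- as_image_list(male_images)
  if (length(fi) < 2L || length(mi) < 2L)
    stop("need at least 2 images per class", call. = FALSE)
  af <- vapply(fi, function(im) ci_activation(w, im, center), numeric(1))
  am <- vapply(mi, function(im) ci_activation(w, im, center), numeric(1))
  structure(summarize_separation(af, am), class = "activation_distribution")
}

summarize_separation <- function(af, am, strict = TRUE) {
  nf <- length(af); nm <- length(am)
  sp <- sqrt(((nf - 1) * stats::var(af) + (nm - 1) * stats::var(am)) /
               (nf + nm - 2))
  if (sp == 0) {
    if (strict)
      stop("degenerate pooled SD: activations are constant", call. = FALSE)
    return(list(female = af, male = am, mean_female = mean(af),
                mean_male = mean(am), pooled_sd = 0, d = NA_real_))
  }
  list(female = af, male = am, mean_female = mean(af),
       mean_male = mean(am), pooled_sd = sp,
       d = (mean(af) - mean(am)) / sp)
}

#' @export
print.activation_distribution <- function(x, ...) {
  cat("CI activations: ", length(x$female), " female / ", length(x$male),
      " male images\n", sep = "")
  cat("  class means: ", signif(x$mean_female, 4), " vs ",
      signif(x$mean_male, 4), "; pooled SD ", signif(x$pooled_sd, 4),
      "\n  Cohen's d (female - male): ", signif(x$d, 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.activation_distribution <- function(x, breaks = 30, ...) {
  rng <- range(c(x$female, x$male))
  br <- seq(rng[1], rng[2], length.out = breaks)
  hf <- graphics::hist(x$female, breaks = br, plot = FALSE)
  hm <- graphics::hist(x$male, breaks = br, plot = FALSE)
  ylim <- c(0, max(hf$counts, hm$counts))
  graphics::plot(hf, col = grDevices::adjustcolor("tomato", 0.5),
                 ylim = ylim, xlab = "activation",
                 main = "CI activation by class", ...)
  graphics::plot(hm, col = grDevices::adjustcolor("steelblue", 0.5),
                 add = TRUE)
  graphics::legend("topright", c("female", "male"),
                   fill = grDevices::adjustcolor(c("tomato", "steelblue"),
                                                 0.5), bty = "n")
  invisible(x)
}

#' Pixel-permutation baseline for CI class separation
#'
#' Scrambles the CI's pixels `n_perm` times and recomputes the class
#' separation each time. A genuine CI should separate the classes far
#' beyond this baseline; its distribution of |d| quantifies how much
#' separation arises from pixel statistics alone, with the spatial
#' structure destroyed.
#'
#' @inheritParams separation
#' @param n_perm Number of pixel permutations.
#' @param seed Integer seed for the permutations.
#' @return List with `d_perm` (signed d per permutation), `mean_abs_d`,
#'   `q95_abs_d`, and `d_true` (the unpermuted separation).
#' @export
randomized_ci_baseline <- function(ci, female_images, male_images,
                                   n_perm = 200, seed = NULL,
                                   center = TRUE) {
  stopifnot(n_perm >= 1)
  w <- as_pixel_matrix(ci, "ci")
  fm <- stimulus_stack(as_image_list(female_images))
  mm <- stimulus_stack(as_image_list(male_images))
  if (center) {
    fm <- sweep(fm, 2, colMeans(fm))
    mm <- sweep(mm, 2, colMeans(mm))
  }
  wv <- as.numeric(w)
  d_true <- summarize_separation(as.numeric(crossprod(fm, wv)),
                                 as.numeric(crossprod(mm, wv)))$d
  d_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pw <- wv[sample.int(length(wv))]
    summarize_separation(as.numeric(crossprod(fm, pw)),
                         as.numeric(crossprod(mm, pw)),
                         strict = FALSE)$d
  }, numeric(1)))
  list(d_perm = d_perm,
       mean_abs_d = mean(abs(d_perm), na.rm = TRUE),
       q95_abs_d = unname(stats::quantile(abs(d_perm), 0.95, na.rm = TRUE)),
       d_true = d_true)
}
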