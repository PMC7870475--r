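# Synthetic ground truth: axes, templates, and class-labelled image
# populations. These stand in for the internal templates and aligned face
# sets that a real experiment would estimate or collect, and give every
# pipeline stage a known answer to recover.

#' Build a ground-truth axis from known basis components
#'
#' An axis is a sparse, known linear combination of noise-basis components,
#' normalized to unit Frobenius norm. It plays the role of the internal
#' class-diagnostic template of a synthetic observer: a [linear_observer()]
#' built on it classifies by the noise's projection on the axis, and the
#' reverse-correlation pipeline should recover it.
#'
#' The `"lowfreq"` preset draws components concentrated at the two lowest
#' scales (at least 80% of the squared coefficient mass), mirroring the
#' empirical finding that gender-diagnostic information lives mainly at low
#' spatial frequencies.
#'
#' @param basis A [noise_basis()].
#' @param components Integer vector of component indices; `NULL` draws them
#'   according to `preset`.
#' @param coefficients Numeric coefficients, one per component; `NULL` uses
#'   random signs of equal magnitude.
#' @param preset `"lowfreq"` (low-scale dominant draw) or `"uniform"`
#'   (components drawn uniformly over the basis).
#' @param n_components Number of components when drawing.
#' @param seed Integer seed.
#' @return Object of class `ground_truth_axis`: `pixels` (unit-norm
#'   matrix), `indices`, `coefficients` (rescaled so the recorded
#'   combination reconstructs `pixels` exactly), and `scale_mass`, the
#'   squared-coefficient share per scale.
#' @export
make_axis <- function(basis, components = NULL, coefficients = NULL,
                      preset = c("lowfreq", "uniform"),
                      n_components = 10, seed = NULL) {
  stopifnot(inherits(basis, "noise_basis"))
  preset <- match.arg(preset)
  if (is.null(components)) {
    components <- with_seed(seed, draw_components(basis, preset,
                                                  n_components))
  }
  components <- as.integer(components)
  if (length(components) == 0L)
    stop("empty component specification", call. = FALSE)
  if (any(components < 1L | components > basis$K))
    stop("component indices out of range [1, ", basis$K, "]", call. = FALSE)
  if (is.null(coefficients)) {
    coefficients <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                              sample(c(-1, 1), length(components),
                                     replace = TRUE))
  }
  stopifnot(length(coefficients) == length(components))
  pv <- numeric(basis$K)
  pv[components] <- coefficients
  px <- synthesize_noise(basis, pv)
  attr(px, "amp_bound") <- NULL
  nrm <- sqrt(sum(px^2))
  if (nrm == 0) stop("axis synthesizes to zero", call. = FALSE)
  px <- px / nrm
  coefficients <- coefficients / nrm
  mass <- vapply(basis$scales, function(s) {
    k <- basis$scale_index[[match_scale(basis, s)]]
    sum(coefficients[components %in% k]^2)
  }, numeric(1))
  names(mass) <- basis$scales
  structure(list(pixels = px, indices = components,
                 coefficients = coefficients,
                 scale_mass = mass / sum(mass), basis = basis_config(basis)),
            class = "ground_truth_axis")
}

# lowfreq: fixed proportions (0.4, 0.4, 0.1, 0.1, 0, ...) over scales with
# remainder to the lowest scale, guaranteeing >= 80% of the component count
# (and, with equal-magnitude coefficients, squared mass) at the two lowest.
draw_components <- function(basis, preset, n) {
  stopifnot(n >= 1)
  if (preset == "uniform")
    return(sample.int(basis$K, n))
  ns <- length(basis$scales)
  prop <- c(0.4, 0.4, 0.1, 0.1, rep(0, max(0, ns - 4)))[seq_len(ns)]
  counts <- floor(prop * n)
  counts[1] <- counts[1] + n - sum(counts)
  unlist(lapply(seq_len(ns), function(s) {
    if (counts[s] == 0) return(integer(0))
    k <- basis$scale_index[[s]]
    k[sample.int(length(k), counts[s])]
  }))
}

#' @export
print.ground_truth_axis <- function(x, ...) {
  cat("Ground-truth axis:", length(x$indices), "components,",
      nrow(x$pixels), "x", ncol(x$pixels), "px\n")
  cat("  squared-mass by scale:",
      paste0(names(x$scale_mass), "c/img=",
             round(100 * x$scale_mass), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic template image
#'
#' Smooth, mid-gray-dominant square images standing in for the
#' gender-neutral morph template. `"flat"` is constant 0.5 (and makes the
#' linear-observer recovery theorem exact); `"radial"` is a centered
#' Gaussian brightness bump; `"schematic"` sketches a face (darker ellipses
#' at eye/nose/mouth positions) for documentation figures.
#'
#' @param size Pixels per side.
#' @param style `"flat"`, `"radial"` or `"schematic"`.
#' @return Numeric matrix in \code{[0, 1]}.
#' @export
make_template <- function(size, style = c("flat", "radial", "schematic")) {
  style <- match.arg(style)
  stopifnot(size >= 4)
  if (style == "flat") return(matrix(0.5, size, size))
  cx <- (size + 1) / 2
  r <- sqrt(outer((seq_len(size) - cx)^2, (seq_len(size) - cx)^2, "+"))
  img <- 0.35 + 0.3 * exp(-(r / (0.45 * size))^2)
  if (style == "schematic") {
    add_ellipse <- function(img, y0, x0, ry, rx, depth) {
      yy <- (row(img) - y0 * size) / (ry * size)
      xx <- (col(img) - x0 * size) / (rx * size)
      img - depth * exp(-(yy^2 + xx^2) * 4)
    }
    img <- add_ellipse(img, 0.38, 0.33, 0.05, 0.09, 0.25)  # left eye
    img <- add_ellipse(img, 0.38, 0.67, 0.05, 0.09, 0.25)  # right eye
    img <- add_ellipse(img, 0.58, 0.50, 0.10, 0.04, 0.12)  # nose
    img <- add_ellipse(img, 0.78, 0.50, 0.04, 0.14, 0.20)  # mouth
  }
  clip01(img)
}

#' Generate a class-labelled synthetic image population
#'
#' Emulates two aligned face populations differing along a known axis:
#' class-female images are \eqn{\mathrm{clip}(T + e\,A + \epsilon)} and
#' class-male images \eqn{\mathrm{clip}(T - e\,A + \epsilon)}, with
#' template \eqn{T}, unit-norm axis \eqn{A}, effect size \eqn{e} and i.i.d.
#' pixel noise \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2)}. Defaults are
#' chosen so clipping is rare and the closed-form separation
#' \eqn{d = 2e\lVert A\rVert / \mathrm{noise\_sd}} of an ideal CI holds to
#' good approximation.
#'
#' @param template Template pixel matrix.
#' @param axis A `ground_truth_axis` or pixel matrix.
#' @param effect_size Displacement along the axis per class (default 0.1).
#' @param noise_sd Pixel noise SD (default 0.05).
#' @param n_per_class Images per class, at least 2 (default 500).
#' @param seed Integer seed; the recipe plus seed regenerates the
#'   population exactly.
#' @return Object of class `synthetic_population`: 3-D arrays `female` and
#'   `male` (`size` x `size` x `n_per_class`) plus the recipe fields.
#' @export
make_population <- function(template, axis, effect_size = 0.1,
                            noise_sd = 0.05, n_per_class = 500,
                            seed = NULL) {
  template <- as_pixel_matrix(template, "template")
  ax <- as_pixel_matrix(axis, "axis")
  if (!identical(dim(template), dim(ax)))
    stop("template and axis sizes differ", call. = FALSE)
  stopifnot(n_per_class >= 2, noise_sd >= 0)
  size <- nrow(template)
  gen <- function(sign) {
    base <- as.numeric(template + sign * effect_size * ax)
    out <- matrix(stats::rnorm(size * size * n_per_class, 0, noise_sd),
                  nrow = size * size)
    out <- clip01(out + base)
    dim(out) <- c(size, size, n_per_class)
    out
  }
  pop <- with_seed(seed, list(female = gen(+1), male = gen(-1)))
  structure(list(female = pop$female, male = pop$male,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_per_class = as.integer(n_per_class), seed = seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("Synthetic population:", x$n_per_class, "images/class,",
      dim(x$female)[1], "x", dim(x$female)[2], "px\n")
  cat("  effect size", x$effect_size, "| pixel noise SD", x$noise_sd, "\n")
  invisible(x)
}

#' Export a synthetic population as class-labelled PNG directories
#'
#' Writes `female/` and `male/` subdirectories of 8-bit grayscale PNGs, the
#' layout the CI-classifier utilities consume for external image sets.
#'
#' @param population A [make_population()] result.
#' @param directory Output directory.
#' @return Invisibly, a data frame listing the written files.
#' @export
export_population <- function(population, directory) {
  stopifnot(inherits(population, "synthetic_population"))
  rows <- list()
  for (cls in c("female", "male")) {
    dir.create(file.path(directory, cls), recursive = TRUE,
               showWarnings = FALSE)
    arr <- population[[cls]]
    for (i in seq_len(dim(arr)[3])) {
      f <- file.path(directory, cls, sprintf("%s_%04d.png", cls, i))
      write_png_gray(arr[, , i], f)
      rows[[length(rows) + 1L]] <- data.frame(class = cls, file = f)
    }
  }
  invisible(do.call(rbind, rows))
}
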