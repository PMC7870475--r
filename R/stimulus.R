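#' Superimpose noise on a template image
#'
#' Blends a template with a noise image to produce a presentable stimulus:
#' \deqn{S = (1 - w)\,T + w\,\mathrm{rescale}(N),}
#' where `rescale` maps the noise affinely so that its theoretical amplitude
#' range \eqn{[-A, A]} spans \eqn{[0, 1]} (with \eqn{A} the basis amplitude
#' bound carried by [synthesize_noise()]), and the result is clipped to
#' \eqn{[0, 1]}. Analysis operates on this continuous stimulus; 8-bit
#' quantization happens only on export.
#'
#' @param template Numeric matrix in \code{[0, 1]}, same size as the noise.
#' @param noise Noise image from [synthesize_noise()] (or any numeric matrix
#'   if `amp_bound` is supplied).
#' @param blend Noise weight in \code{(0, 1]}; default 0.5 (equal mixture).
#' @param amp_bound Amplitude bound used for the affine rescale; defaults to
#'   the `amp_bound` attribute of `noise`.
#' @return An object of class `noisy_stimulus`: list with `pixels`,
#'   `blend`, `amp_bound`, and provenance fields `pv_id`, `template_id`.
#' @export
superimpose <- function(template, noise, blend = 0.5, amp_bound = NULL) {
  template <- as_pixel_matrix(template, "template")
  if (!identical(dim(template), dim(noise)))
    stop("template is ", paste(dim(template), collapse = "x"),
         " but noise is ", paste(dim(noise), collapse = "x"), call. = FALSE)
  stopifnot(blend > 0, blend <= 1)
  if (is.null(amp_bound)) amp_bound <- attr(noise, "amp_bound")
  if (is.null(amp_bound))
    stop("noise carries no amp_bound attribute; pass amp_bound explicitly",
         call. = FALSE)
  px <- clip01((1 - blend) * template + blend * (noise + amp_bound) /
                 (2 * amp_bound))
  attributes(px) <- list(dim = dim(px))
  structure(list(pixels = px, blend = blend, amp_bound = amp_bound,
                 pv_id = attr(noise, "pv_id"), template_id = NULL),
            class = "noisy_stimulus")
}

#' @export
print.noisy_stimulus <- function(x, ...) {
  cat("Noisy stimulus: ", nrow(x$pixels), "x", ncol(x$pixels),
      " px, blend ", x$blend, "\n", sep = "")
  invisible(x)
}

#' Reconstruct class prototypes from a classification image
#'
#' Rescales the CI so its largest absolute pixel equals `peak`, then adds it
#' to the template for the female prototype and subtracts it for the male
#' prototype (the CI is defined female-minus-male, so addition accentuates
#' female-diagnostic structure). Results are clipped to \code{[0, 1]}.
#'
#' @param template Numeric matrix in \code{[0, 1]}.
#' @param ci A [compute_ci()] result or a numeric pixel matrix.
#' @param peak Target maximum absolute pixel value of the rescaled CI, as a
#'   fraction of the dynamic range; default 0.2.
#' @return List with elements `female` and `male` (pixel matrices) and
#'   `scaled_ci`, the rescaled CI that was added/subtracted.
#' @export
make_prototypes <- function(template, ci, peak = 0.2) {
  template <- as_pixel_matrix(template, "template")
  ci_px <- as_pixel_matrix(ci, "ci")
  if (!identical(dim(template), dim(ci_px)))
    stop("template and CI sizes differ", call. = FALSE)
  m <- max(abs(ci_px))
  if (m == 0)
    stop("classification image is identically zero; no direction to rescale",
         call. = FALSE)
  sc <- ci_px * (peak / m)
  list(female = clip01(template + sc),
       male = clip01(template - sc),
       scaled_ci = sc)
}

#' Export a stimulus set as PNGs with a CSV manifest
#'
#' Writes one 8-bit grayscale PNG per stimulus plus `manifest.csv` linking
#' each file to its parameter-vector id and blend weight, so trial logs can
#' be joined back to the generating noise.
#'
#' @param stimuli List of `noisy_stimulus` objects.
#' @param directory Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The manifest data frame, invisibly.
#' @export
export_stimulus_set <- function(stimuli, directory, prefix = "stim") {
  stopifnot(is.list(stimuli), length(stimuli) >= 1L)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", directory, call. = FALSE)
  n <- length(stimuli)
  files <- sprintf("%s_%05d.png", prefix, seq_len(n))
  for (i in seq_len(n)) {
    path <- file.path(directory, files[i])
    ok <- tryCatch({ write_png_gray(stimuli[[i]]$pixels, path); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write ", path, ": ", conditionMessage(ok),
           call. = FALSE)
  }
  manifest <- data.frame(
    stimulus_id = seq_len(n),
    file = files,
    pv_id = vapply(stimuli, function(s)
      if (is.null(s$pv_id)) NA_integer_ else as.integer(s$pv_id), integer(1)),
    blend = vapply(stimuli, function(s) s$blend, numeric(1))
  )
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
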