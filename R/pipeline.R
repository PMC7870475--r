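# Experiment orchestration: generate stimuli, collect observer responses,
# and run the full reverse-correlation analysis, reproducibly from a seed.

#' Run a reverse-correlation experiment
#'
#' Draws `n_trials` uniform parameter vectors, synthesizes the noise,
#' superimposes it on the template, and collects the observer's responses.
#' Stimuli are processed in chunks so that only the parameter store (not
#' the pixel data) is kept for the whole run; a run is fully determined by
#' its configuration and seed.
#'
#' Under the `"mean_activation"` criterion the decision threshold is the
#' mean decision variable over the whole run (two-pass), matching
#' [classify_batch()].
#'
#' @param observer An `observer_spec`.
#' @param basis A [noise_basis()].
#' @param template Template pixel matrix, same size as the basis.
#' @param n_trials Number of trials.
#' @param blend Noise blend weight passed to [superimpose()].
#' @param seed Integer seed controlling parameters, internal observer noise
#'   and (for the random observer) the labels.
#' @param params Optional pre-drawn parameter matrix (e.g. to present the
#'   identical stimuli to several observers); overrides `n_trials`.
#' @param chunk_size Stimuli synthesized per chunk.
#' @param out_dir Optional directory; writes `trials.csv` and `config.yaml`
#'   (with the config hash) there.
#' @return Object of class `rc_experiment`: `trials` (data frame),
#'   `params`, `basis`, `observer`, `template`, `blend`, `seed`, `config`
#'   and `hash`.
#' @export
run_experiment <- function(observer, basis, template, n_trials = 1000,
                           blend = 0.5, seed = 1, params = NULL,
                           chunk_size = 500, out_dir = NULL) {
  stopifnot(inherits(observer, "observer_spec"),
            inherits(basis, "noise_basis"))
  template <- as_pixel_matrix(template, "template")
  if (nrow(template) != basis$image_size)
    stop("template size does not match the basis", call. = FALSE)
  if (is.null(params)) params <- sample_parameters(basis, n_trials, seed)
  n <- nrow(params)
  A <- basis$amp_bound

  v <- with_seed(seed + 1L, {
    out <- numeric(n)
    tv <- as.numeric(template)
    for (lo in seq(1L, n, by = chunk_size)) {
      hi <- min(lo + chunk_size - 1L, n)
      noise <- synthesize_batch(basis, params[lo:hi, , drop = FALSE])
      stim <- clip01((1 - blend) * tv + blend * (noise + A) / (2 * A))
      out[lo:hi] <- decision_variables(observer, stim, template)$v
    }
    out
  })
  theta <- if (observer$criterion == "mean_activation") mean(v)
           else observer$theta
  lab <- with_seed(seed + 2L, label_from_v(observer, v, theta))
  trials <- data.frame(trial_id = seq_len(n), pv_id = seq_len(n),
                       label = lab$label, response4 = lab$response4,
                       decision_var = v)
  config <- list(basis = basis_config(basis), blend = blend, seed = seed,
                 n_trials = n, observer_kind = observer$kind,
                 criterion = observer$criterion, sigma = observer$sigma,
                 theta = observer$theta)
  run <- structure(list(trials = trials, params = params, basis = basis,
                        observer = observer, template = template,
                        blend = blend, seed = seed, config = config,
                        hash = config_hash(config)),
                   class = "rc_experiment")
  if (!is.null(out_dir)) write_experiment(run, out_dir)
  run
}

write_experiment <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- run$trials
  tr$config_hash <- run$hash
  utils::write.csv(tr, file.path(out_dir, "trials.csv"), row.names = FALSE)
  writeLines(yaml::as.yaml(c(run$config, hash = run$hash)),
             file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.rc_experiment <- function(x, ...) {
  cat("Reverse-correlation run: ", nrow(x$trials), " trials, observer '",
      x$observer$kind, "' (", x$observer$criterion, ")\n", sep = "")
  cat("  labels:", sum(x$trials$label == "female"), "female /",
      sum(x$trials$label == "male"), "male | seed", x$seed,
      "| hash", substr(x$hash, 1, 8), "\n")
  invisible(x)
}

#' Analyze a reverse-correlation run
#'
#' Computes the classification image, its per-scale decomposition, the
#' per-parameter contribution table with per-scale summary and top
#' contributors, and the reconstructed prototypes. With `out_dir` set, all
#' artifacts (CSV tables, display PNGs, a JSON summary and a markdown
#' report, each stamped with the run's config hash) are written to disk.
#'
#' @param run An `rc_experiment`.
#' @param alpha Familywise level for [parameter_tests()].
#' @param top_fraction Cumulative |d| share for [top_contributors()].
#' @param peak Prototype rescale peak for [make_prototypes()].
#' @param out_dir Optional output directory.
#' @return Object of class `rc_analysis`: `ci`, `scale_images` (named
#'   list), `contribution`, `scale_summary`, `top`, `prototypes`, plus the
#'   run's `config` and `hash`.
#' @export
run_analysis <- function(run, alpha = 0.05, top_fraction = 0.8, peak = 0.2,
                         out_dir = NULL) {
  stopifnot(inherits(run, "rc_experiment"))
  ci <- compute_ci(run$trials, run$params, run$basis)
  scale_images <- lapply(run$basis$scales, function(s) ci_by_scale(ci, s))
  names(scale_images) <- run$basis$scales
  contribution <- parameter_tests(run$trials, run$params, run$basis,
                                  alpha = alpha)
  scale_summary <- per_scale_summary(contribution)
  top <- if (all(is.na(contribution$d) | contribution$d == 0)) integer(0)
         else top_contributors(contribution, top_fraction)
  prototypes <- make_prototypes(run$template, ci, peak = peak)
  out <- structure(list(ci = ci, scale_images = scale_images,
                        contribution = contribution,
                        scale_summary = scale_summary, top = top,
                        prototypes = prototypes, alpha = alpha,
                        top_fraction = top_fraction,
                        config = run$config, hash = run$hash),
                   class = "rc_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

write_analysis <- function(an, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ci <- an$ci
  utils::write.csv(
    data.frame(index = seq_along(ci$param_ci), param_ci = ci$param_ci),
    file.path(out_dir, "param_ci.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(an$contribution),
                   file.path(out_dir, "contribution.csv"),
                   row.names = FALSE)
  utils::write.csv(an$scale_summary,
                   file.path(out_dir, "scale_summary.csv"),
                   row.names = FALSE)
  write_png_gray(normalize_ci_for_display(ci) / 255,
                 file.path(out_dir, "ci.png"))
  for (s in names(an$scale_images)) {
    img <- an$scale_images[[s]]
    if (max(img) > min(img))
      write_png_gray(normalize_ci_for_display(img) / 255,
                     file.path(out_dir, paste0("ci_scale_", s, ".png")))
  }
  write_png_gray(an$prototypes$female,
                 file.path(out_dir, "prototype_female.png"))
  write_png_gray(an$prototypes$male,
                 file.path(out_dir, "prototype_male.png"))
  grDevices::png(file.path(out_dir, "manhattan.png"), width = 900,
                 height = 450)
  plot(an$contribution)
  grDevices::dev.off()
  jsonlite::write_json(
    list(hash = an$hash, n_female = ci$n_female, n_male = ci$n_male,
         alpha = an$alpha, n_significant = sum(an$contribution$significant),
         n_top = length(an$top), top_fraction = an$top_fraction,
         scale_summary = an$scale_summary),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  report <- c(
    "# Reverse-correlation analysis report", "",
    paste0("Config hash: `", an$hash, "`"),
    paste0("Trials: ", ci$n_female, " female / ", ci$n_male, " male"),
    paste0("Significant parameters (Bonferroni, alpha = ", an$alpha, "): ",
           sum(an$contribution$significant)), "",
    "## Significant parameters by scale", "",
    paste0("- ", an$scale_summary$scale, " cycles/image: ",
           an$scale_summary$n_significant, "/",
           an$scale_summary$n_params, " (",
           round(an$scale_summary$pct_significant, 1), "%)"),
    "", paste0("Top contributors carrying ", 100 * an$top_fraction,
               "% of total |d|: ", length(an$top), " parameters"))
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.rc_analysis <- function(x, ...) {
  cat("Reverse-correlation analysis (hash ", substr(x$hash, 1, 8), ")\n",
      sep = "")
  print(x$ci)
  cat("  significant parameters:", sum(x$contribution$significant),
      "of", nrow(x$contribution), "\n")
  invisible(x)
}

#' Compare two reverse-correlation runs
#'
#' Quantifies how similar two observers' estimated representations are:
#' Pearson correlation of the two CIs overall and per spatial scale, and
#' Spearman correlation of the per-parameter contributions (|Cohen's d|),
#' optionally restricted to the first run's top contributors.
#'
#' @param a,b `rc_analysis` objects (or `rc_experiment`s, analyzed with
#'   defaults) over identical basis configurations.
#' @param subset Parameter subset for the contribution correlation;
#'   `"top"` uses `a`'s top contributors, `NULL` uses all parameters.
#' @return Object of class `rc_comparison`: `similarity`
#'   (a [ci_similarity()] report with per-scale values) and
#'   `contribution` (a [contribution_correlation()] report).
#' @export
compare_runs <- function(a, b, subset = "top") {
  if (inherits(a, "rc_experiment")) a <- run_analysis(a)
  if (inherits(b, "rc_experiment")) b <- run_analysis(b)
  stopifnot(inherits(a, "rc_analysis"), inherits(b, "rc_analysis"))
  if (!isTRUE(all.equal(a$config$basis, b$config$basis)))
    stop("runs use different basis configurations; comparison undefined",
         call. = FALSE)
  sim <- ci_similarity(a$ci, b$ci, per_scale = TRUE)
  sub <- if (identical(subset, "top")) a$top else subset
  contrib <- contribution_correlation(a$contribution, b$contribution,
                                      subset = sub, per_scale = TRUE)
  structure(list(similarity = sim, contribution = contrib),
            class = "rc_comparison")
}

#' @export
print.rc_comparison <- function(x, ...) {
  print(x$similarity)
  cat("Contribution rank correlation: rho = ",
      signif(x$contribution$rho, 3), " (n = ", x$contribution$n, ")\n",
      sep = "")
  if (!is.null(x$contribution$per_scale)) {
    cat("  per scale:\n")
    for (s in names(x$contribution$per_scale))
      cat(sprintf("    %4s : rho = %s\n", s,
                  signif(x$contribution$per_scale[[s]], 3)))
  }
  invisible(x)
}
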