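#' Synthetic and adapted observers
#'
#' An observer turns a noisy stimulus into a binary gender label (plus an
#' optional 4-level confidence response). Three kinds are provided:
#'
#' * `linear_observer()` — a linear template observer. Its decision variable
#'   is the inner product of the noise content of the stimulus with a fixed
#'   axis image, \eqn{v = \sum_j (S_j - T_j)\,a_j + \epsilon}, with internal
#'   Gaussian noise \eqn{\epsilon \sim N(0, \sigma^2)}; the stimulus is
#'   labelled `"female"` iff \eqn{v > \theta} (ties go to `"male"`).
#'   Subtracting the template makes the observer respond to noise content
#'   only, which is what makes classification-image recovery exact for this
#'   model.
#' * `random_observer()` — labels Bernoulli(0.5), ignoring the stimulus; the
#'   null observer for calibration checks.
#' * `external_observer()` — wraps any classifier callable returning two
#'   class scores, e.g. the two output units of a network. The decision
#'   variable is the first-class score minus the second-class score.
#'
#' Two decision criteria are supported. `"fixed_threshold"` compares the
#' decision variable against `theta`. `"mean_activation"` compares it
#' against its empirical mean over the whole stimulus batch (a two-pass
#' rule), which removes any constant response bias; it is therefore only
#' available through [classify_batch()].
#'
#' @param axis Ground-truth axis image (numeric matrix, stimulus-sized), or
#'   a `ground_truth_axis` from [make_axis()].
#' @param sigma Internal noise standard deviation, \eqn{\ge 0}.
#' @param theta Decision threshold on the decision variable.
#' @param criterion `"fixed_threshold"` or `"mean_activation"`.
#' @param template Template image the observer subtracts before projecting
#'   on the axis; may instead be supplied at classification time.
#' @param confidence Threshold on \eqn{|v - \theta|} separating "possibly"
#'   from "probably" responses; `NULL` (default) uses the within-batch
#'   median.
#' @param seed Integer seed for the observer's internal noise.
#' @return An object of class `observer_spec`.
#' @name observers
NULL

new_observer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "observer_spec")
}

#' @rdname observers
#' @export
linear_observer <- function(axis, sigma = 0, theta = 0,
                            criterion = c("fixed_threshold",
                                          "mean_activation"),
                            template = NULL, confidence = NULL, seed = NULL) {
  axis <- as_pixel_matrix(axis, "axis")
  stopifnot(sigma >= 0)
  new_observer("linear_template", axis = axis, sigma = sigma, theta = theta,
               criterion = match.arg(criterion), template = template,
               confidence = confidence, seed = seed)
}

#' @rdname observers
#' @export
random_observer <- function(seed = NULL) {
  new_observer("random", sigma = 0, theta = 0, criterion = "fixed_threshold",
               confidence = NULL, seed = seed)
}

#' @rdname observers
#' @param score_fun Function taking a pixel matrix and returning two numeric
#'   class scores.
#' @param labels Character vector of length 2 mapping the two score
#'   positions to class labels; default `c("female", "male")`.
#' @export
external_observer <- function(score_fun, labels = c("female", "male"),
                              theta = 0,
                              criterion = c("fixed_threshold",
                                            "mean_activation"),
                              confidence = NULL, seed = NULL) {
  stopifnot(is.function(score_fun), length(labels) == 2L)
  new_observer("external", score_fun = score_fun, labels = labels,
               sigma = 0, theta = theta, criterion = match.arg(criterion),
               confidence = confidence, seed = seed)
}

#' @export
print.observer_spec <- function(x, ...) {
  cat("Observer:", x$kind, "| criterion:", x$criterion)
  if (x$kind == "linear_template")
    cat(" | sigma:", x$sigma, "| theta:", x$theta)
  cat("\n")
  invisible(x)
}

# Decision variables for a stack of stimuli (npix x n matrix). Internal
# observer noise is drawn here (caller must manage the seed).
decision_variables <- function(observer, stim_mat, template) {
  n <- ncol(stim_mat)
  switch(observer$kind,
    linear_template = {
      if (is.null(template)) template <- observer$template
      if (is.null(template))
        stop("linear_template observer needs a template image", call. = FALSE)
      template <- as_pixel_matrix(template, "template")
      a <- as.numeric(observer$axis)
      v <- as.numeric(crossprod(stim_mat, a)) - sum(template * a)
      if (observer$sigma > 0) v <- v + stats::rnorm(n, 0, observer$sigma)
      list(v = v)
    },
    random = list(v = rep(NA_real_, n)),
    external = {
      side <- as.integer(round(sqrt(nrow(stim_mat))))
      sc <- vapply(seq_len(n), function(i) {
        img <- stim_mat[, i]
        dim(img) <- c(side, side)
        out <- observer$score_fun(img)
        if (!is.numeric(out) || length(out) != 2L || !all(is.finite(out)))
          stop("external classifier returned a malformed score payload: ",
               paste(utils::capture.output(print(out)), collapse = " "),
               call. = FALSE)
        as.numeric(out)
      }, numeric(2))
      list(v = sc[1, ] - sc[2, ], score1 = sc[1, ], score2 = sc[2, ])
    },
    stop("unknown observer kind ", observer$kind, call. = FALSE))
}

# Labels + 4-level responses from decision variables and an effective
# threshold. Tie rule: v == theta is labelled "male".
label_from_v <- function(observer, v, theta) {
  if (observer$kind == "random") {
    lab <- ifelse(stats::runif(length(v)) < 0.5, "female", "male")
    conf <- ifelse(stats::runif(length(v)) < 0.5, "possibly", "probably")
    return(list(label = lab, response4 = paste(conf, lab, sep = "_")))
  }
  lab <- ifelse(v > theta, "female", "male")
  dist <- abs(v - theta)
  thr <- observer$confidence
  if (is.null(thr)) thr <- stats::median(dist)
  conf <- ifelse(dist > thr, "probably", "possibly")
  list(label = lab, response4 = paste(conf, lab, sep = "_"))
}

stimulus_stack <- function(stimuli) {
  px <- lapply(stimuli, function(s) as_pixel_matrix(s, "stimulus"))
  npix <- length(px[[1]])
  mat <- vapply(px, as.numeric, numeric(npix))
  dim(mat) <- c(npix, length(px))
  mat
}

#' Classify a single stimulus
#'
#' Applies an observer's decision rule to one stimulus and returns a
#' one-row trial record. The `"mean_activation"` criterion is batch-defined
#' and is rejected here; use [classify_batch()].
#'
#' @param observer An `observer_spec`.
#' @param stimulus A `noisy_stimulus` or pixel matrix.
#' @param template Template image for linear observers (overrides the one
#'   stored in the observer).
#' @param trial Trial index; with a seeded observer, the internal noise for
#'   trial `i` is reproducible.
#' @return A one-row data frame: `trial_id`, `pv_id`, `label`, `response4`,
#'   `decision_var` (plus raw scores for external observers).
#' @export
classify <- function(observer, stimulus, template = NULL, trial = 1L) {
  stopifnot(inherits(observer, "observer_spec"))
  if (observer$criterion == "mean_activation")
    stop("the mean_activation criterion needs the whole batch; ",
         "use classify_batch()", call. = FALSE)
  pv <- if (inherits(stimulus, "noisy_stimulus")) stimulus$pv_id else NULL
  mat <- stimulus_stack(list(stimulus))
  seed_i <- if (is.null(observer$seed)) NULL else observer$seed + trial
  rec <- with_seed(seed_i, {
    d <- decision_variables(observer, mat, template)
    lab <- label_from_v(observer, d$v, observer$theta)
    c(d, lab)
  })
  out <- data.frame(trial_id = as.integer(trial),
                    pv_id = if (is.null(pv)) NA_integer_ else as.integer(pv),
                    label = rec$label, response4 = rec$response4,
                    decision_var = rec$v)
  if (!is.null(rec$score1)) {
    out$score1 <- rec$score1
    out$score2 <- rec$score2
  }
  out
}

#' Classify a batch of stimuli
#'
#' Applies the observer to every stimulus. Under the `"mean_activation"`
#' criterion the decision threshold is the batch mean of the decision
#' variable (computed in a first pass), which is exactly equivalent to
#' `"fixed_threshold"` with `theta` set to that mean.
#'
#' @inheritParams classify
#' @param stimuli Non-empty list of stimuli.
#' @return A data frame of trial records, one row per stimulus.
#' @export
classify_batch <- function(observer, stimuli, template = NULL) {
  stopifnot(inherits(observer, "observer_spec"))
  if (!is.list(stimuli) || length(stimuli) < 1L)
    stop("stimuli must be a non-empty list", call. = FALSE)
  mat <- stimulus_stack(stimuli)
  with_seed(observer$seed, {
    d <- decision_variables(observer, mat, template)
    theta <- if (observer$criterion == "mean_activation") mean(d$v)
             else observer$theta
    lab <- label_from_v(observer, d$v, theta)
    pv <- vapply(stimuli, function(s) {
      id <- if (inherits(s, "noisy_stimulus")) s$pv_id else NULL
      if (is.null(id)) NA_integer_ else as.integer(id)
    }, integer(1))
    out <- data.frame(trial_id = seq_along(stimuli), pv_id = pv,
                      label = lab$label, response4 = lab$response4,
                      decision_var = d$v)
    if (!is.null(d$score1)) {
      out$score1 <- d$score1
      out$score2 <- d$score2
    }
    out
  })
}

#' Collapse a 4-level confidence response to the binary label
#'
#' "probably female" and "possibly female" collapse to `"female"`; likewise
#' for male.
#'
#' @param response4 Character vector of 4-level responses.
#' @return Character vector of binary labels.
#' @export
collapse_response <- function(response4) {
  sub("^(probably|possibly)_", "", response4)
}
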