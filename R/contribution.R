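#' Per-parameter contribution statistics
#'
#' For every basis parameter, compares the amplitude values from female-
#' labelled trials against those from male-labelled trials with a classic
#' pooled-variance two-sample t-test (two-sided), and reports the absolute
#' Cohen's d — the standardized mean difference using the pooled SD — as the
#' parameter's contribution to the classification. Significance is
#' Bonferroni-controlled over the whole family of `K` parameters at family
#' level `alpha`.
#'
#' The pooled (Student) t is used rather than Welch's: class sizes are
#' near-equal in this design and Cohen's d shares the pooled SD, keeping the
#' two statistics consistent. A parameter with zero pooled variance and a
#' nonzero mean difference is flagged `degenerate` and never significant;
#' zero variance with a zero difference reports t = 0, p = 1, d = 0.
#'
#' @param trials Trial data frame (see [compute_ci()]).
#' @param params Parameter matrix, trials in rows.
#' @param basis The [noise_basis()]; supplies per-parameter metadata.
#' @param alpha Familywise significance level (default 0.05).
#' @return A data frame of class `contribution_table` with one row per
#'   parameter: component metadata, group means, `t`, `df`, `p`, `d`
#'   (absolute Cohen's d), `significant`, `degenerate`. Attributes `alpha`
#'   and `bonferroni` record the family level and per-test threshold.
#' @export
parameter_tests <- function(trials, params, basis, alpha = 0.05) {
  stopifnot(is.data.frame(trials), is.matrix(params),
            inherits(basis, "noise_basis"), alpha > 0, alpha < 1)
  idx <- trial_param_rows(trials, params)
  lab <- as.character(trials$label)
  f <- idx[lab == "female"]
  m <- idx[lab == "male"]
  if (length(f) < 2L || length(m) < 2L)
    stop("need at least 2 trials per class", call. = FALSE)
  nf <- length(f); nm <- length(m)
  Xf <- params[f, , drop = FALSE]
  Xm <- params[m, , drop = FALSE]
  mf <- colMeans(Xf); mm <- colMeans(Xm)
  vf <- (colSums(Xf^2) - nf * mf^2) / (nf - 1)
  vm <- (colSums(Xm^2) - nm * mm^2) / (nm - 1)
  df <- nf + nm - 2
  sp <- sqrt(((nf - 1) * vf + (nm - 1) * vm) / df)
  diff <- mf - mm
  tt <- diff / (sp * sqrt(1 / nf + 1 / nm))
  d <- abs(diff / sp)
  degen <- sp == 0
  # zero variance, zero difference: no effect, not degenerate
  null0 <- degen & diff == 0
  tt[null0] <- 0; d[null0] <- 0; degen[null0] <- FALSE
  tt[degen] <- NA_real_; d[degen] <- NA_real_
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  thr <- alpha / basis$K
  sig <- !is.na(p) & p <= thr
  out <- cbind(basis$components,
               data.frame(mean_female = mf, mean_male = mm,
                          t = tt, df = df, p = p, d = d,
                          significant = sig, degenerate = degen))
  rownames(out) <- NULL
  structure(out, alpha = alpha, bonferroni = thr,
            class = c("contribution_table", "data.frame"))
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Contribution table:", nrow(x), "parameters;",
      sum(x$significant), "significant (Bonferroni, family alpha =",
      attr(x, "alpha"), ")\n")
  NextMethod()
}

#' Significant-parameter counts and percentages by spatial scale
#'
#' @param table A [parameter_tests()] result.
#' @return Data frame with one row per scale: `scale`, `n_params`,
#'   `n_significant`, `pct_significant` (in percent of the parameters at
#'   that scale).
#' @export
per_scale_summary <- function(table) {
  stopifnot(inherits(table, "contribution_table"))
  scales <- unique(table$scale)
  out <- do.call(rbind, lapply(scales, function(s) {
    rows <- table$scale == s
    n <- sum(rows); k <- sum(table$significant[rows])
    data.frame(scale = s, n_params = n, n_significant = k,
               pct_significant = 100 * k / n)
  }))
  rownames(out) <- NULL
  out
}

#' Smallest set of parameters carrying a share of the total contribution
#'
#' Parameters are ranked by absolute Cohen's d (ties broken by ascending
#' parameter index) and the shortest prefix whose cumulative |d| reaches
#' `fraction` of the total is returned.
#'
#' @param table A [parameter_tests()] result.
#' @param fraction Cumulative contribution share in \code{(0, 1]}.
#' @return Integer vector of parameter indices, in decreasing order of |d|.
#' @export
top_contributors <- function(table, fraction = 0.8) {
  stopifnot(inherits(table, "contribution_table"),
            fraction > 0, fraction <= 1)
  d <- table$d
  d[is.na(d)] <- 0
  if (all(d == 0))
    stop("all contributions are zero; no ranking exists", call. = FALSE)
  ord <- order(-d, table$index)
  cum <- cumsum(d[ord])
  k <- which(cum >= fraction * sum(d) - 1e-12)[1L]
  table$index[ord[seq_len(k)]]
}

#' Rank correlation of contributions between two observers
#'
#' Spearman correlation of the absolute Cohen's d values from two
#' contribution tables, optionally restricted to a parameter subset (e.g.
#' the joint top contributors) and broken down by spatial scale. A scale
#' with fewer than 3 subset parameters is reported as `NA`.
#'
#' @param table_a,table_b [parameter_tests()] results over the same basis.
#' @param subset Optional integer vector of parameter indices.
#' @param per_scale Also report one correlation per scale.
#' @return List with `rho` (overall Spearman), `n` (parameters used), and
#'   `per_scale` (named vector or `NULL`).
#' @export
contribution_correlation <- function(table_a, table_b, subset = NULL,
                                     per_scale = FALSE) {
  stopifnot(inherits(table_a, "contribution_table"),
            inherits(table_b, "contribution_table"),
            nrow(table_a) == nrow(table_b))
  keep <- if (is.null(subset)) table_a$index
          else intersect(subset, table_a$index)
  if (length(keep) < 3L)
    stop("subset must contain at least 3 parameters", call. = FALSE)
  ia <- match(keep, table_a$index)
  da <- table_a$d[ia]; db <- table_b$d[match(keep, table_b$index)]
  rho <- stats::cor(da, db, method = "spearman", use = "complete.obs")
  ps <- NULL
  if (per_scale) {
    scales <- unique(table_a$scale)
    ps <- vapply(scales, function(s) {
      rows <- table_a$scale[ia] == s
      if (sum(rows) < 3L) return(NA_real_)
      stats::cor(da[rows], db[rows], method = "spearman",
                 use = "complete.obs")
    }, numeric(1))
    names(ps) <- scales
  }
  list(rho = rho, n = length(keep), per_scale = ps)
}

#' Manhattan-style contribution plot
#'
#' Plots absolute Cohen's d against parameter index, colored by scale, with
#' Bonferroni-significant parameters highlighted.
#'
#' @param x A [parameter_tests()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.contribution_table <- function(x, ...) {
  scl <- factor(x$scale, levels = unique(x$scale))
  cols <- grDevices::hcl.colors(nlevels(scl), "Dark 3")[as.integer(scl)]
  graphics::plot(x$index, x$d, pch = 16, cex = 0.4, col = cols,
                 xlab = "parameter index", ylab = "|Cohen's d|", ...)
  sig <- x$significant
  if (any(sig))
    graphics::points(x$index[sig], x$d[sig], pch = 1, cex = 0.9)
  graphics::legend("topright", legend = paste(levels(scl), "c/img"),
                   col = grDevices::hcl.colors(nlevels(scl), "Dark 3"),
                   pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
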