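test_that("the CI is the class mean difference, female minus male", {
  b <- small_basis()
  P <- matrix(0, 2, b$K)
  P[1, 1] <- 1; P[2, 1] <- -1
  ci <- compute_ci(trial_frame(c("female", "male")), P, b)
  expected <- numeric(b$K); expected[1] <- 2
  expect_equal(coef(ci), expected)
  expect_equal(ci$n_female + ci$n_male, 2)
  # pixel CI is the synthesis of the parameter CI
  expect_equal(as.numeric(ci$pixel_ci),
               as.numeric(synthesize_noise(b, coef(ci))), tolerance = 1e-12)
})

test_that("swapping the labels negates the CI exactly", {
  b <- small_basis()
  P <- sample_parameters(b, 40, seed = 13)
  lab <- rep(c("female", "male"), 20)
  ci <- compute_ci(trial_frame(lab), P, b)
  ci_sw <- compute_ci(trial_frame(ifelse(lab == "female", "male", "female")),
                      P, b)
  expect_equal(coef(ci_sw), -coef(ci))
  expect_equal(ci_sw$pixel_ci, -ci$pixel_ci)
})

test_that("single-class trial sets are rejected by name", {
  b <- unit_basis()
  P <- sample_parameters(b, 4, seed = 1)
  expect_error(compute_ci(trial_frame(rep("female", 4)), P, b), "male")
  expect_error(compute_ci(trial_frame(rep("male", 4)), P, b), "female")
})

test_that("random labels leave every CI parameter near zero", {
  b <- small_basis()
  n <- 2000
  P <- sample_parameters(b, n, seed = 17)
  lab <- with(list(), {set.seed(18); sample(c("female", "male"), n, TRUE)})
  ci <- compute_ci(trial_frame(lab), P, b)
  nf <- sum(lab == "female"); nm <- n - nf
  se <- sqrt((1 / 3) * (1 / nf + 1 / nm))
  expect_true(all(abs(coef(ci)) < 4 * se))
})

test_that("per-scale CIs partition the pixel CI", {
  b <- small_basis()
  P <- sample_parameters(b, 30, seed = 23)
  ci <- compute_ci(trial_frame(rep(c("female", "male"), 15)), P, b)
  total <- Reduce(`+`, lapply(b$scales, function(s) ci_by_scale(ci, s)))
  expect_equal(as.numeric(total), as.numeric(ci$pixel_ci),
               tolerance = 1e-12)
  expect_error(ci_by_scale(ci, 99), "unknown scale")
  # a CI with a single scale-4 parameter is that component times its weight
  P1 <- matrix(0, 2, b$K); P1[1, 20] <- 0.5; P1[2, 20] <- -0.5
  ci1 <- compute_ci(trial_frame(c("female", "male")), P1, b)
  e <- numeric(b$K); e[20] <- 1
  expect_equal(as.numeric(ci_by_scale(ci1, 4)),
               as.numeric(synthesize_noise(b, e)), tolerance = 1e-12)
})

test_that("a scale absent from the observer's axis carries only noise", {
  b <- small_basis()
  tpl <- make_template(32, "flat")
  # axis living entirely at scale 2
  ax <- make_axis(b, components = c(2, 5, 9), seed = 3)
  run <- run_experiment(linear_observer(ax$pixels, template = tpl), b, tpl,
                        n_trials = 3000, seed = 29)
  ci <- compute_ci(run$trials, run$params, b)
  nf <- ci$n_female; nm <- ci$n_male
  se <- sqrt((1 / 3) * (1 / nf + 1 / nm))
  k4 <- b$scale_index[[2]]
  expect_true(all(abs(coef(ci)[k4]) < 4 * se))
  # while the axis scale carries clear signal
  expect_gt(max(abs(coef(ci)[b$scale_index[[1]]])), 8 * se)
})

test_that("CI similarity behaves as a correlation", {
  b <- small_basis()
  P <- sample_parameters(b, 60, seed = 31)
  ci <- compute_ci(trial_frame(rep(c("female", "male"), 30)), P, b)
  ci_neg <- compute_ci(
    trial_frame(rep(c("male", "female"), 30)), P, b)
  expect_equal(ci_similarity(ci, ci)$r, 1)
  expect_equal(ci_similarity(ci, ci_neg)$r, -1)
  ps <- ci_similarity(ci, ci, per_scale = TRUE, space = "parameter")
  expect_equal(unname(ps$per_scale), c(1, 1))
  # zero-variance CI reports NA, not 0
  P0 <- matrix(0, 4, b$K)
  ci0 <- compute_ci(trial_frame(rep(c("female", "male"), 2)), P0, b)
  expect_warning(s0 <- ci_similarity(ci0, ci), "zero-variance")
  expect_true(is.na(s0$r))
})

test_that("independent null CIs decorrelate at the simulated null level", {
  b <- reduced_basis()
  n <- 200
  # null CI pairs from random observers on shared stimuli
  r_null <- vapply(1:30, function(i) {
    P <- sample_parameters(b, n, seed = 100 + i)
    set.seed(200 + i)
    lab_a <- sample(c("female", "male"), n, TRUE)
    lab_b <- sample(c("female", "male"), n, TRUE)
    ci_a <- compute_ci(trial_frame(lab_a), P, b)
    ci_b <- compute_ci(trial_frame(lab_b), P, b)
    ci_similarity(ci_a, ci_b)$r
  }, numeric(1))
  # oracle: correlation of images synthesized from white parameter vectors
  set.seed(300)
  r_white <- vapply(1:200, function(i) {
    a <- synthesize_noise(b, rnorm(b$K))
    bb <- synthesize_noise(b, rnorm(b$K))
    cor(as.numeric(a), as.numeric(bb))
  }, numeric(1))
  expect_lt(quantile(abs(r_null), 0.95), quantile(abs(r_white), 0.999))
  expect_lt(abs(mean(r_null)), 0.2)
})

test_that("CI estimation is consistent under trial-set concatenation", {
  b <- unit_basis()
  P <- sample_parameters(b, 50, seed = 37)
  lab <- rep(c("female", "male"), 25)
  ci_all <- compute_ci(trial_frame(lab), P, b)
  # count-weighted combination of the two halves' classwise means
  h1 <- 1:24; h2 <- 25:50
  mean_cls <- function(rows, cls)
    colMeans(P[rows[lab[rows] == cls], , drop = FALSE])
  nf1 <- sum(lab[h1] == "female"); nf2 <- sum(lab[h2] == "female")
  nm1 <- sum(lab[h1] == "male"); nm2 <- sum(lab[h2] == "male")
  mf <- (nf1 * mean_cls(h1, "female") + nf2 * mean_cls(h2, "female")) /
    (nf1 + nf2)
  mm <- (nm1 * mean_cls(h1, "male") + nm2 * mean_cls(h2, "male")) /
    (nm1 + nm2)
  expect_equal(coef(ci_all), unname(mf - mm), tolerance = 1e-12)
})

test_that("display normalization is affine-invariant and rank-preserving", {
  b <- small_basis()
  P <- sample_parameters(b, 20, seed = 41)
  ci <- compute_ci(trial_frame(rep(c("female", "male"), 10)), P, b)
  disp <- normalize_ci_for_display(ci)
  expect_equal(range(disp), c(0, 255))
  expect_true(all(diff(disp[order(ci$pixel_ci)]) >= 0))
  # invariant to positive affine rescaling of the CI
  scaled <- 3.7 * ci$pixel_ci + 0.2
  expect_equal(normalize_ci_for_display(scaled)[, ], disp[, ])
  expect_error(normalize_ci_for_display(matrix(1, 4, 4)), "constant")
})
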