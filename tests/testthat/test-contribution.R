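test_that("the pooled t and Cohen's d match hand computation", {
  b <- unit_basis()
  # female values {1,2,3}, male values {3,4,5}: pooled SD 1, |d| = 2
  P <- matrix(c(1, 2, 3, 3, 4, 5), ncol = 1)
  tr <- trial_frame(c(rep("female", 3), rep("male", 3)))
  tab <- parameter_tests(tr, P, b)
  expect_equal(tab$d, 2)
  expect_equal(tab$t, -2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tab$p, 2 * pt(-2 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  # cross-check against the reference implementation
  ref <- t.test(P[1:3, 1], P[4:6, 1], var.equal = TRUE)
  expect_equal(tab$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tab$p, ref$p.value, tolerance = 1e-12)
})

test_that("no effect and degenerate variance are handled distinctly", {
  b <- unit_basis()
  tr <- trial_frame(c("female", "female", "male", "male"))
  # identical group values: t = 0, d = 0, p = 1
  tab0 <- parameter_tests(tr, matrix(c(2, 2, 2, 2), ncol = 1), b)
  expect_equal(c(tab0$t, tab0$d, tab0$p), c(0, 0, 1))
  expect_false(tab0$degenerate || tab0$significant)
  # zero variance with distinct means: degenerate, never significant
  tabd <- parameter_tests(tr, matrix(c(1, 1, 2, 2), ncol = 1), b)
  expect_true(tabd$degenerate)
  expect_false(tabd$significant)
  expect_true(is.na(tabd$t))
  expect_error(parameter_tests(trial_frame(c("female", "male")),
                               matrix(0, 2, 1), b), "2 trials")
})

test_that("per-scale summary arithmetic is exact", {
  d <- c(rep(1, 12), rep(0.5, 48))
  tab <- fake_contribution(d, scale = c(rep(2, 12), rep(4, 48)))
  tab$significant <- FALSE
  sm0 <- per_scale_summary(tab)
  expect_equal(sm0$pct_significant, c(0, 0))
  tab$significant[1:7] <- TRUE  # 7 of 12 at scale 2
  sm <- per_scale_summary(tab)
  expect_equal(sm$n_significant, c(7, 0))
  expect_equal(sm$pct_significant[1], 700 / 12)  # 58.33%
  tab$significant[1:12] <- TRUE
  expect_equal(per_scale_summary(tab)$pct_significant[1], 100)
})

test_that("top contributors are the shortest prefix by cumulative |d|", {
  tab <- fake_contribution(c(4, 3, 2, 1))
  expect_equal(top_contributors(tab, 0.7), c(1, 2))  # 4+3 = 7 >= 0.7*10
  expect_equal(sort(top_contributors(tab, 1)), 1:4)
  expect_equal(top_contributors(tab, 1e-9), 1)
  # ties broken by ascending parameter index
  expect_equal(top_contributors(fake_contribution(c(2, 3, 3, 2)), 0.5),
               c(2, 3))
  expect_error(top_contributors(fake_contribution(c(0, 0))), "zero")
  # randomized property: prefix matches an independent cumulative-sum oracle
  set.seed(55)
  for (i in 1:20) {
    d <- round(runif(30), 3)
    f <- runif(1, 0.05, 0.95)
    got <- top_contributors(fake_contribution(d), f)
    ord <- order(-d, seq_along(d))
    k_oracle <- which(cumsum(d[ord]) >= f * sum(d) - 1e-12)[1]
    expect_equal(got, ord[seq_len(k_oracle)])
  }
})

test_that("contribution rank correlations respect ranks and subsets", {
  set.seed(60)
  d <- runif(60)
  scl <- c(rep(2, 12), rep(4, 48))
  a <- fake_contribution(d, scl)
  expect_equal(contribution_correlation(a, a, per_scale = TRUE)$rho, 1)
  # monotone transform leaves Spearman at 1
  bmono <- fake_contribution(d^3 + 0.1 * d, scl)
  cc <- contribution_correlation(a, bmono, per_scale = TRUE)
  expect_equal(cc$rho, 1)
  expect_equal(unname(cc$per_scale), c(1, 1))
  # a scale with < 3 subset parameters is reported NA
  cc2 <- contribution_correlation(a, bmono, subset = c(1, 2, 13:20),
                                  per_scale = TRUE)
  expect_true(is.na(cc2$per_scale[["2"]]))
  expect_equal(cc2$per_scale[["4"]], 1)
  expect_error(contribution_correlation(a, bmono, subset = 1:2), "3")
})

test_that("a linear observer's significant set concentrates on its axis", {
  b <- noise_basis(image_size = 32)  # full 4092-parameter structure
  tpl <- make_template(32, "flat")
  # 10 known components; coefficients inversely proportional to component
  # energy so each member projects equally on the axis
  set.seed(71)
  comps <- c(sample(b$scale_index[[1]], 4), sample(b$scale_index[[2]], 4),
             sample(b$scale_index[[3]], 2))
  norms2 <- vapply(comps, function(k) {
    e <- numeric(b$K); e[k] <- 1
    sum(synthesize_noise(b, e)^2)
  }, numeric(1))
  ax <- make_axis(b, components = comps, coefficients = 1 / norms2)
  run <- run_experiment(linear_observer(ax$pixels, template = tpl), b, tpl,
                        n_trials = 4000, seed = 72)
  tab <- parameter_tests(run$trials, run$params, b)
  sig <- tab$index[tab$significant]
  expect_gte(sum(ax$indices %in% sig), 8)          # >= 8 of the 10 found
  expect_gte(mean(sig %in% ax$indices), 0.9)       # few false discoveries
})

test_that("|d| and |t| rank parameters identically for equal class sizes", {
  b <- reduced_basis()
  P <- sample_parameters(b, 40, seed = 81)
  tab <- parameter_tests(trial_frame(rep(c("female", "male"), 20)), P, b)
  expect_equal(order(tab$d), order(abs(tab$t)))
})
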