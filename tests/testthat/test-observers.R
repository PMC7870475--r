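test_that("the linear observer projects noise on its axis, ties to male", {
  b <- small_basis()
  tpl <- make_template(32, "flat")
  obs <- linear_observer(axis = matrix(1, 32, 32), template = tpl)
  # zero noise: stimulus equals template up to the mid-gray shift; with a
  # flat template the decision variable is exactly 0 -> tie -> male
  st <- superimpose(tpl, synthesize_noise(b, numeric(b$K)))
  rec <- classify(obs, st)
  expect_equal(rec$decision_var, 0)
  expect_equal(rec$label, "male")
})

test_that("axis = one component makes the label a dot-product sign", {
  b <- small_basis()
  tpl <- make_template(32, "flat")
  k <- 15
  e <- numeric(b$K); e[k] <- 1
  comp <- synthesize_noise(b, e)
  attr(comp, "amp_bound") <- NULL
  obs <- linear_observer(axis = comp, template = tpl)
  st_pos <- superimpose(tpl, synthesize_noise(b, e))
  st_neg <- superimpose(tpl, synthesize_noise(b, -e))
  expect_equal(classify(obs, st_pos)$label, "female")
  expect_equal(classify(obs, st_neg)$label, "male")
  # decision variable matches a brute-force dot product over the patch
  v <- classify(obs, st_pos)$decision_var
  expect_equal(v, sum((st_pos$pixels - tpl) * comp), tolerance = 1e-12)
})

test_that("label signs follow the brute-force noise/axis inner product", {
  b <- small_basis()
  tpl <- make_template(32, "flat")
  ax <- make_axis(b, n_components = 5, seed = 2)
  obs <- linear_observer(ax$pixels, template = tpl)
  P <- sample_parameters(b, 50, seed = 21)
  stims <- lapply(seq_len(50), function(i)
    superimpose(tpl, synthesize_noise(b, P[i, ])))
  recs <- classify_batch(obs, stims)
  for (i in seq_len(50)) {
    ip <- sum(synthesize_noise(b, P[i, ]) * ax$pixels) / (2 * b$amp_bound) *
      0.5  # blend / (2 * amp_bound) is the affine factor on the noise
    expect_equal(recs$label[i], if (ip > 0) "female" else "male")
  }
})

test_that("the random observer is a fair coin", {
  b <- unit_basis()
  stims <- rep(list(matrix(0.5, 16, 16)), 10000)
  recs <- classify_batch(random_observer(seed = 5), stims)
  frac <- mean(recs$label == "female")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # 4-level responses collapse to the binary label
  expect_identical(collapse_response(recs$response4), recs$label)
  # identical seeds give identical record streams
  recs2 <- classify_batch(random_observer(seed = 5), stims)
  expect_identical(recs, recs2)
})

test_that("mean_activation equals fixed_threshold at the batch mean", {
  b <- small_basis()
  tpl <- make_template(32, "radial")
  ax <- make_axis(b, n_components = 4, seed = 7)
  P <- sample_parameters(b, 200, seed = 31)
  stims <- lapply(seq_len(200), function(i)
    superimpose(tpl, synthesize_noise(b, P[i, ])))
  obs_ma <- linear_observer(ax$pixels, template = tpl,
                            criterion = "mean_activation")
  recs_ma <- classify_batch(obs_ma, stims)
  theta <- mean(recs_ma$decision_var)
  obs_ft <- linear_observer(ax$pixels, template = tpl, theta = theta)
  recs_ft <- classify_batch(obs_ft, stims)
  expect_identical(recs_ma$label, recs_ft$label)
  # a batch of one: v equals its own mean, tie rule gives male
  expect_equal(classify_batch(obs_ma, stims[1])$label, "male")
  expect_error(classify(obs_ma, stims[[1]]), "classify_batch")
  expect_error(classify_batch(obs_ma, list()), "non-empty")
})

test_that("mean_activation removes a constant response bias", {
  # constant-bias observer: v = v0 + pixel sum; the mean-activation rule
  # should label ~50/50 regardless of v0
  v0 <- 1000
  biased <- external_observer(function(img) c(v0 + sum(img), 0),
                              criterion = "mean_activation")
  set.seed(44)
  stims <- lapply(1:400, function(i) matrix(runif(16 * 16), 16, 16))
  recs <- classify_batch(biased, stims)
  expect_gt(mean(recs$label == "female"), 0.35)
  expect_lt(mean(recs$label == "female"), 0.65)
  # and is invariant to the shift itself
  unbiased <- external_observer(function(img) c(sum(img), 0),
                                criterion = "mean_activation")
  expect_identical(classify_batch(unbiased, stims)$label, recs$label)
})

test_that("the external adapter enforces the two-score contract", {
  stub <- external_observer(function(img) c(1, 0))
  st <- matrix(0.5, 16, 16)
  rec <- classify(stub, st)
  expect_equal(rec$label, "female")  # class-1 score higher
  expect_equal(c(rec$score1, rec$score2), c(1, 0))
  # brightness-driven stub flips with image brightness
  br <- external_observer(function(img) c(mean(img), 1 - mean(img)))
  expect_equal(classify(br, matrix(0.9, 16, 16))$label, "female")
  expect_equal(classify(br, matrix(0.1, 16, 16))$label, "male")
  # ties (mean = 0.5) go to male, matching "male when the male unit is
  # at least as high"
  expect_equal(classify(br, matrix(0.5, 16, 16))$label, "male")
  bad <- external_observer(function(img) "oops")
  expect_error(classify(bad, st), "malformed")
})
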