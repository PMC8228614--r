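test_that("single-component PLS recovers an exact one-column relation", {
  set.seed(1)
  X <- cbind(rnorm(8), 0, 0)
  y <- 2 * X[, 1] + 1
  m <- fit_pls(X, y, 1)
  expect_equal(unname(model_stats(m, X, y)["r2"]), 1, tolerance = 1e-12)

  # constant response shift moves only the intercept
  m2 <- fit_pls(X, y + 5, 1)
  expect_equal(m2$coef, m$coef, tolerance = 1e-12)
  expect_equal(m2$intercept, m$intercept + 5, tolerance = 1e-12)
})

test_that("full-rank PLS equals least squares (normal-equations oracle)", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 4), 6, 4)
    y <- rnorm(6)
    m <- fit_pls(X, y, 4)
    expect_equal(predict(m, X), ols_fit(X, y), tolerance = 1e-8,
                 info = paste("seed", seed))
  }
  # slightly larger: 8 x 6
  set.seed(99)
  X <- matrix(rnorm(48), 8, 6)
  y <- rnorm(8)
  expect_equal(predict(fit_pls(X, y, 6), X), ols_fit(X, y),
               tolerance = 1e-8)
})

test_that("fit_pls rejects degenerate inputs", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fit_pls(X, rep(1, 4), 1), "zero-variance")
  expect_error(fit_pls(X, rnorm(4), 4), "n_components")
  expect_error(fit_pls(X[1:2, ], rnorm(2), 1), "3 samples")
})

test_that("predictions behave as a centered linear model", {
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- fit_pls(X, y, 2)
  expect_equal(predict(m, X), as.vector(X %*% m$coef) + m$intercept)
  # a row of training column means predicts the training response mean
  expect_equal(predict(m, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-12)
  expect_error(predict(m, X[, 1:2]), "columns")
})

test_that("LOO q2: perfect latent structure, brute-force equality", {
  sim <- gen_latent_pls_data(n = 20, p = 15, factors = 1, snr = Inf,
                             x_noise_sd = 0, seed = 4)
  expect_gt(as.numeric(loo_q2(sim$X, sim$y, 1)), 0.99)

  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 9), 12, 9)
    y <- rnorm(12)
    for (a in c(1, 3)) {
      expect_equal(as.numeric(loo_q2(X, y, a)), loo_q2_naive(X, y, a),
                   tolerance = 0, info = paste("seed", seed, "ncomp", a))
    }
  }
})

test_that("permuted responses destroy q2", {
  sim <- gen_latent_pls_data(n = 20, p = 12, factors = 2, snr = 20,
                             seed = 8)
  set.seed(42)
  hits <- 0L
  n_perm <- 100L
  for (b in seq_len(n_perm)) {
    q <- as.numeric(loo_q2(sim$X, sample(sim$y), 2))
    if (q <= 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("component selection finds the planted factor count", {
  sim <- gen_latent_pls_data(n = 40, p = 30, factors = 3, snr = 10,
                             seed = 5)
  sel <- select_components(sim$X, sim$y, max_components = 5)
  expect_equal(as.integer(sel), 3L)
  q2s <- attr(sel, "q2")
  # the parsimony margin never selects above the strict maximizer
  expect_lte(as.integer(sel), which.max(q2s))
  # with margin 0 the rule is the strict maximum
  sel0 <- select_components(sim$X, sim$y, 5, parsimony = 0)
  expect_equal(as.integer(sel0), which.max(attr(sel0, "q2")))
})

test_that("training statistics follow the stated formulas", {
  set.seed(6)
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  m <- fit_pls(X, y, 2)
  s <- model_stats(m, X, y)
  fitted <- predict(m, X)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(unname(s["r2"]), 1 - sse / sst, tolerance = 1e-12)
  expect_equal(unname(s["SEE"]), sqrt(sse / (6 - 2 - 1)), tolerance = 1e-12)
  expect_equal(unname(s["F"]),
               ((sst - sse) / 2) / (sse / (6 - 2 - 1)), tolerance = 1e-10)

  yy <- 2 * X[, 1]
  expect_equal(unname(model_stats(fit_pls(X, yy, 3), X, yy)["r2"]), 1,
               tolerance = 1e-10)
  Xw <- cbind(X, matrix(rnorm(24), 6, 4))
  expect_error(model_stats(fit_pls(Xw, y, 5), Xw, y), "n - c - 1")
})

test_that("field contributions are |b|*sd shares normalized to 100", {
  set.seed(7)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  m <- fit_pls(X, y, 2)
  map1 <- data.frame(field = rep("CoMFA_S", 5), point = 1:5, column = 1:5)
  expect_equal(unname(field_contributions(m, map1)), 100)

  # duplicated blocks split 50/50
  X2 <- cbind(X, X)
  m2 <- fit_pls(X2, y, 2)
  map2 <- data.frame(field = rep(c("CoMFA_S", "CoMFA_E"), each = 5),
                     point = rep(1:5, 2), column = 1:10)
  co <- field_contributions(m2, map2)
  expect_equal(unname(co), c(50, 50), tolerance = 0.1)

  # hand-computed two-field shares
  map3 <- data.frame(field = c("A", "A", "B", "B", "B"),
                     point = 1:5, column = 1:5)
  w <- abs(m$coef) * apply(X, 2, sd)
  expect_equal(unname(field_contributions(m, map3)),
               unname(100 * c(sum(w[1:2]), sum(w[3:5])) / sum(w)),
               tolerance = 1e-10)

  # fields dropped by the column filter report 0
  co0 <- field_contributions(m, map1, zero_fields = "CoMSIA_D")
  expect_equal(unname(co0), c(100, 0))
  expect_equal(sum(co0), 100)
})

test_that("planted coefficients are recovered at moderate noise", {
  sim <- gen_latent_pls_data(n = 50, p = 40, factors = 3, snr = 10,
                             seed = 10)
  sel <- select_components(sim$X, sim$y, 5)
  m <- fit_pls(sim$X, sim$y, as.integer(sel))
  cosine <- sum(m$coef * sim$truth$beta) /
    sqrt(sum(m$coef^2) * sum(sim$truth$beta^2))
  expect_gte(cosine, 0.9)
})
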