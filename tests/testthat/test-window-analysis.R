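# dense-grid oracle for the achievable AUC change of a quadratic
effect_grid_oracle <- function(b, range, n = 200001) {
  w <- seq(range[1], range[2], length.out = n)
  v <- b[1] + b[2] * w + b[3] * w^2
  max(v) - min(v)
}

test_that("noiseless quadratic data are recovered exactly", {
  w <- rep(WINDOW_SIZES, each = 3)
  auc <- 0.9 - 1e-5 * (w - 80)^2
  f <- fit_quadratic(data.frame(window_size = w, auc = auc))
  expect_equal(unname(f$coefficients),
               c(0.9 - 1e-5 * 6400, 2e-5 * 80, -1e-5), tolerance = 1e-6)
  expect_equal(f$local_max_window, 80, tolerance = 1e-6)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-9)
  # achievable change: 0.9 at the vertex minus 0.9 - 1e-5*69^2 at w=149
  expect_equal(f$effect_size, 1e-5 * 69^2, tolerance = 1e-6)
  expect_false(f$relevant)  # 0.0476 just under the 0.05 rule
})

test_that("constant response gives null coefficients and zero effect", {
  pts <- data.frame(window_size = rep(WINDOW_SIZES, 2), auc = 0.8)
  f <- fit_quadratic(pts)
  expect_lt(abs(f$coefficients[["b1"]]), 1e-10)
  expect_lt(abs(f$coefficients[["b2"]]), 1e-10)
  expect_lt(f$effect_size, 1e-6)
  expect_false(f$relevant)
  expect_true(is.na(f$local_max_window))
})

test_that("effect size has the closed form and matches the grid oracle", {
  expect_equal(quad_effect_size(c(0.8, 0, 0)), 0)
  # pure linear: |s| * (149 - 15)
  s <- 3.7e-4
  expect_equal(quad_effect_size(c(0.5, s, 0)), s * 134)
  expect_equal(quad_effect_size(c(0.5, -s, 0)), s * 134)
  # random quadratics vs dense grid
  set.seed(30)
  for (i in 1:50) {
    b <- c(runif(1, 0, 1), runif(1, -0.01, 0.01), runif(1, -1e-4, 1e-4))
    expect_lt(abs(quad_effect_size(b) - effect_grid_oracle(b, WINDOW_RANGE)),
              1e-9)
  }
})

test_that("adjusted R2 never exceeds R2 and the vertex rule is respected", {
  set.seed(31)
  w <- rep(WINDOW_SIZES, each = 10)
  auc <- 0.7 + 5e-4 * w + rnorm(length(w), 0, 0.02)
  f <- fit_quadratic(data.frame(window_size = w, auc = auc))
  expect_lte(f$adjusted_r2, f$r2)
  # convex fits (b2 > 0) report no local maximum even with interior vertex
  aucx <- 0.9 - 1e-5 * (w - 80)^2
  fx <- fit_quadratic(data.frame(window_size = w, auc = 0.8 + 1e-5 * (w - 80)^2))
  expect_true(is.na(fx$local_max_window))
  expect_error(fit_quadratic(data.frame(window_size = c(15, 15, 32),
                                        auc = c(0.7, 0.8, 0.9))),
               "3 distinct")
})

test_that("relevance report applies the 0.05 rule", {
  # build exact quadratics with known effect sizes 0.062 and 0.027
  mk <- function(es, act) {
    b1 <- es / 134  # linear response over the 15-149 range
    w <- rep(WINDOW_SIZES, each = 5)
    data.frame(activity = act, window_size = w, auc = 0.7 + b1 * w)
  }
  runs <- rbind(mk(0.062, "door_handle"), mk(0.027, "seal"))
  fits <- fit_window_response(runs)
  rel <- classify_relevance(fits)
  expect_setequal(rel$relevant, "door_handle")
  expect_equal(fits$effect_size[fits$activity == "door_handle"], 0.062,
               tolerance = 1e-9)
  expect_equal(fits$effect_size[fits$activity == "seal"], 0.027,
               tolerance = 1e-9)
  # report is sorted by effect size, flags match the threshold exactly
  expect_equal(rel$report$activity, c("door_handle", "seal"))
  expect_identical(rel$report$relevant, c(TRUE, FALSE))
})

test_that("false-relevance rate under a flat truth is small and estimable", {
  set.seed(32)
  hits <- replicate(100, {
    w <- rep(WINDOW_SIZES, each = 10)                # 60 runs per activity
    f <- fit_quadratic(data.frame(window_size = w,
                                  auc = 0.8 + rnorm(length(w), 0, 0.02)))
    f$relevant
  })
  expect_lt(mean(hits), 0.1)
})
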