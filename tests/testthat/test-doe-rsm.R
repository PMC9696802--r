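test_that("the centerless Box-Behnken design has the published structure", {
  bb <- generate_bbd(l01_bbd_factors(), n_center = 0)
  expect_equal(nrow(bb$coded), 12)
  # every run sits on an edge midpoint: exactly two nonzero coordinates
  expect_true(all(rowSums(bb$coded != 0) == 2))
  # column identity behind the aliasing: sum of squares is 2 on every run
  expect_equal(unname(rowSums(bb$coded^2)), rep(2, 12))
  bb3 <- generate_bbd(l01_bbd_factors(), n_center = 3)
  expect_equal(nrow(bb3$coded), 15)
  expect_equal(sum(rowSums(bb3$coded != 0) == 0), 3)
  expect_error(generate_bbd(factor_def(c("a", "b"), low = c(0, 0),
                                       high = c(1, 1))), "3-factor")
})

test_that("aliasing on the centerless design drops one quadratic", {
  bb <- generate_bbd(l01_bbd_factors())
  al <- detect_aliasing(bb)
  expect_equal(al$rank, 9)  # 10 candidate columns, rank 9
  expect_equal(al$dropped, "time^2")
  expect_length(al$estimable, 8)
  # the drop rule is configurable
  al2 <- detect_aliasing(bb, prefer_drop = "NaNO3^2")
  expect_equal(al2$dropped, "NaNO3^2")
  # one centre point restores estimability of all 10 terms
  al3 <- detect_aliasing(generate_bbd(l01_bbd_factors(), n_center = 1))
  expect_length(al3$dropped, 0)
  # a linear-only model is never rank-deficient here
  al4 <- detect_aliasing(bb, terms = c("NaNO3", "PO4", "time"))
  expect_length(al4$dropped, 0)
  # rank 9 holds for any coding: the identity is structural
  bb_alt <- generate_bbd(factor_def(c("x", "y", "z"), low = c(0, 5, 10),
                                    high = c(1, 9, 30)))
  expect_equal(detect_aliasing(bb_alt)$rank, 9)
})

test_that("quadratic fits on noiseless data recover the surface exactly", {
  m <- l01_yield_model()
  bb <- generate_bbd(l01_bbd_factors())
  y <- simulate_responses(m, bb, noise_sd = 0)
  fit <- fit_quadratic(bb, y)
  expect_equal(fit$model$intercept, m$intercept, tolerance = 1e-10)
  expect_equal(fit$model$linear, m$linear, tolerance = 1e-10)
  expect_equal(fit$model$interaction, m$interaction, tolerance = 1e-10)
  expect_equal(fit$model$quadratic, m$quadratic, tolerance = 1e-10)
  expect_equal(fit$dropped, "time^2")
  # constant responses: intercept only
  fc <- fit_quadratic(bb, rep(4, 12))
  expect_equal(fc$model$intercept, 4)
  expect_equal(unname(fc$model$linear), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(fc$model$quadratic), rep(0, 2), tolerance = 1e-12)
})

test_that("noisy fits are unbiased with least-squares sampling error", {
  m <- l01_yield_model()
  bb <- generate_bbd(l01_bbd_factors())
  set.seed(97)
  sims <- replicate(500, {
    y <- simulate_responses(m, bb, noise_sd = 0.07)
    f <- fit_quadratic(bb, y)
    c(f$model$linear, f$sigma2)
  })
  # linear coefficients: mean bias below 2 Monte-Carlo standard errors
  for (i in 1:3) {
    bias <- mean(sims[i, ]) - m$linear[[i]]
    expect_lt(abs(bias), 2 * sd(sims[i, ]) / sqrt(500))
  }
  # residual MS centred on sigma^2 = 0.0049 (chi-square_3 / 3 scaling)
  expect_equal(mean(sims[4, ]), 0.07^2, tolerance = 0.1)
})

test_that("prediction evaluates the published polynomial", {
  m <- l01_yield_model()
  expect_equal(predict(m, c(0, 0, 0)), 8.21)
  expect_equal(predict(m, c(1, 0, 0)), 8.21 - 0.4175 - 1.15)
  # batch evaluation matches elementwise evaluation
  pts <- matrix(runif(30, -1, 1), ncol = 3)
  expect_equal(predict(m, pts),
               apply(pts, 1, function(r) predict(m, r)))
  zero <- quadratic_model(0, c(a = 0, b = 0))
  expect_equal(predict(zero, matrix(rnorm(10), ncol = 2)), rep(0, 5))
})

test_that("partial-SS ANOVA satisfies its structural identities", {
  m <- l01_yield_model()
  bb <- generate_bbd(l01_bbd_factors())
  y <- simulate_responses(m, bb, noise_sd = 0.07, seed = 12)
  fit <- fit_quadratic(bb, y)
  tab <- anova_partial(fit)
  ss <- function(src) tab$ss[tab$source == src]
  df <- function(src) tab$df[tab$source == src]
  expect_equal(ss("Model") + ss("Residual"), ss("Cor Total"),
               tolerance = 1e-9)
  expect_equal(df("Cor Total"), 11)
  expect_equal(df("time^2"), 0)
  expect_equal(ss("time^2"), 0)
  # MS = SS/df and F = MS/MS_residual wherever defined
  rows <- tab$df > 0 & !tab$source %in% c("Cor Total")
  expect_equal(tab$ms[rows], tab$ss[rows] / tab$df[rows])
  mse <- ss("Residual") / df("Residual")
  frows <- !is.na(tab$f)
  expect_equal(tab$f[frows], tab$ms[frows] / mse)
  # p-values recompute from the F tail
  expect_equal(tab$p[frows],
               pvalue_from_f(tab$f[frows], tab$df[frows], 3))
  # SS identity holds across 500 noisy refits
  set.seed(13)
  ok <- replicate(500, {
    yy <- simulate_responses(m, bb, noise_sd = 0.2)
    tt <- anova_partial(fit_quadratic(bb, yy))
    abs(tt$ss[tt$source == "Model"] + tt$ss[tt$source == "Residual"] -
          tt$ss[tt$source == "Cor Total"]) < 1e-9
  })
  expect_true(all(ok))
  # an interpolating fit (saturated design) has no residual df: explicit
  # error rather than a silent zero-MSE table
  half <- design_matrix(matrix(c(-1, -1, -1,
                                 1, 1, -1,
                                 1, -1, 1,
                                 -1, 1, 1), ncol = 3, byrow = TRUE),
                        l01_bbd_factors(), kind = "bbd")
  fi <- fit_quadratic(half, c(1, 2, 3, 4),
                      terms = c("NaNO3", "PO4", "time"))
  expect_equal(fi$df_residual, 0)
  expect_error(anova_partial(fi), "residual df = 0")
})

test_that("box-constrained maximisation is exact against a grid oracle", {
  m <- l01_yield_model()
  opt <- optimize_box(m)
  # dense oracle: the surface is linear in time, so the maximiser has
  # time = +-1; scan B x C at 0.001 resolution on both faces
  g <- seq(-1, 1, by = 0.001)
  grid <- as.matrix(expand.grid(NaNO3 = g, PO4 = g))
  best <- -Inf; arg <- NULL
  for (e in c(-1, 1)) {
    v <- predict(m, cbind(grid, time = e))
    i <- which.max(v)
    if (v[i] > best) { best <- v[i]; arg <- c(grid[i, ], time = e) }
  }
  expect_equal(opt$predicted, best, tolerance = 1e-5)
  expect_equal(unname(opt$coded), unname(arg), tolerance = 2e-3)
  expect_true(opt$at_boundary[["time"]])
  expect_false(any(opt$at_boundary[c("NaNO3", "PO4")]))
  # never below the model value at random box points
  set.seed(3)
  pts <- matrix(runif(3e5, -1, 1), ncol = 3)
  expect_true(all(predict(m, pts) <= opt$predicted + 1e-9))
  # pure concave single-factor model: interior optimum at 0
  conc <- quadratic_model(0, c(B = 0), quadratic = c(B = -1))
  oc <- optimize_box(conc)
  expect_equal(unname(oc$coded), 0)
  expect_equal(oc$predicted, 0)
  # pure linear model: vertex optimum
  lin <- quadratic_model(1, c(a = 2, b = -1))
  ol <- optimize_box(lin)
  expect_equal(unname(ol$coded), c(1, -1))
  expect_equal(ol$predicted, 1 + 2 + 1)
})

test_that("coded/natural transforms invert each other", {
  f <- l01_bbd_factors()
  expect_equal(drop(decode_levels(f, c(0, 0, 0))),
               c(NaNO3 = 2.5, PO4 = 23.75, time = 126))
  expect_equal(drop(decode_levels(f, c(0, 0, 1)))[["time"]], 132)
  set.seed(8)
  x <- matrix(runif(30, -2, 2), ncol = 3)
  expect_equal(unname(encode_levels(f, decode_levels(f, x))), unname(x),
               tolerance = 1e-12)
  # low/high parametrisation agrees with centre/step
  f2 <- factor_def("NaNO3", low = 2.0, high = 3.0)
  expect_equal(f2$center, 2.5)
  expect_equal(f2$step, 0.5)
})

test_that("parameter recovery is unbiased across random surfaces", {
  set.seed(55)
  fd <- factor_def(c("x1", "x2", "x3"), low = rep(-1, 3), high = rep(1, 3))
  bb <- generate_bbd(fd, n_center = 1)
  for (sd_noise in c(0, 0.05, 0.2)) {
    biases <- replicate(100, {
      truth <- quadratic_model(
        runif(1, -2, 2),
        setNames(runif(3, -2, 2), fd$name),
        setNames(runif(3, -2, 2), c("x1:x2", "x1:x3", "x2:x3")),
        setNames(runif(3, -2, 2), fd$name))
      y <- simulate_responses(truth, bb, noise_sd = sd_noise)
      f <- fit_quadratic(bb, y)
      c(f$model$linear - truth$linear,
        f$model$quadratic - truth$quadratic)
    })
    if (sd_noise == 0) {
      expect_lt(max(abs(biases)), 1e-8)
    } else {
      se <- apply(biases, 1, sd) / sqrt(ncol(biases))
      expect_true(all(abs(rowMeans(biases)) < 2.5 * se + 1e-12))
    }
  }
})
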