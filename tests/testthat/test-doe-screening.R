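test_that("the 12-run screening design is balanced and orthogonal", {
  d5 <- generate_pb12(l01_pb_factors())
  expect_equal(dim(d5$coded), c(12, 5))
  expect_true(all(colSums(d5$coded == 1) == 6))
  expect_true(all(colSums(d5$coded == -1) == 6))
  d11 <- generate_pb12(paste0("f", 1:11))
  g <- crossprod(d11$coded)
  expect_equal(g, diag(12, 11), ignore_attr = TRUE)
  # cyclic construction: each of rows 2..11 is a rotation of row 1
  first <- d11$coded[1, ]
  for (r in 2:11) {
    rotations <- vapply(0:10, function(s)
      all(d11$coded[r, ] == first[((seq_len(11) - 1 + s) %% 11) + 1]),
      logical(1))
    expect_true(any(rotations))
  }
  expect_equal(unname(d11$coded[12, ]), rep(-1, 11))
  expect_error(generate_pb12(paste0("f", 1:12)), "1 to 11")
})

test_that("main-effect fit matches a least-squares oracle", {
  d <- generate_pb12(l01_pb_factors())
  # random responses: effects must equal 2 x the lm coefficients, with
  # identical t statistics
  set.seed(42)
  y <- rnorm(12, 5, 1)
  fit <- fit_pb(d, y)
  oracle <- summary(lm(y ~ d$coded))
  expect_equal(fit$effects$effect, unname(2 * coef(oracle)[-1, 1]),
               tolerance = 1e-12)
  expect_equal(fit$effects$t, unname(coef(oracle)[-1, 3]),
               tolerance = 1e-12)
  expect_equal(fit$effects$p, unname(coef(oracle)[-1, 4]),
               tolerance = 1e-12)
  expect_equal(fit$residual_df, 6)
  # orthogonality: one shared standard error
  expect_length(unique(fit$effects$se), 1)
  # means interpretation: effect = mean(y | +1) - mean(y | -1)
  eff_b <- mean(y[d$coded[, 2] == 1]) - mean(y[d$coded[, 2] == -1])
  expect_equal(fit$effects$effect[2], eff_b)
})

test_that("zero-noise effects are recovered exactly", {
  d <- generate_pb12(l01_pb_factors())
  y <- 3 + 2 * d$coded[, "NaNO3"]
  fit <- fit_pb(d, y)
  expect_equal(fit$effects$effect[2], 4, tolerance = 1e-10)
  expect_equal(fit$effects$effect[-2], rep(0, 4), tolerance = 1e-10)
  # constant responses: all effects zero, all p = 1
  fc <- fit_pb(d, rep(7, 12))
  expect_equal(fc$effects$effect, rep(0, 5))
  expect_equal(fc$effects$p, rep(1, 5))
  expect_error(fit_pb(d, rep(1, 11)), "one finite value per run")
})

test_that("significant factors follow alpha and carry effect signs", {
  hits <- significant_factors(l01_pb_screen())
  expect_setequal(hits$factor, c("NaNO3", "time"))
  expect_true(all(hits$sign == "+"))
  expect_equal(nrow(significant_factors(l01_pb_screen(), alpha = 1)), 5)
  # below every strictly positive p nothing is selected (the NaNO3 row
  # prints p = 0.000, i.e. < 0.0005, so it survives any alpha)
  expect_equal(nrow(significant_factors(l01_pb_screen()[-2, ], alpha = 1e-9)),
               0)
  # negative effects are signed "-"
  tab <- data.frame(factor = "pH", effect = -0.148, p = 0.01)
  expect_equal(significant_factors(tab)$sign, "-")
})

test_that("ascent paths are uniform arithmetic progressions", {
  p <- build_ascent_path(c(NaNO3 = 1.0, PO4 = 20, time = 108),
                         c(NaNO3 = 3.0, PO4 = 25, time = 132),
                         n_trials = 5)
  expect_equal(unname(unlist(p[4, c("NaNO3", "PO4", "time")])),
               c(2.5, 23.75, 126))
  expect_equal(unname(attr(p, "increments")), c(0.5, 1.25, 6))
  # full run sheet reproduces the published ascent table
  pub <- l01_ascent()
  expect_equal(p$NaNO3, pub$NaNO3)
  expect_equal(p$PO4, pub$PO4)
  expect_equal(p$time, pub$time)
  # two trials: just the endpoints
  p2 <- build_ascent_path(c(a = 0), c(a = 1), 2)
  expect_equal(p2$a, c(0, 1))
  # affine: scaling natural units scales the whole path
  p10 <- build_ascent_path(c(a = 10, b = 200), c(a = 30, b = 250), 5)
  expect_equal(as.matrix(p10[, c("a", "b")]),
               10 * as.matrix(build_ascent_path(c(a = 1, b = 20),
                                                c(a = 3, b = 25), 5)[, c("a", "b")]),
               ignore_attr = TRUE)
  expect_error(build_ascent_path(c(a = 1), c(a = 1), 3), "no direction")
})

test_that("centre selection takes the argmax with warnings on edges", {
  ctr <- select_center(l01_ascent())
  expect_equal(ctr$trial, 4)
  expect_equal(ctr$yield, 8.23)
  expect_equal(unname(ctr$levels), c(2.5, 23.75, 126))
  mono <- build_ascent_path(c(a = 0), c(a = 4), 5)
  expect_warning(out <- select_center(mono, yields = 1:5), "beyond")
  expect_equal(out$trial, 5)
  expect_warning(tie <- select_center(mono, yields = rep(2, 5)), "tied")
  expect_equal(tie$trial, 1)
  expect_error(select_center(mono), "yields")
})
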