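test_that("pure-noise neural block adds essentially no variance explained", {
  pd <- planted_design(4000, seed = 1,
                       beta = c(sex = -0.5, age = 0.4, nonverbal_iq = 0.3,
                                setNames(rep(0, 9), neural_predictors())),
                       r2_target = 0.3)
  fit <- fit_hierarchical(pd$data)
  expect_lt(fit$delta_r2, 2 * 9 / 4000)
})

test_that("a planted two-block model is recovered at n = 2000", {
  pd <- planted_design(2000, seed = 42, r2_target = 0.68)
  fit <- fit_hierarchical(pd$data)
  expect_true(all(abs(fit$beta_std - pd$beta_std_true) < 0.05))
  expect_equal(fit$r2_total, 0.68, tolerance = 0.03)
  expect_equal(fit$delta_r2, fit$r2_total - fit$r2_block1, tolerance = 1e-15)
  expect_true(all(fit$tolerance > 0 & fit$tolerance <= 1))
})

test_that("OLS coefficients equal the normal-equations oracle", {
  for (seed in 1:5) {
    pd <- planted_design(60, seed = seed)
    fit <- fit_hierarchical(pd$data)
    X <- cbind(1, as.matrix(pd$data[names(pd$beta)]))
    y <- pd$data$phono_awareness
    oracle <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(fit$coefficients), as.numeric(oracle),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  pd <- planted_design(100, seed = 3)
  pd$data$h7 <- pd$data$h6  # exact duplicate
  expect_error(fit_hierarchical(pd$data), "h7")
})

test_that("frozen prediction reproduces in-sample fitted values exactly", {
  pd <- planted_design(200, seed = 7)
  fit <- fit_hierarchical(pd$data)
  sc <- predict_scores(fit, pd$data)
  lmfit <- lm(phono_awareness ~ ., data = pd$data)
  expect_equal(as.numeric(sc), unname(fitted(lmfit)), tolerance = 1e-10)
  expect_false(attr(sc, "refit_flag"))
})

test_that("prediction is affine: zeros give the intercept, superposition holds", {
  pd <- planted_design(100, seed = 9)
  fit <- fit_hierarchical(pd$data)
  zeros <- pd$data[1, ]
  zeros[names(pd$beta)] <- 0
  expect_equal(as.numeric(predict_scores(fit, zeros)),
               unname(fit$coefficients["(Intercept)"]))
  a <- pd$data[1, ]; b <- pd$data[2, ]
  mid <- a
  mid[names(pd$beta)] <- (a[names(pd$beta)] + b[names(pd$beta)]) / 2
  s <- predict_scores(fit, rbind(a, b, mid))
  expect_equal(s[3], (s[1] + s[2]) / 2, tolerance = 1e-12)
})

test_that("missing predictors are refused or flagged, never imputed", {
  pd <- planted_design(50, seed = 11)
  fit <- fit_hierarchical(pd$data)
  expect_error(predict_scores(fit, pd$data[setdiff(names(pd$data), "h5")]),
               "h5")
  d2 <- pd$data
  d2$h5[3] <- NA
  sc <- predict_scores(fit, d2)
  expect_true(is.na(sc[3]))
  expect_equal(attr(sc, "flagged"), 3L)
})

test_that("correlation, disattenuation, and error summaries are exact", {
  x <- seq(-3, 3, length.out = 40)
  cs <- correlate_scores(2 * x + 1, x)
  expect_equal(cs$r, 1.0)

  set.seed(2)
  y <- x + rnorm(40, 0, 1)
  cs2 <- correlate_scores(x, y, reliability = 0.9015)
  expect_equal(cs2$r_adjusted, cs2$r / sqrt(0.9015), tolerance = 1e-12)
  # the published-style pairing: r = 0.826 disattenuates to 0.870
  expect_equal(round(0.826 / sqrt(0.9015), 3), 0.870)
  # cap at 1
  cs3 <- correlate_scores(2 * x + 1, x, reliability = 0.5)
  expect_equal(cs3$r_adjusted, 1)

  pe <- prediction_error_summary(c(10, 12, 15, 20), c(10.5, 11, 17, 19))
  expect_equal(pe$median, median(c(0.5, 1, 2, 1)))
  expect_equal(pe$range, range(c(0.5, 1, 2, 1)))
})

test_that("zero-variance inputs are rejected for correlation", {
  expect_error(correlate_scores(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("single-block preliminary models are column-subset fits", {
  pd <- planted_design(300, seed = 13)
  timing <- paste0("peak_latency_", c(21, 31, 41, 51))
  fit_t <- fit_hierarchical(pd$data, block2 = timing)
  expect_equal(fit_t$f_change$df1, 4)
  expect_length(fit_t$beta_std, 7)
  expect_gt(fit_t$delta_r2, 0)
})

test_that("cross-validation transfers frozen coefficients to the holdout", {
  pd <- planted_design(37, seed = 15, r2_target = 0.9999)
  cv <- cross_validate(pd$data, n_train = 20, seed = 1)
  expect_length(cv$holdout_idx, 17)
  expect_equal(cv$holdout_r$r, 1.0, tolerance = 1e-3)
  expect_error(cross_validate(pd$data, n_train = 37, seed = 1), "holdout")

  # brute-force oracle: the trained (shrunk) model's population correlation,
  # measured on a large fresh sample from the same generative process;
  # the 17-child holdout r should scatter around it
  big <- planted_design(5000, seed = 999, r2_target = 0.68)$data
  res <- vapply(1:20, function(s) {
    cv <- cross_validate(planted_design(37, seed = 100 + s,
                                        r2_target = 0.68)$data,
                         n_train = 20, seed = s)
    pop_r <- correlate_scores(predict_scores(cv$train_fit, big),
                              big$phono_awareness)$r
    c(cv$holdout_r$r, pop_r)
  }, numeric(2))
  expect_gt(mean(res[1, ]), 0)
  expect_equal(mean(res[1, ]), mean(res[2, ]), tolerance = 0.15)
})

test_that("fits serialize to JSON and back with coefficients intact", {
  pd <- planted_design(60, seed = 17)
  fit <- fit_hierarchical(pd$data)
  path <- tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  sc1 <- predict_scores(fit, pd$data)
  sc2 <- predict_scores(back, pd$data)
  expect_equal(as.numeric(sc1), as.numeric(sc2), tolerance = 1e-12)
})
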