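test_that("rmse reduces to hand-computed values and averages its targets", {
  x <- tibble::tibble(a = c(1, 2), b = c(3, 4))
  expect_identical(rmse(x, x)$per_target, c(a = 0, b = 0))
  # single column with residuals (3, 4): sqrt((9 + 16) / 2)
  r <- rmse(matrix(c(3, 4)), matrix(c(0, 0)))
  expect_equal(unname(r$per_target), sqrt(12.5))
  expect_equal(r$mean, sqrt(12.5))
  expect_error(rmse(x[0, ], x[0, ]), "empty")
  expect_error(rmse(x, x[1, ]), "shape")
})

test_that("the report average is the arithmetic mean of its per-target values", {
  rep <- evaluation_report(list(
    "Polynomial Regression" = c(latitude = 2.396, longitude = 1.050),
    "Linear Regression" = c(latitude = 0.123, longitude = 0.164)
  ))
  expect_equal(rep$average, rowMeans(cbind(rep$latitude, rep$longitude)))
  expect_equal(rep$average[rep$model == "Polynomial Regression"], 1.723)
})

test_that("half-up rounding behaves at ties", {
  expect_identical(round_half_up(0.1435, 3), 0.144)
  expect_identical(round_half_up(0.01655, 4), 0.0166)
  expect_identical(round_half_up(-0.5), -1)
  expect_identical(round_half_up(2.5), 3)
})

test_that("expanding-window folds grow the train block and test strictly later", {
  folds <- time_series_cv_splits(12, k = 5)
  expect_identical(vapply(folds, function(f) length(f$train), integer(1)),
                   c(2L, 4L, 6L, 8L, 10L))
  for (f in folds) {
    expect_identical(length(f$test), 2L)
    expect_lt(max(f$train), min(f$test))
  }
  one <- time_series_cv_splits(100, k = 1)
  expect_identical(length(one[[1]]$train), 50L)
  expect_identical(length(one[[1]]$test), 50L)
  expect_error(time_series_cv_splits(5, k = 5), "too small")
})


test_that("the network drives degenerate all-zero targets to zero", {
  d <- make_linear_data()
  zeros <- tibble::tibble(u = rep(0, 400), v = rep(0, 400))
  sp <- chronological_split(400)
  fit <- train_mlp(d$features, zeros, sp, mlp_config(epochs = 5, seed = 3))
  pred <- predict(fit, d$features[sp$train, ])
  expect_lt(max(abs(as.matrix(pred))), 1e-2)
})

test_that("the network recovers an exact linear map to near least-squares accuracy", {
  d <- make_linear_data()
  sp <- chronological_split(400)
  fit <- train_mlp(d$features, d$labels, sp, mlp_config(epochs = 500, seed = 2))
  val_rmse <- fit$history$validation_rmse[500]
  expect_lt(val_rmse, 0.05)
  # exact least-squares oracle: the representable optimum has RMSE ~ noise
  X <- cbind(1, as.matrix(d$features))
  ls_resid <- stats::lm.fit(X[sp$train, ], as.matrix(d$labels)[sp$train, ])$residuals
  ls_rmse <- sqrt(mean(ls_resid^2))
  expect_lt(ls_rmse, 0.01)          # sanity of the oracle itself
  expect_lt(val_rmse, 10 * ls_rmse + 0.05)
})

test_that("training is deterministic given a seed and history is consistent", {
  d <- make_linear_data(n = 200)
  sp <- chronological_split(200)
  cfg <- mlp_config(epochs = 20, seed = 11)
  f1 <- train_mlp(d$features, d$labels, sp, cfg)
  f2 <- train_mlp(d$features, d$labels, sp, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  # recorded final train loss equals RMSE of fresh predictions on the train block
  pred <- predict(f1, d$features[sp$train, ])
  got <- sqrt(mean((as.matrix(pred) - as.matrix(d$labels[sp$train, ]))^2))
  expect_equal(got, f1$history$train_rmse[20])
})

test_that("prediction respects row order and rejects malformed inputs", {
  d <- make_linear_data(n = 200)
  sp <- chronological_split(200)
  fit <- train_mlp(d$features, d$labels, sp, mlp_config(epochs = 5, seed = 4))
  perm <- sample(200)
  expect_equal(predict(fit, d$features[perm, ]),
               predict(fit, d$features)[perm, ], ignore_attr = TRUE)
  expect_error(predict(fit, d$features["day"]), "feature column")
})

test_that("tidy and glance summarize a fitted network", {
  d <- make_linear_data(n = 200)
  fit <- train_mlp(d$features, d$labels, chronological_split(200),
                   mlp_config(epochs = 3, seed = 1))
  expect_identical(nrow(tidy(fit)), 3L)
  gl <- glance(fit)
  expect_identical(gl$epochs, 3L)
  expect_gt(gl$n_parameters, 8000)
})

test_that("linear baseline is exact on linear data and matches normal equations", {
  n <- 120
  rows <- tibble::tibble(day = rep(1:30, 4))
  rows$latitude <- 2 * rows$day + 1
  rows$longitude <- rep(7, n)
  res <- fit_linear_baseline(rows)
  expect_lt(max(res$rmse$rmse), 1e-9)
  set.seed(5)
  rows$latitude <- rows$latitude + rnorm(n, 0, 0.3)
  res2 <- fit_linear_baseline(rows)
  X <- cbind(1, rows$day)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% rows$latitude)
  expect_lt(max(abs(res2$coefficients[, "latitude"] - beta_oracle)), 1e-8)
  expect_error(fit_linear_baseline(tibble::tibble(day = rep(3, 10),
                                                  latitude = 1:10,
                                                  longitude = 1:10)),
               "degenerate")
})

test_that("polynomial baseline fits quartics, nests the linear fit, expands bases", {
  expect_identical(as.numeric(polynomial_basis(2, 4)), c(2, 4, 8, 16))
  n <- 120
  rows <- tibble::tibble(day = rep(1:30, 4))
  rows$latitude <- 1e-4 * rows$day^4 - 0.01 * rows$day^2 + 3
  rows$longitude <- 0.5 * rows$day
  res <- fit_polynomial_baseline(rows, degree = 4)
  expect_lt(max(res$rmse$rmse), 1e-6)
  # nesting: on a common training block the quartic residual cannot exceed
  # the straight-line residual
  set.seed(6)
  rows$latitude <- 0.2 * rows$day + rnorm(n, 0, 0.1)
  train <- 1:80
  b1 <- cbind(1, polynomial_basis(rows$day[train], 1))
  b4 <- cbind(1, polynomial_basis(rows$day[train], 4))
  r1 <- sqrt(mean(stats::lm.fit(b1, rows$latitude[train])$residuals^2))
  r4 <- sqrt(mean(stats::lm.fit(b4, rows$latitude[train])$residuals^2))
  expect_lte(r4, r1 + 1e-12)
})

test_that("VAR handles constant series exactly and recovers known dynamics", {
  const <- tibble::tibble(latitude = rep(5.2, 100), longitude = rep(118.66, 100))
  res <- fit_var_baseline(const)
  expect_identical(res$rmse$rmse, c(0, 0))

  # simulate a VAR(1) with known coefficient matrix
  set.seed(14)
  A <- matrix(c(0.6, -0.2, 0.1, 0.5), 2, 2)
  n <- 2000
  y <- matrix(0, n, 2)
  for (t in 2:n) y[t, ] <- A %*% y[t - 1, ] + rnorm(2, 0, 0.1)
  fit <- fit_var_baseline(tibble::as_tibble(as.data.frame(y)), max_lag = 4)
  A_hat <- fit$coefficients[, 2:3]
  expect_lt(max(abs(A_hat - A)), 0.05)
  # independent estimator agrees on the lag-1 dynamics
  ar_fit <- stats::ar.ols(y[1:1600, ], aic = FALSE, order.max = 1,
                          demean = TRUE, intercept = TRUE)
  expect_lt(max(abs(A_hat - ar_fit$ar[1, , ])), 0.02)
})

test_that("white-noise forecasts approach the series standard deviation", {
  set.seed(8)
  y <- tibble::tibble(a = rnorm(1000), b = rnorm(1000))
  fit <- fit_var_baseline(y)
  expect_lt(max(abs(fit$rmse$rmse - 1)), 0.1)
})
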