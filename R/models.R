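#' Configuration of the sequential neural network
#'
#' A fully-connected feed-forward regressor: two hidden layers of 128 and
#' 64 units with rectified-linear activation, a linear output layer, Adam
#' at its canonical defaults, RMSE loss, 500 epochs with batches of 32.
#' Training optimizes the mean squared error, whose gradient direction is
#' identical to RMSE's; losses are recorded and reported as RMSE.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param epochs number of passes over the training block (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate Adam step size.
#' @param n_outputs number of output units (2 for coordinate-only targets,
#'   4 for the spatiotemporal target set); `NULL` infers from the labels.
#' @param seed integer seed making initialization and batch order
#'   reproducible.
#' @return a list of class `"mlp_config"`.
#' @export
mlp_config <- function(hidden_sizes = c(128L, 64L), epochs = 500L,
                       batch_size = 32L, learning_rate = 1e-3,
                       n_outputs = NULL, seed = 1L) {
  stopifnot(all(hidden_sizes >= 1), epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_outputs = n_outputs, seed = as.integer(seed)),
            class = "mlp_config")
}

relu <- function(x) pmax(x, 0)

mlp_forward <- function(w, X) {
  H1 <- relu(sweep(X %*% w$W1, 2, w$b1, "+"))
  H2 <- relu(sweep(H1 %*% w$W2, 2, w$b2, "+"))
  out <- sweep(H2 %*% w$W3, 2, w$b3, "+")
  list(H1 = H1, H2 = H2, out = out)
}

#' Train the sequential neural network
#'
#' Fits the regressor on the training block of a chronological split while
#' recording per-epoch training and validation RMSE; validation is
#' monitored only, never acted on (no early stopping).  Features are
#' standardized with statistics from the training block only; labels are
#' left in native units.  Given the same seed, two runs produce identical
#' weights and losses.
#'
#' @param features,labels aligned data frames (see [build_matrices()]).
#' @param split a [chronological_split()] result.
#' @param config an [mlp_config()].
#' @return an object of class `"mlp_fit"` with elements `weights`,
#'   `config`, `scaling`, `history` (tibble of per-epoch losses),
#'   `feature_names`, `label_names`.
#' @export
train_mlp <- function(features, labels, split, config = mlp_config()) {
  stopifnot(nrow(features) == nrow(labels), inherits(split, "split_index"))
  if (!is.null(config$n_outputs) && config$n_outputs != ncol(labels)) {
    stop("config$n_outputs (", config$n_outputs,
         ") does not match the number of label columns (", ncol(labels), ")",
         call. = FALSE)
  }
  scaling <- standardize(features[split$train, , drop = FALSE])
  X <- as.matrix(apply_scaling(scaling, features))
  Y <- as.matrix(labels)
  K <- ncol(Y); d <- ncol(X)
  h <- config$hidden_sizes
  tr <- split$train; va <- split$validation

  set.seed(config$seed)
  w <- list(
    W1 = matrix(rnorm(d * h[1], 0, sqrt(2 / d)), d, h[1]),
    b1 = rep(0, h[1]),
    W2 = matrix(rnorm(h[1] * h[2], 0, sqrt(2 / h[1])), h[1], h[2]),
    b2 = rep(0, h[2]),
    # near-zero output weights and the output bias at the training-label
    # means: the net starts as the mean predictor, so raw-unit targets
    # (e.g. longitudes near 119) are reachable within the epoch budget
    W3 = matrix(rnorm(h[2] * K, 0, 1e-3), h[2], K),
    b3 = colMeans(Y[tr, , drop = FALSE])
  )
  adam_m <- lapply(w, function(p) p * 0)
  adam_v <- lapply(w, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  step <- 0L

  overall_rmse <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    pred <- mlp_forward(w, X[idx, , drop = FALSE])$out
    sqrt(mean((pred - Y[idx, , drop = FALSE])^2))
  }

  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    order <- sample(tr)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    for (b in batches) {
      Xb <- X[b, , drop = FALSE]; Yb <- Y[b, , drop = FALSE]
      f <- mlp_forward(w, Xb)
      dOut <- 2 * (f$out - Yb) / length(Yb)        # d MSE / d out
      g <- list(
        W3 = crossprod(f$H2, dOut), b3 = colSums(dOut)
      )
      dH2 <- (dOut %*% t(w$W3)) * (f$H2 > 0)
      g$W2 <- crossprod(f$H1, dH2); g$b2 <- colSums(dH2)
      dH1 <- (dH2 %*% t(w$W2)) * (f$H1 > 0)
      g$W1 <- crossprod(Xb, dH1); g$b1 <- colSums(dH1)
      step <- step + 1L
      for (nm in names(w)) {
        adam_m[[nm]] <- b1a * adam_m[[nm]] + (1 - b1a) * g[[nm]]
        adam_v[[nm]] <- b2a * adam_v[[nm]] + (1 - b2a) * g[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1a^step)
        vhat <- adam_v[[nm]] / (1 - b2a^step)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    tr_loss <- overall_rmse(tr)
    va_loss <- overall_rmse(va)
    if (!is.finite(tr_loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_rmse = tr_loss,
                                       validation_rmse = va_loss)
  }

  structure(list(weights = w, config = config, scaling = scaling,
                 history = dplyr::bind_rows(history),
                 feature_names = colnames(features),
                 label_names = colnames(labels), split = split),
            class = "mlp_fit")
}

#' Predict with a fitted network
#'
#' @param object an `"mlp_fit"`.
#' @param newdata data frame with the training feature columns.
#' @param ... ignored.
#' @return a tibble of predictions, one row per input row, columns named
#'   after the training labels.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(apply_scaling(object$scaling,
                               newdata[object$feature_names]))
  out <- mlp_forward(object$weights, X)$out
  colnames(out) <- object$label_names
  tibble::as_tibble(out)
}

#' @method tidy mlp_fit
#' @export
tidy.mlp_fit <- function(x, ...) x$history

#' @method glance mlp_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, integer(1)))
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = x$config$epochs, n_parameters = n_par,
                 final_train_rmse = last$train_rmse,
                 final_validation_rmse = last$validation_rmse)
}

#' @method autoplot mlp_fit
#' @export
autoplot.mlp_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "rmse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$rmse,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "RMSE", colour = NULL)
}

#' Per-target and average root mean squared error
#'
#' @param predicted,actual data frames or matrices of equal shape.
#' @return a list with `per_target` (named numeric, per-column RMSE) and
#'   `mean` (their unweighted arithmetic mean).
#' @export
rmse <- function(predicted, actual) {
  P <- as.matrix(predicted); A <- as.matrix(actual)
  if (length(P) == 0 || length(A) == 0) {
    stop("RMSE is undefined for empty input", call. = FALSE)
  }
  if (!all(dim(P) == dim(A))) stop("shape mismatch", call. = FALSE)
  per <- sqrt(colMeans((P - A)^2))
  names(per) <- colnames(A) %||% paste0("target_", seq_len(ncol(A)))
  list(per_target = per, mean = mean(per))
}

#' Expanding-window time-series cross-validation folds
#'
#' Splits `n` chronologically ordered rows into `k` folds: with block size
#' `floor(n / (k + 1))`, fold `i` trains on the first `i` blocks and tests
#' on the following block (the final fold's test block extends to row `n`),
#' so every test index exceeds every train index of its fold.
#'
#' @param n number of rows.
#' @param k number of folds (default 5).
#' @return a list of `k` lists with integer vectors `train` and `test`.
#' @export
time_series_cv_splits <- function(n, k = 5) {
  stopifnot(k >= 1)
  block <- floor(n / (k + 1))
  if (block < 1) {
    stop("`n` too small for ", k, "-fold time-series cross-validation",
         call. = FALSE)
  }
  lapply(seq_len(k), function(i) {
    test_end <- if (i == k) n else (i + 1L) * block
    list(train = seq_len(i * block),
         test = seq.int(i * block + 1L, test_end))
  })
}

#' Raw polynomial basis of a predictor
#'
#' @param x numeric vector.
#' @param degree highest power.
#' @return matrix with columns `x, x^2, ..., x^degree`.
#' @export
polynomial_basis <- function(x, degree) {
  stopifnot(degree >= 1)
  out <- vapply(seq_len(degree), function(p) x^p, numeric(length(x)))
  out <- matrix(out, ncol = degree)
  colnames(out) <- paste0("day_pow", seq_len(degree))
  out
}

baseline_cv_fit <- function(rows, targets, degree, k, label) {
  stopifnot("day" %in% names(rows))
  missing_cols <- setdiff(targets, names(rows))
  if (length(missing_cols) > 0) {
    stop("rows lack target column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(rows$day)) < 2) {
    stop("degenerate predictor: `day` is constant", call. = FALSE)
  }
  basis_all <- polynomial_basis(rows$day, degree)
  folds <- time_series_cv_splits(nrow(rows), k)
  fold_rmse <- purrr::imap_dfr(folds, function(f, i) {
    Xtr <- cbind(1, basis_all[f$train, , drop = FALSE])
    if (qr(Xtr)$rank < ncol(Xtr)) {
      stop("rank-deficient polynomial design in fold ", i,
           " (degree ", degree, ")", call. = FALSE)
    }
    Xte <- cbind(1, basis_all[f$test, , drop = FALSE])
    purrr::map_dfr(targets, function(tg) {
      beta <- qr.solve(Xtr, rows[[tg]][f$train])
      pred <- drop(Xte %*% beta)
      tibble::tibble(fold = i, target = tg,
                     rmse = sqrt(mean((pred - rows[[tg]][f$test])^2)))
    })
  })
  per_target <- fold_rmse |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(rmse = mean(.data$rmse), .groups = "drop")
  Xall <- cbind(intercept = 1, basis_all)
  coefs <- vapply(targets, function(tg) qr.solve(Xall, rows[[tg]]),
                  numeric(ncol(Xall)))
  structure(list(model = label, degree = degree, rmse = per_target,
                 fold_rmse = fold_rmse, coefficients = coefs),
            class = "baseline_cv")
}

#' Linear-regression baseline with time-series cross-validation
#'
#' Ordinary least squares of each target on the day-of-month predictor,
#' evaluated by expanding-window cross-validation; per-target RMSE is the
#' mean over folds.
#'
#' @param rows data frame with a `day` column and the target columns.
#' @param targets target column names (default latitude and longitude).
#' @param k number of folds.
#' @return a `"baseline_cv"` object with elements `rmse` (per-target
#'   tibble), `fold_rmse` and full-data `coefficients`.
#' @export
fit_linear_baseline <- function(rows, targets = c("latitude", "longitude"),
                                k = 5) {
  baseline_cv_fit(rows, targets, degree = 1L, k = k, label = "Linear Regression")
}

#' Polynomial-regression baseline (degree 4) with cross-validation
#'
#' As [fit_linear_baseline()] but on the raw polynomial basis
#' `day, day^2, ..., day^degree`.  A rank-deficient design errors rather
#' than being silently regularized.
#'
#' @inheritParams fit_linear_baseline
#' @param degree polynomial degree (default 4).
#' @return a `"baseline_cv"` object.
#' @export
fit_polynomial_baseline <- function(rows, degree = 4L,
                                    targets = c("latitude", "longitude"),
                                    k = 5) {
  baseline_cv_fit(rows, targets, degree = as.integer(degree), k = k,
                  label = "Polynomial Regression")
}

#' @method tidy baseline_cv
#' @export
tidy.baseline_cv <- function(x, ...) x$fold_rmse

#' @method glance baseline_cv
#' @export
glance.baseline_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$rmse, names_from = "target",
                             values_from = "rmse")
  dplyr::bind_cols(tibble::tibble(model = x$model, degree = x$degree), wide)
}

#' Vector-autoregression baseline with out-of-sample evaluation
#'
#' Treats the coordinate columns as a multivariate time series.  The lag
#' order is chosen by AIC on the training portion (OLS per equation), then
#' an iterated multi-step forecast covers the reserved holdout and RMSE is
#' computed per coordinate.  A constant series is forecast exactly with
#' RMSE 0.
#'
#' @param series data frame of numeric columns (e.g. latitude, longitude).
#' @param holdout_fraction fraction of rows reserved at the end for
#'   out-of-sample prediction.
#' @param max_lag largest lag order considered (default 8, one day of
#'   2-hourly fixes).
#' @return an object of class `"var_fit"` with `lag`, `coefficients`
#'   (response x (intercept, lag terms)), `rmse` (per-coordinate tibble)
#'   and `forecast`.
#' @export
fit_var_baseline <- function(series, holdout_fraction = 0.2, max_lag = 8) {
  Ym <- as.matrix(series)
  n <- nrow(Ym); K <- ncol(Ym)
  n_test <- max(1L, floor(n * holdout_fraction))
  n_train <- n - n_test
  if (n_train <= max_lag + 1) {
    stop("series too short for max_lag = ", max_lag, " and the holdout",
         call. = FALSE)
  }
  train <- Ym[seq_len(n_train), , drop = FALSE]
  test <- Ym[seq.int(n_train + 1L, n), , drop = FALSE]
  cn <- colnames(Ym) %||% paste0("y", seq_len(K))

  if (all(apply(train, 2, stats::var) < 1e-24)) {
    const <- train[1, ]
    fc <- matrix(const, n_test, K, byrow = TRUE)
    per <- unname(sqrt(colMeans((fc - test)^2)))
    return(structure(list(lag = 0L, coefficients = NULL,
                          rmse = tibble::tibble(target = cn, rmse = per),
                          forecast = fc),
                     class = "var_fit"))
  }

  lag_design <- function(p) {
    Teff <- n_train - p
    Yresp <- train[(p + 1):n_train, , drop = FALSE]
    X <- matrix(1, Teff, 1 + K * p)
    for (l in seq_len(p)) {
      X[, 1 + (l - 1) * K + seq_len(K)] <-
        train[(p + 1 - l):(n_train - l), , drop = FALSE]
    }
    list(Y = Yresp, X = X, Teff = Teff)
  }
  best <- NULL
  for (p in seq_len(max_lag)) {
    d <- lag_design(p)
    fit <- tryCatch(qr.solve(d$X, d$Y), error = function(e) NULL)
    if (is.null(fit)) next
    res <- d$Y - d$X %*% fit
    Sigma <- crossprod(res) / d$Teff
    det_s <- det(Sigma)
    if (!is.finite(det_s) || det_s <= 0) det_s <- .Machine$double.xmin
    aic <- log(det_s) + 2 * (p * K^2 + K) / d$Teff
    if (is.null(best) || aic < best$aic) {
      best <- list(p = p, beta = fit, aic = aic)
    }
  }
  if (is.null(best)) stop("VAR estimation failed for all lag orders",
                          call. = FALSE)
  p <- best$p; beta <- best$beta

  # iterated multi-step forecast over the holdout
  state <- train[(n_train - p + 1):n_train, , drop = FALSE]
  fc <- matrix(NA_real_, n_test, K)
  for (s in seq_len(n_test)) {
    x <- c(1, as.vector(t(state[nrow(state):max(1, nrow(state) - p + 1), ,
                                drop = FALSE])))
    yhat <- drop(x %*% beta)
    fc[s, ] <- yhat
    state <- rbind(state[-1, , drop = FALSE], yhat)
  }
  per <- unname(sqrt(colMeans((fc - test)^2)))
  coefs <- t(beta)
  rownames(coefs) <- cn
  colnames(coefs) <- c("intercept",
                       paste0(rep(cn, p), "_lag", rep(seq_len(p), each = K)))
  structure(list(lag = p, coefficients = coefs,
                 rmse = tibble::tibble(target = cn, rmse = per),
                 forecast = fc),
            class = "var_fit")
}

#' @method tidy var_fit
#' @export
tidy.var_fit <- function(x, ...) {
  if (is.null(x$coefficients)) return(tibble::tibble())
  df <- as.data.frame(x$coefficients)
  df$response <- rownames(x$coefficients)
  tidyr::pivot_longer(tibble::as_tibble(df), -"response",
                      names_to = "term", values_to = "estimate")
}

#' @method glance var_fit
#' @export
glance.var_fit <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$rmse, names_from = "target",
                             values_from = "rmse")
  dplyr::bind_cols(tibble::tibble(lag = x$lag), wide)
}

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (`0.1435 -> 0.144` at
#' three digits), the convention used when summarizing RMSE tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # snap away binary representation error (e.g. 0.1435 * 1000 = 143.49999...)
  # before applying the half-up rule
  z <- round(abs(x) * scale, 9)
  sign(x) * floor(z + 0.5) / scale
}

#' Assemble a model-comparison RMSE report
#'
#' One row per model with its per-target RMSE values and their unweighted
#' arithmetic mean in the `average` column (the report's defining
#' identity: `average` always equals the mean of the per-target columns).
#'
#' @param results named list: one named numeric vector of per-target RMSE
#'   values per model.
#' @return a tibble of class `"evaluation_report"` with columns `model`,
#'   one per target, and `average`.
#' @export
evaluation_report <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- purrr::imap(results, function(v, nm) {
    dplyr::bind_cols(tibble::tibble(model = nm),
                     tibble::as_tibble(as.list(v)),
                     tibble::tibble(average = mean(v)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Bar-chart comparison of model RMSEs
#'
#' @param report an [evaluation_report()] tibble.
#' @return a ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"model",
                            names_to = "target", values_to = "rmse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$rmse,
                                   fill = .data$target)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "RMSE", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
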