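test_that("clock times convert to seconds since midnight and invert exactly", {
  expect_identical(time_to_seconds("12:34:56"), 45296L)
  expect_identical(time_to_seconds("00:00:00"), 0L)
  expect_identical(time_to_seconds("23:59:59"), 86399L)
  # strictly monotone over a day and invertible by divmod
  times <- sprintf("%02d:%02d:%02d", rep(0:23, each = 4),
                   rep(c(0, 15, 30, 45), 24), 7)
  s <- time_to_seconds(times)
  expect_true(all(diff(s) > 0))
  expect_identical(sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L,
                           s %% 60L), times)
  expect_error(time_to_seconds("24:00:00"), "out of range")
  expect_error(time_to_seconds("12:60:00"), "out of range")
  expect_error(time_to_seconds("noonish"), "malformed")
})

test_that("ISO dates split into integer day, month and year", {
  got <- parse_local_date(c("2015-07-04", "2012-01-01", "2018-12-31"))
  expect_identical(got$day, c(4L, 1L, 31L))
  expect_identical(got$month, c(7L, 1L, 12L))
  expect_identical(got$year, c(2015L, 2012L, 2018L))
  expect_error(parse_local_date("04/07/2015"), "malformed")
})

test_that("matrices encode calendar features and mode-specific labels", {
  rows <- tibble::tibble(local_date = "2015-07-04", local_time = "14:30:00",
                         latitude = 5.2, longitude = 118.7)
  m <- build_matrices(rows)
  expect_identical(as.integer(m$features[1, ]), c(4L, 7L, 2015L, 14L))
  expect_identical(names(m$labels), c("latitude", "longitude"))
  expect_identical(as.numeric(m$labels[1, ]), c(5.2, 118.7))
  mb <- build_matrices(rows, mode = "spatiotemporal")
  expect_identical(names(mb$labels),
                   c("date_days", "time_seconds", "longitude", "latitude"))
  expect_identical(mb$labels$time_seconds, 52200)   # 14 h 30 min
  expect_identical(mb$labels$date_days, 0)
  e <- build_matrices(rows[0, ])
  expect_identical(nrow(e$features), 0L)
  expect_identical(nrow(e$labels), 0L)
})

test_that("duplicate or unordered timestamps are rejected with offenders named", {
  rows <- tibble::tibble(
    local_date = c("2015-07-04", "2015-07-04"),
    local_time = c("14:00:00", "14:00:00"),
    latitude = c(5.2, 5.3), longitude = c(118.7, 118.8))
  expect_error(build_matrices(rows), "2015-07-04 14:00:00")
  rows$local_time <- c("16:00:00", "14:00:00")
  expect_error(build_matrices(rows), "sorted")
})

test_that("chronological split uses floor sizes with the remainder in train", {
  s100 <- chronological_split(100)
  expect_identical(lengths(s100)[c("train", "validation", "test")],
                   c(train = 60L, validation = 20L, test = 20L))
  expect_identical(lengths(chronological_split(10)),
                   c(train = 6L, validation = 2L, test = 2L))
  expect_identical(lengths(chronological_split(7)),
                   c(train = 5L, validation = 1L, test = 1L))
  expect_error(chronological_split(2), "at least 3")
  # blocks are disjoint, exhaustive, ordered
  for (n in c(7, 10, 100, 9168)) {
    s <- chronological_split(n)
    all_idx <- c(s$train, s$validation, s$test)
    expect_identical(sort(all_idx), seq_len(n))
    expect_identical(anyDuplicated(all_idx), 0L)
    expect_lt(max(s$train), min(s$validation))
    expect_lt(max(s$validation), min(s$test))
  }
})

test_that("standardization is fitted on training rows only", {
  tr <- tibble::tibble(a = c(0, 2), b = c(5, 5))
  expect_warning(st <- standardize(tr), "zero-variance.*b")
  scaled <- apply_scaling(st, tr)
  expect_equal(scaled$a, c(-1, 1))
  expect_equal(mean(scaled$a), 0)
  expect_equal(scaled$b, c(0, 0))  # centred, not divided
  # leakage guard: validation rows scaled with train stats differ from
  # self-scaled values
  va <- tibble::tibble(a = c(10, 20), b = c(5, 6))
  with_train_stats <- apply_scaling(st, va)
  self_stats <- suppressWarnings(standardize(va))
  self_scaled <- apply_scaling(self_stats, va)
  expect_false(isTRUE(all.equal(with_train_stats$a, self_scaled$a)))
})
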