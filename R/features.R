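#' Convert a clock time to seconds since midnight
#'
#' `"HH:MM:SS"` (24-hour clock) becomes `3600*H + 60*M + S`, e.g.
#' `"12:34:56"` is 45296 s.  Strictly monotone over a day and exactly
#' invertible by integer division.
#'
#' @param text character vector of clock times.
#' @return integer vector in \[0, 86399\].
#' @export
time_to_seconds <- function(text) {
  ok <- grepl("^\\d{2}:\\d{2}:\\d{2}$", text)
  if (anyNA(text) || any(!ok)) {
    stop("malformed clock time: ",
         paste(utils::head(text[!ok | is.na(text)], 3), collapse = ", "),
         call. = FALSE)
  }
  h <- as.integer(substr(text, 1, 2))
  m <- as.integer(substr(text, 4, 5))
  s <- as.integer(substr(text, 7, 8))
  if (any(h > 23 | m > 59 | s > 59)) {
    bad <- text[h > 23 | m > 59 | s > 59]
    stop("clock-time component out of range: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  3600L * h + 60L * m + s
}

#' Split an ISO 8601 date into day, month and year
#'
#' @param text character vector of `YYYY-MM-DD` dates (or `Date`).
#' @return a tibble with integer columns `day`, `month`, `year`.
#' @export
parse_local_date <- function(text) {
  d <- as.Date(as.character(text), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("malformed ISO date: ",
         paste(utils::head(as.character(text)[is.na(d)], 3), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    day = as.integer(format(d, "%d")),
    month = as.integer(format(d, "%m")),
    year = as.integer(format(d, "%Y"))
  )
}

#' Build feature and label matrices from extracted observation rows
#'
#' Features are the calendar encoding `(day, month, year, hour)` of each
#' observation.  Labels depend on the mode:
#' * `"latlong"` (default): `(latitude, longitude)` — the two-target setup;
#' * `"spatiotemporal"`: `(date_days, time_seconds, longitude, latitude)`,
#'   with the date target encoded as days since the first observation and
#'   the time target as seconds since midnight — the four-target setup.
#'
#' @param rows tibble with `local_date`, `local_time`, `latitude`,
#'   `longitude`, chronologically sorted.
#' @param mode `"latlong"` or `"spatiotemporal"`.
#' @return a list with tibbles `features` and `labels`, aligned row by row.
#' @export
build_matrices <- function(rows, mode = c("latlong", "spatiotemporal")) {
  mode <- match.arg(mode)
  if (nrow(rows) == 0) {
    features <- tibble::tibble(day = integer(), month = integer(),
                               year = integer(), hour = integer())
    labels <- if (mode == "latlong") {
      tibble::tibble(latitude = double(), longitude = double())
    } else {
      tibble::tibble(date_days = double(), time_seconds = double(),
                     longitude = double(), latitude = double())
    }
    return(list(features = features, labels = labels))
  }
  stamp <- paste(rows$local_date, rows$local_time)
  if (is.unsorted(stamp)) {
    stop("rows are not chronologically sorted", call. = FALSE)
  }
  if (anyDuplicated(stamp)) {
    dup <- unique(stamp[duplicated(stamp)])
    stop("duplicate timestamps: ", paste(utils::head(dup, 3), collapse = "; "),
         call. = FALSE)
  }
  secs <- time_to_seconds(rows$local_time)
  dmy <- parse_local_date(rows$local_date)
  features <- dplyr::mutate(dmy, hour = secs %/% 3600L)
  features <- features[, c("day", "month", "year", "hour")]
  labels <- if (mode == "latlong") {
    tibble::tibble(latitude = rows$latitude, longitude = rows$longitude)
  } else {
    d <- as.Date(as.character(rows$local_date))
    tibble::tibble(date_days = as.numeric(d - d[1]),
                   time_seconds = as.numeric(secs),
                   longitude = rows$longitude,
                   latitude = rows$latitude)
  }
  list(features = features, labels = labels)
}

#' Chronological train/validation/test split
#'
#' Contiguous blocks in time order: the first `fractions[1]` of the rows
#' train, the next block validates, the final block tests (by default
#' 60/20/20 of the total).  Block sizes are `floor(n * f)` with the
#' remainder assigned to the training block.
#'
#' @param n number of rows (>= 3).
#' @param fractions length-3 numeric summing to 1.
#' @return a list of class `"split_index"` with integer vectors `train`,
#'   `validation`, `test`.
#' @export
chronological_split <- function(n, fractions = c(0.60, 0.20, 0.20)) {
  if (!is.numeric(n) || length(n) != 1L || n < 3) {
    stop("`n` must be at least 3 to form three non-empty blocks", call. = FALSE)
  }
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0))
  n <- as.integer(n)
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test  # floor(n * f1) + remainder
  structure(list(
    train = seq_len(n_train),
    validation = seq.int(n_train + 1L, length.out = n_val),
    test = seq.int(n_train + n_val + 1L, length.out = n_test)
  ), class = "split_index")
}

#' Column standardization fitted on training rows only
#'
#' Computes per-column mean and standard deviation from the training block;
#' [apply_scaling()] then centres and scales any matrix with those
#' statistics, so no information leaks from validation or test rows.
#' Zero-variance columns are passed through unscaled with a warning.
#' Labels are never scaled anywhere in the package, so RMSE stays in
#' native units.
#'
#' @param train_rows data frame of numeric training features.
#' @return a list of class `"scaling_stats"` with `mean`, `sd` and
#'   `constant` (names of passthrough columns).
#' @export
standardize <- function(train_rows) {
  m <- vapply(train_rows, mean, numeric(1))
  # population SD, so a two-point column (0, 2) maps to exactly (-1, 1)
  s <- vapply(train_rows, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  constant <- names(s)[!is.finite(s) | s == 0]
  if (length(constant) > 0) {
    warning("zero-variance column(s) passed through unscaled: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  structure(list(mean = m, sd = s, constant = constant),
            class = "scaling_stats")
}

#' Apply fitted scaling statistics to a matrix
#'
#' Zero-variance columns are centred at their training mean but not
#' divided (a raw constant such as a calendar year would otherwise feed
#' enormous activations into the network).
#'
#' @param stats a [standardize()] result.
#' @param matrix data frame with the same columns as the training rows.
#' @return a tibble of scaled values.
#' @export
apply_scaling <- function(stats, matrix) {
  stopifnot(inherits(stats, "scaling_stats"))
  out <- tibble::as_tibble(matrix)
  for (col in names(stats$mean)) {
    if (col %in% stats$constant) {
      out[[col]] <- out[[col]] - stats$mean[[col]]
    } else {
      out[[col]] <- (out[[col]] - stats$mean[[col]]) / stats$sd[[col]]
    }
  }
  out
}
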