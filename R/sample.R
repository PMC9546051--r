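#' Classify observations into service / announced / silent categories
#'
#' Each subject contributes a triplet (U, Y, Delta): the observed time U, the
#' abandonment indicator Delta (1 if patience ran out before service), and
#' the announcement indicator Y (1 if the abandonment was announced). The
#' three observable configurations define the categories:
#'
#' * category 1 — served: `delta = 0, y = 0`; U is the waiting time and the
#'   patience time is right-censored at U.
#' * category 2 — announced abandonment: `delta = 1, y = 1`; U is the
#'   patience time, observed exactly.
#' * category 3 — silent abandonment: `delta = 1, y = 0`; U is the (virtual)
#'   waiting time and the patience time is left-censored at U.
#'
#' The configuration `y = 1, delta = 0` is unobservable (an announcement is
#' only seen when the subject abandons, since U = Y*T + (1-Y)*W) and raises
#' an error.
#'
#' @param y,delta Binary vectors of equal length.
#' @return Integer vector of categories in `{1, 2, 3}`.
#' @examples
#' categorize(y = c(0, 1, 0), delta = c(0, 1, 1))  # 1 2 3
#' @export
categorize <- function(y, delta) {
  if (length(y) != length(delta)) stop("`y` and `delta` must have equal length")
  check_binary(y, "y")
  check_binary(delta, "delta")
  bad <- which(y == 1 & delta == 0)
  if (length(bad))
    stop("invalid observation(s) at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": y = 1 with delta = 0 is unobservable")
  ifelse(delta == 0L, 1L, ifelse(y == 1L, 2L, 3L))
}

check_binary <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x != 0 & x != 1))
    stop("`", name, "` must contain only 0/1 values")
  invisible(x)
}

#' Construct a sample of (U, Y, Delta) observation triplets
#'
#' Validates the observation invariants (finite nonnegative times, binary
#' indicators, no `y = 1, delta = 0` rows), derives the category of each
#' observation, and returns a data frame of class `patience_sample`.
#'
#' Zero observed times are legal but flagged with a warning: in practice
#' subjects served immediately (or abandoning without waiting) carry no
#' information on patience, and excluding them is left to the caller.
#'
#' @param u Nonnegative observed times.
#' @param y,delta Binary announcement and abandonment indicators.
#' @param stratum Optional vector of stratum labels (recycled if length 1).
#' @param time_unit `"hours"` (default) or `"minutes"`; metadata only.
#' @return A data frame with columns `u`, `y`, `delta`, `category` and
#'   optionally `stratum`, of class `patience_sample`, with attribute
#'   `time_unit`.
#' @examples
#' patience_sample(u = c(1.5, 0.4), y = c(0, 1), delta = c(0, 1))
#' @export
patience_sample <- function(u, y, delta, stratum = NULL, time_unit = "hours") {
  n <- length(u)
  if (n == 0L) stop("empty sample")
  if (length(y) != n || length(delta) != n)
    stop("`u`, `y` and `delta` must have equal length")
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0))
    stop("`u` must be finite and nonnegative")
  time_unit <- match.arg(time_unit, c("hours", "minutes"))
  category <- categorize(y, delta)
  if (any(u == 0))
    warning("sample contains zero observed times (served or abandoned ",
            "without waiting); consider excluding them")
  out <- data.frame(u = as.numeric(u), y = as.integer(y),
                    delta = as.integer(delta), category = category)
  if (!is.null(stratum)) out$stratum <- rep_len(stratum, n)
  structure(out, class = c("patience_sample", "data.frame"),
            time_unit = time_unit)
}

#' @export
print.patience_sample <- function(x, ...) {
  cc <- category_counts(x)
  cat(sprintf("<patience_sample: n = %d (%s)>\n", nrow(x), attr(x, "time_unit")))
  cat(sprintf("  served %d (%.1f%%) | announced %d (%.1f%%) | silent %d (%.1f%%)\n",
              cc$counts[1], 100 * cc$proportions[1],
              cc$counts[2], 100 * cc$proportions[2],
              cc$counts[3], 100 * cc$proportions[3]))
  if (!is.null(x$stratum))
    cat("  strata:", paste(unique(x$stratum), collapse = ", "), "\n")
  NextMethod()
}

#' Read / write observation samples as CSV
#'
#' The canonical schema is a comma-separated file with header and columns
#' `u,y,delta[,stratum]`; other column names can be supplied through
#' `columns`. Rows violating the observation invariants are rejected with
#' their row numbers reported.
#'
#' @param path Path to a CSV file.
#' @param columns Named character vector mapping the canonical names
#'   (`u`, `y`, `delta`, and optionally `stratum`) to the file's column
#'   names. The `stratum` entry is used only if present in the file.
#' @param time_unit Declared unit of the `u` column.
#' @return For `read_sample`, a [patience_sample()]; for `write_sample`, the
#'   path, invisibly.
#' @export
read_sample <- function(path,
                        columns = c(u = "u", y = "y", delta = "delta",
                                    stratum = "stratum"),
                        time_unit = "hours") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty file: ", path)
  for (nm in c("u", "y", "delta")) {
    col <- if (nm %in% names(columns)) columns[[nm]] else NA_character_
    if (is.na(col) || !col %in% names(raw))
      stop("missing column `", if (is.na(col)) nm else col, "` in ", path)
  }
  u <- raw[[columns[["u"]]]]
  y <- raw[[columns[["y"]]]]
  delta <- raw[[columns[["delta"]]]]
  if (!is.numeric(u) || !is.numeric(y) || !is.numeric(delta))
    stop("columns u/y/delta must be numeric in ", path)
  bad <- which(!is.finite(u) | u < 0 | !(y %in% c(0, 1)) |
                 !(delta %in% c(0, 1)) | (y == 1 & delta == 0))
  if (length(bad))
    stop("invalid observation row(s) in ", path, ": ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  stratum <- NULL
  if ("stratum" %in% names(columns) && columns[["stratum"]] %in% names(raw))
    stratum <- raw[[columns[["stratum"]]]]
  patience_sample(u, y, delta, stratum = stratum, time_unit = time_unit)
}

#' @rdname read_sample
#' @param data A [patience_sample()].
#' @export
write_sample <- function(data, path) {
  stopifnot(inherits(data, "patience_sample"))
  cols <- intersect(c("u", "y", "delta", "stratum"), names(data))
  utils::write.csv(as.data.frame(data)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Category counts and proportions
#'
#' Tallies the three observation categories (served / announced abandonment /
#' silent abandonment). Proportions are exact; rounding is left to display,
#' as in the accounting tables of stratified case studies.
#'
#' @param data A [patience_sample()], or anything with `category` entries in
#'   `{1,2,3}` via `counts`.
#' @return A list with `counts` (length-3 integer), `proportions` (summing
#'   to 1), and `n`.
#' @examples
#' s <- patience_sample(u = 1:4, y = c(0, 0, 1, 0), delta = c(0, 0, 1, 1))
#' category_counts(s)
#' @export
category_counts <- function(data) {
  stopifnot(inherits(data, "patience_sample"))
  n <- nrow(data)
  if (n == 0L) stop("empty sample")
  counts <- vapply(1:3, function(k) sum(data$category == k), integer(1))
  list(counts = counts, proportions = counts / n, n = n)
}

#' Format category counts in accounting-table style
#'
#' Renders counts as `"8478 (98.8%)"` strings with percentages at one
#' decimal, the convention of stratified category-accounting tables.
#'
#' @param counts A result of [category_counts()].
#' @return Named character vector of length 3.
#' @export
format_category_counts <- function(counts) {
  labs <- c("service", "announced", "silent")
  out <- sprintf("%d (%.1f%%)", counts$counts, 100 * counts$proportions)
  names(out) <- labs
  out
}

#' Time-unit conversion helpers
#'
#' The estimators are unit-agnostic, but simulation settings are
#' parameterized in hours while case-study tables are often reported in
#' minutes.
#'
#' @param x Numeric vector of times.
#' @return The converted vector.
#' @export
hours_to_minutes <- function(x) x * 60

#' @rdname hours_to_minutes
#' @export
minutes_to_hours <- function(x) x / 60
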