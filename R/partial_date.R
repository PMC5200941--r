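#' Partially specified calendar dates
#'
#' Registry and bibliographic records frequently carry dates with no
#' day-of-month ("June 2010") and occasionally a full day ("January 1, 2006").
#' `partial_date` is a vector class holding a year, a month, and an optional
#' day. All ordering comparisons (`<`, `>=`, `sort()`, ...) operate at
#' **month precision**: the day, when present, is stored and round-tripped
#' but never consulted, because eligibility windows and publication/completion
#' comparisons in the audit are month-granular.
#'
#' @param year Integer vector of calendar years (1900--2100).
#' @param month Integer vector of months (1--12).
#' @param day Optional integer vector of days (1--31); use `NA` for absent.
#'
#' @return A `partial_date` vector.
#' @examples
#' partial_date(2016, 11) < partial_date(2016, 12)
#' partial_date(2012, 5, 1) == partial_date(2012, 5, 31)  # month precision
#' @importFrom vctrs vec_ptype_abbr vec_proxy_compare vec_proxy_equal
#'   vec_ptype2 vec_cast vec_data
#' @export
partial_date <- function(year, month, day = NA_integer_) {
  args <- vctrs::vec_recycle_common(
    year = vctrs::vec_cast(year, integer()),
    month = vctrs::vec_cast(month, integer()),
    day = vctrs::vec_cast(day, integer())
  )
  year <- args$year; month <- args$month; day <- args$day
  bad_year <- !is.na(year) & (year < 1900L | year > 2100L)
  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  bad_day <- !is.na(day) & (day < 1L | day > 31L)
  if (any(bad_year)) stop("partial_date: year out of range 1900-2100")
  if (any(bad_month)) stop("partial_date: month out of range 1-12")
  if (any(bad_day)) stop("partial_date: day out of range 1-31")
  if (any(is.na(month) & !is.na(day))) {
    stop("partial_date: month must be present whenever day is present")
  }
  code <- ifelse(is.na(year) | is.na(month), NA_integer_,
                 year * 10000L + month * 100L + ifelse(is.na(day), 0L, day))
  new_partial_date(as.integer(code))
}

new_partial_date <- function(code = integer()) {
  vctrs::new_vctr(code, class = "partial_date", inherit_base_type = FALSE)
}

#' @export
format.partial_date <- function(x, ...) {
  code <- vctrs::vec_data(x)
  day <- code %% 100L
  out <- ifelse(is.na(code), NA_character_,
                ifelse(day == 0L,
                       sprintf("%04d-%02d", code %/% 10000L, (code %/% 100L) %% 100L),
                       sprintf("%04d-%02d-%02d", code %/% 10000L, (code %/% 100L) %% 100L, day)))
  out
}

#' @export
vec_ptype_abbr.partial_date <- function(x, ...) "pdate"

# Ordering and equality are month-precision by design: the proxy drops the day.
#' @export
vec_proxy_compare.partial_date <- function(x, ...) {
  vctrs::vec_data(x) %/% 100L
}

#' @export
vec_proxy_equal.partial_date <- function(x, ...) {
  vctrs::vec_data(x) %/% 100L
}

#' @export
vec_ptype2.partial_date.partial_date <- function(x, y, ...) new_partial_date()

#' @export
vec_cast.partial_date.partial_date <- function(x, to, ...) x

#' @export
vec_cast.character.partial_date <- function(x, to, ...) format(x)

#' Accessors for partial-date components
#'
#' @param x A `partial_date` vector.
#' @return Integer vector; `pd_day()` is `NA` where the day was absent.
#' @export
pd_year <- function(x) {
  stopifnot(inherits(x, "partial_date"))
  vctrs::vec_data(x) %/% 10000L
}

#' @rdname pd_year
#' @export
pd_month <- function(x) {
  stopifnot(inherits(x, "partial_date"))
  (vctrs::vec_data(x) %/% 100L) %% 100L
}

#' @rdname pd_year
#' @export
pd_day <- function(x) {
  stopifnot(inherits(x, "partial_date"))
  d <- vctrs::vec_data(x) %% 100L
  ifelse(is.na(d) | d == 0L, NA_integer_, d)
}

#' Exact calendar-month difference
#'
#' `months_between(from, to)` is `(year(to) - year(from)) * 12 +
#' (month(to) - month(from))`: the signed number of whole calendar months
#' separating the two values, ignoring days. A completion date clears the
#' audit's look-back window when `months_between(completion, as_of)` strictly
#' exceeds the window length.
#'
#' @param from,to `partial_date` vectors (recycled).
#' @return Integer vector of month differences.
#' @examples
#' months_between(partial_date(2015, 1), partial_date(2016, 10))  # 21
#' @export
months_between <- function(from, to) {
  stopifnot(inherits(from, "partial_date"), inherits(to, "partial_date"))
  args <- vctrs::vec_recycle_common(from = from, to = to)
  idx <- function(p) {
    code <- vctrs::vec_data(p)
    (code %/% 10000L) * 12L + (code %/% 100L) %% 100L
  }
  idx(args$to) - idx(args$from)
}

# Month names accepted in registry/citation date strings.
.month_lookup <- stats::setNames(rep(1:12, 2L), c(tolower(month.name), tolower(month.abb)))

#' Parse a date string into a partial date
#'
#' Accepts the date dialects found in registry records and citation exports:
#' `"November 2016"`, `"January 1, 2006"`, `"2016-11"`, `"2016-11-01"`,
#' and abbreviated month names (`"Nov 2016"`). The day component is kept only
#' when the text supplies one.
#'
#' @param text Character vector of date strings.
#' @param field,record Context used in the error message when parsing fails
#'   (typically the XML element name and the record identifier).
#' @return A `partial_date` vector the same length as `text`.
#' @examples
#' parse_partial_date("November 2016")
#' parse_partial_date("January 1, 2006")
#' @export
parse_partial_date <- function(text, field = "date", record = NULL) {
  stopifnot(is.character(text))
  parse_one <- function(s) {
    s0 <- trimws(s)
    if (is.na(s0) || !nzchar(s0)) return(NULL)
    # ISO forms YYYY-MM / YYYY-MM-DD
    m <- regmatches(s0, regexec("^([0-9]{4})-([0-9]{1,2})(?:-([0-9]{1,2}))?$", s0))[[1]]
    if (length(m)) {
      day <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
      return(c(as.integer(m[2]), as.integer(m[3]), day))
    }
    # "Month YYYY" or "Month DD, YYYY"
    m <- regmatches(s0, regexec("^([A-Za-z]+)\\s+(?:([0-9]{1,2})\\s*,\\s*)?([0-9]{4})$", s0))[[1]]
    if (length(m)) {
      mon <- .month_lookup[tolower(m[2])]
      if (!is.na(mon)) {
        day <- if (nzchar(m[3])) as.integer(m[3]) else NA_integer_
        return(c(as.integer(m[4]), as.integer(mon), day))
      }
    }
    NULL
  }
  out <- vector("list", length(text))
  for (i in seq_along(text)) {
    if (is.na(text[i])) { out[[i]] <- c(NA_integer_, NA_integer_, NA_integer_); next }
    p <- parse_one(text[i])
    if (is.null(p)) {
      stop_parse_error(
        sprintf("cannot parse %s value %s%s", field, dQuote(text[i], q = FALSE),
                if (is.null(record)) "" else sprintf(" in record %s", record)),
        field = field, record = record, value = text[i]
      )
    }
    out[[i]] <- p
  }
  mat <- do.call(rbind, out)
  if (is.null(mat)) return(partial_date(integer(), integer()))
  tryCatch(
    partial_date(mat[, 1], mat[, 2], mat[, 3]),
    error = function(e) stop_parse_error(
      sprintf("invalid %s value%s: %s", field,
              if (is.null(record)) "" else sprintf(" in record %s", record),
              conditionMessage(e)),
      field = field, record = record, value = text
    )
  )
}

stop_parse_error <- function(message, field = NULL, record = NULL, value = NULL) {
  cnd <- structure(
    class = c("trialaudit_parse_error", "error", "condition"),
    list(message = message, call = sys.call(-1),
         field = field, record = record, value = value)
  )
  stop(cnd)
}
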