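#' Read serial laboratory results from CSV
#'
#' Reads and validates a delimited file of serial results with columns
#' `subject_id`, `timestamp` (ISO-8601) and `value` (optional extra columns
#' such as `analyte` or `sex` are carried through), applies the standard
#' pre-analysis exclusions -- values below the reporting limit and samples
#' collected outside the morning window -- and returns the rows sorted by
#' subject and collection time.  Exclusion counts are attached as attribute
#' `"exclusions"` and reported via [message()].
#'
#' @param path CSV file path.
#' @param reporting_limit exclude values strictly below this limit
#'   (`NULL` = keep all).
#' @param diurnal_window length-2 `c("HH:MM", "HH:MM")` clock window to
#'   retain, or `NULL` to keep all collection times.
#' @param tz timezone used to parse timestamps (default `"UTC"`).
#' @return data frame `subject_id`, `timestamp` (POSIXct), `value`, plus any
#'   extra input columns.
#' @export
read_results <- function(path, reporting_limit = NULL, diurnal_window = NULL,
                         tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ts <- parse_iso8601(raw$timestamp, tz = tz)
  if (anyNA(ts))
    stop("unparseable timestamp at row ", which(is.na(ts))[1], ": '",
         raw$timestamp[which(is.na(ts))[1]], "'", call. = FALSE)
  val <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(val))
    stop("unparseable value at row ", which(is.na(val))[1], ": '",
         raw$value[which(is.na(val))[1]], "'", call. = FALSE)
  raw$timestamp <- ts
  raw$value <- val

  excl <- c(reporting_limit = 0L, diurnal_window = 0L)
  if (!is.null(reporting_limit)) {
    keep <- raw$value >= reporting_limit
    excl["reporting_limit"] <- sum(!keep)
    raw <- raw[keep, , drop = FALSE]
  }
  if (!is.null(diurnal_window)) {
    keep <- in_clock_window(raw$timestamp, diurnal_window)
    excl["diurnal_window"] <- sum(!keep)
    raw <- raw[keep, , drop = FALSE]
  }
  raw <- raw[order(raw$subject_id, as.numeric(raw$timestamp)), , drop = FALSE]
  rownames(raw) <- NULL
  if (any(excl > 0))
    message("excluded ", excl["reporting_limit"], " result(s) below the ",
            "reporting limit and ", excl["diurnal_window"],
            " outside the collection window")
  attr(raw, "exclusions") <- excl
  raw
}

validate_results_schema <- function(data) {
  need <- c("subject_id", "timestamp", "value")
  if (!is.data.frame(data))
    stop("results must be a data frame", call. = FALSE)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0) stop("results table is empty", call. = FALSE)
  if (is.character(data$timestamp)) {
    ts <- parse_iso8601(data$timestamp)
    if (anyNA(ts))
      stop("unparseable timestamp at row ", which(is.na(ts))[1], call. = FALSE)
  }
  if (!is.numeric(data$value))
    stop("`value` must be numeric", call. = FALSE)
  invisible(TRUE)
}

parse_iso8601 <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  retry <- is.na(out)
  if (any(retry))
    out[retry] <- as.POSIXct(x[retry], tz = tz, format = "%Y-%m-%d %H:%M:%S")
  retry <- is.na(out)
  if (any(retry))
    out[retry] <- as.POSIXct(x[retry], tz = tz, format = "%Y-%m-%d")
  out
}

#' Write / read a PEB parameter block
#'
#' Flat `key = value` text serialization of a [peb_parameters] object, with
#' numeric fields written at full precision so a write/read round trip is
#' value-identical.
#'
#' @param params a [peb_parameters] object.
#' @param path output (or input) file path.
#' @return `write_peb_parameters()` returns `path` invisibly;
#'   `read_peb_parameters()` returns a [peb_parameters] object.
#' @export
write_peb_parameters <- function(params, path) {
  stopifnot(inherits(params, "peb_parameters"))
  num <- function(v) format(v, digits = 17, scientific = TRUE)
  lines <- c(
    paste0("mu_pop = ", num(params$mu_pop)),
    paste0("sigma_pop = ", num(params$sigma_pop)),
    paste0("b1 = ", num(params$b1)),
    paste0("scale = ", params$scale),
    paste0("lambda = ", num(params$lambda)),
    paste0("analyte = ", params$analyte),
    paste0("subgroup = ", params$subgroup)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peb_parameters
#' @export
read_peb_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  get <- function(k, numeric = TRUE) {
    i <- match(k, keys)
    if (is.na(i)) stop("parameter block is missing key '", k, "'",
                       call. = FALSE)
    if (numeric) as.numeric(vals[i]) else vals[i]
  }
  peb_parameters(mu_pop = get("mu_pop"), sigma_pop = get("sigma_pop"),
                 b1 = get("b1"), scale = get("scale", numeric = FALSE),
                 lambda = get("lambda"),
                 analyte = get("analyte", numeric = FALSE),
                 subgroup = get("subgroup", numeric = FALSE))
}
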