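#' Longitudinal repeated-measures dataset
#'
#' Validates and wraps long-format repeated measures: one row per
#' (mouse, day) with a binary group label and a numeric response. Days may
#' be negative (pre-surgery baseline). The constructor checks that every
#' value is finite, that each mouse carries a single group label, and that
#' no (mouse, day) pair is duplicated; rows are sorted by mouse and day so
#' that days are strictly increasing within mouse.
#'
#' @param df data.frame with columns `mouse_id`, `group`, `day`, `value`.
#'   `group` may be coded 0/1 or "allograft"/"autograft" (case-insensitive;
#'   allograft = 0, autograft = 1).
#' @param response_name label for the response column (e.g. "THC", "StO2").
#'
#' @return An object of class `longidata`: a list with elements `data`
#'   (the validated, ordered data.frame with `group` as integer 0/1),
#'   `response`, `N` (number of mice), `n_i` (named per-mouse counts) and
#'   `n` (total observations).
#' @export
longitudinal_data <- function(df, response_name = "value") {
  required <- c("mouse_id", "group", "day", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty input: no measurements")

  df$mouse_id <- as.character(df$mouse_id)
  df$group <- normalize_group(df$group)
  df$day <- as.numeric(df$day)
  df$value <- as.numeric(df$value)
  if (!all(is.finite(df$day))) stop("non-finite day values")
  if (!all(is.finite(df$value))) stop("non-finite response values")

  by_mouse <- split(df$group, df$mouse_id)
  bad <- names(by_mouse)[vapply(by_mouse, function(g) length(unique(g)) > 1L,
                                logical(1))]
  if (length(bad) > 0L) {
    stop("inconsistent group labels for mouse: ", paste(bad, collapse = ", "))
  }

  df <- df[order(df$mouse_id, df$day), , drop = FALSE]
  dup <- duplicated(df[, c("mouse_id", "day")])
  if (any(dup)) {
    stop("duplicate (mouse, day) rows: ",
         paste(unique(df$mouse_id[dup]), collapse = ", "))
  }
  rownames(df) <- NULL

  n_i <- vapply(split(seq_len(nrow(df)), df$mouse_id), length, integer(1))
  structure(
    list(data = df, response = response_name,
         N = length(n_i), n_i = n_i, n = nrow(df)),
    class = "longidata"
  )
}

# Map group labels to integer 0/1 (allograft = 0, autograft = 1).
normalize_group <- function(g) {
  if (is.numeric(g)) {
    if (!all(g %in% c(0, 1))) stop("numeric group labels must be 0 or 1")
    return(as.integer(g))
  }
  key <- tolower(trimws(as.character(g)))
  map <- c("0" = 0L, "1" = 1L, "allograft" = 0L, "autograft" = 1L)
  if (!all(key %in% names(map))) {
    stop("unrecognised group labels: ",
         paste(unique(key[!key %in% names(map)]), collapse = ", "))
  }
  unname(map[key])
}

#' @export
print.longidata <- function(x, ...) {
  cat("Longitudinal dataset:", x$response, "\n")
  cat("  ", x$N, " mice (",
      sum(tapply(x$data$group, x$data$mouse_id, `[`, 1) == 0), " allograft, ",
      sum(tapply(x$data$group, x$data$mouse_id, `[`, 1) == 1), " autograft), ",
      x$n, " measurements\n", sep = "")
  cat("  day range: [", min(x$data$day), ", ", max(x$data$day), "]\n", sep = "")
  invisible(x)
}

#' Load a long-format longitudinal CSV
#'
#' Reads a comma-separated file with a header row, maps columns to the
#' canonical names, rejects rows whose day or value does not parse as a
#' number (reporting their line numbers), and validates the result.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping canonical names
#'   (`mouse_id`, `group`, `day`, `value`) to the file's column names.
#' @param response_name label for the response.
#'
#' @return A [longitudinal_data()] object. Rejected rows (if any) are
#'   attached as attribute `"rejected"`, a data.frame with the 1-based file
#'   line number and a reason, and reported via [message()].
#' @export
load_long_csv <- function(path,
                          schema = c(mouse_id = "mouse_id", group = "group",
                                     day = "day", value = "value"),
                          response_name = "value") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty input: no data rows in ", path)

  canonical <- c("mouse_id", "group", "day", "value")
  if (!all(canonical %in% names(schema))) {
    stop("schema must map all of: ", paste(canonical, collapse = ", "))
  }
  missing_cols <- setdiff(unname(schema[canonical]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(mouse_id = raw[[schema[["mouse_id"]]]],
                   group = raw[[schema[["group"]]]],
                   day = suppressWarnings(as.numeric(raw[[schema[["day"]]]])),
                   value = suppressWarnings(as.numeric(raw[[schema[["value"]]]])),
                   stringsAsFactors = FALSE)

  bad_day <- is.na(df$day)
  bad_value <- is.na(df$value)
  bad <- bad_day | bad_value
  rejected <- data.frame(
    line = which(bad) + 1L, # header is line 1
    reason = ifelse(bad_day[bad] & bad_value[bad], "day and value non-numeric",
                    ifelse(bad_day[bad], "day non-numeric",
                           "value non-numeric"))
  )
  if (nrow(rejected) > 0L) {
    message("rejected ", nrow(rejected), " row(s) with non-numeric fields ",
            "at line(s): ", paste(rejected$line, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("empty input: all rows rejected in ", path)

  out <- longitudinal_data(df, response_name = response_name)
  attr(out, "rejected") <- rejected
  out
}

#' Normalize each mouse by its own baseline value
#'
#' Divides every measurement of a mouse by that mouse's value at
#' `baseline_day` (the pre-surgery measurement), producing a relative
#' response (e.g. rTHC from THC). Mice without a baseline measurement are
#' dropped and reported.
#'
#' @param data a `longidata` object.
#' @param baseline_day day of the pre-surgery baseline (default -1).
#'
#' @return A `longidata` object with relative values and the response name
#'   prefixed "r". Dropped mice (if any) are attached as attribute
#'   `"dropped"` (character vector) and reported via [message()].
#' @export
to_relative <- function(data, baseline_day = -1) {
  stopifnot(inherits(data, "longidata"))
  df <- data$data
  keep <- character(0)
  dropped <- character(0)
  pieces <- list()
  for (m in names(data$n_i)) {
    rows <- df[df$mouse_id == m, , drop = FALSE]
    at_base <- rows$day == baseline_day
    if (sum(at_base) == 0L) {
      dropped <- c(dropped, m)
      next
    }
    b <- rows$value[at_base][1]
    if (b == 0) stop("baseline value is zero for mouse: ", m)
    rows$value <- rows$value / b
    pieces[[m]] <- rows
    keep <- c(keep, m)
  }
  if (length(keep) == 0L) stop("empty output: no mouse has a baseline at day ",
                               baseline_day)
  if (length(dropped) > 0L) {
    message("dropped ", length(dropped), " mouse/mice without a day ",
            baseline_day, " baseline: ", paste(dropped, collapse = ", "))
  }
  out <- longitudinal_data(do.call(rbind, pieces),
                           response_name = paste0("r", data$response))
  attr(out, "dropped") <- dropped
  out
}

#' Restrict a dataset to a time window
#'
#' Retains measurements with day in `[min_day, max_day]`, optionally keeping
#' the baseline record outside the window (used to drop the first
#' post-surgery week while preserving the pre-surgery measurement).
#'
#' @param data a `longidata` object.
#' @param min_day,max_day window bounds in days (inclusive).
#' @param keep_baseline keep the `baseline_day` measurement even if outside
#'   the window.
#' @param baseline_day day of the baseline measurement (default -1).
#'
#' @return A `longidata` object with updated counts.
#' @export
filter_time_window <- function(data, min_day, max_day, keep_baseline = FALSE,
                               baseline_day = -1) {
  stopifnot(inherits(data, "longidata"), min_day <= max_day)
  df <- data$data
  sel <- df$day >= min_day & df$day <= max_day
  if (keep_baseline) sel <- sel | df$day == baseline_day
  if (!any(sel)) stop("empty output: window [", min_day, ", ", max_day,
                      "] excludes all data")
  longitudinal_data(df[sel, , drop = FALSE], response_name = data$response)
}

#' Write a longitudinal dataset back to CSV
#'
#' @param data a `longidata` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  stopifnot(inherits(data, "longidata"))
  utils::write.csv(data$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Response vector, group vector (per row), and split indices used throughout.
response_vector <- function(data) data$data$value
group_vector <- function(data) data$data$group
mouse_index <- function(data) {
  factor(data$data$mouse_id, levels = names(data$n_i))
}
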