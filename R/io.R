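TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_timestamps <- function(x, lines) {
  ts <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  simple <- is.na(ts) & !is.na(x)
  ts[simple] <- as.POSIXct(x[simple], format = "%Y-%m-%d", tz = "UTC")
  if (any(is.na(ts)))
    stop("unparseable ISO-8601 timestamp at line(s) ",
         paste(lines[is.na(ts)], collapse = ", "))
  ts
}

file_format <- function(path) {
  if (grepl("\\.jsonl$", path)) "jsonl"
  else if (grepl("\\.csv$", path)) "csv"
  else stop("unsupported file extension (want .csv or .jsonl): ", path)
}

read_table_file <- function(path, format = NULL) {
  if (is.null(format)) format <- file_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    attr(df, "line_offset") <- 1L   # header line
    df
  } else {
    lines <- readLines(path)
    keep <- nzchar(lines)
    rows <- lapply(lines[keep], function(l) jsonlite::fromJSON(l))
    cols <- unique(unlist(lapply(rows, names)))
    df <- as.data.frame(
      lapply(stats::setNames(cols, cols), function(c)
        unlist(lapply(rows, function(r) r[[c]] %||% NA))),
      stringsAsFactors = FALSE)
    if (!length(rows)) df <- data.frame()
    attr(df, "line_offset") <- 0L
    df
  }
}

coerce_cols <- function(df, numeric_cols = character(0),
                        logical_cols = character(0),
                        char_cols = character(0)) {
  blank_na <- function(v) {
    if (is.character(v)) v[!is.na(v) & v == ""] <- NA
    v
  }
  for (c in numeric_cols)
    df[[c]] <- if (c %in% names(df)) as.numeric(blank_na(df[[c]])) else NA_real_
  for (c in logical_cols)
    df[[c]] <- if (c %in% names(df)) as.logical(blank_na(df[[c]])) else NA
  for (c in char_cols) {
    v <- if (c %in% names(df)) as.character(df[[c]]) else NA_character_
    v[!is.na(v) & v == ""] <- NA_character_   # CSV empty field means missing
    df[[c]] <- v
  }
  df
}

#' Read self-monitoring records
#'
#' Reads the CSV or JSONL record format (chosen by extension), parses
#' ISO-8601 timestamps, and validates every row against the record
#' invariants; invalid rows are rejected with their line numbers.
#'
#' @param path Path to a `.csv` or `.jsonl` file.
#' @return A validated record data.frame in canonical column order.
#' @export
read_records <- function(path) {
  df <- read_table_file(path)
  off <- attr(df, "line_offset")
  need <- c("record_id", "patient_id", "timestamp", "kind")
  if (nrow(df) == 0 && !all(need %in% names(df)))
    return(empty_records())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("record file lacks column(s): ", paste(miss, collapse = ", "))
  lines <- seq_len(nrow(df)) + off
  df <- coerce_cols(df,
    numeric_cols = c("sbp", "dbp", "heart_rate", "bg_value", "pef", "score"),
    logical_cols = "ketone",
    char_cols = c("record_id", "patient_id", "kind", "bg_type", "scale",
                  "detail"))
  df$timestamp <- parse_timestamps(as.character(df$timestamp), lines)
  df <- df[, RECORD_COLUMNS, drop = FALSE]
  pr <- record_problems(df)
  if (any(pr != ""))
    stop("invalid record row(s): ",
         paste(sprintf("line %d: %s", lines[pr != ""], pr[pr != ""]),
               collapse = "; "))
  df
}

#' Write self-monitoring records
#'
#' @param records Record data.frame.
#' @param path Destination `.csv` or `.jsonl` path; round-trips through
#'   [read_records()] to equality.
#' @export
write_records <- function(records, path) {
  df <- records[, RECORD_COLUMNS, drop = FALSE]
  df$timestamp <- format(df$timestamp, TS_FORMAT, tz = "UTC")
  write_table_file(df, path)
  invisible(path)
}

write_table_file <- function(df, path) {
  if (file_format(path) == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      row <- as.list(df[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read patient profiles
#'
#' @param path Path to a `.csv` or `.jsonl` profile file.
#' @return A validated profile data.frame.
#' @export
read_profiles <- function(path) {
  df <- read_table_file(path)
  df <- coerce_cols(df,
    numeric_cols = c("age", "sbp_target", "dbp_target", "fbg_target",
                     "pbg_target", "pef_personal_best"),
    logical_cols = c("smoking", "obesity", "organ_damage", "lipid_controlled"),
    char_cols = c("patient_id", "sex", "education", "diseases"))
  df$enrollment_date <- as.Date(df$enrollment_date)
  df <- df[, PROFILE_COLUMNS, drop = FALSE]
  df$lipid_controlled[is.na(df$lipid_controlled)] <- TRUE
  for (c in c("smoking", "obesity", "organ_damage"))
    df[[c]][is.na(df[[c]])] <- FALSE
  validate_profiles(df)
  df
}

#' Write patient profiles
#'
#' @param profiles Profile data.frame.
#' @param path Destination `.csv` or `.jsonl` path.
#' @export
write_profiles <- function(profiles, path) {
  df <- as.data.frame(profiles)[, PROFILE_COLUMNS, drop = FALSE]
  df$enrollment_date <- as.character(df$enrollment_date)
  write_table_file(df, path)
  invisible(path)
}

INTERVENTION_COLUMNS <- c("provider_id", "patient_id", "kind",
                          "requested_at", "completed_at", "notes")

#' Read provider intervention records
#'
#' @param path Path to a `.csv` or `.jsonl` intervention file.
#' @return A validated intervention data.frame (completion never precedes
#'   the request).
#' @export
read_interventions <- function(path) {
  df <- read_table_file(path)
  off <- attr(df, "line_offset")
  df <- coerce_cols(df, char_cols = c("provider_id", "patient_id", "kind",
                                      "notes"))
  df$requested_at <- as.Date(df$requested_at)
  df$completed_at <- as.Date(df$completed_at)
  df <- df[, INTERVENTION_COLUMNS, drop = FALSE]
  bad <- which(df$completed_at < df$requested_at)
  if (length(bad))
    stop("completed_at precedes requested_at at line(s) ",
         paste(bad + off, collapse = ", "))
  df
}

#' Write provider intervention records
#'
#' @param interventions Intervention data.frame.
#' @param path Destination `.csv` or `.jsonl` path.
#' @export
write_interventions <- function(interventions, path) {
  df <- interventions[, INTERVENTION_COLUMNS, drop = FALSE]
  df$requested_at <- as.character(df$requested_at)
  df$completed_at <- as.character(df$completed_at)
  write_table_file(df, path)
  invisible(path)
}

#' Write an engine event log as JSONL
#'
#' One JSON object per event with `type`, `date`, `patient_id` and the
#' event payload.
#'
#' @param events List of events (e.g. `engine_state$events`).
#' @param path Destination `.jsonl` path.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in events)
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  invisible(path)
}
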