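# Delimited-text exports mirroring the per-train / per-click / per-minute
# tables that POD processing software produces. One directory per pod, three
# CSVs; timestamps ISO-8601 UTC with microseconds. Round-trip safe.

#' Write a pod's detections to a directory of CSV exports
#'
#' Writes `trains.csv`, `clicks.csv` and `minutes.csv`. Timestamps are
#' ISO-8601 UTC with microseconds; an empty dataset yields valid header-only
#' files. Output is byte-stable for identical inputs.
#'
#' @param detections a `pod_detections` object (or a list with `trains`,
#'   `clicks`, `minutes` data frames in the same layout).
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [readPodExport()]
#' @export
writePodExport <- function(detections, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- detections$trains
  tr_out <- data.frame(pod_label = tr$pod, train_id = tr$train_id,
                       start_time = format_iso_us(tr$start_time),
                       end_time = format_iso_us(tr$end_time),
                       n_clicks = tr$n_clicks, quality = tr$quality,
                       species = tr$species,
                       truth_behavior = tr$truth_behavior)
  utils::write.csv(tr_out, file.path(path, "trains.csv"), row.names = FALSE,
                   quote = FALSE)
  cl <- detections$clicks
  cl_out <- data.frame(pod_label = cl$pod, train_id = cl$train_id,
                       time = format_iso_us(cl$time),
                       ici_ms = ifelse(is.na(cl$ici_ms), "",
                                       sprintf("%.6f", cl$ici_ms)),
                       truth_label = cl$truth_label)
  utils::write.csv(cl_out, file.path(path, "clicks.csv"), row.names = FALSE,
                   quote = FALSE)
  mn <- detections$minutes
  mn_out <- data.frame(pod_label = mn$pod, minute = format_iso_us(mn$minute),
                       nall = mn$nall, temperature_c = mn$temperature_c)
  utils::write.csv(mn_out, file.path(path, "minutes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a pod export directory
#'
#' Inverse of [writePodExport()]: `readPodExport(writePodExport(x))`
#' reproduces `x`'s tables. Timestamps out of order are an error by default;
#' with `sort = TRUE` they are sorted on read.
#'
#' @param path directory containing `trains.csv`, `clicks.csv`,
#'   `minutes.csv`.
#' @param sort sort rows by time instead of erroring on out-of-order
#'   timestamps.
#' @return a `pod_detections`-shaped list (`trains`, `clicks`, `minutes`).
#' @export
readPodExport <- function(path, sort = FALSE) {
  need <- file.path(path, c("trains.csv", "clicks.csv", "minutes.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing export file(s): ",
                            paste(missing, collapse = ", "))
  tr_raw <- utils::read.csv(need[1], stringsAsFactors = FALSE,
                            colClasses = "character")
  trains <- data.frame(
    pod = tr_raw$pod_label, train_id = tr_raw$train_id,
    start_time = parse_iso_us(tr_raw$start_time),
    end_time = parse_iso_us(tr_raw$end_time),
    n_clicks = as.integer(tr_raw$n_clicks), quality = tr_raw$quality,
    species = tr_raw$species, truth_behavior = tr_raw$truth_behavior,
    stringsAsFactors = FALSE)
  cl_raw <- utils::read.csv(need[2], stringsAsFactors = FALSE,
                            colClasses = "character")
  clicks <- data.frame(
    pod = cl_raw$pod_label, train_id = cl_raw$train_id,
    time = parse_iso_us(cl_raw$time),
    ici_ms = suppressWarnings(as.numeric(ifelse(cl_raw$ici_ms == "", NA,
                                                cl_raw$ici_ms))),
    truth_label = cl_raw$truth_label, stringsAsFactors = FALSE)
  mn_raw <- utils::read.csv(need[3], stringsAsFactors = FALSE,
                            colClasses = "character")
  minutes <- data.frame(
    pod = mn_raw$pod_label, minute = parse_iso_us(mn_raw$minute),
    nall = as.numeric(mn_raw$nall),
    temperature_c = as.numeric(mn_raw$temperature_c),
    stringsAsFactors = FALSE)
  check_sorted <- function(x, file) {
    if (is.unsorted(as.numeric(x))) {
      if (sort) return(order(as.numeric(x)))
      bad <- which(diff(as.numeric(x)) < 0)[1] + 1
      stop("out-of-order timestamps in ", file, " at line ", bad + 1,
           " (use sort = TRUE to sort on read)")
    }
    seq_along(x)
  }
  trains <- trains[check_sorted(trains$start_time, "trains.csv"), ]
  clicks <- clicks[check_sorted(clicks$time, "clicks.csv"), ]
  minutes <- minutes[check_sorted(minutes$minute, "minutes.csv"), ]
  rownames(trains) <- rownames(clicks) <- rownames(minutes) <- NULL
  structure(list(trains = trains, clicks = clicks, minutes = minutes),
            class = "pod_detections")
}

#' Read a sun table CSV
#'
#' Expected columns: `date` (YYYY-MM-DD) and `civil_dawn`, `sunrise`,
#' `sunset`, `civil_dusk` as either full ISO-8601 timestamps or `HH:MM`
#' local-day times.
#'
#' @param path CSV file path.
#' @return sun table data frame (see [dielPeriod()]).
#' @export
readSunTable <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "civil_dawn", "sunrise", "sunset", "civil_dusk")
  if (!all(need %in% names(raw))) {
    stop("sun table needs columns: ", paste(need, collapse = ", "))
  }
  parse_col <- function(x, dates) {
    if (all(grepl("T", x))) return(parse_iso_us(x))
    as.POSIXct(paste(dates, x), tz = "UTC")
  }
  out <- data.frame(date = as.Date(raw$date))
  for (cc in need[-1]) out[[cc]] <- parse_col(raw[[cc]], raw$date)
  bad <- !(out$civil_dawn < out$sunrise & out$sunrise < out$sunset &
             out$sunset < out$civil_dusk)
  if (any(bad)) stop("sun table ordering violated on ", out$date[bad][1])
  out
}

#' Read a tide table CSV
#'
#' Expected columns: `time` (ISO-8601), `type` (`high`/`low`), `height_m`.
#'
#' @param path CSV file path.
#' @return tide table data frame (see [tideCovariates()]).
#' @export
readTideTable <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "type", "height_m")
  if (!all(need %in% names(raw))) {
    stop("tide table needs columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(time = parse_iso_us(raw$time),
                    type = tolower(raw$type),
                    height_m = as.numeric(raw$height_m))
  validateTideTable(out)
}

#' Write the sun/tide tables of a simulated scenario
#' @param sun,tide tables as produced by [synthSunTable()] /
#'   [synthTideTable()].
#' @param path directory.
#' @return `path`, invisibly.
#' @keywords internal
writeEnvironmentTables <- function(sun, tide, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sun_out <- data.frame(date = format(sun$date),
                        civil_dawn = format_iso_us(sun$civil_dawn),
                        sunrise = format_iso_us(sun$sunrise),
                        sunset = format_iso_us(sun$sunset),
                        civil_dusk = format_iso_us(sun$civil_dusk))
  utils::write.csv(sun_out, file.path(path, "sun.csv"), row.names = FALSE,
                   quote = FALSE)
  tide_out <- data.frame(time = format_iso_us(tide$time), type = tide$type,
                         height_m = tide$height_m)
  utils::write.csv(tide_out, file.path(path, "tide.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
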