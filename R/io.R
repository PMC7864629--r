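#' Write / read a voltage trace (CSV + JSON sidecar)
#'
#' Traces are stored as two/three-column CSV (`time_s`, `voltage_mv` and,
#' when present, `stimulus_pa`) with a JSON sidecar (`<path>.json`)
#' carrying sampling rate, holding potential, series resistance and the
#' junction-potential state. Round-tripping preserves values to double
#' precision.
#'
#' @param trace A [voltage_trace()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly (write) or a [voltage_trace()] (read).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  df <- data.frame(time_s = trace_times(trace),
                   voltage_mv = trace$voltage,
                   stimulus_pa = trace$stimulus)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(sampling_rate_hz = trace$sampling_rate,
               holding_potential_mv = trace$holding_potential,
               series_resistance_mohm = trace$series_resistance,
               ljp_corrected = trace$ljp_corrected,
               ljp_mv = trace$ljp_mv)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "voltage_mv")
  if (!all(need %in% names(df))) {
    stop("trace file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  stim <- if ("stimulus_pa" %in% names(df)) df$stimulus_pa else
    rep(0, nrow(df))
  voltage_trace(df$voltage_mv, stim,
                sampling_rate = side$sampling_rate_hz,
                holding_potential = side$holding_potential_mv,
                series_resistance = side$series_resistance_mohm %||% NA_real_,
                ljp_corrected = isTRUE(side$ljp_corrected),
                ljp_mv = side$ljp_mv %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a spike raster CSV
#'
#' Long-format CSV with columns `well`, `electrode`, `time_s`. Reading
#' accepts unsorted rows (sorted with a warning) and rejects malformed rows
#' with their line numbers.
#'
#' @param raster A [spike_raster()].
#' @param path CSV path.
#' @param duration_s Recording duration; stored/restored via the header
#'   comment is avoided, so supply it on read (default 300).
#' @return `path` invisibly (write); a [spike_raster()] (read).
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  rows <- lapply(names(raster), function(e) {
    if (length(raster[[e]]) == 0) return(NULL)
    data.frame(well = attr(raster, "well_id"), electrode = e,
               time_s = raster[[e]], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) {
    df <- data.frame(well = character(0), electrode = character(0),
                     time_s = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, duration_s = 300) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "electrode", "time_s")
  if (!all(need %in% names(df))) {
    stop("raster file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(!is.finite(df$time_s))
  if (length(bad) > 0) {
    stop("malformed time_s at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  wells <- unique(df$well)
  if (length(wells) > 1) {
    return(lapply(split(df, df$well), function(d) {
      spike_raster(d[, c("electrode", "time_s")], duration_s = duration_s,
                   well_id = d$well[1])
    }))
  }
  spike_raster(df[, c("electrode", "time_s")], duration_s = duration_s,
               well_id = if (length(wells)) wells else "well")
}

#' Write / read a long-format Ct table CSV
#'
#' @param ct_table A `ct_table` data.frame.
#' @param path CSV path.
#' @return `path` invisibly (write); a `ct_table` (read).
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad) > 0) {
    stop("malformed ct at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a feature table with an explicit-missing convention
#'
#' @param df Data.frame of per-cell or per-well features (unit-suffixed
#'   column names).
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_feature_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}
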