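#' Write a trace to delimited text
#'
#' Comma-separated columns `time_s`, `displacement_mm` (or `velocity` for
#' velocity traces) and, when present in the metadata, the companion
#' `velocity` channel. Fiducials go to `<path stem>_fiducials.csv` and the
#' resolved configuration to `<path stem>_manifest.json`.
#'
#' @param trace a [cwm_trace()].
#' @param path output CSV path.
#' @param manifest write the JSON manifest sidecar (default TRUE when the
#'   trace carries a config).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, manifest = TRUE) {
  stopifnot(inherits(trace, "cwm_trace"))
  value_col <- if (startsWith(trace$units, "displacement"))
    "displacement_mm" else "velocity"
  df <- data.frame(time_s = trace_time(trace), value = trace$samples)
  names(df)[2] <- value_col
  if (value_col == "displacement_mm" && !is.null(trace$meta$velocity) &&
      length(trace$meta$velocity) == length(trace$samples))
    df$velocity <- trace$meta$velocity
  utils::write.csv(df, path, row.names = FALSE)
  stem <- sub("\\.[^.]*$", "", path)
  if (!is.null(trace$fiducials))
    utils::write.csv(trace$fiducials[, c("cycle", "marker", "time_s")],
                     paste0(stem, "_fiducials.csv"), row.names = FALSE)
  if (manifest && !is.null(trace$meta$config)) {
    man <- list(tool = "cwmsim",
                version = as.character(utils::packageVersion("cwmsim")),
                config = unclass(trace$meta$config),
                amplitude_mm = trace$meta$amplitude_mm,
                bbi_s = trace$meta$bbi,
                hrv_sigma = trace$meta$hrv$sigma)
    jsonlite::write_json(man, paste0(stem, "_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a trace from delimited text
#'
#' Expects the [write_trace()] layout: a `time_s` column plus a
#' `displacement_mm` or `velocity` value column. The time axis must be
#' uniform and strictly increasing; malformed rows are reported with
#' their line numbers. A `<stem>_fiducials.csv` sibling is picked up when
#' present.
#'
#' @param path CSV path.
#' @return a [cwm_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed trace file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!"time_s" %in% names(df))
    stop("trace file ", path, ": missing required column time_s ",
         "(expected header: time_s, displacement_mm [, velocity])",
         call. = FALSE)
  value_col <- intersect(c("displacement_mm", "velocity"), names(df))[1]
  if (is.na(value_col))
    stop("trace file ", path, ": expected a displacement_mm or velocity ",
         "column", call. = FALSE)
  bad <- which(!is.finite(df$time_s) | !is.finite(df[[value_col]]))
  if (length(bad))
    stop("trace file ", path, ": non-numeric value(s) at data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop("trace file ", path, ": time_s not strictly increasing at data ",
         "line ", which(dt <= 0)[1] + 2L, call. = FALSE)
  fs <- 1 / stats::median(dt)
  fid <- NULL
  fp <- paste0(sub("\\.[^.]*$", "", path), "_fiducials.csv")
  if (file.exists(fp)) fid <- utils::read.csv(fp, stringsAsFactors = FALSE)
  units <- if (value_col == "displacement_mm") "displacement_mm" else "velocity"
  meta <- list()
  if (value_col == "displacement_mm" && "velocity" %in% names(df))
    meta$velocity <- df$velocity
  cwm_trace(df[[value_col]], fs, units = units, fiducials = fid, meta = meta)
}
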