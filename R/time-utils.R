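#' Timestamp utilities
#'
#' Timestamps are carried internally as numeric minutes since the Unix epoch
#' (UTC), which keeps arithmetic exact at the minute resolution of ward
#' observation charts. Elapsed times are always expressed in hours as real
#' numbers, the unit in which the fusion blend operates.
#'
#' @param x character vector of ISO-8601 timestamps ("YYYY-MM-DD HH:MM" or
#'   "YYYY-MM-DDTHH:MM\[:SS\]"), or numeric minutes for [minutes_to_iso()].
#' @return `iso_to_minutes()`: numeric minutes since epoch (NA for empty
#'   cells); `minutes_to_iso()`: character ISO-8601 strings.
#' @examples
#' m <- iso_to_minutes("2014-03-01 08:30")
#' minutes_to_iso(m)
#' @export
iso_to_minutes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  nonblank <- !is.na(x) & nzchar(trimws(x))
  if (!any(nonblank)) return(out)
  xx <- gsub("T", " ", trimws(x[nonblank]), fixed = TRUE)
  xx <- sub("Z$", "", xx)
  p <- as.POSIXct(xx, tz = "UTC",
                  tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                 "%Y-%m-%d"))
  bad <- is.na(p)
  if (any(bad)) {
    stop("unparseable timestamp at row ", which(nonblank)[which(bad)[1]],
         ": '", x[nonblank][which(bad)[1]], "'")
  }
  out[nonblank] <- round(as.numeric(p) / 60)
  out
}

#' @rdname iso_to_minutes
#' @export
minutes_to_iso <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- format(as.POSIXct(round(x[ok]) * 60, origin = "1970-01-01",
                               tz = "UTC"),
                    "%Y-%m-%d %H:%M", tz = "UTC")
  out
}

# elapsed hours between two minute-resolution timestamps
hours_between <- function(from_min, to_min) (to_min - from_min) / 60
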