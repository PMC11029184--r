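#' Load an Early Warning Score band table
#'
#' EWS systems assign integer points to banded vital-sign values and sum the
#' points over components. Band tables are plain CSV files with columns
#' `component, lower, upper, code, points`: numeric components use closed
#' `[lower, upper]` intervals on the chart's measurement precision
#' ([vital_precision()]); categorical rows (AVPU, the NEWS supplemental-O2
#' flag) use `code` instead of bounds. Tables for MEWS, SEWS, NEWS and CEWS
#' transcribed from their primary publications are bundled with the package;
#' `table_file` overrides the bundled file.
#'
#' On load the table is validated: numeric bands must be contiguous,
#' non-overlapping and cover the full plausibility range of the vital, and
#' all points must be non-negative integers.
#'
#' @param system_id one of "MEWS", "SEWS", "NEWS", "CEWS" (any case).
#' @param table_file optional path to a band CSV replacing the bundled one.
#' @return object of class `scoring_table`: list with `system_id`, `numeric`
#'   (named list of band data.frames), `avpu` (named points vector) and
#'   `supplemental_o2` (points for TRUE, 0 if the system has no such
#'   component).
#' @examples
#' news <- load_scoring_table("NEWS")
#' names(news$numeric)
#' @export
load_scoring_table <- function(system_id, table_file = NULL) {
  system_id <- toupper(system_id)
  if (is.null(table_file)) {
    table_file <- system.file("extdata", "ews",
                              paste0(tolower(system_id), ".csv"),
                              package = "rsindex")
    if (!nzchar(table_file)) {
      stop("no bundled band table for system '", system_id, "'")
    }
  }
  raw <- read.csv(table_file, stringsAsFactors = FALSE, comment.char = "#",
                  colClasses = c(code = "character"))
  needed <- c("component", "lower", "upper", "code", "points")
  if (!all(needed %in% names(raw))) {
    stop("band file must have columns: ", paste(needed, collapse = ", "))
  }
  if (any(is.na(raw$points)) || any(raw$points < 0) ||
      any(raw$points != round(raw$points))) {
    stop("points must be non-negative integers (component '",
         raw$component[which(is.na(raw$points) | raw$points < 0 |
                               raw$points != round(raw$points))[1]], "')")
  }
  bounds <- vital_bounds()
  prec <- vital_precision()
  numeric_tabs <- list()
  for (comp in intersect(unique(raw$component), names(bounds))) {
    b <- raw[raw$component == comp, c("lower", "upper", "points")]
    b <- b[order(b$lower), , drop = FALSE]
    if (any(is.na(b$lower)) || any(is.na(b$upper))) {
      stop("numeric component '", comp, "' has rows without bounds")
    }
    p <- prec[[comp]]
    rng <- bounds[[comp]]
    if (abs(b$lower[1] - rng[1]) > 1e-9 ||
        abs(b$upper[nrow(b)] - rng[2]) > 1e-9) {
      stop("bands for '", comp, "' do not cover the plausibility range [",
           rng[1], ", ", rng[2], "]")
    }
    if (nrow(b) > 1) {
      gap <- b$lower[-1] - b$upper[-nrow(b)]
      bad <- which(abs(gap - p) > 1e-9)
      if (length(bad)) {
        kind <- if (gap[bad[1]] > p) "gap" else "overlap"
        stop(kind, " between bands for '", comp, "' at boundary ",
             b$upper[bad[1]], " / ", b$lower[bad[1] + 1])
      }
    }
    numeric_tabs[[comp]] <- b
  }
  avpu <- raw[raw$component == "avpu", , drop = FALSE]
  avpu_points <- if (nrow(avpu)) {
    if (!setequal(avpu$code, avpu_levels())) {
      stop("avpu rows must cover codes A, V, P, U exactly")
    }
    setNames(avpu$points[match(avpu_levels(), avpu$code)], avpu_levels())
  } else NULL
  o2 <- raw[raw$component == "supplemental_o2", , drop = FALSE]
  o2_points <- if (nrow(o2)) {
    tv <- o2$points[match("TRUE", toupper(o2$code))]
    if (is.na(tv)) stop("supplemental_o2 rows must include code TRUE")
    tv
  } else 0
  unknown <- setdiff(unique(raw$component),
                     c(names(bounds), "avpu", "supplemental_o2"))
  if (length(unknown)) stop("unknown component '", unknown[1], "' in band file")
  structure(list(system_id = system_id, numeric = numeric_tabs,
                 avpu = avpu_points, supplemental_o2 = o2_points,
                 source_file = table_file),
            class = "scoring_table")
}

#' @export
print.scoring_table <- function(x, ...) {
  cat("scoring_table:", x$system_id, "-", length(x$numeric),
      "numeric components", if (!is.null(x$avpu)) "+ AVPU",
      if (x$supplemental_o2 > 0) "+ supplemental O2", "\n")
  invisible(x)
}

band_points <- function(band_tab, values, precision) {
  # closed bands on the precision grid: snap the value to the grid first
  v <- round(values / precision) * precision
  # shift by half a precision step so findInterval respects closed uppers
  idx <- findInterval(v + 1e-9, band_tab$lower)
  pts <- rep(NA_real_, length(values))
  ok <- !is.na(v) & idx >= 1 & v <= band_tab$upper[pmax(idx, 1)] + 1e-9
  pts[ok] <- band_tab$points[idx[ok]]
  pts
}

#' Score observation sets with an Early Warning Score system
#'
#' Computes the integer EWS total for each ward observation set as the sum of
#' the per-component band points. `score_ews()` scores a single observation
#' and returns the per-component breakdown; `score_ews_cohort()` is the
#' vectorised equivalent over an observations table.
#'
#' @param table a [load_scoring_table()] result.
#' @param obs a single observation: named list or one-row data.frame with the
#'   vital-sign fields of [cohort_tables()] observations.
#' @param missing_policy "zero" (default): a missing component contributes 0
#'   points; "strict": a missing component is an error.
#' @return `score_ews()`: list with `score` (integer) and `breakdown` (named
#'   numeric, summing to `score`); `score_ews_cohort()`: integer vector of
#'   totals, one per observation row.
#' @examples
#' news <- load_scoring_table("NEWS")
#' score_ews(news, list(heart_rate = 115, systolic_bp = 120, resp_rate = 16,
#'                      temperature = 37, spo2 = 98, supplemental_o2 = FALSE,
#'                      avpu = "A"))$score
#' @export
score_ews <- function(table, obs, missing_policy = c("zero", "strict")) {
  missing_policy <- match.arg(missing_policy)
  obs <- as.list(obs)
  prec <- vital_precision()
  breakdown <- numeric(0)
  for (comp in names(table$numeric)) {
    val <- obs[[comp]]
    if (is.null(val) || is.na(val)) {
      if (missing_policy == "strict") {
        stop("missing vital '", comp, "' under strict missing policy")
      }
      breakdown[comp] <- 0
      next
    }
    pts <- band_points(table$numeric[[comp]], val, prec[[comp]])
    if (is.na(pts)) {
      stop(comp, " value ", val, " outside plausibility bounds")
    }
    breakdown[comp] <- pts
  }
  if (!is.null(table$avpu)) {
    av <- obs$avpu
    if (is.null(av) || is.na(av)) {
      if (missing_policy == "strict") stop("missing AVPU under strict missing policy")
      breakdown["avpu"] <- 0
    } else {
      if (!av %in% avpu_levels()) stop("unknown AVPU code '", av, "'")
      breakdown["avpu"] <- table$avpu[[av]]
    }
  }
  if (table$supplemental_o2 > 0) {
    so <- obs$supplemental_o2
    if (is.null(so) || is.na(so)) {
      if (missing_policy == "strict") {
        stop("missing supplemental_o2 under strict missing policy")
      }
      breakdown["supplemental_o2"] <- 0
    } else {
      breakdown["supplemental_o2"] <- if (isTRUE(so)) table$supplemental_o2 else 0
    }
  }
  list(score = as.integer(sum(breakdown)), breakdown = breakdown)
}

#' @rdname score_ews
#' @param observations observations table (see [cohort_tables()]).
#' @export
score_ews_cohort <- function(table, observations,
                             missing_policy = c("zero", "strict")) {
  missing_policy <- match.arg(missing_policy)
  n <- nrow(observations)
  total <- numeric(n)
  prec <- vital_precision()
  for (comp in names(table$numeric)) {
    val <- observations[[comp]]
    pts <- band_points(table$numeric[[comp]], val, prec[[comp]])
    miss <- is.na(val)
    if (any(miss) && missing_policy == "strict") {
      stop("missing vital '", comp, "' under strict missing policy")
    }
    out_of_range <- !miss & is.na(pts)
    if (any(out_of_range)) {
      stop(comp, " value ", val[which(out_of_range)[1]],
           " outside plausibility bounds")
    }
    pts[miss] <- 0
    total <- total + pts
  }
  if (!is.null(table$avpu)) {
    av <- observations$avpu
    miss <- is.na(av)
    if (any(miss) && missing_policy == "strict") {
      stop("missing AVPU under strict missing policy")
    }
    pts <- ifelse(miss, 0, table$avpu[av])
    if (anyNA(pts)) stop("unknown AVPU code '", av[which(is.na(pts))[1]], "'")
    total <- total + pts
  }
  if (table$supplemental_o2 > 0) {
    so <- observations$supplemental_o2
    miss <- is.na(so)
    if (any(miss) && missing_policy == "strict") {
      stop("missing supplemental_o2 under strict missing policy")
    }
    total <- total + ifelse(!miss & so, table$supplemental_o2, 0)
  }
  as.integer(total)
}
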