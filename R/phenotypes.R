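#' Absolute critical swimming speed from a fatigue observation
#'
#' Computes the Brett-type critical swimming speed
#' \deqn{U_{crit} = U_{-1} + (t / \Delta t)\,\Delta U}
#' where \eqn{U_{-1}} is the flow speed of the last fully maintained level,
#' \eqn{\Delta U} the increment to the level in which the fish fatigued,
#' \eqn{t} the minutes swum in that level and \eqn{\Delta t} the fixed level
#' duration. A fish that fatigues exactly at a level boundary is recorded
#' with \code{time_in_level} equal to the full duration of the completed
#' level, which makes the statistic continuous across level boundaries.
#'
#' @param fatigue_level integer vector: last level the fish entered; both
#'   this level and the one below must exist in the schedule.
#' @param time_in_level numeric vector: minutes swum in the fatigue level,
#'   in \code{[0, level_duration]}.
#' @param schedule a \code{\link{speed_schedule}}.
#' @return Numeric vector of absolute Ucrit in cm/s, bounded between the
#'   speeds of the two levels involved.
#' @examples
#' sch <- default_speed_schedule()
#' ucrit_absolute(8, 15, sch)  # 65 + (15/30) * 8 = 69
#' @export
ucrit_absolute <- function(fatigue_level, time_in_level, schedule) {
  stopifnot(inherits(schedule, "speed_schedule"))
  fatigue_level <- as.integer(fatigue_level)
  time_in_level <- as.numeric(time_in_level)
  if (length(fatigue_level) != length(time_in_level))
    stop("fatigue_level and time_in_level must have equal length",
         call. = FALSE)
  ok <- !is.na(fatigue_level) & !is.na(time_in_level)
  dt <- schedule$level_duration
  if (any(ok & (time_in_level < 0 | time_in_level > dt)))
    stop("time_in_level must lie in [0, ", dt, "] minutes", call. = FALSE)
  u_final <- schedule_speed_at(schedule, fatigue_level)
  u_prev <- schedule_speed_at(schedule, fatigue_level - 1L)
  if (any(ok & (is.na(u_final) | is.na(u_prev))))
    stop("fatigue_level (and the level below it) must exist in the schedule",
         call. = FALSE)
  out <- u_prev + (time_in_level / dt) * (u_final - u_prev)
  out[!ok] <- NA_real_
  out
}

#' Relative critical swimming speed
#'
#' Absolute Ucrit scaled by the fish's standard length at testing, giving a
#' size-standardised speed in body (standard) lengths per second.
#'
#' @param ucrit_abs absolute Ucrit in cm/s.
#' @param sl_test standard length at swim testing in cm; must be positive.
#' @return Relative Ucrit in SL/s.
#' @export
ucrit_relative <- function(ucrit_abs, sl_test) {
  ucrit_abs <- as.numeric(ucrit_abs)
  sl_test <- as.numeric(sl_test)
  if (any(!is.na(sl_test) & sl_test <= 0))
    stop("sl_test must be positive", call. = FALSE)
  ucrit_abs / sl_test
}

#' Lateral surface area of a fish approximated as an ellipse
#'
#' \deqn{SA = \frac{\pi}{4}\, SL \times H}
#' with standard length \eqn{SL} and maximum body height \eqn{H} as the
#' ellipse axes.
#'
#' @param sl_test standard length at testing (cm), positive.
#' @param h_test maximum dorso-ventral height at testing (cm), positive.
#' @return Surface area in cm^2.
#' @export
surface_area <- function(sl_test, h_test) {
  sl_test <- as.numeric(sl_test)
  h_test <- as.numeric(h_test)
  if (any(!is.na(sl_test) & sl_test <= 0) ||
      any(!is.na(h_test) & h_test <= 0))
    stop("sl_test and h_test must be positive", call. = FALSE)
  (pi / 4) * sl_test * h_test
}

#' Daily growth coefficient
#'
#' \deqn{DGC = 100\,\frac{HW^{1/3} - W_{start}^{1/3}}{\mathrm{days}}}
#' The cube-root scale makes the coefficient approximately independent of
#' body size over the grow-out trajectory. Negative values (shrinkage) are
#' allowed; non-positive weights or durations are rejected.
#'
#' @param hw harvest weight in g, positive.
#' @param w_start stocking weight in g, positive.
#' @param days grow-out duration in days, positive (145 or 146 in the
#'   design this package emulates; always carried per fish).
#' @return DGC (unitless growth coefficient).
#' @export
daily_growth_coefficient <- function(hw, w_start, days) {
  hw <- as.numeric(hw); w_start <- as.numeric(w_start)
  days <- as.numeric(days)
  if (any(!is.na(hw) & hw <= 0) || any(!is.na(w_start) & w_start <= 0))
    stop("weights must be positive", call. = FALSE)
  if (any(!is.na(days) & days <= 0))
    stop("days must be positive", call. = FALSE)
  100 * (hw^(1 / 3) - w_start^(1 / 3)) / days
}

#' Derive analysis traits from raw swim-test and grow-out records
#'
#' Adds \code{ucrit_abs}, \code{ucrit_rel}, \code{sa_test} and \code{dgc}
#' columns to a phenotype table, from whichever raw fields are present:
#' Ucrit needs \code{fatigue_level}/\code{time_in_level} plus a schedule,
#' surface area needs \code{sltest}/\code{htest}, and DGC needs
#' \code{hw}/\code{wstart}/\code{days}.
#'
#' @param table data.frame of raw per-fish records.
#' @param schedule a \code{\link{speed_schedule}}; required when fatigue
#'   columns are present.
#' @return The table with derived trait columns appended.
#' @export
derive_phenotypes <- function(table, schedule = NULL) {
  stopifnot(is.data.frame(table))
  if (all(c("fatigue_level", "time_in_level") %in% names(table))) {
    if (is.null(schedule))
      stop("a speed schedule is required to derive Ucrit", call. = FALSE)
    table$ucrit_abs <- ucrit_absolute(table$fatigue_level,
                                      table$time_in_level, schedule)
    if ("sltest" %in% names(table))
      table$ucrit_rel <- ucrit_relative(table$ucrit_abs, table$sltest)
  }
  if (all(c("sltest", "htest") %in% names(table)))
    table$sa_test <- surface_area(table$sltest, table$htest)
  if (all(c("hw", "wstart", "days") %in% names(table)))
    table$dgc <- daily_growth_coefficient(table$hw, table$wstart, table$days)
  table
}

#' Descriptive statistics for phenotype traits
#'
#' Per-trait count, mean, sample SD (n - 1 denominator), coefficient of
#' variation (100 SD / mean), minimum and maximum, with missing values
#' excluded and \code{n} reflecting the non-missing count.
#'
#' @param table data.frame of phenotypes.
#' @param traits character vector of column names to summarise; defaults to
#'   all numeric columns.
#' @return data.frame with one row per trait and columns
#'   \code{trait, n, mean, sd, cv, min, max}.
#' @export
trait_summary <- function(table, traits = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(traits))
    traits <- names(table)[vapply(table, is.numeric, logical(1))]
  missing_cols <- setdiff(traits, names(table))
  if (length(missing_cols))
    stop("trait(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- lapply(traits, function(tr) {
    x <- table[[tr]]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      stop("trait '", tr, "' has no non-missing values", call. = FALSE)
    m <- mean(x)
    s <- if (length(x) >= 2L) stats::sd(x) else NA_real_
    data.frame(trait = tr, n = length(x), mean = m, sd = s,
               cv = if (!is.na(s) && m != 0) 100 * s / m else
                 if (!is.na(s) && s == 0) 0 else NA_real_,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a phenotype table from CSV/TSV
#'
#' One row per fish. Column names can be remapped onto the package's
#' canonical names (\code{fish_id}, \code{test_day}, \code{fatigue_level},
#' \code{time_in_level}, \code{wtest}, \code{sltest}, \code{htest},
#' \code{agetest}, \code{sex}, \code{wstart}, \code{hw}, \code{days},
#' \code{age_harvest}) through a named mapping, given directly or as a YAML
#' file with a \code{columns:} block. Empty strings and "NA" are read as
#' missing.
#'
#' @param path CSV or TSV file (delimiter inferred from extension).
#' @param mapping named character vector or YAML path; names are canonical
#'   column names, values are the names used in the file.
#' @return data.frame of phenotype records.
#' @export
read_phenotypes <- function(path, mapping = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
      mapping <- unlist(yaml::read_yaml(mapping)$columns)
    mapping <- unlist(mapping)
    bad <- setdiff(unname(mapping), names(tab))
    if (length(bad))
      stop("mapped column(s) absent from file: ",
           paste(bad, collapse = ", "), call. = FALSE)
    names(tab)[match(mapping, names(tab))] <- names(mapping)
  }
  tab
}
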