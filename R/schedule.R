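#' Culture schedule for a steady or periodically alternating condition
#'
#' Describes the sequence of media a pooled culture experiences on the 3-h
#' transfer grid. Steady conditions (`period_h = 0`) stay in a single medium;
#' periodic conditions alternate between the two media `"N"` and `"S"` with the
#' given period (half a period in each medium). Cultures are initialized in
#' `init_condition` before time 0, and periodic schedules enter
#' `first_condition` at time 0.
#'
#' @param condition Condition label, e.g. `"N"`, `"S"`, `"NS6"`.
#' @param period_h Oscillation period in hours; `0` for a steady condition.
#'   Must be a multiple of `2 * transfer_interval_h`.
#' @param transfer_interval_h Hours between serial transfers (default 3).
#' @param first_condition Medium entered at time 0 by a periodic schedule
#'   (default `"S"`).
#' @param steady_medium Medium of a steady schedule; defaults to the condition
#'   label itself.
#' @param init_condition Medium used during pre-experiment initialization
#'   (default `"N"`).
#' @param total_h Total experiment duration in hours after initialization
#'   (default 72, i.e. days 0 to 3).
#' @return An object of class `"pf_schedule"`.
#' @examples
#' schedule("NS6", period_h = 6)
#' schedule("N", period_h = 0)
#' @export
schedule <- function(condition, period_h, transfer_interval_h = 3,
                     first_condition = "S", steady_medium = condition,
                     init_condition = "N", total_h = 72) {
  stopifnot(is.character(condition), length(condition) == 1L)
  if (!is.numeric(period_h) || length(period_h) != 1L || period_h < 0)
    stop("`period_h` must be a single non-negative number", call. = FALSE)
  if (transfer_interval_h <= 0)
    stop("`transfer_interval_h` must be positive", call. = FALSE)
  if (period_h > 0 && period_h %% (2 * transfer_interval_h) != 0)
    stop("`period_h` must be a multiple of 2 * transfer_interval_h (or 0)",
         call. = FALSE)
  structure(
    list(condition = condition, period_h = period_h,
         transfer_interval_h = transfer_interval_h,
         first_condition = first_condition,
         steady_medium = steady_medium,
         init_condition = init_condition,
         total_h = total_h),
    class = "pf_schedule"
  )
}

#' @export
print.pf_schedule <- function(x, ...) {
  kind <- if (x$period_h == 0) {
    sprintf("steady %s", x$steady_medium)
  } else {
    sprintf("period %g h, starting in %s", x$period_h, x$first_condition)
  }
  cat(sprintf("<pf_schedule> %s: %s; %g-h transfers over %g h\n",
              x$condition, kind, x$transfer_interval_h, x$total_h))
  invisible(x)
}

#' Per-slot medium sequence of a schedule
#'
#' Enumerates the medium occupied during each transfer slot, starting at time
#' 0. The sequence may extend beyond `total_h` (the periodic pattern is
#' continued), which is needed to evaluate the medium switch occurring exactly
#' at a sampling time.
#'
#' @param sched A [schedule()].
#' @param n_slots Number of slots to enumerate; defaults to the slots covering
#'   `total_h`.
#' @return Character vector of media (`"N"`/`"S"`), one entry per slot.
#' @export
slot_sequence <- function(sched, n_slots = NULL) {
  stopifnot(inherits(sched, "pf_schedule"))
  if (is.null(n_slots)) n_slots <- ceiling(sched$total_h / sched$transfer_interval_h)
  if (sched$period_h == 0) return(rep(sched$steady_medium, n_slots))
  half_slots <- sched$period_h / (2 * sched$transfer_interval_h)
  media <- c("N", "S")
  other <- setdiff(media, sched$first_condition)
  # position within the period determines the medium
  slot <- seq_len(n_slots) - 1L
  phase <- (slot %/% half_slots) %% 2L
  ifelse(phase == 0L, sched$first_condition, other)
}

#' Exposure-time and change-count covariates for one day
#'
#' For a condition and day `d`, sums the time spent in each medium over the
#' interval (0, 24d] and counts the medium changes in that interval. A change
#' is counted at every slot boundary t in (0, 24d] where the medium after t
#' differs from the medium before t, including the boundary at the sampling
#' time 24d itself (the schedule is continued one slot past the interval to
#' evaluate it). The switch into the experiment at t = 0 is not counted.
#'
#' @param sched A [schedule()].
#' @param day Day index (>= 1); `day = 0` returns the all-zero row.
#' @return A one-row tibble: `condition`, `period_h`, `day`, `t_N`, `t_S`
#'   (hours), `n_changes`, `f_N`, `f_S` (time fractions).
#' @examples
#' design_row(schedule("NS6", 6), 1)   # 8 changes in day 1
#' design_row(schedule("N", 0), 3)     # steady: t_S = 0, no changes
#' @export
design_row <- function(sched, day) {
  stopifnot(inherits(sched, "pf_schedule"), length(day) == 1L, day >= 0)
  if (day == 0) {
    return(tibble::tibble(condition = sched$condition, period_h = sched$period_h,
                          day = 0, t_N = 0, t_S = 0, n_changes = 0L,
                          f_N = NA_real_, f_S = NA_real_))
  }
  slots_per_day <- 24 / sched$transfer_interval_h
  if (day * 24 > sched$total_h)
    stop(sprintf("day %g exceeds the %g-h experiment", day, sched$total_h),
         call. = FALSE)
  n <- day * slots_per_day
  media <- slot_sequence(sched, n_slots = n + 1L)
  occupied <- media[seq_len(n)]
  t_N <- sum(occupied == "N") * sched$transfer_interval_h
  t_S <- sum(occupied == "S") * sched$transfer_interval_h
  n_changes <- sum(media[-1L] != media[-length(media)])
  tibble::tibble(condition = sched$condition, period_h = sched$period_h,
                 day = day, t_N = t_N, t_S = t_S,
                 n_changes = as.integer(n_changes),
                 f_N = t_N / (24 * day), f_S = t_S / (24 * day))
}

#' Design covariates for every condition and day of an experiment
#'
#' @param schedules A list of [schedule()] objects (one per condition), or a
#'   data frame with columns `condition` and `period_h` from which schedules
#'   are built with default settings.
#' @param days Days to tabulate (default `0:3`).
#' @param ... Passed to [schedule()] when `schedules` is a data frame.
#' @return A tibble with one row per condition x day, columns as in
#'   [design_row()].
#' @export
design_table <- function(schedules, days = 0:3, ...) {
  if (is.data.frame(schedules)) {
    schedules <- purrr::pmap(
      list(schedules$condition, schedules$period_h),
      function(cond, p) schedule(cond, p, ...)
    )
  }
  purrr::map_dfr(schedules, function(s) {
    purrr::map_dfr(days, function(d) design_row(s, d))
  })
}
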