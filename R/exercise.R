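#' Graded exercise test stage schedule
#'
#' Incremental cycling protocol: men begin at 100 W, women at 50 W, and power
#' increases by 30 W every 2-minute stage.
#'
#' @param sex `"M"` or `"F"`.
#' @param n_stages Number of stages (>= 1).
#' @param increment_w Power increment per stage (default 30 W).
#' @param stage_duration_s Planned stage duration (default 120 s).
#' @return A tibble with columns `stage`, `power_w`, `planned_duration_s`.
#' @examples
#' build_gxt_schedule("F", 3)$power_w # 50 80 110
#' @export
build_gxt_schedule <- function(sex, n_stages, increment_w = 30,
                               stage_duration_s = 120) {
  sex <- toupper(as.character(sex))
  if (!sex %in% c("M", "F")) stop("unknown sex code: ", sex, call. = FALSE)
  if (n_stages < 1) stop("n_stages must be >= 1", call. = FALSE)
  start <- if (sex == "M") 100 else 50
  tibble::tibble(
    stage = seq_len(n_stages),
    power_w = start + increment_w * (seq_len(n_stages) - 1),
    planned_duration_s = stage_duration_s
  )
}

#' Peak power output from a stage log
#'
#' W_max is defined as the power output during the final, fully completed
#' stage of the graded exercise test.
#'
#' @param stages Data frame with columns `power_w` and `completed` (logical),
#'   in stage order.
#' @return W_max in watts.
#' @examples
#' st <- build_gxt_schedule("F", 3)
#' st$completed <- c(TRUE, TRUE, FALSE)
#' wmax_from_stages(st) # 80
#' @export
wmax_from_stages <- function(stages) {
  done <- which(stages$completed)
  if (!length(done))
    stop("no fully completed stage: the test is not scorable", call. = FALSE)
  stages$power_w[max(done)]
}

#' Did the test attain VO2peak?
#'
#' At least one of the following criteria must hold: a plateau in VO2 or HR
#' with further increase in workload (increase across the final two stages
#' below a configurable epsilon), RER strictly greater than 1.1, inability to
#' maintain the target cadence, or volitional exhaustion. Criteria whose
#' channels are absent are skipped with a warning.
#'
#' @param stages Data frame of stage measurements in order, optionally with
#'   columns `vo2` (ml/kg/min) and `hr` (bpm) as end-stage values.
#' @param rer_max Maximum respiratory exchange ratio, or `NULL`.
#' @param cadence_ok `FALSE` if the participant could not maintain the 70-90
#'   RPM band; `NA` to skip.
#' @param volitional_exhaustion Logical; `NA` to skip.
#' @param eps_vo2 Plateau threshold for VO2 (default 1.5 ml/kg/min).
#' @param eps_hr Plateau threshold for HR (default 4 bpm).
#' @return A list with `attained` (logical) and `flags`, a named logical
#'   vector over `vo2_or_hr_plateau`, `rer_gt_1.1`, `cadence_failure`,
#'   `volitional_exhaustion` (`NA` where skipped).
#' @export
vo2peak_attained <- function(stages = NULL, rer_max = NULL, cadence_ok = NA,
                             volitional_exhaustion = NA,
                             eps_vo2 = 1.5, eps_hr = 4) {
  plateau <- NA
  if (!is.null(stages) && nrow(stages) >= 2) {
    last2 <- utils::tail(stages, 2)
    checks <- logical(0)
    if (!is.null(last2$vo2) && !anyNA(last2$vo2))
      checks <- c(checks, diff(last2$vo2) < eps_vo2)
    if (!is.null(last2$hr) && !anyNA(last2$hr))
      checks <- c(checks, diff(last2$hr) < eps_hr)
    if (length(checks)) plateau <- any(checks)
  }
  if (is.na(plateau)) warning("no VO2/HR stage channels: plateau criterion skipped")
  rer_flag <- if (is.null(rer_max)) {
    warning("no RER channel: RER criterion skipped")
    NA
  } else rer_max > 1.1
  flags <- c(
    vo2_or_hr_plateau = plateau,
    `rer_gt_1.1` = rer_flag,
    cadence_failure = if (is.na(cadence_ok)) NA else !cadence_ok,
    volitional_exhaustion = volitional_exhaustion
  )
  list(attained = isTRUE(any(flags, na.rm = TRUE)), flags = flags)
}

#' Personalized interval exercise protocol
#'
#' The 19-minute interval test: a 2-min warm-up at 5 percent W_max, three
#' repetitions of a 2-min low-intensity interval followed by a 3-min
#' high-intensity interval, and a 2-min cool-down at 5 percent W_max. The
#' HIIT group cycles at 60 / 90 percent W_max (low / high); the LIIT control
#' at 8 / 12 percent, preserving the same 2:3 low:high intensity ratio.
#'
#' @param wmax Peak power output in watts (> 0).
#' @param group `"HIIT"` or `"LIIT"`.
#' @return An object of class `"interval_protocol"`: a tibble of segments
#'   with columns `phase` (warmup/low/high/cooldown), `start_s`, `end_s`,
#'   `duration_s`, `intensity_fraction`, `power_w`; attributes `group`,
#'   `wmax`, `total_duration_s` (always 1140 s).
#' @examples
#' build_interval_protocol(200, "HIIT")
#' @export
build_interval_protocol <- function(wmax, group = c("HIIT", "LIIT")) {
  group <- match.arg(group)
  if (!is.numeric(wmax) || wmax <= 0) stop("wmax must be positive", call. = FALSE)
  frac <- if (group == "HIIT") c(low = 0.60, high = 0.90) else c(low = 0.08, high = 0.12)
  phase <- c("warmup", rep(c("low", "high"), 3), "cooldown")
  duration <- c(120, rep(c(120, 180), 3), 120)
  fraction <- c(0.05, rep(unname(frac), 3), 0.05)
  seg <- tibble::tibble(
    phase = phase,
    start_s = cumsum(c(0, duration[-length(duration)])),
    end_s = cumsum(duration),
    duration_s = duration,
    intensity_fraction = fraction,
    power_w = fraction * wmax
  )
  structure(seg, group = group, wmax = wmax,
            total_duration_s = sum(duration),
            class = c("interval_protocol", class(seg)))
}

#' High-intensity dose completed
#'
#' Sums the time actually spent inside high-intensity segments from a
#' per-segment log, for participants who abandoned the protocol early. The
#' log is not assumed to be bounded by the printed 3 x 3-min schedule (some
#' recorded doses exceed 9 min, implying extra or repeated intervals), but
#' within each logged segment the elapsed time may not exceed its planned
#' duration.
#'
#' @param segment_log Data frame with columns `phase`, `planned_s`,
#'   `elapsed_s`.
#' @return A list with `seconds` (total high-intensity seconds), `minutes`
#'   and `label` (`"4 m 0 s"` style).
#' @examples
#' proto <- build_interval_protocol(150, "HIIT")
#' log <- data.frame(phase = proto$phase, planned_s = proto$duration_s,
#'                   elapsed_s = proto$duration_s)
#' hiit_dose_completed(log)$label # "9 m 0 s"
#' @export
hiit_dose_completed <- function(segment_log) {
  if (any(segment_log$elapsed_s > segment_log$planned_s + 1e-9))
    stop("elapsed time exceeds planned segment duration", call. = FALSE)
  secs <- sum(segment_log$elapsed_s[segment_log$phase == "high"])
  list(seconds = secs, minutes = secs / 60,
       label = sprintf("%d m %g s", secs %/% 60, secs %% 60))
}

#' Parse a dose label such as "10 m 30 s" into seconds
#'
#' @param label Character vector of `"<m> m"` or `"<m> m <s> s"` labels.
#' @return Numeric seconds.
#' @export
parse_dose_label <- function(label) {
  vapply(label, function(x) {
    m <- regmatches(x, regexec("^\\s*([0-9]+)\\s*m(?:\\s*([0-9.]+)\\s*s)?\\s*$", x))[[1]]
    if (length(m) == 0L) stop("unparseable dose label: '", x, "'", call. = FALSE)
    60 * as.numeric(m[2]) + if (m[3] == "") 0 else as.numeric(m[3])
  }, numeric(1), USE.NAMES = FALSE)
}
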