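#' Rhythm tolerance settings
#'
#' The study's inter-onset-interval (IOI) criterion counts an interval as
#' correct when it is within 10 percent faster or slower than expected
#' (boundary inclusive). Earlier literature used a more lenient 30 percent
#' criterion, kept here as `legacy_fraction` for comparison.
#'
#' @param fraction Relative tolerance (default 0.10).
#' @param legacy_fraction The prior-literature criterion (default 0.30).
#' @return A list of class `"rhythm_tolerance"`.
#' @export
rhythm_tolerance <- function(fraction = 0.10, legacy_fraction = 0.30) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("tolerance fraction must be in [0, 1)", call. = FALSE)
  structure(list(fraction = fraction, legacy_fraction = legacy_fraction),
            class = "rhythm_tolerance")
}

as_tol_fraction <- function(tol) {
  if (inherits(tol, "rhythm_tolerance")) tol$fraction else as.numeric(tol)
}

#' Match performed pitches to a target sequence
#'
#' Identifies sub-sequences of the target pitch sequence within the performed
#' sequence: an order-preserving matching of maximum cardinality (the longest
#' common subsequence). Among equal-cardinality matchings the leftmost one is
#' returned — each matched pair takes the earliest feasible performance index,
#' then the earliest feasible target index — so that rhythm scoring, which
#' depends on which occurrences were matched, is reproducible.
#'
#' @param performed,target Integer vectors of MIDI pitches (either may be
#'   empty). Pitch equality is exact MIDI-number equality.
#' @return An object of class `"pitch_match"`: a data frame with columns
#'   `perf_index` and `target_index` (both strictly increasing, 1-based).
#' @examples
#' m <- study_melody(1)
#' match_pitches(m$pitches, m$pitches) # identity alignment, 12 pairs
#' @export
match_pitches <- function(performed, target) {
  pairs <- lcs_match_cpp(as.integer(performed), as.integer(target))
  structure(
    data.frame(perf_index = pairs[, 1], target_index = pairs[, 2]),
    class = c("pitch_match", "data.frame")
  )
}

#' Pitch accuracy of a matched performance
#'
#' The percentage of correctly performed notes: the number of matched notes
#' divided by the longer of the target sequence length and the number of
#' performed notes (the longer denominator penalizes excessive notes).
#'
#' @param match A [match_pitches()] result.
#' @param n_target Number of notes in the target melody (>= 1).
#' @param n_performed Number of performed notes.
#' @return Percentage in `[0, 100]`; 100 exactly when the performance is the
#'   target pitch sequence (same length, all matched).
#' @export
pitch_accuracy <- function(match, n_target, n_performed) {
  if (n_target < 1) stop("invalid melody: n_target must be >= 1", call. = FALSE)
  100 * nrow(match) / max(n_target, n_performed)
}

#' Rhythm accuracy of a performance
#'
#' The percentage of inter-onset intervals within the tolerance of the
#' expected IOI. Timing of each expected note is compared with the preceding
#' *correct* (matched) note, which absorbs natural timing variation earlier in
#' the trial; the expected interval between two matched notes is the sum of
#' the melody's expected IOIs spanning their target indices. A first matched
#' note with no preceding correct note is compared with the melody's tempo
#' grid: if its target index is 1 it anchors the grid and is not judged
#' (there is no IOI before the first melody note); otherwise its onset is
#' judged against its nominal grid onset (`first_note = "grid"`, the default)
#' or counted correct unconditionally (`first_note = "always"`).
#'
#' The denominator is the longer of the target IOI count (`n_target - 1`) and
#' the performed IOI count (`n_performed - 1`); empty and single-note
#' performances score 0 whenever the target has at least 2 notes.
#'
#' @param perf A [performance()] object.
#' @param melody A [melody_from_spec()] object.
#' @param match The [match_pitches()] result for this performance/melody pair.
#'   If `NULL`, it is computed.
#' @param tol A [rhythm_tolerance()] or a bare fraction (default 0.10,
#'   boundary inclusive).
#' @param first_note `"grid"` or `"always"` (see above).
#' @return Percentage in `[0, 100]`.
#' @export
rhythm_accuracy <- function(perf, melody, match = NULL,
                            tol = rhythm_tolerance(),
                            first_note = c("grid", "always")) {
  first_note <- match.arg(first_note)
  ev <- perf$events
  if (is.null(match)) match <- match_pitches(ev$pitch, melody$pitches)
  if (nrow(match) &&
      (max(match$perf_index) > nrow(ev) ||
       max(match$target_index) > length(melody$pitches) ||
       any(ev$pitch[match$perf_index] != melody$pitches[match$target_index])))
    stop("match is inconsistent with this performance/melody pair", call. = FALSE)
  counts <- rhythm_count_cpp(
    as.matrix(match), ev$onset, melody_onsets(melody),
    as_tol_fraction(tol), if (first_note == "always") 1L else 0L)
  denom <- max(length(melody$pitches) - 1L, nrow(ev) - 1L)
  if (denom < 1L) return(0)
  100 * counts[2] / denom
}

#' Acceptable uniform-tempo range under an IOI tolerance
#'
#' A rendition played at a uniform tempo T of a melody notated at
#' `tempo_bpm` has every IOI deviating by `|tempo_bpm / T - 1|`; it is fully
#' within tolerance when T lies in
#' `[tempo_bpm / (1 + tol), tempo_bpm / (1 - tol)]`. The bounds are rounded
#' half-away-from-zero to whole bpm.
#'
#' @param tempo_bpm Notated tempo (> 0).
#' @param tol_fraction Relative IOI tolerance in (0, 1) (0 allowed).
#' @return Integer vector `c(low_bpm, high_bpm)`.
#' @examples
#' acceptable_tempo_range(75, 0.10) # 68 83
#' acceptable_tempo_range(75, 0.30) # 58 107
#' @export
acceptable_tempo_range <- function(tempo_bpm, tol_fraction) {
  if (tempo_bpm <= 0) stop("tempo_bpm must be positive", call. = FALSE)
  if (tol_fraction < 0 || tol_fraction >= 1)
    stop("tolerance fraction must be in [0, 1)", call. = FALSE)
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  out <- as.integer(round_half_away(c(tempo_bpm / (1 + tol_fraction),
                                      tempo_bpm / (1 - tol_fraction))))
  names(out) <- c("low_bpm", "high_bpm")
  out
}

#' Score one test trial
#'
#' Composes [match_pitches()], [pitch_accuracy()] and [rhythm_accuracy()] into
#' the trial's two dependent measures.
#'
#' @inheritParams rhythm_accuracy
#' @return An object of class `"accuracy_score"`: list with `pitch_accuracy`,
#'   `rhythm_accuracy` (percent), the count numerators/denominators
#'   (`n_correct_notes`, `n_performed`, `n_target`, `n_correct_iois`,
#'   `n_performed_iois`) and the `match` used.
#' @examples
#' m <- study_melody(1)
#' p <- performance(m$pitches, melody_onsets(m))
#' score_trial(p, m) # perfect rendition: 100 / 100
#' @export
score_trial <- function(perf, melody, tol = rhythm_tolerance(),
                        first_note = c("grid", "always")) {
  first_note <- match.arg(first_note)
  ev <- perf$events
  match <- match_pitches(ev$pitch, melody$pitches)
  counts <- rhythm_count_cpp(
    as.matrix(match), ev$onset, melody_onsets(melody),
    as_tol_fraction(tol), if (first_note == "always") 1L else 0L)
  n_t <- length(melody$pitches)
  denom <- max(n_t - 1L, nrow(ev) - 1L)
  structure(
    list(
      pitch_accuracy = 100 * nrow(match) / max(n_t, nrow(ev)),
      rhythm_accuracy = if (denom >= 1L) 100 * counts[2] / denom else 0,
      n_correct_notes = nrow(match),
      n_performed = nrow(ev),
      n_target = n_t,
      n_correct_iois = counts[2],
      n_performed_iois = max(nrow(ev) - 1L, 0L),
      match = match
    ),
    class = "accuracy_score"
  )
}

#' @exportS3Method print accuracy_score
print.accuracy_score <- function(x, ...) {
  cat(sprintf("<accuracy_score> pitch %.1f%% (%d/%d matched of %d performed) | rhythm %.1f%% (%d correct IOIs)\n",
              x$pitch_accuracy, x$n_correct_notes, x$n_target, x$n_performed,
              x$rhythm_accuracy, x$n_correct_iois))
  invisible(x)
}

#' Score a batch of test-trial performances
#'
#' @param performances List of [performance()] objects (test trials).
#' @param melody Target melody.
#' @inheritParams rhythm_accuracy
#' @return A tibble with one row per trial: the metadata fields plus
#'   `pitch_accuracy` and `rhythm_accuracy`.
#' @export
score_trials <- function(performances, melody, tol = rhythm_tolerance(),
                         first_note = c("grid", "always")) {
  first_note <- match.arg(first_note)
  rows <- lapply(performances, function(p) {
    s <- score_trial(p, melody, tol, first_note)
    tibble::tibble(
      participant_id = p$participant_id, group = p$group, phase = p$phase,
      session = p$session, block = p$block, trial_index = p$trial_index,
      pitch_accuracy = s$pitch_accuracy, rhythm_accuracy = s$rhythm_accuracy,
      n_performed = s$n_performed
    )
  })
  dplyr::bind_rows(rows)
}
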