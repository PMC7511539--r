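#' Construct a performance (one trial of timed keypresses)
#'
#' A performance is the ordered list of note events recorded during a single
#' trial, plus the trial's metadata. Events are sorted by onset; simultaneous
#' key presses are serialized by ascending pitch so that event order is total
#' and deterministic (the melodies are monophonic, so true chords are
#' participant error).
#'
#' Time zero is the end of the four-beat metronome count-in that precedes
#' training and test trials; see [read_performance_midi()] for the count-in
#' offset handling.
#'
#' @param pitch Integer MIDI note numbers.
#' @param onset Onset times in seconds from trial start (>= 0 not enforced:
#'   early presses before the count-in ends are legitimate data).
#' @param duration Optional key-hold durations in seconds (`NA` allowed).
#' @param participant_id,group,phase,session,block,trial_type,trial_index
#'   Trial metadata. `group` is `"HIIT"`/`"LIIT"`, `phase` one of
#'   familiarization/acquisition/retention/transfer, `session` one of
#'   Acq/R1/R24/R7/Tran, `trial_type` one of listen/train/test. Only test
#'   trials are scored.
#' @return An object of class `"performance"`: list with `events` (data frame
#'   `pitch`, `onset`, `duration`) and the metadata fields.
#' @examples
#' p <- performance(pitch_to_midi(c("A4", "B4")), c(0, 0.8))
#' @export
performance <- function(pitch = integer(0), onset = numeric(0),
                        duration = rep(NA_real_, length(pitch)),
                        participant_id = NA_character_, group = NA_character_,
                        phase = NA_character_, session = NA_character_,
                        block = NA_integer_, trial_type = "test",
                        trial_index = NA_integer_) {
  stopifnot(length(pitch) == length(onset), length(duration) == length(pitch))
  pitch <- as.integer(pitch)
  if (length(pitch) && any(pitch < 0L | pitch > 127L))
    stop("MIDI pitch out of range 0-127", call. = FALSE)
  ord <- order(onset, pitch)
  structure(
    list(
      events = data.frame(pitch = pitch[ord], onset = as.numeric(onset)[ord],
                          duration = as.numeric(duration)[ord]),
      participant_id = participant_id, group = group, phase = phase,
      session = session, block = block, trial_type = trial_type,
      trial_index = trial_index
    ),
    class = "performance"
  )
}

#' @exportS3Method print performance
print.performance <- function(x, ...) {
  cat("<performance> ", nrow(x$events), " events",
      if (!is.na(x$participant_id)) paste0(" | participant ", x$participant_id),
      if (!is.na(x$session)) paste0(" | ", x$session),
      if (!is.na(x$trial_index)) paste0(" | trial ", x$trial_index),
      "\n", sep = "")
  if (nrow(x$events)) {
    show <- utils::head(x$events, 12L)
    cat(paste0("  ", format(midi_to_pitch(show$pitch), width = 3), " @ ",
               format(round(show$onset, 3), nsmall = 3), " s",
               collapse = "\n"), "\n")
    if (nrow(x$events) > 12L) cat("  ... (", nrow(x$events) - 12L, " more)\n", sep = "")
  }
  invisible(x)
}

n_events <- function(p) nrow(p$events)
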