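#' Convert scientific pitch names to MIDI note numbers
#'
#' Accepts names such as `"A4"`, `"C#5"`, `"Eb3"` (octave numbering with
#' C4 = middle C = MIDI 60) or numbers, which are passed through after a
#' range check.
#'
#' @param pitch Character vector of pitch names, or numeric MIDI numbers.
#' @return Integer vector of MIDI note numbers (0-127).
#' @examples
#' pitch_to_midi(c("A4", "B4", "C5", "D5", "E5"))
#' @export
pitch_to_midi <- function(pitch) {
  if (is.numeric(pitch)) {
    p <- as.integer(round(pitch))
    if (any(p < 0L | p > 127L)) stop("MIDI pitch out of range 0-127", call. = FALSE)
    return(p)
  }
  base <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  m <- regmatches(pitch, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", pitch))
  out <- vapply(seq_along(pitch), function(i) {
    g <- m[[i]]
    if (length(g) == 0L) stop("unknown pitch name: '", pitch[i], "'", call. = FALSE)
    n <- base[[toupper(g[2])]] +
      switch(g[3], "#" = 1L, "b" = -1L, 0L) +
      12L * (as.integer(g[4]) + 1L)
    n
  }, integer(1))
  if (any(out < 0L | out > 127L)) stop("MIDI pitch out of range 0-127", call. = FALSE)
  out
}

#' Convert MIDI note numbers to scientific pitch names
#'
#' @param midi Integer vector of MIDI note numbers.
#' @return Character vector of names; black keys use sharps.
#' @export
midi_to_pitch <- function(midi) {
  midi <- as.integer(midi)
  names12 <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  paste0(names12[midi %% 12L + 1L], midi %/% 12L - 1L)
}

#' Construct a target melody
#'
#' A melody is an ordered pitch sequence with note values (in beats) and a
#' tempo. Expected inter-onset intervals (IOIs) are derived as
#' `note_value * 60 / tempo_bpm`; only the first `n - 1` note values
#' contribute IOIs (the last note's value does not precede any onset).
#'
#' @param pitches Pitch names or MIDI numbers, in order.
#' @param note_values Beat lengths per note (1 = quarter, 0.5 = eighth).
#' @param tempo_bpm Tempo in beats per minute (> 0).
#' @param strict If `TRUE`, enforce the study-melody constraints: exactly 12
#'   notes, pitches within \{A4, B4, C5, D5, E5\}, note values in \{1, 0.5\},
#'   tempo 75 bpm.
#' @return An object of class `"melody"`: a list with elements `pitches`
#'   (integer MIDI numbers), `note_values`, `tempo_bpm` and `expected_iois`
#'   (seconds, length `n - 1`).
#' @examples
#' m <- melody_from_spec(rep("A4", 12), rep(1, 12), 75)
#' m$expected_iois # all 0.8 s
#' @export
melody_from_spec <- function(pitches, note_values, tempo_bpm = 75,
                             strict = FALSE) {
  if (!is.numeric(tempo_bpm) || length(tempo_bpm) != 1L || tempo_bpm <= 0)
    stop("tempo_bpm must be a single positive number", call. = FALSE)
  p <- pitch_to_midi(pitches)
  v <- as.numeric(note_values)
  if (length(p) != length(v))
    stop("pitches and note_values must have equal length", call. = FALSE)
  if (length(p) < 1L) stop("melody must contain at least one note", call. = FALSE)
  if (any(v <= 0)) stop("note values must be positive", call. = FALSE)
  if (strict) {
    study <- pitch_to_midi(c("A4", "B4", "C5", "D5", "E5"))
    if (length(p) != 12L) stop("study melodies have 12 notes", call. = FALSE)
    if (!all(p %in% study)) stop("study melodies use only A4, B4, C5, D5, E5", call. = FALSE)
    if (!all(v %in% c(1, 0.5))) stop("study melodies use quarter and eighth notes", call. = FALSE)
    if (tempo_bpm != 75) stop("study melodies are at 75 bpm", call. = FALSE)
  }
  iois <- if (length(p) > 1L) v[-length(v)] * 60 / tempo_bpm else numeric(0)
  structure(
    list(pitches = p, note_values = v, tempo_bpm = tempo_bpm,
         expected_iois = iois),
    class = "melody"
  )
}

#' @exportS3Method print melody
print.melody <- function(x, ...) {
  cat("<melody> ", length(x$pitches), " notes at ", x$tempo_bpm, " bpm\n", sep = "")
  cat("  pitches:  ", paste(midi_to_pitch(x$pitches), collapse = " "), "\n", sep = "")
  cat("  values:   ", paste(x$note_values, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.melody <- function(x) length(x$pitches)

#' Expected onset grid of a melody
#'
#' Nominal onset time (seconds from trial start) of every melody note under
#' the notated tempo: the cumulative sum of expected IOIs, starting at 0.
#'
#' @param melody A [melody_from_spec()] object.
#' @return Numeric vector, one onset per note.
#' @export
melody_onsets <- function(melody) {
  cumsum(c(0, melody$expected_iois))
}

#' Read / write a melody as JSON
#'
#' The JSON dialect stores `pitch` (names), `note_value` per note and a single
#' `tempo_bpm`. `melody_to_json()` / `melody_from_json()` round-trip exactly.
#'
#' @param path File path.
#' @param melody A melody object.
#' @param strict Passed to [melody_from_spec()].
#' @return `melody_from_json()` returns a melody; `melody_to_json()` returns
#'   `path` invisibly.
#' @export
melody_to_json <- function(melody, path) {
  obj <- list(
    tempo_bpm = melody$tempo_bpm,
    notes = data.frame(pitch = midi_to_pitch(melody$pitches),
                       note_value = melody$note_values)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname melody_to_json
#' @export
melody_from_json <- function(path, strict = FALSE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  melody_from_spec(obj$notes$pitch, obj$notes$note_value, obj$tempo_bpm,
                   strict = strict)
}

#' Read / write a melody as CSV
#'
#' Columns: `pitch`, `note_value`, `tempo_bpm` (tempo repeated on each row).
#'
#' @inheritParams melody_to_json
#' @export
melody_to_csv <- function(melody, path) {
  utils::write.csv(
    data.frame(pitch = midi_to_pitch(melody$pitches),
               note_value = melody$note_values,
               tempo_bpm = melody$tempo_bpm),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname melody_to_csv
#' @export
melody_from_csv <- function(path, strict = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  melody_from_spec(d$pitch, d$note_value, d$tempo_bpm[1], strict = strict)
}

#' Built-in study melodies
#'
#' The original study's two 12-note target melodies (and its three
#' familiarization melodies) are published only as engraved figures, not as
#' note text. The package therefore ships placeholder melodies that satisfy
#' every stated structural constraint: 12 notes drawn from the five pitches
#' A4-E5 (each pitch used), a mix of quarter and eighth notes (7 quarters and
#' 5 eighths), and a tempo of 75 bpm. They are *synthetic stand-ins*, suitable
#' for testing the scoring pipeline, not transcriptions of the originals.
#'
#' @param which 1 (acquisition-style) or 2 (transfer-style).
#' @return A strict-valid melody object.
#' @examples
#' study_melody(1)
#' @export
study_melody <- function(which = 1) {
  which <- match.arg(as.character(which), c("1", "2"))
  if (which == "1") {
    melody_from_spec(
      c("A4", "B4", "C5", "B4", "A4", "C5", "D5", "E5", "D5", "C5", "B4", "A4"),
      c(1, 1, 0.5, 0.5, 1, 1, 0.5, 0.5, 1, 1, 1, 0.5),
      75, strict = TRUE)
  } else {
    melody_from_spec(
      c("E5", "D5", "C5", "D5", "E5", "C5", "B4", "A4", "B4", "C5", "D5", "E5"),
      c(1, 0.5, 0.5, 1, 1, 1, 0.5, 0.5, 1, 1, 1, 0.5),
      75, strict = TRUE)
  }
}

#' Familiarization melodies
#'
#' Three short, simple placeholder melodies in the style of the task's
#' familiarization stimuli (synthetic stand-ins; see [study_melody()]).
#'
#' @param which 1, 2 or 3.
#' @return A melody object (not strict: these are shorter than 12 notes).
#' @export
familiarization_melody <- function(which = 1) {
  which <- match.arg(as.character(which), c("1", "2", "3"))
  switch(which,
    "1" = melody_from_spec(c("A4", "B4", "C5", "B4", "A4"), rep(1, 5), 75),
    "2" = melody_from_spec(c("C5", "D5", "E5", "D5", "C5"), rep(1, 5), 75),
    "3" = melody_from_spec(c("A4", "C5", "E5", "C5", "A4"), c(1, 1, 1, 0.5, 0.5), 75)
  )
}
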