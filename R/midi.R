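# Minimal Standard MIDI File (SMF) reader/writer, formats 0 and 1.
# Only the event classes the pipeline needs are interpreted: note-on,
# note-off, and set-tempo meta events; everything else is skipped by length.

# --- variable-length quantities -------------------------------------------

encode_vlq <- function(x) {
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

# reads a VLQ from raw vector `r` starting at `pos`; returns list(value, pos)
decode_vlq <- function(r, pos) {
  val <- 0
  repeat {
    if (pos > length(r)) stop("truncated variable-length quantity at byte offset ",
                              pos - 1L, call. = FALSE)
    b <- as.integer(r[pos]); pos <- pos + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

int_to_bytes <- function(x, n) {
  out <- integer(n)
  for (i in n:1) { out[i] <- x %% 256L; x <- x %/% 256L }
  as.raw(out)
}

bytes_to_int <- function(r) {
  Reduce(function(a, b) a * 256 + as.integer(b), r, accumulate = FALSE, init = 0)
}

# --- writer ----------------------------------------------------------------

#' Write a performance as a Standard MIDI File
#'
#' Emits a single-track (format 0) SMF containing one note-on/note-off pair
#' per event, with a set-tempo meta event so that tick times map exactly to
#' the stored onsets. Onsets read back with [read_performance_midi()] match
#' the originals within one tick at the written pulses-per-quarter (PPQ).
#'
#' @param perf A [performance()] object.
#' @param path Output file path.
#' @param ppq Pulses per quarter note (default 480).
#' @param tempo_bpm Tempo written to the file (default 75, the study tempo);
#'   purely a time-encoding choice, one tick = `60 / (tempo_bpm * ppq)` s.
#' @param default_duration Seconds of key hold used when an event's duration
#'   is `NA`.
#' @return `path`, invisibly.
#' @export
write_performance_midi <- function(perf, path, ppq = 480L, tempo_bpm = 75,
                                   default_duration = 0.25) {
  stopifnot(inherits(perf, "performance"))
  tempo_us <- round(60e6 / tempo_bpm)
  sec_per_tick <- tempo_us / 1e6 / ppq
  ev <- perf$events
  track <- list()
  # set-tempo at tick 0
  track[[1]] <- list(tick = 0, bytes = as.raw(c(0xFF, 0x51, 0x03, int_to_bytes(tempo_us, 3))))
  if (nrow(ev)) {
    dur <- ifelse(is.na(ev$duration), default_duration, ev$duration)
    on_tick <- round(ev$onset / sec_per_tick)
    off_tick <- round((ev$onset + dur) / sec_per_tick)
    for (i in seq_len(nrow(ev))) {
      track[[length(track) + 1L]] <-
        list(tick = on_tick[i], kind = "on", pitch = ev$pitch[i],
             bytes = as.raw(c(0x90, ev$pitch[i], 0x50)))
      track[[length(track) + 1L]] <-
        list(tick = off_tick[i], kind = "off", pitch = ev$pitch[i],
             bytes = as.raw(c(0x80, ev$pitch[i], 0x00)))
    }
  }
  ticks <- vapply(track, `[[`, numeric(1), "tick")
  kind <- vapply(track, function(e) if (is.null(e$kind)) "meta" else e$kind, "")
  pitch <- vapply(track, function(e) if (is.null(e$pitch)) -1L else as.integer(e$pitch), 0L)
  # at equal ticks: meta, then note-offs, then note-ons ascending pitch
  ord <- order(ticks, match(kind, c("meta", "off", "on")), pitch)
  track <- track[ord]; ticks <- ticks[ord]
  body <- raw(0)
  last <- 0
  for (i in seq_along(track)) {
    body <- c(body, encode_vlq(ticks[i] - last), track[[i]]$bytes)
    last <- ticks[i]
  }
  body <- c(body, encode_vlq(0), as.raw(c(0xFF, 0x2F, 0x00)))  # end of track
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), int_to_bytes(6, 4), int_to_bytes(0, 2),
             int_to_bytes(1, 2), int_to_bytes(ppq, 2),
             charToRaw("MTrk"), int_to_bytes(length(body), 4), body),
           con)
  invisible(path)
}

# --- reader ----------------------------------------------------------------

# parse one MTrk body (raw vector), absolute start offset for error messages
parse_track <- function(r, offset0) {
  pos <- 1L
  tick <- 0
  status <- NULL
  notes <- list(); tempos <- list()
  while (pos <= length(r)) {
    d <- decode_vlq(r, pos); pos <- d$pos
    tick <- tick + d$value
    if (pos > length(r)) stop("truncated track at byte offset ", offset0 + pos - 1L, call. = FALSE)
    b <- as.integer(r[pos])
    if (b >= 0x80L) { status <- b; pos <- pos + 1L } else if (is.null(status)) {
      stop("running status with no prior status byte at byte offset ",
           offset0 + pos - 1L, call. = FALSE)
    }
    if (status == 0xFFL) {            # meta event
      type <- as.integer(r[pos]); pos <- pos + 1L
      d <- decode_vlq(r, pos); pos <- d$pos
      dat <- r[seq_len(d$value) + pos - 1L]; pos <- pos + d$value
      if (type == 0x51L) tempos[[length(tempos) + 1L]] <- list(tick = tick, us = bytes_to_int(dat))
      if (type == 0x2FL) break        # end of track
      status <- NULL                  # meta events cancel running status
    } else if (status %in% c(0xF0L, 0xF7L)) {  # sysex
      d <- decode_vlq(r, pos); pos <- d$pos + d$value
      status <- NULL
    } else {
      hi <- status %/% 16L
      nbytes <- if (hi %in% c(0xCL, 0xDL)) 1L else 2L
      if (pos + nbytes - 1L > length(r))
        stop("truncated event at byte offset ", offset0 + pos - 1L, call. = FALSE)
      dat <- as.integer(r[pos + seq_len(nbytes) - 1L]); pos <- pos + nbytes
      if (hi == 0x9L) {
        notes[[length(notes) + 1L]] <- list(tick = tick, pitch = dat[1],
                                            on = dat[2] > 0L)
      } else if (hi == 0x8L) {
        notes[[length(notes) + 1L]] <- list(tick = tick, pitch = dat[1], on = FALSE)
      }
    }
  }
  list(notes = notes, tempos = tempos)
}

#' Read a performance from a Standard MIDI File
#'
#' Parses an SMF (format 0 or 1), converts note-on ticks to seconds via the
#' file's tempo map (default 120 bpm where no set-tempo event precedes an
#' event, per the SMF standard), pairs note-offs to compute durations, and
#' returns a [performance()] with events sorted by onset (ties broken by
#' ascending pitch).
#'
#' @param path SMF file path.
#' @param count_in_beats Number of metronome count-in beats to subtract from
#'   all onsets (the recording clock starts at the beginning of the count-in
#'   in some capture setups). The offset is `count_in_beats * 60 / tempo` using
#'   the file's initial tempo. Default 0 (time zero is already the end of the
#'   count-in).
#' @param ... Metadata fields passed to [performance()] (e.g. `participant_id`,
#'   `session`, `trial_index`).
#' @return A performance object. A file with zero note-on events yields an
#'   empty performance (scorable as 0 percent) with a warning.
#' @export
read_performance_midi <- function(path, count_in_beats = 0, ...) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 14L || !identical(rawToChar(r[1:4]), "MThd"))
    stop("not a Standard MIDI File: missing 'MThd' magic at byte offset 0",
         call. = FALSE)
  hlen <- bytes_to_int(r[5:8])
  fmt <- bytes_to_int(r[9:10])
  ntrk <- bytes_to_int(r[11:12])
  division <- bytes_to_int(r[13:14])
  if (!fmt %in% c(0L, 1L)) stop("unsupported SMF format ", fmt, call. = FALSE)
  if (division >= 32768L) stop("SMPTE time division not supported", call. = FALSE)
  pos <- 9L + hlen
  notes <- list(); tempos <- list()
  for (t in seq_len(ntrk)) {
    if (pos + 7L > length(r))
      stop("truncated file: expected track ", t, " at byte offset ", pos - 1L, call. = FALSE)
    if (!identical(rawToChar(r[pos:(pos + 3L)]), "MTrk"))
      stop("malformed track header at byte offset ", pos - 1L,
           " (track ", t, ")", call. = FALSE)
    tlen <- bytes_to_int(r[(pos + 4L):(pos + 7L)])
    body <- r[pos + 7L + seq_len(tlen)]
    parsed <- parse_track(body, pos + 7L)
    notes <- c(notes, parsed$notes)
    tempos <- c(tempos, parsed$tempos)   # format 1: tempo track applies globally
    pos <- pos + 8L + tlen
  }
  # tempo map: piecewise-constant us/quarter over ticks
  tmap <- if (length(tempos)) {
    tm <- do.call(rbind, lapply(tempos, function(x) c(x$tick, x$us)))
    tm <- tm[order(tm[, 1]), , drop = FALSE]
    tm
  } else matrix(c(0, 500000), 1)
  if (tmap[1, 1] > 0) tmap <- rbind(c(0, 500000), tmap)
  tick_to_sec <- function(tick) {
    # cumulative seconds at each tempo-change tick
    seg_start <- tmap[, 1]
    seg_us <- tmap[, 2]
    cum <- c(0, cumsum(diff(seg_start) * seg_us[-length(seg_us)] / 1e6 / division))
    i <- findInterval(tick, seg_start)
    cum[i] + (tick - seg_start[i]) * seg_us[i] / 1e6 / division
  }
  if (!length(notes)) {
    warning("MIDI file contains no note-on events; returning an empty performance")
    return(performance(...))
  }
  nt <- data.frame(
    tick = vapply(notes, `[[`, numeric(1), "tick"),
    pitch = vapply(notes, `[[`, 0L, "pitch"),
    on = vapply(notes, `[[`, TRUE, "on")
  )
  ons <- which(nt$on)
  if (!length(ons)) {
    warning("MIDI file contains no note-on events; returning an empty performance")
    return(performance(...))
  }
  onset <- tick_to_sec(nt$tick[ons])
  duration <- rep(NA_real_, length(ons))
  used_off <- rep(FALSE, nrow(nt))
  for (k in seq_along(ons)) {
    i <- ons[k]
    j <- which(!nt$on & nt$pitch == nt$pitch[i] & seq_len(nrow(nt)) > i & !used_off)
    if (length(j)) {
      j <- j[1]
      used_off[j] <- TRUE
      duration[k] <- tick_to_sec(nt$tick[j]) - onset[k]
    }
  }
  offset <- if (count_in_beats > 0) count_in_beats * 60 / (6e7 / tmap[1, 2]) else 0
  performance(pitch = nt$pitch[ons], onset = onset - offset,
              duration = duration, ...)
}
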