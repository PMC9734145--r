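# Standard MIDI File (format 0/1) reading and writing, implemented directly
# on raw vectors. Only note-on/note-off and set-tempo events are interpreted;
# everything else is skipped. All times are converted to milliseconds at
# parse time via the file's tempo map; ticks are an I/O detail only.

DEFAULT_DIVISION <- 480L          # ticks per quarter note on write
DEFAULT_USPQ <- 500000            # SMF default: 120 qbpm

encode_vlq <- function(x) {
  # variable-length quantity: 7 bits per byte, MSB set on all but the last
  stopifnot(x >= 0)
  bytes <- as.integer(x %% 128L)
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(as.integer(x %% 128L) + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

uint_be <- function(x, width) {
  out <- integer(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- x %% 256L
    x <- x %/% 256L
  }
  as.raw(out)
}

read_uint_be <- function(bytes) {
  sum(as.integer(bytes) * 256^(rev(seq_along(bytes)) - 1))
}

#' Write a performance as a Standard MIDI File
#'
#' Serializes a performance to a format-0 SMF (one track, 480 ticks per
#' quarter) with a single set-tempo event at the cued tempo. Round-tripping
#' through [read_performance()] preserves pitch and velocity exactly and
#' times to within one tick of quantization.
#'
#' Overlapping notes of the same pitch cannot be serialized unambiguously
#' under note-on/note-off pairing and are rejected.
#'
#' @param perf a [performance()] object.
#' @param path output file path; if `NULL`, the raw bytes are returned.
#' @param cued_tempo_qbpm tempo written to the file's set-tempo event;
#'   defaults to the performance's own cued tempo.
#' @param division ticks per quarter note (>= 24).
#' @return The path (invisibly), or the raw byte vector when `path = NULL`.
#' @export
write_performance <- function(perf, path = NULL,
                              cued_tempo_qbpm = perf$cued_tempo_qbpm,
                              division = DEFAULT_DIVISION) {
  stopifnot(inherits(perf, "performance"), division >= 24L)
  notes <- perf$notes
  if (cued_tempo_qbpm <= 0) stop("tempo must be positive", call. = FALSE)
  # reject overlapping same-pitch notes: ambiguous under FIFO pairing
  if (nrow(notes) > 1L) {
    for (p in unique(notes$pitch)) {
      sub <- notes[notes$pitch == p, ]
      if (nrow(sub) > 1L &&
          any(sub$onset_ms[-1L] < sub$offset_ms[-nrow(sub)])) {
        stop("overlapping notes of the same pitch (", p,
             ") cannot be written to SMF", call. = FALSE)
      }
    }
  }
  uspq <- round(60e6 / cued_tempo_qbpm)
  ticks_per_ms <- division / (uspq / 1000)
  ev_tick <- round(c(notes$onset_ms, notes$offset_ms) * ticks_per_ms)
  ev_on <- rep(c(TRUE, FALSE), each = nrow(notes))
  ev_pitch <- rep(notes$pitch, 2L)
  ev_vel <- c(notes$velocity, rep(0L, nrow(notes)))
  # offs before ons at the same tick, so back-to-back same-pitch notes pair
  ord <- order(ev_tick, ev_on, ev_pitch)
  ev_tick <- ev_tick[ord]; ev_on <- ev_on[ord]
  ev_pitch <- ev_pitch[ord]; ev_vel <- ev_vel[ord]

  track <- list(as.raw(c(0x00, 0xFF, 0x51, 0x03)), uint_be(uspq, 3L))
  last <- 0
  for (k in seq_along(ev_tick)) {
    status <- if (ev_on[k]) 0x90L else 0x80L
    track <- c(track, list(encode_vlq(ev_tick[k] - last),
                           as.raw(c(status, ev_pitch[k], ev_vel[k]))))
    last <- ev_tick[k]
  }
  track <- c(track, list(as.raw(c(0x00, 0xFF, 0x2F, 0x00))))
  body <- do.call(c, track)
  out <- c(charToRaw("MThd"), uint_be(6L, 4L), uint_be(0L, 2L),
           uint_be(1L, 2L), uint_be(division, 2L),
           charToRaw("MTrk"), uint_be(length(body), 4L), body)
  if (is.null(path)) return(out)
  writeBin(out, path)
  invisible(path)
}

# -- parsing ----------------------------------------------------------------

smf_cursor <- function(bytes) new.env(parent = emptyenv())

parse_vlq <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

parse_track <- function(bytes, pos, len) {
  end <- pos + len
  tick <- 0
  status <- NA_integer_
  ev <- list(tick = numeric(0), on = logical(0), pitch = integer(0),
             vel = integer(0))
  tempo <- list(tick = numeric(0), uspq = numeric(0))
  while (pos < end) {
    d <- parse_vlq(bytes, pos); pos <- d$pos
    tick <- tick + d$value
    b <- as.integer(bytes[pos])
    if (b >= 128L) { status <- b; pos <- pos + 1L }
    if (is.na(status)) stop("malformed SMF: data byte without running status",
                            call. = FALSE)
    hi <- status %/% 16L
    if (status == 255L) {               # meta event
      type <- as.integer(bytes[pos]); pos <- pos + 1L
      d <- parse_vlq(bytes, pos); pos <- d$pos
      if (type == 0x51L && d$value == 3L) {
        tempo$tick <- c(tempo$tick, tick)
        tempo$uspq <- c(tempo$uspq, read_uint_be(bytes[pos:(pos + 2L)]))
      }
      pos <- pos + d$value
      status <- NA_integer_             # meta cancels running status
    } else if (status %in% c(240L, 247L)) {   # sysex
      d <- parse_vlq(bytes, pos); pos <- d$pos + d$value
      status <- NA_integer_
    } else if (hi %in% c(8L, 9L)) {     # note off / note on
      pitch <- as.integer(bytes[pos]); vel <- as.integer(bytes[pos + 1L])
      pos <- pos + 2L
      ev$tick <- c(ev$tick, tick)
      ev$on <- c(ev$on, hi == 9L && vel > 0L)  # on with vel 0 == off
      ev$pitch <- c(ev$pitch, pitch)
      ev$vel <- c(ev$vel, vel)
    } else if (hi %in% c(10L, 11L, 14L)) {    # 2 data bytes, skipped
      pos <- pos + 2L
    } else if (hi %in% c(12L, 13L)) {   # 1 data byte, skipped
      pos <- pos + 1L
    } else {
      stop("malformed SMF: unexpected status byte ", status, call. = FALSE)
    }
  }
  list(events = ev, tempo = tempo, pos = end)
}

ticks_to_ms <- function(ticks, tempo_ticks, tempo_uspq, division) {
  # piecewise-linear conversion under the (merged) tempo map
  if (length(tempo_ticks) == 0L || tempo_ticks[1L] > 0) {
    tempo_ticks <- c(0, tempo_ticks)
    tempo_uspq <- c(DEFAULT_USPQ, tempo_uspq)
  }
  seg_ms <- c(0, cumsum(diff(tempo_ticks) *
                          tempo_uspq[-length(tempo_uspq)] / division / 1000))
  idx <- findInterval(ticks, tempo_ticks)
  seg_ms[idx] + (ticks - tempo_ticks[idx]) * tempo_uspq[idx] / division / 1000
}

#' Read a performance from a Standard MIDI File
#'
#' Parses a format-0 or format-1 SMF, merges all tracks, pairs each note-on
#' with the first subsequent note-off of the same pitch (a note-on with
#' velocity 0 counts as a note-off, per the SMF standard), and converts tick
#' times to milliseconds through the file's tempo map.
#'
#' @param src file path or a raw byte vector.
#' @param participant_id,condition,technique,trial_index,cued_tempo_qbpm
#'   trial descriptors attached to the returned object; `cued_tempo_qbpm`
#'   defaults to the tempo of the file's first set-tempo event.
#' @return A [performance()] object.
#' @export
read_performance <- function(src, participant_id = NA_character_,
                             condition = "performing",
                             technique = "articulation", trial_index = 1L,
                             cued_tempo_qbpm = NULL) {
  bytes <- if (is.raw(src)) src else readBin(src, "raw",
                                             n = file.info(src)$size)
  if (length(bytes) < 14L || rawToChar(bytes[1:4]) != "MThd") {
    stop("not a Standard MIDI File: missing MThd header", call. = FALSE)
  }
  hdr_len <- read_uint_be(bytes[5:8])
  format <- read_uint_be(bytes[9:10])
  ntrks <- read_uint_be(bytes[11:12])
  division <- read_uint_be(bytes[13:14])
  if (division >= 32768L) {
    stop("SMPTE time division is not supported", call. = FALSE)
  }
  if (!format %in% c(0L, 1L)) {
    stop("only SMF formats 0 and 1 are supported (got ", format, ")",
         call. = FALSE)
  }
  pos <- 9L + hdr_len
  ev <- list(tick = numeric(0), on = logical(0), pitch = integer(0),
             vel = integer(0))
  tempo <- list(tick = numeric(0), uspq = numeric(0))
  for (t in seq_len(ntrks)) {
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") {
      stop("malformed SMF: expected MTrk chunk", call. = FALSE)
    }
    len <- read_uint_be(bytes[(pos + 4L):(pos + 7L)])
    tr <- parse_track(bytes, pos + 8L, len)
    ev <- Map(c, ev, tr$events)
    tempo <- Map(c, tempo, tr$tempo)
    pos <- tr$pos
  }
  ord <- order(tempo$tick)
  tempo$tick <- tempo$tick[ord]; tempo$uspq <- tempo$uspq[ord]
  # merge tracks: stable order by tick, offs before ons at equal tick
  ord <- order(ev$tick, ev$on)
  ev <- lapply(ev, `[`, ord)

  ms <- ticks_to_ms(ev$tick, tempo$tick, tempo$uspq, division)
  # FIFO pairing per pitch
  open <- vector("list", 128L)   # queues of indices into the result
  res <- list(pitch = integer(0), on_ms = numeric(0), off_ms = numeric(0),
              vel = integer(0))
  for (k in seq_along(ev$tick)) {
    p <- ev$pitch[k]
    if (ev$on[k]) {
      res$pitch <- c(res$pitch, p)
      res$on_ms <- c(res$on_ms, ms[k])
      res$off_ms <- c(res$off_ms, NA_real_)
      res$vel <- c(res$vel, ev$vel[k])
      open[[p + 1L]] <- c(open[[p + 1L]], length(res$pitch))
    } else {
      q <- open[[p + 1L]]
      if (length(q) == 0L) next      # stray note-off: ignored
      res$off_ms[q[1L]] <- ms[k]
      open[[p + 1L]] <- q[-1L]
    }
  }
  dangling <- which(is.na(res$off_ms))
  if (length(dangling) > 0L) {
    stop("dangling note-on at end of file: pitch ",
         paste(res$pitch[dangling], collapse = ", "),
         " (onset ms ", paste(round(res$on_ms[dangling], 2), collapse = ", "),
         ")", call. = FALSE)
  }
  if (is.null(cued_tempo_qbpm)) {
    cued_tempo_qbpm <- if (length(tempo$uspq) > 0L) {
      60e6 / tempo$uspq[1L]
    } else 60e6 / DEFAULT_USPQ
  }
  notes <- note_events(res$pitch, res$on_ms, res$off_ms, res$vel)
  performance(notes, participant_id = participant_id, condition = condition,
              technique = technique, trial_index = trial_index,
              cued_tempo_qbpm = cued_tempo_qbpm)
}
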