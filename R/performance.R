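#' Note-event tables and performance objects
#'
#' A performance is one recorded trial: an ordered table of key presses
#' (note events) plus trial descriptors. Each note event carries the MIDI
#' pitch (0-127), onset and offset times in milliseconds from trial start,
#' and the key velocity (0-127), the MIDI proxy for loudness.
#'
#' @param pitch integer vector of MIDI note numbers (0-127).
#' @param onset_ms,offset_ms numeric vectors, milliseconds from trial start;
#'   `offset_ms` must exceed `onset_ms` for every note.
#' @param velocity integer vector of key velocities (0-127).
#' @return A tibble with columns `pitch`, `onset_ms`, `offset_ms`,
#'   `velocity`, sorted by onset (ties broken by ascending pitch).
#' @export
note_events <- function(pitch, onset_ms, offset_ms, velocity) {
  n <- length(pitch)
  stopifnot(length(onset_ms) == n, length(offset_ms) == n,
            length(velocity) == n)
  if (n == 0L) {
    return(tibble::tibble(pitch = integer(), onset_ms = numeric(),
                          offset_ms = numeric(), velocity = integer()))
  }
  pitch <- as.integer(pitch)
  velocity <- as.integer(velocity)
  if (any(pitch < 0L | pitch > 127L)) {
    stop("pitch must be within the MIDI range 0-127", call. = FALSE)
  }
  if (any(velocity < 0L | velocity > 127L)) {
    stop("velocity must be within the MIDI range 0-127", call. = FALSE)
  }
  if (any(offset_ms <= onset_ms)) {
    stop("every offset_ms must be greater than its onset_ms", call. = FALSE)
  }
  ord <- order(onset_ms, pitch)
  tibble::tibble(pitch = pitch[ord], onset_ms = as.numeric(onset_ms[ord]),
                 offset_ms = as.numeric(offset_ms[ord]),
                 velocity = velocity[ord])
}

#' Construct a performance (one trial)
#'
#' @param notes a note-event tibble, see [note_events()]; passed through the
#'   same validation.
#' @param participant_id participant identifier.
#' @param condition `"teaching"` or `"performing"`.
#' @param technique `"articulation"` or `"dynamics"`.
#' @param trial_index 1-based trial number within the condition x technique
#'   cell.
#' @param cued_tempo_qbpm metronome tempo in quarter beats per minute.
#' @return An object of class `performance`.
#' @export
performance <- function(notes, participant_id = NA_character_,
                        condition = c("performing", "teaching"),
                        technique = c("articulation", "dynamics"),
                        trial_index = 1L, cued_tempo_qbpm = 80) {
  condition <- match.arg(condition)
  technique <- match.arg(technique)
  notes <- note_events(notes$pitch, notes$onset_ms, notes$offset_ms,
                       notes$velocity)
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L) {
    stop("trial_index must be >= 1", call. = FALSE)
  }
  if (cued_tempo_qbpm <= 0) stop("cued_tempo_qbpm must be positive",
                                 call. = FALSE)
  structure(
    list(notes = notes, participant_id = as.character(participant_id),
         condition = condition, technique = technique,
         trial_index = trial_index,
         cued_tempo_qbpm = as.numeric(cued_tempo_qbpm)),
    class = "performance")
}

#' @export
print.performance <- function(x, ...) {
  cat(sprintf(
    "<performance> participant %s | %s | %s | trial %d | %g qbpm | %d notes\n",
    x$participant_id, x$condition, x$technique, x$trial_index,
    x$cued_tempo_qbpm, nrow(x$notes)))
  print(x$notes, n = 6)
  invisible(x)
}

#' Read/write a note-event table as CSV
#'
#' Plain-text alternative to Standard MIDI Files: columns `pitch`,
#' `onset_ms`, `offset_ms`, `velocity`, one row per note.
#'
#' @param path file path.
#' @return For `read_note_table()`, a validated note-event tibble.
#' @export
read_note_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pitch", "onset_ms", "offset_ms", "velocity")
  if (!all(need %in% names(df))) {
    stop("note table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  note_events(df$pitch, df$onset_ms, df$offset_ms, df$velocity)
}

#' @param notes a note-event tibble.
#' @rdname read_note_table
#' @export
write_note_table <- function(notes, path) {
  utils::write.csv(
    notes[, c("pitch", "onset_ms", "offset_ms", "velocity")],
    path, row.names = FALSE)
  invisible(path)
}
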