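#' Scores: ordered notated pitches with expressive-notation spans
#'
#' A score is a tibble with one row per notated note: `index` (0-based
#' position), `pitch` (MIDI note number), `notation` (`"legato"`,
#' `"staccato"`, `"forte"`, `"piano"` or `"none"`), `metrical_value`
#' (`"sixteenth"` or `"eighth"`) and `analyzed` (whether the note enters the
#' dependent-variable pools: true iff it carries a notation and sits on the
#' experiment's analysis subdivision). Score-level attributes record the
#' meter, measure count, experiment profile and the nominal tempo options.
#'
#' @name score
NULL

SCORE_NOTATIONS <- c("none", "legato", "staccato", "forte", "piano")

new_score <- function(df, meter = 4L, measures,
                      experiment_profile = c("exp1", "exp2"),
                      nominal_tempo_options_qbpm,
                      subdivisions_per_quarter) {
  experiment_profile <- match.arg(experiment_profile)
  stopifnot(all(df$notation %in% SCORE_NOTATIONS),
            all(df$pitch >= 0L & df$pitch <= 127L),
            identical(df$index, seq_len(nrow(df)) - 1L))
  out <- tibble::as_tibble(df)
  attr(out, "meter") <- as.integer(meter)
  attr(out, "measures") <- as.integer(measures)
  attr(out, "experiment_profile") <- experiment_profile
  attr(out, "nominal_tempo_options_qbpm") <- as.numeric(nominal_tempo_options_qbpm)
  attr(out, "subdivisions_per_quarter") <- as.integer(subdivisions_per_quarter)
  class(out) <- c("midi_score", class(out))
  out
}

#' @export
print.midi_score <- function(x, ...) {
  cat(sprintf("<score> %s | %d measures of %d/4 | %d notes (%d analyzed)\n",
              attr(x, "experiment_profile"), attr(x, "measures"),
              attr(x, "meter"), nrow(x), sum(x$analyzed)))
  NextMethod()
}

#' Nominal inter-onset interval implied by a tempo
#'
#' @param tempo_qbpm tempo in quarter beats per minute.
#' @param subdivisions_per_quarter notes per quarter beat (4 for sixteenths,
#'   2 for eighths).
#' @return Nominal IOI in milliseconds: `60000 / tempo / subdivisions`.
#' @export
nominal_ioi_ms <- function(tempo_qbpm, subdivisions_per_quarter) {
  if (any(tempo_qbpm <= 0)) stop("tempo must be positive", call. = FALSE)
  60000 / tempo_qbpm / subdivisions_per_quarter
}

# C-major (white-key) pitches from C4 upward, used by the fixture stimuli
c_major_from <- function(start = 60L, n = 24L) {
  steps <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  octaves <- rep(seq(0L, 6L), each = 7L)
  pool <- start + rep(steps, 7L) + 12L * octaves
  pool[seq_len(n)]
}

#' Construct a fixture score emulating the two experiments' stimuli
#'
#' Deterministic stand-in stimuli with the structural properties the
#' analysis depends on: monophonic right-hand C-major melodies in 4/4, with
#' expressive notations laid out in contiguous one-measure runs so that both
#' subcomponents occur repeatedly and, for dynamics, both forte-to-piano and
#' piano-to-forte boundaries appear at least twice.
#'
#' * `exp1`: 6 measures of isochronous sixteenth notes (96 notes) at one
#'   nominal tempo (80 qbpm); every note is notated and analyzed.
#' * `exp2`: 12 measures of isochronous eighth notes (96 notes) with three
#'   tempo options (100, 110, 120 qbpm); exactly one eighth note in the 4th
#'   measure carries no expressive notation and is excluded from analysis.
#'
#' The pitch content is an arched scale pattern; no analysis depends on the
#' specific pitches beyond monophony and alignability.
#'
#' @param profile `"exp1"` or `"exp2"`.
#' @param technique `"articulation"` (legato/staccato spans) or
#'   `"dynamics"` (forte/piano spans).
#' @return A score tibble, see [score].
#' @export
make_fixture_score <- function(profile = c("exp1", "exp2"),
                               technique = c("articulation", "dynamics")) {
  profile <- match.arg(profile)
  technique <- match.arg(technique)
  if (profile == "exp1") {
    measures <- 6L; per_measure <- 16L
    metrical <- "sixteenth"; subdiv <- 4L; tempi <- 80
  } else {
    measures <- 12L; per_measure <- 8L
    metrical <- "eighth"; subdiv <- 2L; tempi <- c(100, 110, 120)
  }
  n <- measures * per_measure
  # arched run per measure over a window that walks up then down the scale
  pool <- c_major_from(60L, 22L)
  pitches <- integer(n)
  half <- per_measure %/% 2L
  starts <- c(seq_len(measures %/% 2L),
              rev(seq_len(measures - measures %/% 2L)))
  for (m in seq_len(measures)) {
    up <- pool[starts[m] + seq_len(half) - 1L]
    down <- rev(pool[starts[m] + seq_len(per_measure - half)])
    pitches[(m - 1L) * per_measure + seq_len(per_measure)] <- c(up, down)
  }
  labels <- if (technique == "articulation") c("legato", "staccato")
            else c("forte", "piano")
  notation <- rep(labels[(seq_len(measures) - 1L) %% 2L + 1L],
                  each = per_measure)
  if (profile == "exp2") {
    # the lone unlabelled eighth note sits in the 4th measure
    notation[3L * per_measure + 5L] <- "none"
  }
  df <- tibble::tibble(
    index = seq_len(n) - 1L,
    pitch = pitches,
    notation = notation,
    metrical_value = metrical,
    analyzed = notation != "none")
  new_score(df, meter = 4L, measures = measures, experiment_profile = profile,
            nominal_tempo_options_qbpm = tempi,
            subdivisions_per_quarter = subdiv)
}

#' Read/write a score as CSV
#'
#' Columns, in order: `index`, `pitch`, `notation`, `metrical_value`,
#' `analyzed`, plus header-encoded attributes stored in the first comment
#' line (`# profile,meter,measures,subdivisions,tempi...`).
#'
#' @param score a score tibble.
#' @param path file path.
#' @export
write_score_table <- function(score, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s,%d,%d,%d,%s",
                     attr(score, "experiment_profile"), attr(score, "meter"),
                     attr(score, "measures"),
                     attr(score, "subdivisions_per_quarter"),
                     paste(attr(score, "nominal_tempo_options_qbpm"),
                           collapse = ";")), con)
  utils::write.csv(as.data.frame(score)[, c("index", "pitch", "notation",
                                            "metrical_value", "analyzed")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# ")) stop("missing score header line", call. = FALSE)
  parts <- strsplit(sub("^# ", "", hdr), ",", fixed = TRUE)[[1L]]
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  df$index <- as.integer(df$index)
  df$analyzed <- as.logical(df$analyzed)
  new_score(df, meter = as.integer(parts[2L]),
            measures = as.integer(parts[3L]),
            experiment_profile = parts[1L],
            nominal_tempo_options_qbpm =
              as.numeric(strsplit(parts[5L], ";", fixed = TRUE)[[1L]]),
            subdivisions_per_quarter = as.integer(parts[4L]))
}
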