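#' Expressive features of a cleaned, aligned trial
#'
#' The dependent variables of the analysis, computed per trial from the
#' cleaned note table returned by [clean_performance()]:
#'
#' * **IOI** (inter-onset interval, ms): onset of the next note minus onset
#'   of the current note, for consecutively matched, score-adjacent note
#'   pairs; a tempo measure. Pairs spanning a removed or missing note yield
#'   no IOI.
#' * **KOT** (key-overlap time, ms): offset of the current note minus onset
#'   of the next; positive means overlapping, smooth legato, negative means
#'   separated, sharp staccato.
#' * **KOR** (key-overlap ratio): KOT divided by the trial's mean IOI; a
#'   tempo-normalized articulation measure.
#' * **KV** (key velocity, 0-127): per-note loudness proxy; forte high,
#'   piano low.
#' * **KV difference at transition points**: KV of the following note minus
#'   KV of the current note at score positions where the dynamics notation
#'   switches (forte-to-piano expected negative, piano-to-forte positive).
#'
#' Labels follow the score's notation spans: a note's KV label is its own
#' notation; an interval is labelled with the shared notation of its two
#' notes, or `"transition"` when the notation changes across it. Notes the
#' score marks as not analyzed are excluded from every dependent variable.
#'
#' @name expressive-features
NULL

#' Compute inter-onset intervals for a cleaned trial
#'
#' @param cleaned cleaned note table from [clean_performance()] (columns
#'   `score_index`, `onset_ms`, ...).
#' @return List with `ioi`: tibble `(from_score_index, to_score_index,
#'   ioi_ms)` for consecutively matched score-adjacent pairs, and
#'   `mean_ioi_ms` (`NA` when fewer than 2 matched notes).
#' @export
compute_iois <- function(cleaned) {
  n <- nrow(cleaned)
  if (n < 2L) {
    return(list(ioi = tibble::tibble(from_score_index = integer(),
                                     to_score_index = integer(),
                                     ioi_ms = numeric()),
                mean_ioi_ms = NA_real_))
  }
  adj <- which(diff(cleaned$score_index) == 1L)
  ioi <- cleaned$onset_ms[adj + 1L] - cleaned$onset_ms[adj]
  list(ioi = tibble::tibble(from_score_index = cleaned$score_index[adj],
                            to_score_index = cleaned$score_index[adj] + 1L,
                            ioi_ms = ioi),
       mean_ioi_ms = if (length(ioi) > 0L) mean(ioi) else NA_real_)
}

#' Normalize a trial's mean IOI by its cued tempo
#'
#' `normalized = mean_ioi_ms / (60000 / tempo / subdivisions_per_quarter)`;
#' equals 1 for a performance at exactly the nominal tempo, above 1 for
#' slower playing.
#'
#' @param mean_ioi_ms trial mean IOI in ms.
#' @param cued_tempo_qbpm cued tempo in quarter beats per minute.
#' @param subdivisions_per_quarter analysis subdivisions per quarter beat.
#' @return Dimensionless normalized IOI.
#' @export
normalize_ioi <- function(mean_ioi_ms, cued_tempo_qbpm,
                          subdivisions_per_quarter) {
  mean_ioi_ms / nominal_ioi_ms(cued_tempo_qbpm, subdivisions_per_quarter)
}

#' Compute key-overlap times for a cleaned trial
#'
#' @inheritParams compute_iois
#' @return Tibble `(from_score_index, to_score_index, kot_ms)` over
#'   consecutively matched score-adjacent pairs;
#'   `kot = offset(current) - onset(next)`.
#' @export
compute_kot <- function(cleaned) {
  n <- nrow(cleaned)
  if (n < 2L) {
    return(tibble::tibble(from_score_index = integer(),
                          to_score_index = integer(), kot_ms = numeric()))
  }
  adj <- which(diff(cleaned$score_index) == 1L)
  tibble::tibble(from_score_index = cleaned$score_index[adj],
                 to_score_index = cleaned$score_index[adj] + 1L,
                 kot_ms = cleaned$offset_ms[adj] - cleaned$onset_ms[adj + 1L])
}

#' Key-overlap ratio
#'
#' @param kot_ms key-overlap time(s) in ms.
#' @param mean_ioi_ms the trial's mean IOI (must be positive).
#' @return `kot_ms / mean_ioi_ms`, dimensionless.
#' @export
compute_kor <- function(kot_ms, mean_ioi_ms) {
  if (is.na(mean_ioi_ms) || mean_ioi_ms <= 0) {
    stop("mean IOI must be positive to form key-overlap ratios",
         call. = FALSE)
  }
  kot_ms / mean_ioi_ms
}

interval_labels <- function(score, from_idx) {
  notation <- score$notation
  analyzed <- score$analyzed
  a <- notation[from_idx + 1L]; b <- notation[from_idx + 2L]
  ok <- analyzed[from_idx + 1L] & analyzed[from_idx + 2L]
  label <- ifelse(!ok, NA_character_, ifelse(a == b, a, "transition"))
  ttype <- rep("none", length(a))
  ttype[ok & a == "forte" & b == "piano"] <- "FtoP"
  ttype[ok & a == "piano" & b == "forte"] <- "PtoF"
  list(label = label, transition_type = ttype)
}

#' Label features by notation subcomponent
#'
#' Attaches subcomponent labels to an interval table: the shared notation
#' of the flanking notes, or `"transition"` (with `transition_type` FtoP or
#' PtoF for dynamics scores) when the notation changes across the interval.
#' Intervals touching a note with `analyzed = FALSE` get `NA` and should be
#' dropped from all dependent-variable pools.
#'
#' @param intervals tibble with a `from_score_index` column (0-based),
#'   e.g. from [compute_kot()].
#' @param score the score tibble.
#' @return `intervals` with `subcomponent` and `transition_type` columns.
#' @export
label_subcomponents <- function(intervals, score) {
  lab <- interval_labels(score, intervals$from_score_index)
  intervals$subcomponent <- lab$label
  intervals$transition_type <- lab$transition_type
  intervals
}

#' Key-velocity differences at dynamics transition points
#'
#' At each score boundary where the notation switches between forte and
#' piano, the KV difference is the velocity of the following note minus the
#' velocity of the current note, provided both flanking notes survived
#' cleaning and are score-adjacent.
#'
#' @inheritParams compute_iois
#' @param score the (dynamics-notated) score tibble.
#' @return Tibble `(from_score_index, transition_type, kv_diff)`.
#' @export
kv_transition_diffs <- function(cleaned, score) {
  n <- nrow(cleaned)
  if (n < 2L) {
    return(tibble::tibble(from_score_index = integer(),
                          transition_type = character(),
                          kv_diff = numeric()))
  }
  adj <- which(diff(cleaned$score_index) == 1L)
  from <- cleaned$score_index[adj]
  lab <- interval_labels(score, from)
  keep <- lab$transition_type %in% c("FtoP", "PtoF")
  tibble::tibble(
    from_score_index = from[keep],
    transition_type = lab$transition_type[keep],
    kv_diff = as.numeric(cleaned$velocity[adj + 1L] -
                           cleaned$velocity[adj])[keep])
}

#' All expressive features of one cleaned trial
#'
#' Convenience composition of the per-trial feature extractors; this is the
#' unit the cohort pipeline maps over trials.
#'
#' @inheritParams compute_iois
#' @param score the score tibble.
#' @param cued_tempo_qbpm the trial's cued tempo.
#' @return List with
#'   * `notes`: per-note KV rows `(score_index, velocity, subcomponent)`
#'     for analyzed notes that survived cleaning;
#'   * `intervals`: per-interval rows `(from_score_index, ioi_ms, kot_ms,
#'     kor, subcomponent, transition_type, kv_diff)` for analyzed pairs;
#'   * `mean_ioi_ms`, `normalized_ioi`.
#' @export
trial_features <- function(cleaned, score, cued_tempo_qbpm) {
  analyzed <- score$analyzed[cleaned$score_index + 1L]
  notes <- tibble::tibble(
    score_index = cleaned$score_index[analyzed],
    velocity = as.numeric(cleaned$velocity[analyzed]),
    subcomponent = score$notation[cleaned$score_index[analyzed] + 1L])

  n <- nrow(cleaned)
  subdiv <- attr(score, "subdivisions_per_quarter")
  if (n < 2L) {
    return(list(notes = notes,
                intervals = tibble::tibble(
                  from_score_index = integer(), ioi_ms = numeric(),
                  kot_ms = numeric(), kor = numeric(),
                  subcomponent = character(), transition_type = character(),
                  kv_diff = numeric()),
                mean_ioi_ms = NA_real_, normalized_ioi = NA_real_))
  }
  adj <- which(diff(cleaned$score_index) == 1L)
  from <- cleaned$score_index[adj]
  lab <- interval_labels(score, from)
  ioi <- cleaned$onset_ms[adj + 1L] - cleaned$onset_ms[adj]
  kot <- cleaned$offset_ms[adj] - cleaned$onset_ms[adj + 1L]
  kvd <- as.numeric(cleaned$velocity[adj + 1L] - cleaned$velocity[adj])
  keep <- !is.na(lab$label)
  mean_ioi <- if (any(keep)) mean(ioi[keep]) else NA_real_
  intervals <- tibble::tibble(
    from_score_index = from[keep],
    ioi_ms = ioi[keep],
    kot_ms = kot[keep],
    kor = if (!is.na(mean_ioi) && mean_ioi > 0) kot[keep] / mean_ioi
          else NA_real_,
    subcomponent = lab$label[keep],
    transition_type = lab$transition_type[keep],
    kv_diff = kvd[keep])
  list(notes = notes, intervals = intervals, mean_ioi_ms = mean_ioi,
       normalized_ioi = if (is.na(mean_ioi)) NA_real_ else
         normalize_ioi(mean_ioi, cued_tempo_qbpm, subdiv))
}

#' Summarize a dependent variable across a cohort
#'
#' Aggregation is participant-mean based, matching repeated-measures
#' reporting: within each participant x condition x subcomponent cell the
#' retained values are averaged; cohort-level `M` and `SD` are the mean and
#' standard deviation of those participant means, and `Mdn`/`IQR` are
#' computed across participant means as well.
#'
#' @param values long tibble with columns `participant`, `condition`,
#'   a grouping column named by `by`, and `value`.
#' @param by name of the subcomponent/grouping column (default
#'   `"subcomponent"`); use `NULL` for condition-only grouping.
#' @return List with `participant_means` (one row per participant cell) and
#'   `cohort` (M, SD, Mdn, IQR, n per condition x group). Cells backed by a
#'   single participant get `SD = NA` with a warning.
#' @export
summarize_features <- function(values, by = "subcomponent") {
  stopifnot(all(c("participant", "condition", "value") %in% names(values)))
  keys <- c("participant", "condition", by)
  pm <- stats::aggregate(values["value"], values[keys], mean)
  names(pm)[names(pm) == "value"] <- "mean_value"
  cohort <- do.call(rbind, lapply(
    split(pm, pm[c("condition", by)], drop = TRUE), function(g) {
      data.frame(condition = g$condition[1L],
                 group = if (is.null(by)) NA_character_ else g[[by]][1L],
                 M = mean(g$mean_value), SD = stats::sd(g$mean_value),
                 Mdn = stats::median(g$mean_value),
                 IQR = stats::IQR(g$mean_value), n = nrow(g))
    }))
  rownames(cohort) <- NULL
  if (any(cohort$n < 2L)) {
    warning("some cells contain a single participant; SD undefined")
  }
  list(participant_means = tibble::as_tibble(pm),
       cohort = tibble::as_tibble(cohort))
}
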