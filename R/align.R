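#' Align a performance to its score and classify pitch errors
#'
#' Pitch errors are identified by comparing the performed pitch sequence
#' with the notated one under a global unit-cost edit-distance alignment
#' (timing is ignored). The three error categories map onto the three edit
#' operations: an *extra* tone is an insertion (only a performance index),
#' a *missing* tone a deletion (only a score index), and a *substituted*
#' tone a mismatching aligned pair (both indices). Among minimal alignments,
#' ties are broken deterministically: match over substitution over missing
#' over extra, resolved left-to-right — so of two identical consecutive
#' performed tones aligned against one notated tone, the second is the
#' extra.
#'
#' @param perf a [performance()] object (notes ordered by onset).
#' @param score a score tibble (monophonic), see [make_fixture_score()].
#' @return An object of class `alignment_result`: a list with
#'   * `pairs`: tibble of matched `(score_index, perf_index)` (0-based,
#'     strictly increasing in both),
#'   * `errors`: tibble `(category, score_index, perf_index)`,
#'   * `edit_distance`: `|extra| + |missing| + |substituted|`,
#'   * `offset_anomalies`: filled by [detect_offset_anomalies()].
#' @export
align <- function(perf, score) {
  stopifnot(inherits(perf, "performance"))
  if (nrow(score) == 0L) stop("empty score", call. = FALSE)
  res <- align_cpp(as.integer(score$pitch), as.integer(perf$notes$pitch))
  op <- res$op
  pairs <- tibble::tibble(score_index = res$score_index[op == 0L],
                          perf_index = res$perf_index[op == 0L])
  cat_map <- c("substituted", "missing", "extra")
  err <- op != 0L
  errors <- tibble::tibble(
    category = cat_map[op[err]],
    score_index = ifelse(res$score_index[err] >= 0L,
                         res$score_index[err], NA_integer_),
    perf_index = ifelse(res$perf_index[err] >= 0L,
                        res$perf_index[err], NA_integer_))
  structure(list(pairs = pairs, errors = errors,
                 edit_distance = res$edit_distance,
                 offset_anomalies = integer(0)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment> %d matched, edit distance %d (extra %d, missing %d, substituted %d), %d offset anomalies\n",
    nrow(x$pairs), x$edit_distance,
    sum(x$errors$category == "extra"), sum(x$errors$category == "missing"),
    sum(x$errors$category == "substituted"), length(x$offset_anomalies)))
  invisible(x)
}

#' Detect notes whose key-release order contradicts the key-press order
#'
#' Some performers hold a note longer than notated, so the order of offsets
#' no longer corresponds to that of onsets even when the onset order is
#' correct. Among the matched notes (ordered by onset), every note whose
#' offset rank differs from its onset rank is flagged as erroneous and
#' removed by [clean_performance()]. Ordinary legato overlap (an offset
#' slightly past the next onset but before the next offset) preserves the
#' ranks and is not flagged.
#'
#' @param perf a [performance()] object.
#' @param alignment result of [align()] for `perf`.
#' @return Integer vector of flagged performance indices (0-based).
#' @export
detect_offset_anomalies <- function(perf, alignment) {
  idx <- alignment$pairs$perf_index
  if (length(idx) < 2L) return(integer(0))
  offsets <- perf$notes$offset_ms[idx + 1L]
  bad <- rank(offsets, ties.method = "first") != seq_along(offsets)
  idx[bad]
}

#' Clean a performance against its score
#'
#' Composes [align()] and [detect_offset_anomalies()]: removes extra and
#' substituted performed notes and offset-anomalous notes; missing score
#' notes simply leave gaps (no imputation). A trial is additionally flagged
#' invalid — the performer did not follow the score or stopped early — when
#' the edit distance exceeds a quarter of the score length or fewer than
#' three quarters of the score notes are matched.
#'
#' @param perf a [performance()] object.
#' @param score a score tibble.
#' @param max_edit_frac,min_match_frac validity thresholds.
#' @return A list:
#'   * `cleaned`: tibble of retained notes with their `score_index`
#'     (0-based), `pitch`, `onset_ms`, `offset_ms`, `velocity`;
#'   * `alignment`: the [align()] result with `offset_anomalies` filled;
#'   * `valid`: logical trial flag; `reason`: why a trial was invalidated;
#'   * `n_removed`: notes removed (extra + substituted + offset anomalies).
#' @export
clean_performance <- function(perf, score, max_edit_frac = 0.25,
                              min_match_frac = 0.75) {
  al <- align(perf, score)
  al$offset_anomalies <- detect_offset_anomalies(perf, al)
  drop_perf <- sort(unique(c(
    al$errors$perf_index[!is.na(al$errors$perf_index)],
    al$offset_anomalies)))
  keep <- al$pairs$perf_index[!(al$pairs$perf_index %in% drop_perf)]
  score_idx <- al$pairs$score_index[!(al$pairs$perf_index %in% drop_perf)]
  cleaned <- tibble::tibble(
    score_index = score_idx,
    pitch = perf$notes$pitch[keep + 1L],
    onset_ms = perf$notes$onset_ms[keep + 1L],
    offset_ms = perf$notes$offset_ms[keep + 1L],
    velocity = perf$notes$velocity[keep + 1L])
  valid <- TRUE; reason <- NA_character_
  if (al$edit_distance > ceiling(max_edit_frac * nrow(score))) {
    valid <- FALSE; reason <- "edit distance above threshold"
  } else if (nrow(al$pairs) < min_match_frac * nrow(score)) {
    valid <- FALSE; reason <- "matched fraction below threshold"
  }
  list(cleaned = cleaned, alignment = al, valid = valid, reason = reason,
       n_removed = nrow(perf$notes) - nrow(cleaned))
}

#' Per-category pitch-error rates over a cohort of alignments
#'
#' @param alignments list of `alignment_result` objects (one per trial).
#' @return Tibble with the percentage of trials containing at least one
#'   error of each category (a trial counts once per category regardless of
#'   how many errors of that category it contains) plus the overall rate.
#' @export
error_rates <- function(alignments) {
  if (length(alignments) == 0L) stop("empty cohort", call. = FALSE)
  per_trial <- vapply(alignments, function(a) {
    c(extra = any(a$errors$category == "extra"),
      missing = any(a$errors$category == "missing"),
      substituted = any(a$errors$category == "substituted"))
  }, logical(3L))
  rates <- rowMeans(per_trial) * 100
  tibble::tibble(
    category = c("any", names(rates)),
    pct_trials = c(mean(colSums(per_trial) > 0) * 100, unname(rates)))
}
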