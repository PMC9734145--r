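#' Tempo-based participant exclusion
#'
#' Participants whose tempo (proxied by their grand-mean IOI across all
#' retained trials) lies outside `tempo_sd` standard deviations from the
#' average across participants are excluded. The SD uses the n-1
#' denominator, and participants exactly on the boundary are retained.
#' With fewer than 3 participants the rule is skipped with a warning.
#'
#' @param participant_mean_ioi named numeric vector (or tibble with columns
#'   `participant`, `mean_ioi`) of per-participant grand-mean IOIs in ms.
#' @param tempo_sd SD multiple defining the exclusion band (default 2).
#' @return List with `retained` and `excluded` participant ids, plus a
#'   per-participant report tibble (`mean_ioi`, `z`, `excluded`, `reason`).
#' @export
exclude_by_tempo <- function(participant_mean_ioi, tempo_sd = 2) {
  if (is.data.frame(participant_mean_ioi)) {
    x <- participant_mean_ioi$mean_ioi
    names(x) <- participant_mean_ioi$participant
    participant_mean_ioi <- x
  }
  ids <- names(participant_mean_ioi)
  if (is.null(ids)) ids <- as.character(seq_along(participant_mean_ioi))
  if (length(participant_mean_ioi) < 3L) {
    warning("fewer than 3 participants; tempo exclusion skipped")
    return(list(retained = ids, excluded = character(0),
                report = tibble::tibble(participant = ids,
                                        mean_ioi = unname(participant_mean_ioi),
                                        z = NA_real_, excluded = FALSE,
                                        reason = NA_character_)))
  }
  m <- mean(participant_mean_ioi)
  s <- stats::sd(participant_mean_ioi)
  z <- if (s > 0) (participant_mean_ioi - m) / s else
    rep(0, length(participant_mean_ioi))
  out <- abs(z) > tempo_sd          # boundary (== tempo_sd) retained
  list(retained = ids[!out], excluded = ids[out],
       report = tibble::tibble(
         participant = ids, mean_ioi = unname(participant_mean_ioi),
         z = unname(z), excluded = unname(out),
         reason = ifelse(out, sprintf("mean IOI outside %g SD of cohort mean",
                                      tempo_sd), NA_character_)))
}

#' Single-pass 3-SD outlier removal
#'
#' Values more than `sd_limit` standard deviations from the mean of the
#' supplied vector are removed. The mean and SD are computed once over the
#' full vector (single pass, non-iterative); re-running on the output could
#' remove more values, so the pipeline applies the rule exactly once per
#' dependent variable. Groups of fewer than 2 values, or with zero SD, are
#' returned unchanged.
#'
#' @param x numeric vector of one dependent variable's values.
#' @param sd_limit SD multiple (default 3).
#' @return List: `keep` (logical mask), `n_removed`, `fraction_removed`.
#' @export
remove_outliers <- function(x, sd_limit = 3) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    return(list(keep = ok, n_removed = 0L, fraction_removed = 0))
  }
  m <- mean(x[ok]); s <- stats::sd(x[ok])
  keep <- ok & (s == 0 | abs(x - m) <= sd_limit * s)
  keep[is.na(keep)] <- FALSE
  list(keep = keep, n_removed = sum(ok) - sum(keep),
       fraction_removed = (sum(ok) - sum(keep)) / sum(ok))
}

#' Apply outlier screening to a long feature table
#'
#' The scope over which the mean and SD of each dependent variable are
#' taken is configurable: `"variable"` (default) pools all values of a
#' variable within an experiment x technique, across participants and
#' conditions; `"participant"` screens within each participant separately.
#'
#' @param values numeric vector of one dependent variable.
#' @param participant participant id vector (used for `"participant"`
#'   scope).
#' @param scope `"variable"` or `"participant"`.
#' @param sd_limit SD multiple (default 3).
#' @return As [remove_outliers()], aggregated over scope groups.
#' @export
screen_variable <- function(values, participant = NULL,
                            scope = c("variable", "participant"),
                            sd_limit = 3) {
  scope <- match.arg(scope)
  if (scope == "variable" || is.null(participant)) {
    return(remove_outliers(values, sd_limit))
  }
  keep <- logical(length(values))
  for (p in unique(participant)) {
    i <- participant == p
    keep[i] <- remove_outliers(values[i], sd_limit)$keep
  }
  n_ok <- sum(!is.na(values))
  list(keep = keep, n_removed = n_ok - sum(keep),
       fraction_removed = (n_ok - sum(keep)) / n_ok)
}
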