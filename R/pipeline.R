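# End-to-end orchestration: clean -> features -> screening -> inference,
# in that fixed order, with an audit log of every exclusion.

# Per-trial processing over a whole cohort. Works on the raw trial records
# (plain vectors) for speed; the user-facing single-trial API wraps the
# same primitives.
extract_cohort_features <- function(cohort) {
  scores <- cohort$scores
  pre <- lapply(scores, function(sc) {
    nn <- nrow(sc)
    lab <- interval_labels(sc, seq_len(nn - 1L) - 1L)
    list(pitch = as.integer(sc$pitch), analyzed = sc$analyzed,
         notation = sc$notation, ilabel = lab$label,
         itype = lab$transition_type,
         subdiv = attr(sc, "subdivisions_per_quarter"), n = nn)
  })
  nt <- length(cohort$trials)
  stopifnot(nt == nrow(cohort$manifest),
            identical(vapply(cohort$trials, `[[`, "", "participant"),
                      as.character(cohort$manifest$participant)))
  trial_rows <- vector("list", nt)
  acc <- list()   # per-trial feature fragments
  for (i in seq_len(nt)) {
    tr <- cohort$trials[[i]]
    sc <- pre[[tr$technique]]
    al <- align_cpp(sc$pitch, as.integer(tr$pitch))
    op <- al$op
    m <- op == 0L
    mperf <- al$perf_index[m] + 1L   # 1-based rows into trial vectors
    mscore <- al$score_index[m] + 1L
    # offset-order anomalies among matched notes
    anom <- integer(0)
    if (length(mperf) >= 2L) {
      offs <- tr$offset_ms[mperf]
      bad <- rank(offs, ties.method = "first") != seq_along(offs)
      anom <- mperf[bad]
      mscore <- mscore[!bad]; mperf <- mperf[!bad]
    }
    ed <- al$edit_distance
    n_extra <- sum(op == 3L); n_missing <- sum(op == 2L)
    n_sub <- sum(op == 1L)
    valid <- ed <= ceiling(0.25 * sc$n) &&
      sum(m) >= 0.75 * sc$n
    trial_rows[[i]] <- c(ed, n_extra, n_missing, n_sub, length(anom),
                         valid)
    if (!valid) next
    nominal <- nominal_ioi_ms(tr$cued_tempo_qbpm, sc$subdiv)
    # per-note KV rows (analyzed notes only)
    keep_n <- sc$analyzed[mscore]
    # per-interval rows (consecutive matched, score-adjacent)
    adj <- which(diff(mscore) == 1L)
    from <- mscore[adj]                       # 1-based score row
    ilab <- sc$ilabel[from]
    ok <- !is.na(ilab)
    adj <- adj[ok]; from <- from[ok]; ilab <- ilab[ok]
    ioi <- tr$onset_ms[mperf[adj + 1L]] - tr$onset_ms[mperf[adj]]
    kot <- tr$offset_ms[mperf[adj]] - tr$onset_ms[mperf[adj + 1L]]
    mean_ioi <- if (length(ioi) > 0L) mean(ioi) else NA_real_
    acc[[length(acc) + 1L]] <- list(
      i = i,
      n_note = sum(keep_n), n_int = length(adj),
      note_vel = as.numeric(tr$velocity[mperf[keep_n]]),
      note_sub = sc$notation[mscore[keep_n]],
      int_from = from - 1L,
      int_ioi = ioi,
      int_kot = kot,
      int_kor = if (!is.na(mean_ioi) && mean_ioi > 0) kot / mean_ioi
                else rep(NA_real_, length(kot)),
      int_sub = ilab,
      int_type = sc$itype[from],
      int_kvd = as.numeric(tr$velocity[mperf[adj + 1L]] -
                             tr$velocity[mperf[adj]]),
      mean_ioi = mean_ioi,
      norm_ioi = mean_ioi / nominal,
      nominal = nominal)
  }
  man <- cohort$manifest
  tm <- do.call(rbind, trial_rows)
  trial_table <- tibble::tibble(
    participant = man$participant, condition = man$condition,
    technique = man$technique, trial = man$trial,
    tempo_qbpm = man$tempo_qbpm,
    edit_distance = as.integer(tm[, 1L]), n_extra = as.integer(tm[, 2L]),
    n_missing = as.integer(tm[, 3L]), n_substituted = as.integer(tm[, 4L]),
    n_offset_anomalies = as.integer(tm[, 5L]), valid = as.logical(tm[, 6L]))

  tid <- vapply(acc, `[[`, 0L, "i")
  rep_by <- function(field, nfield) {
    unlist(lapply(acc, `[[`, field), use.names = FALSE)
  }
  counts_n <- vapply(acc, `[[`, 0L, "n_note")
  counts_i <- vapply(acc, `[[`, 0L, "n_int")
  note_idx <- rep(tid, counts_n)
  int_idx <- rep(tid, counts_i)
  notes <- tibble::tibble(
    participant = man$participant[note_idx],
    condition = man$condition[note_idx],
    technique = man$technique[note_idx],
    trial = man$trial[note_idx],
    velocity = rep_by("note_vel"),
    subcomponent = rep_by("note_sub"))
  intervals <- tibble::tibble(
    participant = man$participant[int_idx],
    condition = man$condition[int_idx],
    technique = man$technique[int_idx],
    trial = man$trial[int_idx],
    from_score_index = rep_by("int_from"),
    ioi_ms = rep_by("int_ioi"),
    ioi_norm = rep_by("int_ioi") / rep(vapply(acc, `[[`, 0, "nominal"),
                                       counts_i),
    kot_ms = rep_by("int_kot"),
    kor = rep_by("int_kor"),
    subcomponent = rep_by("int_sub"),
    transition_type = rep_by("int_type"),
    kv_diff = rep_by("int_kvd"))
  trials_valid <- tibble::tibble(
    participant = man$participant[tid], condition = man$condition[tid],
    technique = man$technique[tid], trial = man$trial[tid],
    mean_ioi_ms = vapply(acc, `[[`, 0, "mean_ioi"),
    normalized_ioi = vapply(acc, `[[`, 0, "norm_ioi"))
  list(trial_table = trial_table, notes = notes, intervals = intervals,
       trial_means = trials_valid)
}

#' Run the full analysis pipeline
#'
#' Fixed order: score alignment and cleaning of every trial, feature
#' extraction (valid trials only), tempo-based participant exclusion,
#' single-pass 3-SD outlier removal per dependent variable, then the
#' inferential battery per technique: a Shapiro-Wilk-gated paired
#' comparison of mean IOIs, a Condition x Subcomponent repeated-measures
#' ANOVA with Tukey-adjusted post-hoc contrasts for the articulation
#' (key-overlap) and loudness (key-velocity) measures, and — for the
#' dynamics technique — a Condition x Transition-Type ANOVA on the
#' key-velocity differences at forte/piano boundaries. Time variables are
#' analysed in ms under the `exp1` profile and tempo-normalized (IOI ratio,
#' key-overlap ratio) under `exp2`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] or
#'   [read_cohort()]; alternatively pass `config` to simulate one.
#' @param config a `generator_config` used when `cohort` is missing.
#' @param outlier_scope `"variable"` (pooled; default) or `"participant"`.
#' @param outlier_sd,tempo_sd SD multiples for the two screening rules.
#' @param alpha significance level used in the report (default 0.05).
#' @return A `pipeline_report`: list with `trial_table`, `error_rates`,
#'   `screening` (tempo exclusions + per-variable outlier fractions),
#'   `summaries`, `stats` (per technique: `ioi_test`, `kot_anova`,
#'   `kv_anova`, `transition_anova` and matching `*_posthoc`), and `log`.
#' @export
run_pipeline <- function(cohort = NULL, config = NULL,
                         outlier_scope = c("variable", "participant"),
                         outlier_sd = 3, tempo_sd = 2, alpha = 0.05) {
  outlier_scope <- match.arg(outlier_scope)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  if (is.null(cohort)) {
    if (is.null(config)) stop("supply a cohort or a generator config",
                              call. = FALSE)
    cohort <- generate_cohort(config)
    say("simulated cohort: %d trials, seed %d", length(cohort$trials),
        config$seed)
  }
  profile <- attr(cohort$scores[[1L]], "experiment_profile")
  feats <- extract_cohort_features(cohort)
  tt <- feats$trial_table
  say("cleaned %d trials; %d invalid (excluded): %s", nrow(tt),
      sum(!tt$valid), paste(which(!tt$valid), collapse = " "))

  # cohort error rates, all trials
  er <- tibble::tibble(
    category = c("any", "extra", "missing", "substituted"),
    pct_trials = c(mean(tt$edit_distance > 0),
                   mean(tt$n_extra > 0), mean(tt$n_missing > 0),
                   mean(tt$n_substituted > 0)) * 100)

  # tempo-based participant exclusion on grand-mean IOI
  tmeans <- feats$trial_means
  pm <- tapply(tmeans$mean_ioi_ms, tmeans$participant, mean)
  tex <- exclude_by_tempo(pm, tempo_sd = tempo_sd)
  if (length(tex$excluded) > 0L) {
    say("tempo exclusion: removed participants %s",
        paste(tex$excluded, collapse = ", "))
  }
  keep_p <- function(df) df[df$participant %in% tex$retained, ,
                            drop = FALSE]
  notes <- keep_p(feats$notes)
  intervals <- keep_p(feats$intervals)
  tmeans <- keep_p(tmeans)

  # outlier removal, per technique x dependent variable
  time_var <- if (profile == "exp1") "ioi_ms" else "ioi_norm"
  kot_var <- if (profile == "exp1") "kot_ms" else "kor"
  intervals[[paste0("keep_", time_var)]] <- FALSE
  intervals[[paste0("keep_", kot_var)]] <- FALSE
  intervals$keep_kv_diff <- FALSE
  notes$keep_velocity <- FALSE
  out_frac <- list()
  for (tq in unique(intervals$technique)) {
    ii <- intervals$technique == tq
    for (v in c(time_var, kot_var)) {
      scr <- screen_variable(intervals[[v]][ii],
                             intervals$participant[ii],
                             scope = outlier_scope, sd_limit = outlier_sd)
      intervals[[paste0("keep_", v)]][ii] <- scr$keep
      out_frac[[paste(tq, v, sep = ".")]] <- scr$fraction_removed
    }
    ni <- notes$technique == tq
    scr <- screen_variable(notes$velocity[ni], notes$participant[ni],
                           scope = outlier_scope, sd_limit = outlier_sd)
    notes$keep_velocity[ni] <- scr$keep
    out_frac[[paste(tq, "velocity", sep = ".")]] <- scr$fraction_removed
    if (tq == "dynamics") {
      it <- ii & intervals$transition_type %in% c("FtoP", "PtoF")
      scr <- screen_variable(intervals$kv_diff[it],
                             intervals$participant[it],
                             scope = outlier_scope, sd_limit = outlier_sd)
      intervals$keep_kv_diff[it] <- scr$keep
      out_frac[["dynamics.kv_diff"]] <- scr$fraction_removed
    }
  }
  for (nm in names(out_frac)) {
    say("outlier removal %s: %.2f%% removed", nm, 100 * out_frac[[nm]])
  }
  screening <- list(tempo = tex,
                    outlier_fraction = unlist(out_frac),
                    outlier_scope = outlier_scope,
                    outlier_sd = outlier_sd, tempo_sd = tempo_sd)

  stats_out <- list()
  summaries <- list()
  for (tq in unique(intervals$technique)) {
    res <- analyze_technique(
      intervals = intervals[intervals$technique == tq, , drop = FALSE],
      notes = notes[notes$technique == tq, , drop = FALSE],
      technique = tq, profile = profile, alpha = alpha)
    stats_out[[tq]] <- res$stats
    summaries[[tq]] <- res$summaries
    log <- c(log, res$log)
  }
  structure(list(trial_table = tt, error_rates = er,
                 screening = screening, summaries = summaries,
                 stats = stats_out, profile = profile, alpha = alpha,
                 log = log),
            class = "pipeline_report")
}

# participant x condition cell means of a screened variable
cell_means <- function(df, var, keep_col, by = "subcomponent") {
  keep <- df[[keep_col]]
  d <- df[keep & !is.na(df[[var]]), c("participant", "condition", by, var)]
  names(d)[4L] <- "value"
  stats::aggregate(d["value"], d[c("participant", "condition", by)], mean)
}

# wide n x 4 matrix ordered teaching.B1, teaching.B2, performing.B1,
# performing.B2; participants with incomplete cells dropped listwise
cells_matrix <- function(pm, levels_b, by = "subcomponent") {
  pm <- pm[pm[[by]] %in% levels_b, , drop = FALSE]
  key <- paste(pm$condition, pm[[by]], sep = ".")
  wanted <- c(paste("teaching", levels_b, sep = "."),
              paste("performing", levels_b, sep = "."))
  parts <- sort(unique(pm$participant))
  M <- matrix(NA_real_, length(parts), 4L,
              dimnames = list(parts, wanted))
  idx <- cbind(match(pm$participant, parts), match(key, wanted))
  ok <- !is.na(idx[, 2L])
  M[idx[ok, , drop = FALSE]] <- pm$value[ok]
  M[stats::complete.cases(M), , drop = FALSE]
}

#' Run the inferential battery for one technique
#'
#' @param intervals,notes screened long feature tables for one technique
#'   (with `keep_*` mask columns), as built by [run_pipeline()].
#' @param technique `"articulation"` or `"dynamics"`.
#' @param profile `"exp1"` (time variables in ms) or `"exp2"`
#'   (tempo-normalized).
#' @param alpha significance level recorded in the report.
#' @return List with `stats` (test/ANOVA/post-hoc objects), `summaries`
#'   (per-variable condition x subcomponent descriptives) and `log`.
#' @export
analyze_technique <- function(intervals, notes, technique, profile,
                              alpha = 0.05) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  time_var <- if (profile == "exp1") "ioi_ms" else "ioi_norm"
  kot_var <- if (profile == "exp1") "kot_ms" else "kor"
  subs <- if (technique == "articulation") c("legato", "staccato")
          else c("forte", "piano")
  stats_out <- list()
  summaries <- list()

  # IOI paired comparison (participant means across retained intervals)
  ip <- intervals[intervals[[paste0("keep_", time_var)]], ]
  pm <- stats::aggregate(ip[time_var],
                         ip[c("participant", "condition")], mean)
  names(pm)[3L] <- "value"
  wide <- cells_pair(pm)
  if (nrow(wide) >= 5L) {
    stats_out$ioi_test <- paired_comparison(
      wide$teaching, wide$performing,
      labels = c("teaching", "performing"))
    say("%s IOI: %s, p = %.4g", technique, stats_out$ioi_test$method,
        stats_out$ioi_test$p_value)
  } else {
    say("%s IOI comparison skipped: fewer than 5 complete pairs", technique)
  }
  summaries$ioi <- summarize_condition(pm)

  # key-overlap ANOVA
  kp <- cell_means(intervals, kot_var, paste0("keep_", kot_var))
  kotM <- cells_matrix(kp, subs)
  if (nrow(kotM) >= 3L) {
    fit <- rm_anova_2x2(kotM,
                        factor_names = c("Condition", cap(technique)),
                        level_names = list(c("teaching", "performing"),
                                           subs))
    stats_out$kot_anova <- fit
    stats_out$kot_posthoc <- posthoc_emm_tukey(fit)
    say("%s %s ANOVA: interaction F = %.3f, p = %.4g", technique,
        toupper(kot_var), fit$effects$F[3L], fit$effects$p[3L])
  } else say("%s key-overlap ANOVA skipped: insufficient data", technique)
  summaries$kot <- summarize_cells(kp)

  # key-velocity ANOVA
  vp <- cell_means(notes, "velocity", "keep_velocity")
  kvM <- cells_matrix(vp, subs)
  if (nrow(kvM) >= 3L) {
    fit <- rm_anova_2x2(kvM,
                        factor_names = c("Condition", cap(technique)),
                        level_names = list(c("teaching", "performing"),
                                           subs))
    stats_out$kv_anova <- fit
    stats_out$kv_posthoc <- posthoc_emm_tukey(fit)
    say("%s KV ANOVA: interaction F = %.3f, p = %.4g", technique,
        fit$effects$F[3L], fit$effects$p[3L])
  } else say("%s KV ANOVA skipped: insufficient data", technique)
  summaries$kv <- summarize_cells(vp)

  # KV difference at dynamics transition points
  if (technique == "dynamics" && "keep_kv_diff" %in% names(intervals)) {
    tp <- cell_means(intervals[intervals$transition_type %in%
                                 c("FtoP", "PtoF"), ],
                     "kv_diff", "keep_kv_diff", by = "transition_type")
    trM <- cells_matrix(tp, c("FtoP", "PtoF"), by = "transition_type")
    if (nrow(trM) >= 3L) {
      fit <- rm_anova_2x2(trM,
                          factor_names = c("Condition", "TransitionType"),
                          level_names = list(c("teaching", "performing"),
                                             c("FtoP", "PtoF")))
      stats_out$transition_anova <- fit
      stats_out$transition_posthoc <- posthoc_emm_tukey(fit)
      say("dynamics transition ANOVA: interaction F = %.3f, p = %.4g",
          fit$effects$F[3L], fit$effects$p[3L])
    } else say("transition ANOVA skipped: insufficient data")
    summaries$transition <- summarize_cells(tp, by = "transition_type")
  }
  list(stats = stats_out, summaries = summaries, log = log)
}

cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

# participant x condition -> wide 2-column table of paired values
cells_pair <- function(pm) {
  w <- stats::reshape(pm, idvar = "participant", timevar = "condition",
                      direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  w[stats::complete.cases(w), , drop = FALSE]
}

summarize_condition <- function(pm) {
  do.call(rbind, lapply(split(pm, pm$condition), function(g) {
    tibble::tibble(condition = g$condition[1L], M = mean(g$value),
                   SD = stats::sd(g$value), Mdn = stats::median(g$value),
                   IQR = stats::IQR(g$value), n = nrow(g))
  }))
}

summarize_cells <- function(pm, by = "subcomponent") {
  groups <- split(pm, pm[c("condition", by)], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    tibble::tibble(condition = g$condition[1L], group = g[[by]][1L],
                   M = mean(g$value), SD = stats::sd(g$value),
                   Mdn = stats::median(g$value), IQR = stats::IQR(g$value),
                   n = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline report> profile %s | %d trials (%d valid)\n",
              x$profile, nrow(x$trial_table), sum(x$trial_table$valid)))
  cat("pitch-error rates (% of trials):\n")
  print(x$error_rates)
  for (tq in names(x$stats)) {
    cat("\n==", tq, "==\n")
    st <- x$stats[[tq]]
    if (!is.null(st$ioi_test)) { cat("IOI: "); print(st$ioi_test) }
    for (nm in c("kot_anova", "kv_anova", "transition_anova")) {
      if (!is.null(st[[nm]])) { cat(nm, ":\n"); print(st[[nm]]) }
    }
  }
  invisible(x)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' When the full-precision note table (`cohort_notes.csv`) is present it is
#' preferred over the SMF files, whose times are quantized to ticks; the
#' pipeline then reproduces the in-memory statistics exactly.
#'
#' @param dir directory containing `manifest.csv`, per-trial SMF files
#'   and/or `cohort_notes.csv`, and the per-technique score tables.
#' @return A `synthetic_cohort`-shaped list suitable for [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  techniques <- unique(man$technique)
  scores <- lapply(stats::setNames(techniques, techniques), function(tq) {
    read_score_table(file.path(dir, sprintf("score_%s.csv", tq)))
  })
  notes_path <- file.path(dir, "cohort_notes.csv")
  if (file.exists(notes_path)) {
    nt <- utils::read.csv(notes_path, stringsAsFactors = FALSE)
    key <- paste(nt$participant, nt$condition, nt$technique, nt$trial)
    groups <- split(nt, factor(key, levels = unique(key)))
    trials <- lapply(groups, function(g) {
      list(participant = g$participant[1L], condition = g$condition[1L],
           technique = g$technique[1L], trial_index = g$trial[1L],
           cued_tempo_qbpm = g$tempo_qbpm[1L], pitch = g$pitch,
           onset_ms = g$onset_ms, offset_ms = g$offset_ms,
           velocity = g$velocity)
    })
    names(trials) <- NULL
  } else {
    trials <- lapply(seq_len(nrow(man)), function(i) {
      p <- read_performance(file.path(dir, man$file[i]),
                            participant_id = man$participant[i],
                            condition = man$condition[i],
                            technique = man$technique[i],
                            trial_index = man$trial[i],
                            cued_tempo_qbpm = man$tempo_qbpm[i])
      list(participant = p$participant_id, condition = p$condition,
           technique = p$technique, trial_index = p$trial_index,
           cued_tempo_qbpm = p$cued_tempo_qbpm, pitch = p$notes$pitch,
           onset_ms = p$notes$onset_ms, offset_ms = p$notes$offset_ms,
           velocity = p$notes$velocity)
    })
  }
  structure(list(trials = trials,
                 manifest = tibble::as_tibble(
                   man[, c("participant", "condition", "technique", "trial",
                           "tempo_qbpm")]),
                 scores = scores, ground_truth = NULL, config = NULL),
            class = "synthetic_cohort")
}

#' Write a pipeline report bundle to disk
#'
#' Emits the tabular outputs as CSV (trial table, error rates, summaries,
#' test and ANOVA tables), the screening report as JSON and the run log as
#' plain text.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$trial_table, file.path(dir, "trial_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$error_rates, file.path(dir, "error_rates.csv"),
                   row.names = FALSE)
  rows <- list()
  for (tq in names(report$stats)) {
    st <- report$stats[[tq]]
    if (!is.null(st$ioi_test)) {
      x <- st$ioi_test
      rows[[length(rows) + 1L]] <- data.frame(
        technique = tq, analysis = "ioi", effect = x$method,
        statistic = x$statistic, df = ifelse(is.null(x$df), NA, x$df),
        p = x$p_value, effect_size = x$effect_size,
        effect_size_type = x$effect_size_type)
    }
    for (nm in c("kot_anova", "kv_anova", "transition_anova")) {
      if (is.null(st[[nm]])) next
      e <- st[[nm]]$effects
      rows[[length(rows) + 1L]] <- data.frame(
        technique = tq, analysis = nm, effect = e$effect, statistic = e$F,
        df = e$df_den, p = e$p, effect_size = e$ges,
        effect_size_type = "ges")
    }
    for (nm in c("kot_posthoc", "kv_posthoc", "transition_posthoc")) {
      if (is.null(st[[nm]])) next
      ph <- st[[nm]]
      utils::write.csv(ph, file.path(dir, sprintf("%s_%s.csv", tq, nm)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "stats_tables.csv"),
                   row.names = FALSE)
  for (tq in names(report$summaries)) {
    for (nm in names(report$summaries[[tq]])) {
      utils::write.csv(report$summaries[[tq]][[nm]],
                       file.path(dir, sprintf("summary_%s_%s.csv", tq, nm)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(tempo_excluded = report$screening$tempo$excluded,
         outlier_fraction = as.list(report$screening$outlier_fraction),
         outlier_scope = report$screening$outlier_scope,
         outlier_sd = report$screening$outlier_sd,
         tempo_sd = report$screening$tempo_sd),
    file.path(dir, "screening.json"), auto_unbox = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
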